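#' Annual exposure level from JEM-coded jobs
#'
#' For each job held in a calendar year, a job-exposure matrix (JEM) assigns
#' a probability of exposure, a frequency of exposure (proportion of an 8 h
#' working day) and an intensity (equivalent f/mL). The per-job annual level
#' is the product intensity x probability x frequency; when several jobs are
#' held in the same year the annual level is the arithmetic mean of the
#' per-job levels.
#'
#' @param jobs_in_year data.frame with columns `probability`, `frequency`,
#'   `intensity` — one row per job held in `year` (rows whose JEM period
#'   does not contain `year` are rejected when period columns are present).
#' @param year calendar year the jobs were held in (used only to validate
#'   `period_start`/`period_end` when those columns are present).
#' @return annual exposure level in equivalent f/mL.
#' @examples
#' jobs <- data.frame(probability = c(1, 1), frequency = c(1, 1),
#'                    intensity = c(0.1, 1))
#' annual_level_from_jobs(jobs)  # (0.1 + 1)/2 = 0.55
#' @export
annual_level_from_jobs <- function(jobs_in_year, year = NULL) {
  if (is.null(jobs_in_year) || nrow(jobs_in_year) == 0)
    stop("no job held in this year")
  req <- c("probability", "frequency", "intensity")
  if (!all(req %in% names(jobs_in_year)))
    stop("jobs_in_year needs columns probability, frequency, intensity")
  if (!is.null(year) && all(c("period_start", "period_end") %in% names(jobs_in_year))) {
    ok <- jobs_in_year$period_start <= year & year <= jobs_in_year$period_end
    if (!all(ok)) stop("year outside the JEM period of some job")
  }
  mean(jobs_in_year$intensity * jobs_in_year$probability * jobs_in_year$frequency)
}

.jem_level_for <- function(jem, job_code, year) {
  hit <- jem$job_code == job_code & jem$period_start <= year & jem$period_end >= year
  if (!any(hit)) stop(sprintf("no JEM entry for job '%s' in year %d", job_code, year))
  row <- jem[which(hit)[1], ]
  row$intensity * row$probability * row$frequency
}

#' Build an annual exposure-intensity series from exposure episodes
#'
#' Converts raw exposure episodes (start/end calendar year plus either a
#' directly reported intensity, e.g. cigarettes/day, or a JEM job code) into
#' one intensity value per calendar year from the first year of exposure to
#' the index year, re-indexed as whole years before the index date (time 0 =
#' index year, increasing into the past). Years inside no episode
#' (interruptions, years after cessation) carry 0.
#'
#' An episode active during any part of a calendar year contributes at full
#' intensity for that year (annual resolution). When several directly
#' reported episodes overlap in a year their intensities are summed (a total
#' daily amount); when several JEM-coded jobs overlap the per-job annual
#' levels are averaged, as in [annual_level_from_jobs()].
#'
#' @param episodes data.frame with columns `start_year`, `end_year`, and
#'   either `intensity` or `job_code` (a non-missing `job_code` routes the
#'   episode through the JEM).
#' @param index_year calendar year of the index date (diagnosis for a case,
#'   interview for a control).
#' @param jem optional JEM data.frame (`job_code`, `period_start`,
#'   `period_end`, `probability`, `frequency`, `intensity`).
#' @param subject_id identifier attached to the result.
#' @return data.frame of class `"annual_series"` with columns `subject_id`,
#'   `t` (years before index, decreasing from first exposure to 0) and
#'   `value`.
#' @export
build_series <- function(episodes, index_year, jem = NULL, subject_id = NA) {
  stopifnot(is.data.frame(episodes), nrow(episodes) >= 1)
  if (any(episodes$start_year > episodes$end_year))
    stop("episode with start_year > end_year")
  if (any(episodes$end_year > index_year))
    stop("episode extends past the index year")
  years <- seq(min(episodes$start_year), index_year)
  has_code <- if ("job_code" %in% names(episodes))
    !is.na(episodes$job_code) & episodes$job_code != "" else rep(FALSE, nrow(episodes))
  if (any(has_code) && is.null(jem)) stop("job-coded episodes need a 'jem' table")
  value <- vapply(years, function(yr) {
    act <- episodes$start_year <= yr & yr <= episodes$end_year
    if (!any(act)) return(0)
    direct <- act & !has_code
    coded <- act & has_code
    v <- if (any(direct)) sum(episodes$intensity[direct]) else 0
    if (any(coded)) {
      lev <- vapply(which(coded), function(i)
        .jem_level_for(jem, episodes$job_code[i], yr), numeric(1))
      v <- v + mean(lev)
    }
    v
  }, numeric(1))
  out <- data.frame(subject_id = subject_id, t = index_year - years, value = value)
  out <- out[order(-out$t), ]
  rownames(out) <- NULL
  class(out) <- c("annual_series", "data.frame")
  out
}

#' Cumulative index of exposure
#'
#' Sum of the annual exposure levels over the entire history: f/mL-years for
#' JEM-assessed asbestos, cigarette-years for smoking.
#'
#' @param series an annual series (data.frame with a `value` column) or a
#'   bare numeric vector of annual levels.
#' @return non-negative scalar; 0 for an empty or all-zero series.
#' @export
cumulative_index <- function(series) {
  v <- if (is.data.frame(series)) series$value else as.numeric(series)
  if (length(v) == 0) return(0)
  if (any(v < 0)) stop("annual levels must be non-negative")
  sum(v)
}

#' Comprehensive smoking index
#'
#' Single lifetime smoking metric combining duration, time since cessation
#' and average intensity:
#' \deqn{CSI = (1 - 0.5^{d^*/\tau}) \; 0.5^{t^*/\tau} \; \ln(I + 1)}
#' with lag-adjusted duration \eqn{d^* = \max(0, d - \max(0, \delta - c))}
#' and cessation time \eqn{t^* = \max(0, c - \delta)}, where d is smoking
#' duration, c time since cessation, I average intensity (cig/day),
#' \eqn{\tau} the half-life and \eqn{\delta} the lag, both in years. The
#' index is 0 for never smokers, increases with duration and intensity, and
#' decays towards 0 with half-life \eqn{\tau} after quitting. \eqn{\tau} and
#' \eqn{\delta} must be supplied (study-specific estimates; no defaults).
#'
#' @param duration total smoking duration in years (>= 0).
#' @param time_since_cessation years since quitting (0 for current smokers).
#' @param avg_intensity lifetime average intensity in cigarettes/day.
#' @param tau half-life in years (> 0).
#' @param delta lag in years (>= 0).
#' @return non-negative scalar (vectorised over the first three arguments).
#' @export
csi <- function(duration, time_since_cessation, avg_intensity, tau, delta) {
  if (any(duration < 0, time_since_cessation < 0, avg_intensity < 0))
    stop("duration, time_since_cessation and avg_intensity must be >= 0")
  if (length(tau) != 1 || tau <= 0) stop("'tau' must be a single value > 0")
  if (length(delta) != 1 || delta < 0) stop("'delta' must be a single value >= 0")
  dstar <- pmax(0, duration - pmax(0, delta - time_since_cessation))
  tstar <- pmax(0, time_since_cessation - delta)
  (1 - 0.5^(dstar / tau)) * 0.5^(tstar / tau) * log(avg_intensity + 1)
}

#' A priori partition of the low-cumulative-exposure class
#'
#' Ever-exposed subjects whose cumulative index of exposure (CIE) is
#' strictly below the cutoff are assigned a priori to a very-low-exposure
#' class and excluded from latent-class estimation; the remainder are
#' modelled. The default cutoff 0.26 f/mL-years is the 8 h occupational
#' limit value of 0.01 f/mL times a 26-year mean exposure duration.
#' Subjects at exactly the cutoff are modelled (strict inequality).
#'
#' @param cie named numeric vector of CIE values for ever-exposed subjects
#'   (names are subject ids).
#' @param cutoff CIE cutoff, > 0.
#' @return list with components `low` and `modelled`, each a character
#'   vector of subject ids; their union is all of `names(cie)`, their
#'   intersection empty.
#' @export
low_exposure_partition <- function(cie, cutoff = 0.26) {
  stopifnot(is.numeric(cie), length(cutoff) == 1, cutoff > 0)
  if (is.null(names(cie))) names(cie) <- as.character(seq_along(cie))
  low <- names(cie)[cie < cutoff]
  list(low = low, modelled = setdiff(names(cie), low))
}
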