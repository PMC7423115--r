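#' Readers for the plain-CSV input schemas
#'
#' All files are comma-separated UTF-8 with a `.` decimal separator.
#' Schemas: episodes (`subject_id, exposure_type, start_year, end_year,
#' intensity, job_code`), subjects (`subject_id, outcome, age_index,
#' stratum, index_year`), JEM (`job_code, period_start, period_end,
#' probability, frequency, intensity`), annual series long format
#' (`subject_id, t, value`). Missing required columns are reported by name.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_episodes <- function(path) .read_schema(path,
  c("subject_id", "start_year", "end_year"))

#' @rdname read_episodes
#' @export
read_subjects <- function(path) {
  d <- .read_schema(path, c("subject_id", "outcome"))
  if (!all(d$outcome %in% 0:1)) stop("'outcome' must be 0/1 in ", path)
  d
}

#' @rdname read_episodes
#' @export
read_jem <- function(path) {
  d <- .read_schema(path, c("job_code", "period_start", "period_end",
                            "probability", "frequency", "intensity"))
  bad <- which(d$probability < 0 | d$probability > 1 | d$frequency < 0 |
                 d$frequency > 1 | d$intensity < 0)
  if (length(bad))
    stop("JEM rows with out-of-range values: ", paste(bad, collapse = ", "))
  d
}

#' @rdname read_episodes
#' @export
read_series <- function(path) {
  d <- .read_schema(path, c("subject_id", "t", "value"))
  bad <- which(d$value < 0 | d$t < 0)
  if (length(bad))
    stop("series rows with negative t or value: ", paste(bad, collapse = ", "))
  d
}

.read_schema <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(path, " is missing columns: ", paste(miss, collapse = ", "))
  d
}

#' Serialise an LCMM fit
#'
#' `fit_to_json()` writes parameters and fit statistics as JSON;
#' `posterior_to_csv()` writes the posterior matrix with modal assignment.
#'
#' @param fit an [lcmm_fit()] result.
#' @param path output file.
#' @export
fit_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "lcmm_fit"))
  obj <- list(
    n_classes = length(fit$params$pi),
    class_proportions = fit$params$pi,
    membership_intercepts = fit$params$xi,
    trajectory_coefficients = fit$params$beta,
    random_intercept_sd = fit$params$sigma,
    link_coefficients = fit$params$w,
    link_knots = fit$link$knots,
    time_inner_knots = fit$tbasis$inner_knots,
    time_boundary_knots = fit$tbasis$boundary_knots,
    loglik = fit$loglik, n_params = fit$n_params,
    AIC = fit$AIC, BIC = fit$BIC,
    converged = fit$converged, criteria = fit$criteria,
    n_subjects = fit$n_subjects, n_obs = fit$n_obs,
    n_starts = fit$spec$n_starts, seed = fit$spec$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname fit_to_json
#' @export
posterior_to_csv <- function(fit, path) {
  stopifnot(inherits(fit, "lcmm_fit"))
  d <- data.frame(subject_id = rownames(fit$posterior),
                  fit$posterior, modal_class = fit$modal_class,
                  row.names = NULL, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Serialise / restore a generating truth
#'
#' @param truth a [synthetic_truth()].
#' @param path JSON file path.
#' @export
truth_to_json <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obj <- unclass(truth)
  obj$tbasis <- list(inner_knots = truth$tbasis$inner_knots,
                     boundary_knots = truth$tbasis$boundary_knots)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname truth_to_json
#' @export
truth_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  synthetic_truth(
    pi = o$pi, beta = matrix(unlist(o$beta), ncol = length(o$pi)),
    sigma = o$sigma, window = as.data.frame(o$window), theta = o$theta,
    alpha = o$alpha, gamma_age = o$gamma_age, sigma_eps = o$sigma_eps,
    tbasis = time_basis(o$tbasis$inner_knots, o$tbasis$boundary_knots),
    label = o$label)
}

#' Write an annual-series table
#'
#' @param series long data.frame (`subject_id`, `t`, `value`).
#' @param path output CSV.
#' @export
write_series <- function(series, path) {
  stopifnot(all(c("subject_id", "t", "value") %in% names(series)))
  utils::write.csv(series[, c("subject_id", "t", "value")], path,
                   row.names = FALSE)
  invisible(path)
}
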