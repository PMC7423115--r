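#' Relative entropy of a posterior classification
#'
#' Normalised discrimination measure
#' \deqn{E = 1 - \frac{\sum_i \sum_g -\hat p_{ig} \ln \hat p_{ig}}{N \ln G}}
#' used in growth-mixture modelling: 1 for a perfectly crisp classification,
#' 0 when every posterior row is uniform. Undefined for a one-class model
#' (returns `NA`).
#'
#' @param posterior N x G matrix of posterior class probabilities (rows sum
#'   to 1).
#' @return scalar in [0, 1], or `NA` when G = 1.
#' @export
lcmm_entropy <- function(posterior) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  if (G < 2) return(NA_real_)
  if (any(abs(rowSums(posterior) - 1) > 1e-6))
    stop("posterior rows must sum to 1")
  plogp <- posterior * log(posterior)
  plogp[posterior == 0] <- 0
  1 - sum(-plogp) / (nrow(posterior) * log(G))
}

#' Posterior classification table
#'
#' Cross-tabulates modal assignment against mean posterior probability:
#' entry (g, l) is the average posterior probability of class l among
#' subjects modally assigned to class g. Diagonal dominance indicates good
#' class discrimination. Rows for empty modal classes are `NA` (flagged by
#' attribute `"empty_classes"`).
#'
#' @inheritParams lcmm_entropy
#' @return G x G matrix; rows index modal class, columns posterior class.
#' @export
classification_table <- function(posterior) {
  posterior <- as.matrix(posterior)
  G <- ncol(posterior)
  if (G < 2) stop("classification table needs G >= 2")
  modal <- max.col(posterior, ties.method = "first")
  tab <- matrix(NA_real_, G, G,
                dimnames = list(paste0("modal", seq_len(G)),
                                paste0("class", seq_len(G))))
  for (g in seq_len(G))
    if (any(modal == g))
      tab[g, ] <- colMeans(posterior[modal == g, , drop = FALSE])
  attr(tab, "empty_classes") <- which(tabulate(modal, G) == 0)
  tab
}

#' Fit and compare LCMMs over a ladder of class numbers
#'
#' Fits models with G = 1 .. `G_max` classes and tabulates the selection
#' evidence: log-likelihood, parameter count, AIC, BIC, relative entropy,
#' smallest class, and class percentages. No winner is declared — model
#' choice also weighs the substantive relevance of the trajectories — but
#' the BIC-minimising G is flagged. Fit failures for individual G are
#' recorded and do not abort the ladder.
#'
#' @param series long data.frame (`subject_id`, `t`, `value`).
#' @param link a [link_spline()] shared across the ladder.
#' @param G_max largest number of classes to fit (default 6).
#' @param tbasis a [time_basis()].
#' @param n_starts,seed,control passed to [lcmm_spec()]; the seed for G is
#'   `seed + G` so each rung has its own reproducible grid.
#' @return object of class `"lcmm_selection"`: `report` data.frame (one row
#'   per G), `fits` list, `classification_tables` list, `best_bic` flagged G.
#' @export
lcmm_select <- function(series, link, G_max = 6, tbasis = time_basis(),
                        n_starts = 50, seed = NULL,
                        control = lcmm_control()) {
  stopifnot(G_max >= 1)
  fits <- vector("list", G_max)
  rows <- vector("list", G_max)
  tabs <- vector("list", G_max)
  for (G in seq_len(G_max)) {
    sp <- lcmm_spec(G, link, tbasis, n_starts = n_starts,
                    seed = if (is.null(seed)) NULL else seed + G,
                    control = control)
    init <- if (G > 1 && inherits(fits[[G - 1]], "lcmm_fit"))
      fits[[G - 1]]$params else NULL
    fit <- tryCatch(lcmm_fit(series, sp, init = init), error = function(e) e)
    fits[[G]] <- fit
    if (inherits(fit, "error")) {
      rows[[G]] <- data.frame(G = G, loglik = NA, n_params = NA, AIC = NA,
                              BIC = NA, entropy = NA, min_class_n = NA,
                              converged = FALSE,
                              pct = NA_character_,
                              error = conditionMessage(fit))
      next
    }
    cls_n <- tabulate(fit$modal_class, G)
    rows[[G]] <- data.frame(
      G = G, loglik = fit$loglik, n_params = fit$n_params,
      AIC = fit$AIC, BIC = fit$BIC,
      entropy = lcmm_entropy(fit$posterior),
      min_class_n = min(cls_n), converged = fit$converged,
      pct = paste(sprintf("%.1f", 100 * cls_n / fit$n_subjects),
                  collapse = "/"),
      error = NA_character_)
    tabs[[G]] <- if (G >= 2) classification_table(fit$posterior) else NULL
  }
  report <- do.call(rbind, rows)
  ok <- which(!is.na(report$BIC))
  best <- if (length(ok)) ok[which.min(report$BIC[ok])] else NA_integer_
  structure(list(report = report, fits = fits,
                 classification_tables = tabs, best_bic = best),
            class = "lcmm_selection")
}

#' @export
print.lcmm_selection <- function(x, ...) {
  cat("LCMM class-number selection\n")
  print(x$report[, c("G", "loglik", "AIC", "BIC", "entropy",
                     "min_class_n", "pct", "converged")], row.names = FALSE)
  if (!is.na(x$best_bic)) cat("BIC minimised at G =", x$best_bic, "\n")
  invisible(x)
}
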