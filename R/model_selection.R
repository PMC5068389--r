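#' Information criterion of a mixture fit
#'
#' BIC = -2 loglik + q log(n); AIC = -2 loglik + 2 q, with
#' q = K J + K J(J+1)/2 + (K - 1) free parameters (component means,
#' covariances, and the simplex-constrained proportions). The sample size is
#' the number of rows entering the joint likelihood (labeled + mixed).
#'
#' @param fit A `mixture_fit`.
#' @param n_obs Sample size; defaults to the fit's `n_obs`.
#' @param which `"BIC"` (default) or `"AIC"`.
#' @return Scalar criterion value (smaller is better).
#' @export
information_criterion <- function(fit, n_obs = fit$n_obs,
                                  which = c("BIC", "AIC")) {
  which <- match.arg(which)
  if (n_obs < 1) stop("n_obs must be >= 1")
  if (!is.finite(fit$loglik)) stop("fit log-likelihood is not finite")
  q <- n_free_parameters(fit$K, length(fit$panel))
  if (which == "BIC") -2 * fit$loglik + q * log(n_obs)
  else -2 * fit$loglik + 2 * q
}

#' Free-parameter count of a K-component MVN mixture
#'
#' @param K Components; @param J Variables.
#' @return `K*J + K*J*(J+1)/2 + (K-1)`.
#' @export
n_free_parameters <- function(K, J) K * J + K * J * (J + 1) / 2 + (K - 1)

#' Estimate the number of contributing sources by model comparison
#'
#' Fits the full initialization + EM pipeline for every K from
#' max(1, K_S) to `K_max` and selects the K with the lowest information
#' criterion (ties broken toward the smallest K). The selection-strength
#' statistic `delta_bic` is the median-minus-minimum criterion gap across
#' the candidate ladder. Individual fits that fail are recorded and
#' excluded with a warning; if all fail, an error is raised.
#'
#' @param labeled Labeled observation table (0 rows allowed).
#' @param mixed Unlabeled observation table (non-empty).
#' @param K_S Number of sampled sources; defaults to the count of distinct
#'   labels in `labeled`. The candidate ladder starts at max(1, K_S): with
#'   no sampled sources a one-component model is still meaningful, a
#'   zero-component one is not.
#' @param K_max Upper end of the ladder (study design: 8).
#' @param controls An [em_controls()] list.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param panel Variable names.
#' @return Object of class `selection_result`: `K_hat`, `criterion_values`
#'   (named by K), `delta_bic`, `table` (K, loglik, q, criterion value,
#'   converged, selected), `fits`, `criterion`, `failed` (named character of
#'   failure messages).
#' @export
estimate_k <- function(labeled, mixed, K_S = NULL, K_max = 8L,
                       controls = em_controls(), criterion = c("BIC", "AIC"),
                       panel = obs_panel(mixed)) {
  criterion <- match.arg(criterion)
  if (!nrow(mixed)) stop("mixed-stock data is required to estimate K")
  if (is.null(K_S))
    K_S <- if (nrow(labeled)) length(unique(labeled$source)) else 0L
  K_min <- max(1L, as.integer(K_S))
  if (K_max < K_min) stop("K_max is below the minimum candidate K")
  Ks <- seq.int(K_min, K_max)
  fits <- list(); vals <- numeric(0); failed <- character(0)
  rows <- list()
  for (K in Ks) {
    f <- tryCatch(fit_mixture(labeled, mixed, K, controls, panel),
                  error = function(e) e)
    if (inherits(f, "error")) {
      failed[as.character(K)] <- conditionMessage(f)
      warning("fit at K = ", K, " failed: ", conditionMessage(f))
      next
    }
    ic <- information_criterion(f, which = criterion)
    fits[[as.character(K)]] <- f
    vals[as.character(K)] <- ic
    rows[[length(rows) + 1L]] <- data.frame(
      K = K, loglik = f$loglik, q = n_free_parameters(K, length(panel)),
      criterion = ic, converged = f$converged)
  }
  if (!length(vals)) stop("all candidate fits failed")
  K_hat <- as.integer(names(vals)[which.min(vals)])  # which.min: first = smallest K
  tab <- do.call(rbind, rows)
  names(tab)[names(tab) == "criterion"] <- criterion
  tab$selected <- tab$K == K_hat
  structure(list(K_hat = K_hat, criterion_values = vals,
                 delta_bic = as.numeric(stats::median(vals) - min(vals)),
                 table = tab, fits = fits, criterion = criterion,
                 failed = failed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Model selection by %s: K_hat = %d (delta = %.2f)\n",
              x$criterion, x$K_hat, x$delta_bic))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a model-selection table
#'
#' @param sel A `selection_result`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(sel, path) {
  utils::write.csv(sel$table, path, row.names = FALSE)
  invisible(path)
}
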