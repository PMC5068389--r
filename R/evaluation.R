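# all permutations of 1..n as a matrix (n! rows); n is small here (<= 8)
all_perms <- function(n) {
  if (n == 0L) return(matrix(integer(0), 1L, 0L))
  if (n == 1L) return(matrix(1L, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    sub <- all_perms(n - 1L)
    cbind(i, matrix(seq_len(n)[-i][sub], nrow(sub)))
  }))
}

#' Match fitted components to true sources
#'
#' Resolves label switching before bias computation: components whose
#' provenance is a known source id are pinned to that source; the remaining
#' ("novel") components are paired with the remaining sources by minimizing
#' the total squared Euclidean distance between fitted and true centroids
#' over all assignments (exhaustive, the counts here are small).
#'
#' @param fit A `mixture_fit` with as many components as there are true
#'   sources.
#' @param true_mus K x J matrix of true centroids with source ids as row
#'   names.
#' @return Integer permutation: element i is the row of `true_mus` matched
#'   to component i.
#' @export
match_components <- function(fit, true_mus) {
  true_mus <- as.matrix(true_mus)
  K <- nrow(true_mus)
  if (fit$K != K)
    stop("number of fitted components differs from number of true sources")
  ids <- rownames(true_mus)
  prov <- fit$provenance
  perm <- integer(K)
  known <- which(prov %in% ids)
  perm[known] <- match(prov[known], ids)
  free_c <- setdiff(seq_len(K), known)
  free_s <- setdiff(seq_len(K), perm[known])
  if (length(free_c)) {
    Mf <- do.call(rbind, lapply(fit$components[free_c], `[[`, "mu"))
    Mt <- true_mus[free_s, , drop = FALSE]
    P <- all_perms(length(free_c))
    cost <- apply(P, 1L, function(pr) sum((Mf - Mt[pr, , drop = FALSE])^2))
    best <- P[which.min(cost), ]
    perm[free_c] <- free_s[best]
  }
  perm
}

#' Assemble one resampling-run record
#'
#' Pairs a fitted model with its generating truth: resolves component
#' matching, and stores the estimated and true mixing proportions and
#' centroids aligned in true-source order, ready for the bias/uncertainty
#' metrics.
#'
#' @param fit A `mixture_fit` with K equal to the number of true sources.
#' @param truth A `run_truth` from [draw_mixed_dataset()].
#' @param K_hat Optional selected number of sources (from [estimate_k()]).
#' @param delta_bic Optional selection-strength statistic.
#' @return Object of class `run_record` with fields `sources`, `p_true`,
#'   `p_hat`, `mu_hat` (rows in true-source order), `matching`, `K_hat`,
#'   `delta_bic`, `truth`, `fit`.
#' @export
make_run_record <- function(fit, truth, K_hat = NA_integer_,
                            delta_bic = NA_real_) {
  perm <- match_components(fit, truth$true_mus)
  ids <- rownames(truth$true_mus)
  K <- length(ids)
  p_hat <- numeric(K); mu_hat <- matrix(NA_real_, K, ncol(truth$true_mus))
  for (i in seq_len(K)) {
    p_hat[perm[i]] <- fit$p_hat[i]
    mu_hat[perm[i], ] <- fit$components[[i]]$mu
  }
  rownames(mu_hat) <- ids
  structure(list(sources = ids,
                 p_true = as.numeric(truth$allocation[ids]),
                 p_hat = p_hat, mu_hat = mu_hat, matching = perm,
                 K_hat = K_hat, delta_bic = delta_bic,
                 truth = truth, fit = fit),
            class = "run_record")
}

stack_p <- function(records) {
  list(err = t(vapply(records, function(r) r$p_hat - r$p_true,
                      numeric(length(records[[1L]]$p_true)))),
       lev = t(vapply(records, function(r) r$p_true,
                      numeric(length(records[[1L]]$p_true)))))
}

#' Bias in mixing-proportion estimates
#'
#' \eqn{BI_p = \sum_m (1/R) \sum_r |\hat p_{mr} - p_{mr}|}: the mean
#' absolute estimation error at each true proportion level m (the levels of
#' the allocated mixing vector), summed over the M levels. Bounded in
#' \[0, 2\] by simplex geometry.
#'
#' @param records List of `run_record`s.
#' @return Scalar bias.
#' @export
bias_p <- function(records) {
  if (!length(records)) stop("no run records")
  s <- stack_p(records)
  levs <- sort(unique(as.numeric(s$lev)))
  sum(vapply(levs, function(l) mean(abs(s$err[s$lev == l])), 0))
}

#' Uncertainty in mixing-proportion estimates
#'
#' \eqn{SE_p = (1/M) \sum_m \sqrt{(1/R) \sum_r (\hat p_{mr} - p_{mr})^2}}:
#' per-level root-mean-square deviation about the true proportion, averaged
#' over the M levels. Taken literally from its defining equation, this is an
#' RMSE about truth (it includes bias), not a dispersion about the mean.
#'
#' @param records List of `run_record`s.
#' @return Scalar uncertainty.
#' @export
se_p <- function(records) {
  if (!length(records)) stop("no run records")
  s <- stack_p(records)
  levs <- sort(unique(as.numeric(s$lev)))
  mean(vapply(levs, function(l) sqrt(mean(s$err[s$lev == l]^2)), 0))
}

#' Systematic bias in estimated signature means
#'
#' \eqn{BI_\theta = \frac{1}{JK}\sum_j\sum_k |\frac{1}{R}\sum_r
#' (\hat\mu_{kr,j} - \mu_{k,j})|}. The absolute value sits outside the
#' run-average, so run-to-run noise that averages out contributes nothing:
#' this measures systematic displacement only, in standardized units.
#'
#' @param records List of `run_record`s.
#' @param true_mu K x J matrix of true centroids (source ids as row names).
#' @return Scalar bias.
#' @export
bias_theta <- function(records, true_mu) {
  if (!length(records)) stop("no run records")
  true_mu <- as.matrix(true_mu)
  ids <- rownames(true_mu)
  D <- Reduce(`+`, lapply(records, function(r)
    r$mu_hat[ids, , drop = FALSE] - true_mu)) / length(records)
  mean(abs(D))
}

#' Uncertainty in estimated signature means
#'
#' For each source, the covariance matrix of its estimated mean vectors
#' across the R resampling runs is summarized by its effective standard
#' deviation \eqn{\det(\hat\Sigma_k)^{1/(2J)}}; the result is averaged over
#' the K sources.
#'
#' @param records List of `run_record`s (R >= 2).
#' @return Scalar uncertainty.
#' @export
se_theta <- function(records) {
  if (length(records) < 2L) stop("need at least 2 runs")
  ids <- records[[1L]]$sources
  mean(vapply(ids, function(sid) {
    M <- t(vapply(records, function(r) r$mu_hat[sid, ],
                  numeric(ncol(records[[1L]]$mu_hat))))
    effective_sd(stats::cov(M))
  }, 0))
}

#' Bias and uncertainty in the estimated number of sources
#'
#' `bias_k` is the mean selected K minus the true K; `se_k` is the
#' empirical standard deviation of the selected K across runs (population
#' denominator R — the dispersion of the estimator itself, the magnitude
#' reported as its standard error).
#'
#' @param records List of `run_record`s carrying `K_hat`.
#' @param K_true True number of sources.
#' @return Scalar.
#' @export
bias_k <- function(records, K_true) {
  kh <- vapply(records, function(r) as.numeric(r$K_hat), 0)
  kh <- kh[!is.na(kh)]
  if (!length(kh)) stop("no records carry K_hat")
  mean(kh) - K_true
}

#' @rdname bias_k
#' @export
se_k <- function(records) {
  kh <- vapply(records, function(r) as.numeric(r$K_hat), 0)
  kh <- kh[!is.na(kh)]
  if (!length(kh)) stop("no records carry K_hat")
  sqrt(mean((kh - mean(kh))^2))
}

#' Summarize a scenario's resampling runs
#'
#' Assembles every bias/uncertainty metric for one (cohort, sampling
#' scenario) cell. K-metrics are reported as `NA` when no record carries a
#' selected K (they are computed in a separate model-selection pass).
#'
#' @param records List of `run_record`s (>= 2).
#' @param true_mu K x J matrix of true centroids; defaults to the first
#'   record's truth.
#' @param K_true True number of sources; defaults to the number of rows of
#'   `true_mu`.
#' @param n_failed Count of failed runs excluded upstream.
#' @return Object of class `evaluation_summary`: one-row data frame with
#'   `BI_p`, `SE_p`, `BI_theta`, `SE_theta`, `BI_K`, `SE_K`,
#'   `delta_bic_mean`, `R_effective`, `n_failed`.
#' @export
summarize_scenario <- function(records, true_mu = records[[1L]]$truth$true_mus,
                               K_true = nrow(true_mu), n_failed = 0L) {
  if (length(records) < 2L) stop("need at least 2 successful runs")
  kh <- vapply(records, function(r) as.numeric(r$K_hat), 0)
  has_k <- any(!is.na(kh))
  db <- vapply(records, function(r) as.numeric(r$delta_bic), 0)
  out <- data.frame(
    BI_p = bias_p(records), SE_p = se_p(records),
    BI_theta = bias_theta(records, true_mu), SE_theta = se_theta(records),
    BI_K = if (has_k) bias_k(records, K_true) else NA_real_,
    SE_K = if (has_k) se_k(records) else NA_real_,
    delta_bic_mean = if (any(!is.na(db))) mean(db, na.rm = TRUE) else NA_real_,
    R_effective = length(records), n_failed = as.integer(n_failed))
  class(out) <- c("evaluation_summary", class(out))
  out
}
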