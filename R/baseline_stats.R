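#' Standardize an observation table
#'
#' Centers and scales every panel variable to sample mean 0 and sample
#' standard deviation 1 (denominator n - 1), so that all element:Ca ratios
#' weigh equally in distance and bias computations. The transform parameters
#' are returned so new data can be mapped onto the same scale with
#' [apply_standardization()].
#'
#' @param table Observation data frame (see [observation_table()]).
#' @param panel Variables to standardize; defaults to the table's panel.
#' @return List with `table` (standardized copy), `center` and `scale`
#'   (named numeric vectors).
#' @export
# reference metric for centroid Mahalanobis distances
resolve_reference_cov <- function(reference_cov, set) {
  if (is.character(reference_cov)) {
    J <- length(set$signatures[[1L]]$mu)
    switch(match.arg(reference_cov, c("pooled", "identity")),
           pooled = pooled_cov(set),
           identity = diag(J))
  } else as.matrix(reference_cov)
}

standardize <- function(table, panel = obs_panel(table)) {
  X <- obs_matrix(table, panel)
  if (nrow(X) < 2L) stop("need at least 2 rows to standardize")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero))
    stop("zero-variance variable(s): ", paste(panel[zero], collapse = ", "))
  table[panel] <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  list(table = table, center = ctr, scale = scl)
}

#' Apply a stored standardization to new data
#'
#' @param table Observation data frame.
#' @param center,scale Named vectors as returned by [standardize()].
#' @return The table with panel variables mapped to the stored scale.
#' @export
apply_standardization <- function(table, center, scale) {
  if (!nrow(table)) return(table)
  panel <- names(center)
  X <- obs_matrix(table, panel)
  table[panel] <- sweep(sweep(X, 2L, center), 2L, scale, `/`)
  table
}

#' Squared Mahalanobis distance between two centroids
#'
#' \eqn{(\mu_a - \mu_b)^T S^{-1} (\mu_a - \mu_b)}, the covariance-scaled
#' squared distance used as the separation index between nursery-signature
#' centroids.
#'
#' @param mu_a,mu_b Numeric vectors of equal length.
#' @param S Positive-definite reference covariance matrix.
#' @return Non-negative scalar; symmetric in `mu_a`, `mu_b`.
#' @export
sq_mahalanobis <- function(mu_a, mu_b, S) {
  d <- as.numeric(mu_a) - as.numeric(mu_b)
  if (length(d) != nrow(as.matrix(S))) stop("dimension mismatch")
  R <- tryCatch(chol(S), error = function(e)
    stop("reference covariance is singular or ill-conditioned"))
  z <- backsolve(R, d, transpose = TRUE)
  sum(z * z)
}

#' Average squared Mahalanobis separation among centroids
#'
#' Unweighted mean of the squared Mahalanobis distance over all K(K-1)/2
#' unordered centroid pairs of a signature set, computed in a single
#' reference metric (by default the pooled within-source covariance).
#'
#' @param set A [signature_set()] with K >= 2 sources.
#' @param reference_cov `"pooled"` (default; the sample-size-weighted
#'   average of the source covariances), `"identity"` (the unit
#'   standardized scale, under which the separation reads directly in
#'   standard deviations of the standardized data), or an explicit J x J
#'   positive-definite matrix.
#' @return Scalar average squared separation.
#' @export
average_separation <- function(set, reference_cov = "pooled") {
  K <- length(set$signatures)
  if (K < 2L) stop("separation needs at least 2 sources")
  S <- resolve_reference_cov(reference_cov, set)
  M <- set_centroids(set)
  tot <- 0
  for (a in seq_len(K - 1L))
    for (b in seq.int(a + 1L, K))
      tot <- tot + sq_mahalanobis(M[a, ], M[b, ], S)
  tot / (K * (K - 1L) / 2)
}

#' Effective standard deviation
#'
#' \eqn{\det(\Sigma)^{1/(2J)}}: the geometric-mean standard deviation of a
#' J-variate covariance matrix, a scalar index of multivariate spread
#' (|S|^(1/14) for the seven-element panel).
#'
#' @param cov Positive-semidefinite covariance matrix.
#' @param J Dimension; defaults to `nrow(cov)`.
#' @return Scalar >= 0 (0 when the determinant is 0).
#' @export
effective_sd <- function(cov, J = nrow(as.matrix(cov))) {
  cov <- as.matrix(cov)
  dt <- det(cov)
  tol <- 1e-12 * max(1, max(abs(cov)))^J
  if (dt < -tol) stop("covariance has negative determinant")
  if (dt <= 0) return(0)
  dt^(1 / (2 * J))
}

#' Rescale a signature set to a target centroid separation
#'
#' Shrinks or inflates all centroids radially about their unweighted grand
#' centroid, holding every covariance matrix fixed, so that the average
#' squared Mahalanobis separation hits `target` exactly:
#' \eqn{\mu_k \leftarrow \bar\mu + c(\mu_k - \bar\mu)} with
#' \eqn{c = \sqrt{target/current}}. This is how virtual cohorts spanning a
#' prescribed separation grid are constructed.
#'
#' @param set A [signature_set()].
#' @param target Desired average squared separation (> 0).
#' @param reference_cov Metric for the separation, as in
#'   [average_separation()].
#' @return A new `signature_set` with rescaled means and untouched
#'   covariances.
#' @export
rescale_separation <- function(set, target, reference_cov = "pooled") {
  if (target <= 0) stop("target separation must be positive")
  cur <- average_separation(set, reference_cov)
  if (cur <= 0) stop("centroids are coincident; cannot rescale separation")
  cc <- sqrt(target / cur)
  M <- set_centroids(set)
  gc <- colMeans(M)
  sigs <- Map(function(s, i) {
    s$mu <- as.numeric(gc + cc * (M[i, ] - gc))
    s
  }, set$signatures, seq_along(set$signatures))
  signature_set(sigs, cohort_id = set$cohort_id, panel = as.character(set$panel))
}
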