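#' Default element panel
#'
#' The seven element:Ca ratios routinely used to fingerprint *Sparus aurata*
#' nursery lagoons: Li, B, Mg, Rb, Sr, Y and Ba. Used as the default variable
#' panel throughout the package; any other set of column names works as long
#' as it is used consistently.
#'
#' @format Character vector of length 7.
#' @export
default_panel <- function() c("Li", "B", "Mg", "Rb", "Sr", "Y", "Ba")

#' Element panel constructor
#'
#' An ordered set of variable identifiers (element:Ca ratio labels). The
#' order is fixed and shared by every mean vector, covariance matrix and
#' observation table that references the panel.
#'
#' @param names Character vector of unique variable names, length >= 2.
#' @return Character vector of class `element_panel`.
#' @export
element_panel <- function(names) {
  names <- as.character(names)
  if (length(names) < 2L) stop("an element panel needs at least 2 variables")
  if (anyDuplicated(names)) stop("element panel names must be unique")
  structure(names, class = "element_panel")
}

#' Nursery signature
#'
#' The baseline parameters of one nursery source in one cohort: a mean
#' vector `mu` and covariance matrix `cov` on the (standardized) element
#' panel, together with the sample size the signature was computed from
#' (`n = 0` for purely synthetic signatures).
#'
#' @param source_id Source label.
#' @param mu Numeric mean vector, length J; names taken as the panel if set.
#' @param cov J x J symmetric positive-definite covariance matrix.
#' @param cohort_id Cohort label (year), default `NA`.
#' @param n Sample size behind the signature (>= 0).
#' @return Object of class `nursery_signature`: a list with fields
#'   `source_id`, `cohort_id`, `mu`, `cov`, `n`.
#' @export
nursery_signature <- function(source_id, mu, cov, cohort_id = NA_character_, n = 0L) {
  mu <- as.numeric(mu)
  cov <- as.matrix(cov)
  J <- length(mu)
  if (!all(is.finite(mu))) stop("signature mean vector must be finite")
  if (!all(dim(cov) == J)) stop("covariance dimensions do not match the mean vector")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance matrix is not symmetric")
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance matrix is not positive definite")
  if (n < 0) stop("sample size must be >= 0")
  structure(list(source_id = as.character(source_id),
                 cohort_id = as.character(cohort_id),
                 mu = mu, cov = (cov + t(cov)) / 2, n = as.integer(n)),
            class = "nursery_signature")
}

#' Signature set
#'
#' A cohort's collection of nursery signatures on a common element panel.
#' This is the baseline object all separation statistics and the synthetic
#' generators operate on.
#'
#' @param signatures List of [nursery_signature()] objects sharing J and
#'   carrying unique `source_id`s.
#' @param cohort_id Cohort label; defaults to the first signature's.
#' @param panel Variable names (length J); defaults to [default_panel()] when
#'   J = 7, else `V1..VJ`.
#' @return Object of class `signature_set`: list with `cohort_id`, `panel`,
#'   `signatures`.
#' @export
signature_set <- function(signatures, cohort_id = NULL, panel = NULL) {
  if (!length(signatures)) stop("signature set cannot be empty")
  if (!all(vapply(signatures, inherits, TRUE, "nursery_signature")))
    stop("all elements must be nursery_signature objects")
  J <- length(signatures[[1L]]$mu)
  if (!all(vapply(signatures, function(s) length(s$mu), 1L) == J))
    stop("all signatures must share the same number of variables")
  ids <- vapply(signatures, function(s) s$source_id, "")
  if (anyDuplicated(ids)) stop("source ids must be unique within a set")
  if (is.null(cohort_id)) cohort_id <- signatures[[1L]]$cohort_id
  if (is.null(panel)) panel <- if (J == 7L) default_panel() else paste0("V", seq_len(J))
  if (length(panel) != J) stop("panel length does not match signature dimension")
  structure(list(cohort_id = as.character(cohort_id),
                 panel = element_panel(panel),
                 signatures = signatures),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  K <- length(x$signatures)
  J <- length(x$panel)
  cat(sprintf("Signature set: cohort %s, %d sources, %d variables (%s)\n",
              x$cohort_id, K, J, paste(x$panel, collapse = ", ")))
  for (s in x$signatures)
    cat(sprintf("  %-12s n = %3d  effective sd = %.3f\n",
                s$source_id, s$n, effective_sd(s$cov)))
  invisible(x)
}

# source ids of a set, in order
set_sources <- function(set) vapply(set$signatures, function(s) s$source_id, "")

# K x J matrix of centroids, rownames = source ids
set_centroids <- function(set) {
  M <- do.call(rbind, lapply(set$signatures, function(s) s$mu))
  rownames(M) <- set_sources(set)
  colnames(M) <- as.character(set$panel)
  M
}

#' Pooled covariance of a signature set
#'
#' Sample-size-weighted average of the per-source covariance matrices; equal
#' weights when no signature carries a sample size. This is the default
#' reference metric for among-centroid Mahalanobis distances.
#'
#' @param set A [signature_set()].
#' @return J x J covariance matrix.
#' @export
pooled_cov <- function(set) {
  ns <- vapply(set$signatures, function(s) s$n, 1L)
  w <- if (sum(ns) > 0) ns / sum(ns) else rep(1 / length(ns), length(ns))
  Reduce(`+`, Map(function(s, wk) wk * s$cov, set$signatures, w))
}
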