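#' Deterministic child seeds
#'
#' Folds a base seed and any number of integer indices (scenario, run, stage)
#' into a reproducible child seed, so every resampling run is independently
#' re-runnable. Linear-congruential folding on the Mersenne-prime modulus
#' 2^31 - 1; all arithmetic stays exact in doubles.
#'
#' @param seed Base integer seed.
#' @param ... Integer indices identifying the child stream.
#' @return Integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.double(abs(as.integer(seed)) %% m)
  for (i in c(...)) s <- (s * 48271 + as.double(i) + 1) %% m
  as.integer(s + 1)
}

# random PD covariance: random orthogonal eigenvectors, log-uniform
# eigenvalues rescaled so effective_sd equals `spread` exactly
random_pd_cov <- function(J, spread) {
  Q <- qr.Q(qr(matrix(stats::rnorm(J * J), J, J)))
  lam <- exp(stats::runif(J, log(0.25), log(4)))
  lam <- lam * (spread^2 / prod(lam)^(1 / J))
  S <- Q %*% diag(lam) %*% t(Q)
  (S + t(S)) / 2
}

#' Generate a random synthetic baseline
#'
#' Builds K multivariate-normal nursery signatures on J standardized
#' variables: random positive-definite covariances with effective standard
#' deviation close to `spread` (a small random jitter keeps sources
#' unequal), and centroids placed in random directions then rescaled so the
#' average squared Mahalanobis separation equals `target_sep` exactly.
#'
#' @param K Number of sources.
#' @param J Number of variables (7 for the standard element panel).
#' @param target_sep Average squared Mahalanobis separation among centroids.
#' @param spread Target effective standard deviation of each source
#'   (standardized units; observed cohorts sit around 0.35-0.65).
#' @param seed Integer seed; the whole set is a pure function of the
#'   arguments.
#' @param cohort_id Label for the synthetic cohort.
#' @param reference_cov Metric in which `target_sep` is expressed. Default
#'   `"identity"`: the separation is measured on the unit standardized
#'   scale, i.e. directly in standard deviations of the standardized data,
#'   which is how observed and virtual cohort separations are reported.
#' @return A [signature_set()] with sources `S1..SK`.
#' @export
random_baseline <- function(K = 4L, J = 7L, target_sep = 2.5, spread = 0.5,
                            seed = 1L, cohort_id = "synthetic",
                            reference_cov = "identity") {
  if (spread <= 0) stop("spread must be positive")
  if (target_sep <= 0) stop("target separation must be positive")
  set.seed(child_seed(seed, 101L))
  sigs <- lapply(seq_len(K), function(k) {
    sp <- spread * exp(stats::runif(1, log(0.85), log(1.15)))
    cv <- random_pd_cov(J, sp)
    mu <- stats::rnorm(J)
    nursery_signature(paste0("S", k), mu, cv, cohort_id = cohort_id, n = 0L)
  })
  rescale_separation(signature_set(sigs, cohort_id = cohort_id), target_sep,
                     reference_cov)
}

#' Build a virtual cohort at a prescribed separation
#'
#' Copies a baseline's covariance matrices unchanged and rescales its
#' centroids to the requested average squared Mahalanobis separation — the
#' construction behind the virtual separation grid
#' \{0.5, 1.5, 2.5, 3.5, 4.5, 5.5\}.
#'
#' @param base A [signature_set()].
#' @param target_sep Target average squared separation.
#' @param cohort_id Optional new cohort label; default tags the target onto
#'   the base label.
#' @param reference_cov Metric for the separation; default `"identity"`
#'   (standard deviations of the standardized data, the scale virtual
#'   cohort grids are specified on).
#' @return A rescaled `signature_set`.
#' @export
make_virtual_cohort <- function(base, target_sep, cohort_id = NULL,
                                reference_cov = "identity") {
  out <- rescale_separation(base, target_sep, reference_cov)
  if (is.null(cohort_id))
    cohort_id <- sprintf("%s_d%.1f", base$cohort_id, target_sep)
  out$cohort_id <- cohort_id
  out$signatures <- lapply(out$signatures, function(s) { s$cohort_id <- cohort_id; s })
  out
}

#' Draw a labeled nursery-source dataset
#'
#' Parametric bootstrap of the baseline: for every cohort in `sets` and
#' every sampled ("known") source, draws `n_per_source` observations from
#' MVN(mu_k, Sigma_k) and labels them with source and cohort. With no
#' sampled sources (the K_S = 0 scenario) an empty, correctly-typed table is
#' returned.
#'
#' @param sets A [signature_set()] or list of them (one per cohort).
#' @param sampled_sources Character vector of source ids to include.
#' @param n_per_source Observations per source per cohort (study design: 25).
#' @param seed Integer seed.
#' @return Labeled observation data frame.
#' @export
draw_nursery_dataset <- function(sets, sampled_sources, n_per_source = 25L,
                                 seed = 1L) {
  if (inherits(sets, "signature_set")) sets <- list(sets)
  panel <- as.character(sets[[1L]]$panel)
  if (!length(sampled_sources)) return(empty_observation_table(panel))
  set.seed(child_seed(seed, 211L))
  rows <- list()
  for (set in sets) {
    ids <- set_sources(set)
    bad <- setdiff(sampled_sources, ids)
    if (length(bad)) stop("unknown source id(s): ", paste(bad, collapse = ", "))
    for (sid in sampled_sources) {
      s <- set$signatures[[match(sid, ids)]]
      X <- MASS::mvrnorm(n_per_source, s$mu, s$cov)
      if (n_per_source == 1L) X <- matrix(X, 1L)
      rows[[length(rows) + 1L]] <-
        observation_table(X, cohort = set$cohort_id, source = sid, panel = panel)
    }
  }
  out <- do.call(rbind, rows)
  out$specimen_id <- paste0("nur", seq_len(nrow(out)))
  attr(out, "panel") <- panel
  out
}

#' Draw an unlabeled mixed-stock dataset
#'
#' Composes a mixed-stock sample of `n_mixed` fish from all sources of one
#' cohort. The proportion vector `m` is randomly permuted across sources
#' within the run, and by default the composition is exact
#' (`n_mixed * m[k]` fish from the source allocated proportion `m[k]`), so
#' the allocated proportions are the exact per-run truth; `method =
#' "multinomial"` draws the composition instead. Source labels are stripped;
#' the truth record keeps them.
#'
#' @param set A [signature_set()] (one cohort).
#' @param m Mixing proportions, length K, summing to 1 (study design:
#'   0.1/0.2/0.3/0.4).
#' @param n_mixed Total sample size (study design: 100).
#' @param seed Integer seed.
#' @param method `"exact"` (default) or `"multinomial"` composition.
#' @return List with `table` (unlabeled observation data frame) and `truth`
#'   (class `run_truth`: named `allocation` of true p_k per source,
#'   `true_mus` matrix, `counts`, `seed_used`).
#' @export
draw_mixed_dataset <- function(set, m = c(0.1, 0.2, 0.3, 0.4), n_mixed = 100L,
                               seed = 1L, method = c("exact", "multinomial")) {
  method <- match.arg(method)
  ids <- set_sources(set)
  K <- length(ids)
  if (length(m) != K) stop("length of m must equal the number of sources")
  if (abs(sum(m) - 1) > 1e-12) stop("proportions must sum to 1")
  set.seed(child_seed(seed, 307L))
  perm <- sample.int(K)
  p <- stats::setNames(m[perm], ids)       # source ids[k] contributes m[perm[k]]
  if (method == "exact") {
    counts <- n_mixed * p
    if (max(abs(counts - round(counts))) > 1e-9)
      stop("n_mixed * m must be integral for exact composition")
    counts <- as.integer(round(counts))
  } else {
    counts <- stats::setNames(as.integer(stats::rmultinom(1, n_mixed, p)), ids)
  }
  rows <- Map(function(s, nk) {
    if (nk == 0L) return(NULL)
    X <- MASS::mvrnorm(nk, s$mu, s$cov)
    if (nk == 1L) X <- matrix(X, 1L)
    observation_table(X, cohort = set$cohort_id, source = NA_character_,
                      panel = as.character(set$panel))
  }, set$signatures, counts)
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  ord <- sample.int(nrow(out))             # shuffle so order carries no label
  out <- out[ord, , drop = FALSE]
  out$specimen_id <- paste0("mix", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "panel") <- as.character(set$panel)
  truth <- structure(list(allocation = p, counts = counts,
                          true_mus = set_centroids(set), seed_used = seed),
                     class = "run_truth")
  list(table = out, truth = truth)
}

#' Build a grid of simulation scenarios
#'
#' Cartesian product of cohorts (observed-style signature sets and/or a
#' virtual-separation grid over one base set) with the sampling scenarios
#' K_S, each cell carrying a deterministic child seed.
#'
#' @param cohorts Named list of [signature_set()]s (may be empty).
#' @param K_S Integer vector of sampled-source counts (study design: 0:4).
#' @param base Optional base set for virtual cohorts.
#' @param separations Numeric vector of target separations for virtual
#'   cohorts built from `base` (study grid: `seq(0.5, 5.5, 1)`).
#' @param R Replicates per cell.
#' @param n_nursery,n_mixed,m Sampling design shared by all cells.
#' @param base_seed Base seed; cell seeds derive from it.
#' @return List of `scenario_config` lists with fields `cohort_id`, `set`,
#'   `K_S`, `R`, `n_nursery`, `n_mixed`, `m`, `seed`.
#' @export
build_scenario_grid <- function(cohorts = list(), K_S = 0:4, base = NULL,
                                separations = NULL, R = 1000L,
                                n_nursery = 25L, n_mixed = 100L,
                                m = c(0.1, 0.2, 0.3, 0.4), base_seed = 1L) {
  sets <- cohorts
  if (!is.null(separations)) {
    if (is.null(base)) stop("virtual separations need a base signature set")
    for (d in separations)
      sets[[sprintf("virtual_%.1f", d)]] <- make_virtual_cohort(base, d)
  }
  out <- list()
  i <- 0L
  for (nm in names(sets)) for (ks in K_S) {
    i <- i + 1L
    out[[i]] <- structure(list(
      cohort_id = nm, set = sets[[nm]], K_S = as.integer(ks), R = as.integer(R),
      n_nursery = as.integer(n_nursery), n_mixed = as.integer(n_mixed), m = m,
      seed = child_seed(base_seed, 401L, i)), class = "scenario_config")
  }
  out
}
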