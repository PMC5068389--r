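#' EM control parameters
#'
#' Tuning knobs of the unconditional EM fit. Defaults are deliberately
#' conservative; the bias/uncertainty results are insensitive to halving or
#' doubling them.
#'
#' @param max_iter Maximum EM iterations.
#' @param rel_tol Relative log-likelihood change declaring convergence.
#' @param cov_det_floor Lower bound enforced on det(Sigma_k) each M-step
#'   (the positive-definiteness constraint, on standardized data).
#' @param eig_floor Lower bound on covariance eigenvalues.
#' @param kmeans_restarts Random restarts of the semi-supervised K-means
#'   initialization.
#' @param em_restarts Number of independent initializations tried when at
#'   least one source is unsampled. Each is advanced by a short EM run
#'   (`short_iter` iterations) and the one with the highest log-likelihood
#'   is run to convergence — the usual guard against the local maxima that
#'   plague mixture likelihoods (set to 1 for a single initialization
#'   chain).
#' @param short_iter Iterations of each exploratory short run.
#' @param seed Seed for the initialization randomness (`NULL` = leave RNG
#'   state alone).
#' @param update_known If `TRUE` (default, the unconditional model) the
#'   signatures of known sources are re-estimated jointly from nursery and
#'   mixed-stock data; if `FALSE` they stay at their nursery-sample values.
#' @return List of class `em_controls`.
#' @export
em_controls <- function(max_iter = 1000L, rel_tol = 1e-8, cov_det_floor = 1e-9,
                        eig_floor = 1e-6, kmeans_restarts = 10L,
                        em_restarts = 4L, short_iter = 30L, seed = NULL,
                        update_known = TRUE) {
  stopifnot(max_iter >= 1, rel_tol > 0, rel_tol < 1, cov_det_floor > 0,
            eig_floor > 0, kmeans_restarts >= 1, em_restarts >= 1,
            short_iter >= 1)
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 cov_det_floor = cov_det_floor, eig_floor = eig_floor,
                 kmeans_restarts = as.integer(kmeans_restarts),
                 em_restarts = as.integer(em_restarts),
                 short_iter = as.integer(short_iter), seed = seed,
                 update_known = isTRUE(update_known)),
            class = "em_controls")
}

#' Multivariate normal log-density
#'
#' Log of the MVN density, evaluated stably through the Cholesky factor of
#' the covariance (no explicit inverse).
#'
#' @param x Numeric vector, or matrix with one observation per row.
#' @param mu Mean vector.
#' @param cov Positive-definite covariance matrix.
#' @return Scalar, or vector with one value per row of `x`.
#' @export
mvn_logdensity <- function(x, mu, cov) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  J <- length(mu)
  if (ncol(x) != J) stop("dimension mismatch between x and mu")
  R <- tryCatch(chol(cov), error = function(e)
    stop("covariance matrix is not positive definite"))
  z <- backsolve(R, t(x) - as.numeric(mu), transpose = TRUE)
  out <- -0.5 * J * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z * z)
  if (length(out) == 1L) out[[1L]] else out
}

#' Enforce the covariance constraint
#'
#' Symmetrizes, floors eigenvalues at `eig_floor`, and — if the determinant
#' is still below `cov_det_floor` — adds the smallest multiple of the
#' identity that restores it. Applied after every M-step so all component
#' covariances stay positive definite with bounded-below volume.
#'
#' @param cov Symmetric matrix (possibly degenerate).
#' @param controls An [em_controls()] list.
#' @return Positive-definite matrix with `det >= cov_det_floor`.
#' @export
regularize_cov <- function(cov, controls = em_controls()) {
  S <- (cov + t(cov)) / 2
  # fast path: if S is PD and a conservative lower bound on its smallest
  # eigenvalue (det / trace^(J-1)) clears the floor, no repair is needed
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(R)) {
    dt <- prod(diag(R))^2
    lam_min_lb <- dt / max(sum(diag(S)), .Machine$double.eps)^(nrow(S) - 1L)
    if (dt >= controls$cov_det_floor && lam_min_lb >= controls$eig_floor)
      return(S)
  }
  ee <- eigen(S, symmetric = TRUE)
  lam <- pmax(ee$values, controls$eig_floor)
  floor_log <- log(controls$cov_det_floor)
  if (sum(log(lam)) < floor_log) {
    f <- function(tau) sum(log(lam + tau)) - floor_log
    upper <- controls$cov_det_floor^(1 / length(lam)) + 1
    tau <- stats::uniroot(f, c(0, upper), tol = 1e-15)$root
    lam <- lam + tau
  }
  S <- ee$vectors %*% (lam * t(ee$vectors))
  (S + t(S)) / 2
}

# --- internal component bookkeeping ---------------------------------------
# a component is list(mu, cov, provenance); provenance is a known source id
# or "novel-<i>"

comp_provenance <- function(components)
  vapply(components, function(c) c$provenance, "")

# labeled row indices per component; errors on unmatched labels
label_index <- function(src, components) {
  prov <- comp_provenance(components)
  lapply(prov, function(p) which(src == p))
}

check_labels_covered <- function(src, components) {
  prov <- comp_provenance(components)
  bad <- setdiff(unique(src[!is.na(src)]), prov)
  if (length(bad))
    stop("labeled source(s) with no matching component: ",
         paste(bad, collapse = ", "))
}

#' Joint log-likelihood of nursery-source and mixed-stock data
#'
#' Labeled rows contribute the log-density under their own source's
#' component; unlabeled rows contribute the log of the K-component mixture
#' density \eqn{f(x) = \sum_k p_k g(x; \mu_k, \Sigma_k)}. This is the
#' objective the unconditional EM maximizes.
#'
#' @param labeled Labeled observation table (may have 0 rows).
#' @param mixed Unlabeled observation table (may have 0 rows).
#' @param p Mixing proportions, length K.
#' @param components List of K components, each `list(mu, cov, provenance)`.
#' @param panel Variable names; defaults to the mixed (or labeled) table's.
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(labeled, mixed, p, components,
                         panel = obs_panel(if (nrow(mixed)) mixed else labeled)) {
  K <- length(components)
  if (length(p) != K) stop("length of p must equal the number of components")
  ll <- 0
  if (nrow(labeled)) {
    check_labels_covered(labeled$source, components)
    Xl <- obs_matrix(labeled, panel)
    idx <- label_index(labeled$source, components)
    for (k in seq_len(K)) if (length(idx[[k]]))
      ll <- ll + sum(mvn_logdensity(Xl[idx[[k]], , drop = FALSE],
                                    components[[k]]$mu, components[[k]]$cov))
  }
  if (nrow(mixed)) {
    Xm <- obs_matrix(mixed, panel)
    L <- vapply(seq_len(K), function(k)
      log(p[k]) + mvn_logdensity(Xm, components[[k]]$mu, components[[k]]$cov),
      numeric(nrow(Xm)))
    if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
    mx <- apply(L, 1L, max)
    ll <- ll + sum(mx + log(rowSums(exp(L - mx))))
  }
  ll
}

#' Initial parameters for the known (sampled) sources
#'
#' Per-source sample mean and sample covariance (denominator n - 1) computed
#' directly from the labeled nursery-source dataset. Sources with fewer than
#' J + 2 rows, or with a degenerate sample covariance, fall back to the
#' pooled within-source covariance of the whole labeled dataset
#' (regularized).
#'
#' @param labeled Labeled observation table.
#' @param controls An [em_controls()] list (regularization of fallbacks).
#' @param panel Variable names.
#' @return List of components tagged with their source ids (empty when the
#'   table is empty — the K_S = 0 scenario).
#' @export
init_known <- function(labeled, controls = em_controls(),
                       panel = obs_panel(labeled)) {
  if (!nrow(labeled)) return(list())
  X <- obs_matrix(labeled, panel)
  src <- labeled$source
  if (anyNA(src)) stop("nursery-source dataset contains unlabeled rows")
  ids <- unique(src)
  J <- ncol(X)
  # pooled within-source ML covariance, the fallback for thin groups
  ctr <- X
  for (sid in ids) {
    i <- src == sid
    ctr[i, ] <- sweep(X[i, , drop = FALSE], 2L, colMeans(X[i, , drop = FALSE]))
  }
  pooled <- regularize_cov(crossprod(ctr) / nrow(X), controls)
  lapply(ids, function(sid) {
    Xi <- X[src == sid, , drop = FALSE]
    mu <- colMeans(Xi)
    cv <- if (nrow(Xi) >= J + 2L) stats::cov(Xi) else pooled
    if (!all(is.finite(cv)) || min(eigen((cv + t(cv)) / 2, symmetric = TRUE,
                                         only.values = TRUE)$values) <= controls$eig_floor)
      cv <- pooled
    list(mu = as.numeric(mu), cov = regularize_cov(cv, controls),
         provenance = sid)
  })
}

#' Semi-supervised K-means with fixed and mobile centroids
#'
#' Lloyd iterations over the mixed-stock data in which every observation is
#' assigned to its nearest centroid — fixed (the known sources' means) or
#' mobile — but only the mobile centroids are updated. The best of
#' `restarts` random initializations by total within-cluster sum of squares
#' is kept. This seeds the starting means of the K_U unsampled sources.
#'
#' @param mixed Unlabeled observation table.
#' @param fixed_centroids Matrix (rows = fixed centroids) or `NULL`.
#' @param K_U Number of mobile centroids (>= 1).
#' @param controls An [em_controls()] list (`kmeans_restarts`, `seed`).
#' @param panel Variable names.
#' @return List with `centers` (K_U x J mobile centroids), `assignments`
#'   (index into fixed then mobile centroids, per row), `wss`.
#' @export
seeded_kmeans <- function(mixed, fixed_centroids = NULL, K_U,
                          controls = em_controls(), panel = obs_panel(mixed)) {
  X <- obs_matrix(mixed, panel)
  n <- nrow(X)
  if (K_U < 1L) stop("K_U must be >= 1")
  if (K_U > n) stop("more mobile centroids than observations")
  F0 <- if (is.null(fixed_centroids)) matrix(numeric(0), 0L, ncol(X))
        else as.matrix(fixed_centroids)
  KF <- nrow(F0)
  if (!is.null(controls$seed)) set.seed(child_seed(controls$seed, 557L))
  x2 <- rowSums(X * X)
  assign_step <- function(C) {
    # n x (KF+K_U) squared distances via the expansion trick
    D <- outer(x2, rowSums(C * C), `+`) - 2 * X %*% t(C)
    a <- max.col(-D, ties.method = "first")
    list(a = a, d = D[cbind(seq_len(n), a)])
  }
  best <- NULL
  for (r in seq_len(controls$kmeans_restarts)) {
    mob <- X[sample.int(n, K_U), , drop = FALSE]
    a_old <- integer(n)
    for (it in seq_len(100L)) {
      st <- assign_step(rbind(F0, mob))
      if (identical(st$a, a_old)) break
      a_old <- st$a
      for (j in seq_len(K_U)) {
        rows <- which(st$a == KF + j)
        if (length(rows)) mob[j, ] <- colMeans(X[rows, , drop = FALSE])
        else mob[j, ] <- X[which.max(st$d), ]     # re-seed empty cluster
      }
    }
    st <- assign_step(rbind(F0, mob))
    wss <- sum(st$d)
    if (is.null(best) || wss < best$wss)
      best <- list(centers = mob, assignments = st$a, wss = wss, n_fixed = KF)
  }
  best
}

#' Initial parameters for the unknown (unsampled) sources
#'
#' Sample mean and covariance of the mixed-stock observations clustered
#' into each mobile K-means cluster. Clusters thinner than J + 2 rows (or
#' empty: the centroid is kept) get the pooled covariance of the whole
#' mixed-stock dataset.
#'
#' @param mixed Unlabeled observation table.
#' @param km Result of [seeded_kmeans()].
#' @param controls An [em_controls()] list.
#' @param panel Variable names.
#' @return List of components tagged `novel-1..novel-K_U`.
#' @export
init_unknown <- function(mixed, km, controls = em_controls(),
                         panel = obs_panel(mixed)) {
  X <- obs_matrix(mixed, panel)
  J <- ncol(X)
  K_U <- nrow(km$centers)
  KF <- km$n_fixed
  pooled <- regularize_cov(stats::cov(X), controls)
  lapply(seq_len(K_U), function(j) {
    rows <- which(km$assignments == KF + j)
    if (length(rows) >= J + 2L) {
      Xi <- X[rows, , drop = FALSE]
      mu <- colMeans(Xi)
      cv <- regularize_cov(stats::cov(Xi), controls)
    } else {
      mu <- km$centers[j, ]
      cv <- pooled
    }
    list(mu = as.numeric(mu), cov = cv, provenance = paste0("novel-", j))
  })
}

#' Initial mixing proportions by hard density assignment
#'
#' Assigns every mixed-stock observation to the component under which its
#' density is highest (equal-prior comparison), and returns the empirical
#' proportions. Components that capture no observation are floored at
#' 1/(2 n) and the vector renormalized, so no starting weight is exactly 0.
#'
#' @param mixed Unlabeled observation table.
#' @param components List of K components.
#' @param panel Variable names.
#' @return Length-K proportion vector on the open simplex.
#' @export
init_proportions <- function(mixed, components, panel = obs_panel(mixed)) {
  X <- obs_matrix(mixed, panel)
  n <- nrow(X)
  K <- length(components)
  L <- vapply(seq_len(K), function(k)
    mvn_logdensity(X, components[[k]]$mu, components[[k]]$cov), numeric(n))
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  hard <- max.col(L, ties.method = "first")
  p <- tabulate(hard, K) / n
  p[p == 0] <- 1 / (2 * n)
  p / sum(p)
}

#' Unconditional EM fit of the mixture model
#'
#' Maximizes the joint likelihood of the labeled nursery-source data and the
#' unlabeled mixed-stock data. Labeled rows carry fixed unit membership in
#' their own source's component; mixed rows get E-step responsibilities
#' \eqn{z_{jk} = p_k g(y_j;\theta_k) / \sum_l p_l g(y_j;\theta_l)}. The
#' M-step updates the mixing proportions from mixed-row responsibilities
#' only (nursery sampling is by design, not proportional to stock
#' composition), and updates each component's mean and ML covariance from
#' its labeled rows plus responsibility-weighted mixed rows, re-applying the
#' covariance constraint every iteration.
#'
#' @param labeled Labeled observation table (0 rows allowed).
#' @param mixed Unlabeled observation table (0 rows allowed).
#' @param K Number of components (>= number of distinct labeled sources).
#' @param init List with `p` (length K) and `components` (length K), e.g.
#'   assembled by [fit_mixture()]'s initialization pipeline.
#' @param controls An [em_controls()] list.
#' @param panel Variable names.
#' @return Object of class `mixture_fit`: `K`, `p_hat`, `components`
#'   (each with `mu`, `cov`, `provenance`), `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, `monotone`, `provenance`, `n_labeled`,
#'   `n_mixed`, `n_obs`, `panel`, `notes`.
#' @export
em_fit <- function(labeled, mixed, K, init, controls = em_controls(),
                   panel = obs_panel(if (nrow(mixed)) mixed else labeled)) {
  K <- as.integer(K)
  nl <- nrow(labeled); nm <- nrow(mixed)
  if (nl) {
    src_ids <- unique(labeled$source)
    if (K < length(src_ids))
      stop("K is smaller than the number of distinct labeled sources")
  }
  comps <- lapply(init$components, function(c)
    list(mu = as.numeric(c$mu), cov = regularize_cov(c$cov, controls),
         provenance = c$provenance))
  if (length(comps) != K) stop("init must supply exactly K components")
  p <- as.numeric(init$p)
  if (length(p) != K || any(p < 0)) stop("invalid initial proportions")
  p <- p / sum(p)

  Xl <- if (nl) obs_matrix(labeled, panel) else matrix(numeric(0), 0L, length(panel))
  Xm <- if (nm) obs_matrix(mixed, panel) else matrix(numeric(0), 0L, length(panel))
  J <- length(panel)
  if (nl) check_labels_covered(labeled$source, comps)
  idx <- if (nl) label_index(labeled$source, comps) else rep(list(integer(0)), K)
  nlab_k <- lengths(idx)
  notes <- character(0)

  finish <- function(p, comps, trace, n_iter, converged, monotone) {
    structure(list(K = K, p_hat = p, components = comps,
                   loglik = trace[length(trace)], loglik_trace = trace,
                   n_iter = n_iter, converged = converged, monotone = monotone,
                   provenance = comp_provenance(comps),
                   n_labeled = nl, n_mixed = nm, n_obs = nl + nm,
                   panel = panel, notes = notes),
              class = "mixture_fit")
  }

  if (nm == 0L) {                      # labeled-only: closed-form per-source fit
    notes <- c(notes, "no mixed-stock data: mixing proportions undefined (uniform)")
    p <- rep(1 / K, K)
    for (k in seq_len(K)) if (nlab_k[k]) {
      Xi <- Xl[idx[[k]], , drop = FALSE]
      comps[[k]]$mu <- colMeans(Xi)
      comps[[k]]$cov <- regularize_cov(crossprod(sweep(Xi, 2L, comps[[k]]$mu)) /
                                         nrow(Xi), controls)
    }
    ll <- joint_loglik(labeled, mixed, p, comps, panel)
    return(finish(p, comps, ll, 0L, TRUE, TRUE))
  }

  if (K == 1L) {                       # single component: closed form
    X <- rbind(Xl, Xm)
    mu <- colMeans(X)
    cv <- regularize_cov(crossprod(sweep(X, 2L, mu)) / nrow(X), controls)
    comps <- list(list(mu = as.numeric(mu), cov = cv,
                       provenance = comps[[1L]]$provenance))
    ll <- joint_loglik(labeled, mixed, 1, comps, panel)
    return(finish(1, comps, ll, 0L, TRUE, TRUE))
  }

  const <- -0.5 * J * log(2 * pi)
  comp_logdens <- function(c, X) {
    R <- chol(c$cov)
    z <- backsolve(R, t(X) - c$mu, transpose = TRUE)
    const - sum(log(diag(R))) - 0.5 * colSums(z * z)
  }
  ll_old <- -Inf
  trace <- numeric(0)
  monotone <- TRUE
  converged <- FALSE
  it <- 0L
  repeat {
    # E-step + current log-likelihood
    Lm <- vapply(comps, function(c) comp_logdens(c, Xm), numeric(nm))
    if (is.null(dim(Lm))) Lm <- matrix(Lm, nrow = 1L)
    Lp <- Lm + rep(log(p), each = nm)
    mx <- Lp[, 1L]
    for (k in seq_len(K)[-1L]) mx <- pmax(mx, Lp[, k])
    lse <- mx + log(rowSums(exp(Lp - mx)))
    ll <- sum(lse)
    if (nl) for (k in seq_len(K)) if (nlab_k[k])
      ll <- ll + sum(comp_logdens(comps[[k]], Xl[idx[[k]], , drop = FALSE]))
    if (!is.finite(ll)) stop("non-finite log-likelihood at EM iteration ", it)
    trace <- c(trace, ll)
    if (it > 0L) {
      if (ll < ll_old - 1e-9 * (1 + abs(ll_old))) monotone <- FALSE
      if (abs(ll - ll_old) < controls$rel_tol * (abs(ll_old) + 1e-3)) {
        converged <- TRUE
        break
      }
    }
    if (it >= controls$max_iter) break
    it <- it + 1L
    ll_old <- ll
    resp <- exp(Lp - lse)              # n_m x K responsibilities
    # M-step
    p <- colMeans(resp)
    p <- pmax(p, 0)
    p <- p / sum(p)
    for (k in seq_len(K)) {
      known <- !startsWith(comps[[k]]$provenance, "novel-")
      if (known && !controls$update_known) next
      wk <- resp[, k]
      wsum <- nlab_k[k] + sum(wk)
      if (wsum < 1e-8) next            # vanished component: keep parameters
      Xk <- Xl[idx[[k]], , drop = FALSE]
      mu <- (colSums(Xk) + colSums(Xm * wk)) / wsum
      Dl <- Xk - rep(mu, each = nrow(Xk))
      Dm <- Xm - rep(mu, each = nm)
      S <- (crossprod(Dl) + crossprod(Dm * sqrt(wk))) / wsum
      comps[[k]]$mu <- as.numeric(mu)
      comps[[k]]$cov <- regularize_cov(S, controls)
    }
  }
  finish(p, comps, trace, it, converged, monotone)
}

#' Full initialization + EM pipeline
#'
#' The standard fitting sequence for one (nursery-source, mixed-stock) data
#' pair at a given K: per-source starting values from the labeled data
#' ([init_known()]), mobile centroids for the K_U unsampled sources by
#' semi-supervised K-means ([seeded_kmeans()]), their starting covariances
#' from the induced clusters ([init_unknown()]), starting proportions by
#' hard density assignment ([init_proportions()]), then the unconditional
#' EM ([em_fit()]). When K_U > 0 the likelihood surface is multimodal, so
#' `em_restarts` independent initializations are explored with short EM
#' runs and the best by log-likelihood is run to convergence.
#'
#' @param labeled Labeled observation table (0 rows for the K_S = 0
#'   scenario).
#' @param mixed Unlabeled observation table.
#' @param K Total number of components to fit.
#' @param controls An [em_controls()] list.
#' @param panel Variable names.
#' @return A `mixture_fit` (see [em_fit()]).
#' @export
fit_mixture <- function(labeled, mixed, K, controls = em_controls(),
                        panel = obs_panel(if (nrow(mixed)) mixed else labeled)) {
  known <- init_known(labeled, controls, panel)
  K_S <- length(known)
  K_U <- K - K_S
  if (K_U < 0L) stop("K is smaller than the number of labeled sources")
  if (K_U == 0L || !nrow(mixed)) {
    if (K_U > 0L) stop("unsampled sources require mixed-stock data")
    p0 <- if (nrow(mixed)) init_proportions(mixed, known, panel)
          else rep(1 / K, K)
    return(em_fit(labeled, mixed, K, list(p = p0, components = known),
                  controls, panel))
  }
  fixed <- if (K_S) do.call(rbind, lapply(known, `[[`, "mu")) else NULL
  base_seed <- if (is.null(controls$seed)) sample.int(2147483646L, 1L)
               else controls$seed
  short <- controls
  short$max_iter <- min(controls$short_iter, controls$max_iter)
  best <- NULL
  for (i in seq_len(controls$em_restarts)) {
    ctl_i <- controls
    ctl_i$seed <- child_seed(base_seed, 71L, i)
    km <- seeded_kmeans(mixed, fixed, K_U, ctl_i, panel)
    comps <- c(known, init_unknown(mixed, km, controls, panel))
    p0 <- init_proportions(mixed, comps, panel)
    f <- em_fit(labeled, mixed, K, list(p = p0, components = comps),
                short, panel)
    if (is.null(best) || f$loglik > best$loglik) best <- f
  }
  if (best$converged && controls$em_restarts > 1L) return(best)
  em_fit(labeled, mixed, K, list(p = best$p_hat, components = best$components),
         controls, panel)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Mixture fit: K = %d (%d labeled + %d mixed obs), loglik = %.3f\n",
              x$K, x$n_labeled, x$n_mixed, x$loglik))
  cat(sprintf("  %s after %d iterations\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  tab <- data.frame(component = x$provenance, p_hat = round(x$p_hat, 4))
  print(tab, row.names = FALSE)
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize / restore a mixture fit
#'
#' Writes the fitted parameters, provenance tags, iteration count and
#' convergence flags to a JSON file at full double precision.
#'
#' @param fit A `mixture_fit`.
#' @param path Output path.
#' @return `write_mixture_fit()` returns `path` invisibly;
#'   `read_mixture_fit()` returns the restored list (plain, not re-classed).
#' @export
write_mixture_fit <- function(fit, path) {
  obj <- list(K = fit$K, p_hat = fit$p_hat,
              components = lapply(fit$components, function(c)
                list(mu = c$mu, cov = as.numeric(c$cov),
                     provenance = c$provenance)),
              J = length(fit$panel), panel = as.character(fit$panel),
              loglik = fit$loglik, n_iter = fit$n_iter,
              trace_length = length(fit$loglik_trace),
              converged = fit$converged, monotone = fit$monotone,
              notes = fit$notes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixture_fit
#' @export
read_mixture_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  J <- obj$J
  if (is.data.frame(obj$components)) {
    obj$components <- lapply(seq_len(nrow(obj$components)), function(i)
      list(mu = obj$components$mu[[i]],
           cov = matrix(obj$components$cov[[i]], J, J),
           provenance = obj$components$provenance[[i]]))
  } else {
    obj$components <- lapply(obj$components, function(c)
      list(mu = c$mu, cov = matrix(c$cov, J, J), provenance = c$provenance))
  }
  obj
}
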