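test_that("MVN log-density matches closed forms and is translation invariant", {
  expect_equal(mvn_logdensity(0, 0, matrix(1)), -0.5 * log(2 * pi))
  expect_equal(mvn_logdensity(c(1, 2), c(0, 0), diag(c(1, 4))),
               -(log(2 * pi) + 0.5 * log(4) + 0.5 * (1 + 1)))
  set.seed(2)
  x <- rnorm(3); mu <- rnorm(3); sh <- rnorm(3)
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  expect_equal(mvn_logdensity(x, mu, S), mvn_logdensity(x + sh, mu + sh, S))
  # vectorized rows agree with per-row evaluation and with dmvnorm oracle
  X <- matrix(rnorm(15), 5, 3)
  v <- mvn_logdensity(X, mu, S)
  expect_equal(v[2], mvn_logdensity(X[2, ], mu, S))
  expect_equal(exp(v[4]), naive_dmvnorm(X[4, ], mu, S))
  expect_error(mvn_logdensity(x, mu, matrix(1, 3, 3)), "positive definite")
})

test_that("covariance regularization restores the determinant floor", {
  ctl <- em_controls()
  S <- crossprod(matrix(rnorm(9, sd = 2), 3)) + diag(3)
  expect_equal(regularize_cov(S, ctl), (S + t(S)) / 2, tolerance = 1e-10)
  # rank-deficient input is repaired
  R1 <- regularize_cov(matrix(1, 3, 3), ctl)
  expect_gte(det(R1), ctl$cov_det_floor * (1 - 1e-8))
  expect_gt(min(eigen(R1, only.values = TRUE)$values), 0)
  # eigenvalue flooring alone already clears the determinant floor here
  R2 <- regularize_cov(diag(c(1, 1e-18)), ctl)
  expect_gte(det(R2), ctl$cov_det_floor)
  # with a tiny eigenvalue floor the isotropic inflation step must engage,
  # landing exactly on the determinant floor
  ctl2 <- em_controls(eig_floor = 1e-12)
  R3 <- regularize_cov(diag(c(1, 1e-18)), ctl2)
  expect_equal(det(R3), ctl2$cov_det_floor, tolerance = 1e-6)
})

test_that("joint log-likelihood equals a brute-force per-point sum", {
  comps <- list(list(mu = c(0, 0), cov = diag(2), provenance = "A"),
                list(mu = c(3, 1), cov = diag(c(2, 1)), provenance = "novel-1"))
  p <- c(0.4, 0.6)
  lab <- observation_table(rbind(c(0.5, -0.2)), cohort = "t", source = "A",
                           panel = c("x", "y"))
  mix <- observation_table(rbind(c(0, 0), c(3, 1), c(1.5, 0.5)), cohort = "t",
                           panel = c("x", "y"))
  X <- as.matrix(mix[, c("x", "y")])
  expected <- log(naive_dmvnorm(c(0.5, -0.2), comps[[1]]$mu, comps[[1]]$cov)) +
    naive_mixture_loglik(X, p, lapply(comps, `[[`, "mu"), lapply(comps, `[[`, "cov"))
  expect_equal(joint_loglik(lab, mix, p, comps), expected)
  # empty labeled set reduces to the pure mixture log-likelihood
  expect_equal(joint_loglik(lab[0, ], mix, p, comps),
               naive_mixture_loglik(X, p, lapply(comps, `[[`, "mu"),
                                    lapply(comps, `[[`, "cov")))
  # K = 1 reduces to the total MVN log-likelihood
  one <- list(list(mu = c(1, 1), cov = diag(2), provenance = "novel-1"))
  expect_equal(joint_loglik(lab[0, ], mix, 1, one),
               sum(mvn_logdensity(X, c(1, 1), diag(2))))
  expect_error(joint_loglik(
    observation_table(rbind(c(0, 0)), source = "Z", panel = c("x", "y")),
    mix, p, comps), "no matching component")
})

test_that("known-source initialization uses per-source sample moments", {
  lab <- observation_table(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)),
                           cohort = "t", source = "A", panel = c("x", "y"))
  ck <- init_known(lab)
  expect_length(ck, 1)
  expect_equal(ck[[1]]$mu, c(1, 1))
  expect_equal(ck[[1]]$provenance, "A")
  expect_equal(ck[[1]]$cov, cov(cbind(c(0, 2, 0, 2), c(0, 0, 2, 2))),
               tolerance = 1e-8, ignore_attr = TRUE)
  # K_S = 0 gives an empty parameter set
  expect_length(init_known(lab[0, ]), 0)
  # duplicate-only rows trigger the regularized fallback (still PD)
  dup <- observation_table(matrix(1, 5, 2), cohort = "t", source = "B",
                           panel = c("x", "y"))
  cd <- init_known(dup)
  expect_gt(min(eigen(cd[[1]]$cov, only.values = TRUE)$values), 0)
})

test_that("seeded K-means moves only mobile centroids", {
  tab <- two_blob_table(n_per = 40, delta = 10, seed = 3)
  ctl <- em_controls(seed = 1)
  # no fixed centroids: ordinary K-means recovers the two blobs
  km <- seeded_kmeans(tab, NULL, K_U = 2, ctl)
  cx <- sort(km$centers[, 1])
  expect_lt(abs(cx[1] - 0), 1)
  expect_lt(abs(cx[2] - 10), 1)
  # a fixed centroid on blob A forces the mobile one into blob B
  km2 <- seeded_kmeans(tab, matrix(c(0, 0), 1), K_U = 1, ctl)
  expect_lt(abs(km2$centers[1, 1] - 10), 1)
  expect_equal(km2$n_fixed, 1)
  # assignments cover fixed and mobile indices
  expect_setequal(sort(unique(km2$assignments)), c(1, 2))
  expect_error(seeded_kmeans(tab, NULL, K_U = 1000, ctl), "more mobile")
  # a mobile centroid initialized near the fixed cluster migrates to the
  # uncovered far cluster (checked against exhaustive 2-assignment optimum)
  wss_opt <- sum((tab$x - ifelse(tab$x > 5, 10, 0))^2 + tab$y^2) # near-truth split
  expect_lt(km2$wss, wss_opt * 1.05)
})

test_that("starting proportions come from hard density assignment", {
  comps <- list(list(mu = c(-3, 0), cov = diag(2), provenance = "A"),
                list(mu = c(3, 0), cov = diag(2), provenance = "B"))
  X <- rbind(c(-3, 0.1), c(-2.5, 0), c(3, 0), c(2.8, -0.2))
  tab <- observation_table(X, panel = c("x", "y"))
  expect_equal(init_proportions(tab, comps), c(0.5, 0.5))
  # matches the brute-force per-point density comparison
  hard <- apply(X, 1, function(x)
    which.max(c(naive_dmvnorm(x, comps[[1]]$mu, comps[[1]]$cov),
                naive_dmvnorm(x, comps[[2]]$mu, comps[[2]]$cov))))
  expect_equal(init_proportions(tab, comps),
               as.numeric(table(factor(hard, 1:2)) / 4))
  # empty components are floored, never exactly zero
  far <- observation_table(matrix(rnorm(20, -3, 0.1), 10, 2), panel = c("x", "y"))
  p <- init_proportions(far, comps)
  expect_gt(p[2], 0)
  expect_equal(sum(p), 1)
})

test_that("K = 1 EM reduces to the pooled closed form", {
  tab <- two_blob_table(n_per = 15, delta = 2, seed = 4)
  f <- fit_mixture(tab[0, ], tab, 1, em_controls(seed = 1))
  X <- as.matrix(tab[, c("x", "y")])
  expect_equal(f$p_hat, 1)
  expect_equal(f$components[[1]]$mu, colMeans(X), ignore_attr = TRUE)
  expect_equal(f$components[[1]]$cov,
               crossprod(sweep(X, 2, colMeans(X))) / nrow(X),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(f$converged)
})

test_that("EM log-likelihood is monotone and proportions stay on the simplex", {
  set.seed(6)
  base <- random_baseline(K = 3, J = 4, target_sep = 2, spread = 0.5, seed = 6)
  for (ks in c(0, 2, 3)) {
    sampled <- if (ks) paste0("S", 1:ks) else character(0)
    lab <- draw_nursery_dataset(base, sampled, 20, seed = 10 + ks)
    md <- draw_mixed_dataset(base, c(0.2, 0.3, 0.5), 90, seed = 20 + ks)
    f <- fit_mixture(lab, md$table, 3, em_controls(seed = 30 + ks))
    expect_true(f$monotone)
    expect_gte(min(diff(f$loglik_trace)), -1e-9 * (1 + abs(f$loglik)))
    expect_equal(sum(f$p_hat), 1, tolerance = 1e-10)
    expect_true(all(f$p_hat >= 0 & f$p_hat <= 1))
    for (c in f$components) {
      ev <- eigen(c$cov, only.values = TRUE)$values
      expect_gt(min(ev), 0)
      expect_gte(det(c$cov), em_controls()$cov_det_floor * (1 - 1e-6))
    }
  }
})

test_that("EM recovers proportions at strong separation", {
  s1 <- nursery_signature("A", c(0, 0), diag(2))
  s2 <- nursery_signature("B", c(5, 0), diag(2))   # identity-scale sep 25
  set <- signature_set(list(s1, s2), cohort_id = "sep25", panel = c("x", "y"))
  lab <- draw_nursery_dataset(set, c("A", "B"), 25, seed = 1)
  md <- draw_mixed_dataset(set, c(0.3, 0.7), 400, seed = 2)
  f <- fit_mixture(lab, md$table, 2, em_controls(seed = 3))
  rec <- make_run_record(f, md$truth)
  expect_lt(max(abs(rec$p_hat - rec$p_true)), 0.05)
})

test_that("proportions are recovered accurately at well-separated baselines", {
  # 4 sources at average squared separation 5, two sampled, 400-fish mixed
  # stocks: mean absolute proportion error stays below 0.03 across seeds
  errs <- vapply(1:10, function(s) {
    b <- random_baseline(4, 7, 5.0, 0.5, seed = 1000 + s)
    lab <- draw_nursery_dataset(b, paste0("S", 1:2), 25, seed = s * 3 + 1)
    md <- draw_mixed_dataset(b, n_mixed = 400, seed = s * 3 + 2)
    f <- fit_mixture(lab, md$table, 4, em_controls(seed = s * 3 + 3))
    rec <- make_run_record(f, md$truth)
    mean(abs(rec$p_hat - rec$p_true))
  }, 0)
  expect_lt(mean(errs), 0.03)
})

test_that("labeled-only fits return per-source estimates and flag p as undefined", {
  base <- random_baseline(K = 2, J = 3, target_sep = 3, spread = 0.5, seed = 8)
  lab <- draw_nursery_dataset(base, c("S1", "S2"), 30, seed = 1)
  f <- fit_mixture(lab, lab[0, ], 2, em_controls(seed = 1))
  expect_equal(f$p_hat, c(0.5, 0.5))
  expect_match(paste(f$notes, collapse = " "), "undefined")
  X1 <- as.matrix(lab[lab$source == "S1", as.character(base$panel)])
  k1 <- match("S1", f$provenance)
  expect_equal(f$components[[k1]]$mu, colMeans(X1), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(fit_mixture(lab, lab[0, ], 1, em_controls()), "smaller")
})

test_that("with no labeled data the EM agrees with an independent GMM EM", {
  tab <- two_blob_table(n_per = 30, delta = 6, sigma = 1, seed = 12)
  X <- as.matrix(tab[, c("x", "y")])
  # identical starting point for both implementations
  start_p <- c(0.5, 0.5)
  start_mu <- list(c(-1, 0), c(7, 0))
  start_cov <- list(diag(2), diag(2))
  comps <- list(list(mu = start_mu[[1]], cov = start_cov[[1]], provenance = "novel-1"),
                list(mu = start_mu[[2]], cov = start_cov[[2]], provenance = "novel-2"))
  f <- em_fit(tab[0, ], tab, 2, list(p = start_p, components = comps),
              em_controls(rel_tol = 1e-12))
  o <- naive_gmm_em(X, start_p, start_mu, start_cov, tol = 1e-12)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-6)
  ord <- order(vapply(f$components, function(c) c$mu[1], 0))
  oord <- order(vapply(o$mus, `[[`, 0, 1))
  expect_equal(f$p_hat[ord], o$p[oord], tolerance = 1e-5)
  expect_equal(f$components[[ord[1]]]$mu, o$mus[[oord[1]]], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("mixture fits serialize losslessly to JSON", {
  base <- random_baseline(K = 2, J = 3, target_sep = 4, spread = 0.5, seed = 5)
  lab <- draw_nursery_dataset(base, c("S1", "S2"), 20, seed = 1)
  md <- draw_mixed_dataset(base, c(0.4, 0.6), 50, seed = 2)
  f <- fit_mixture(lab, md$table, 2, em_controls(seed = 3))
  path <- tempfile(fileext = ".json")
  write_mixture_fit(f, path)
  back <- read_mixture_fit(path)
  expect_equal(back$p_hat, f$p_hat)
  expect_equal(back$loglik, f$loglik)
  expect_equal(back$components[[1]]$cov, f$components[[1]]$cov,
               ignore_attr = TRUE)
  expect_equal(back$components[[2]]$provenance, f$components[[2]]$provenance)
  unlink(path)
})
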