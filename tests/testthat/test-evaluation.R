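mu4 <- matrix(rnorm(28, sd = 2), 4, 7,
              dimnames = list(paste0("S", 1:4), default_panel()))

# mixture_fit stub with prescribed means/provenance
stub_fit <- function(mus, prov) {
  structure(list(K = nrow(mus),
                 p_hat = rep(1 / nrow(mus), nrow(mus)),
                 components = lapply(seq_len(nrow(mus)), function(i)
                   list(mu = mus[i, ], cov = diag(ncol(mus)),
                        provenance = prov[i])),
                 provenance = prov, panel = colnames(mus)),
            class = "mixture_fit")
}

test_that("component matching pins known sources and optimally assigns novel ones", {
  # all known: identity mapping
  f <- stub_fit(mu4, rownames(mu4))
  expect_equal(match_components(f, mu4), 1:4)
  # fitted means equal to a permutation of the truth recover that permutation
  prm <- c(3, 1, 4, 2)
  f2 <- stub_fit(mu4[prm, ], paste0("novel-", 1:4))
  expect_equal(match_components(f2, mu4), prm)
  # mixed known/novel: known pinned even when a novel centroid is closer
  f3 <- stub_fit(rbind(mu4["S2", ] + 0.01, mu4[c("S1", "S3", "S4"), ]),
                 c("S2", paste0("novel-", 1:3)))
  expect_equal(match_components(f3, mu4), c(2, 1, 3, 4))
  # 3 novel components: agrees with brute-force enumeration of all 3! costs
  set.seed(4)
  noisy <- mu4[2:4, ] + matrix(rnorm(21, sd = 0.5), 3, 7)
  f4 <- stub_fit(rbind(mu4["S1", ], noisy[c(2, 3, 1), ]),
                 c("S1", paste0("novel-", 1:3)))
  got <- match_components(f4, mu4)
  perms <- list(c(2,3,4), c(2,4,3), c(3,2,4), c(3,4,2), c(4,2,3), c(4,3,2))
  costs <- vapply(perms, function(pr)
    sum((rbind(noisy[c(2, 3, 1), ]) - mu4[pr, ])^2), 0)
  expect_equal(got[2:4], perms[[which.min(costs)]])
  expect_error(match_components(stub_fit(mu4[1:3, ], paste0("novel-", 1:3)), mu4),
               "differs")
})

test_that("proportion bias follows its defining equation", {
  p_true <- c(0.1, 0.2, 0.3, 0.4)
  perfect <- fake_record(p_true, p_true, mu4, mu4)
  expect_equal(bias_p(list(perfect, perfect)), 0)
  # single run, hand arithmetic: four errors of 0.05 sum to 0.20
  r1 <- fake_record(p_true, c(0.15, 0.25, 0.25, 0.35), mu4, mu4)
  expect_equal(bias_p(list(r1)), 0.20)
  # absolute values do not cancel across runs
  r2a <- fake_record(p_true, c(0.2, 0.2, 0.3, 0.4), mu4, mu4)   # +0.1 at level 0.1
  r2b <- fake_record(p_true, c(0.0, 0.2, 0.3, 0.4), mu4, mu4)   # -0.1 at level 0.1
  expect_equal(bias_p(list(r2a, r2b)), 0.10)
  expect_error(bias_p(list()), "no run records")
})

test_that("proportion uncertainty is the level-averaged RMSE about truth", {
  p_true <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(se_p(list(fake_record(p_true, p_true, mu4, mu4))), 0)
  r2a <- fake_record(p_true, c(0.2, 0.2, 0.3, 0.4), mu4, mu4)
  r2b <- fake_record(p_true, c(0.0, 0.2, 0.3, 0.4), mu4, mu4)
  expect_equal(se_p(list(r2a, r2b)), 0.025)        # (1/4) * 0.1
  # a constant error gives the same value: the RMSE includes bias
  expect_equal(se_p(list(r2a, r2a)), 0.025)
  # Jensen: level-mean absolute error / M never exceeds the averaged RMSE
  set.seed(8)
  recs <- lapply(1:20, function(i) {
    e <- rnorm(4, sd = 0.05)
    fake_record(p_true, p_true + e - mean(e), mu4, mu4)
  })
  expect_gte(se_p(recs) + 1e-12, bias_p(recs) / 4)
  expect_lte(bias_p(recs), 2)                      # simplex bound
})

test_that("signature bias measures systematic displacement only", {
  p_true <- c(0.1, 0.2, 0.3, 0.4)
  shift <- mu4; shift["S2", 3] <- shift["S2", 3] + 0.2
  r <- fake_record(p_true, p_true, mu4, shift)
  expect_equal(bias_theta(list(r, r), mu4), 0.2 / 28)
  # alternating offsets cancel inside the absolute value
  shift2 <- mu4; shift2["S2", 3] <- shift2["S2", 3] - 0.2
  r2 <- fake_record(p_true, p_true, mu4, shift2)
  expect_equal(bias_theta(list(r, r2), mu4), 0)
  # invariant to relabeling sources and permuting variables
  pr <- c(4, 1, 3, 2); pv <- c(7, 3, 1, 2, 5, 6, 4)
  r_p <- fake_record(p_true[pr], p_true[pr], mu4[pr, pv],
                     shift[pr, pv])
  expect_equal(bias_theta(list(r_p, r_p), mu4[pr, pv]),
               bias_theta(list(r, r), mu4))
})

test_that("signature uncertainty is the mean effective sd of run-level means", {
  p_true <- c(0.5, 0.5)
  mu2 <- matrix(0, 2, 2, dimnames = list(c("S1", "S2"), c("x", "y")))
  same <- fake_record(p_true, p_true, mu2, mu2)
  expect_equal(se_theta(list(same, same, same)), 0)
  # four symmetric displacements give run-covariance diag(4, 4): eff sd = 2
  a <- sqrt(6)
  offs <- list(c(a, 0), c(-a, 0), c(0, a), c(0, -a))
  recs <- lapply(offs, function(o)
    fake_record(p_true, p_true, mu2, mu2 + rep(o, each = 2)))
  expect_equal(se_theta(recs), 2)
  expect_error(se_theta(recs[1]), "at least 2")
})

test_that("K metrics follow their hand-computed forms", {
  p_true <- c(0.1, 0.2, 0.3, 0.4)
  rec_k <- function(k) fake_record(p_true, p_true, mu4, mu4, K_hat = k)
  expect_equal(bias_k(list(rec_k(4), rec_k(4)), 4), 0)
  expect_equal(se_k(list(rec_k(4), rec_k(4))), 0)
  expect_equal(bias_k(list(rec_k(3), rec_k(3)), 4), -1)
  expect_equal(bias_k(list(rec_k(3), rec_k(4)), 4), -0.5)
  expect_equal(se_k(list(rec_k(3), rec_k(4))), 0.5)
  expect_error(bias_k(list(fake_record(p_true, p_true, mu4, mu4)), 4), "K_hat")
})

test_that("scenario summaries compose the per-metric results", {
  p_true <- c(0.1, 0.2, 0.3, 0.4)
  shift <- mu4 + 0.1
  recs <- list(fake_record(p_true, c(0.15, 0.25, 0.25, 0.35), mu4, shift,
                           K_hat = 3, delta_bic = 10),
               fake_record(p_true, p_true, mu4, shift, K_hat = 4,
                           delta_bic = 20))
  s <- summarize_scenario(recs, true_mu = mu4, K_true = 4, n_failed = 1)
  expect_equal(s$BI_p, bias_p(recs))
  expect_equal(s$SE_p, se_p(recs))
  expect_equal(s$BI_theta, 0.1)
  expect_equal(s$SE_theta, se_theta(recs))
  expect_equal(s$BI_K, -0.5)
  expect_equal(s$SE_K, 0.5)
  expect_equal(s$delta_bic_mean, 15)
  expect_equal(s$R_effective, 2L)
  expect_equal(s$n_failed, 1L)
  # without K_hat the K metrics are absent, the rest computed
  recs2 <- list(fake_record(p_true, p_true, mu4, mu4),
                fake_record(p_true, p_true, mu4, mu4))
  s2 <- summarize_scenario(recs2, mu4, 4)
  expect_true(is.na(s2$BI_K) && is.na(s2$SE_K))
  expect_equal(s2$BI_p, 0)
  # metrics are pure functions of the records
  expect_identical(summarize_scenario(recs, mu4, 4, 1),
                   summarize_scenario(recs, mu4, 4, 1))
})
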