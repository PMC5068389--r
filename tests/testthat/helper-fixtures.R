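# shared fixtures, built in code

# a tiny 2-variable, 2-source signature set with hand-chosen parameters
tiny_set <- function() {
  s1 <- nursery_signature("A", c(0, 0), diag(2), cohort_id = "t", n = 10)
  s2 <- nursery_signature("B", c(2, 0), matrix(c(1, 0.3, 0.3, 1), 2), cohort_id = "t", n = 10)
  signature_set(list(s1, s2), cohort_id = "t", panel = c("x", "y"))
}

# two well-separated 2-d blobs (sd ~ sigma, centers 0 and (delta, 0))
two_blob_table <- function(n_per = 30, delta = 10, sigma = 1, seed = 1) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n_per, 0, sigma), rnorm(n_per, 0, sigma)),
             cbind(rnorm(n_per, delta, sigma), rnorm(n_per, 0, sigma)))
  observation_table(X, cohort = "t", panel = c("x", "y"))
}

# centroids of a signature set as a plain list
set_mus <- function(set) lapply(set$signatures, `[[`, "mu")

# hand-built run record with prescribed estimates (truth on a 4-source set)
fake_record <- function(p_true, p_hat, mu_true, mu_hat, K_hat = NA_integer_,
                        delta_bic = NA_real_) {
  ids <- rownames(mu_true)
  structure(list(sources = ids, p_true = as.numeric(p_true),
                 p_hat = as.numeric(p_hat), mu_hat = mu_hat,
                 matching = seq_along(ids), K_hat = K_hat,
                 delta_bic = delta_bic,
                 truth = structure(list(allocation = stats::setNames(p_true, ids),
                                        true_mus = mu_true),
                                   class = "run_truth"),
                 fit = NULL),
            class = "run_record")
}
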