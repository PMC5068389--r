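#!/usr/bin/env Rscript
# Build the study baselines: three synthetic 4-source cohorts whose
# among-centroid separations match the three observed within-cohort values
# (1.18, 2.78, 3.29 standardized units), plus the six-step virtual
# separation grid (0.5..5.5) derived from the intermediate cohort.
# Writes signature tables and a descriptive-statistics summary.

suppressPackageStartupMessages(library(otomix))

seed <- 42L
out <- "results/baselines"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

seps <- c(1.18, 2.78, 3.29)
cohorts <- lapply(seq_along(seps), function(i)
  random_baseline(K = 4, J = 7, target_sep = seps[i], spread = 0.5,
                  seed = child_seed(seed, 1L, i),
                  cohort_id = sprintf("synth_%.2f", seps[i])))

rows <- list()
for (co in cohorts) {
  write_signature_set(co,
                      file.path(out, paste0(co$cohort_id, "_mu.csv")),
                      file.path(out, paste0(co$cohort_id, "_cov.csv")))
  rows[[co$cohort_id]] <- data.frame(
    cohort = co$cohort_id,
    separation_identity = average_separation(co, "identity"),
    separation_pooled = average_separation(co, "pooled"),
    eff_sd_min = min(vapply(co$signatures, function(s) effective_sd(s$cov), 0)),
    eff_sd_max = max(vapply(co$signatures, function(s) effective_sd(s$cov), 0)))
}

# virtual grid from the intermediate cohort: covariances copied, means rescaled
for (d in seq(0.5, 5.5, by = 1)) {
  v <- make_virtual_cohort(cohorts[[2]], d)
  stopifnot(abs(average_separation(v, "identity") - d) < 1e-10)
  rows[[v$cohort_id]] <- data.frame(
    cohort = v$cohort_id,
    separation_identity = average_separation(v, "identity"),
    separation_pooled = average_separation(v, "pooled"),
    eff_sd_min = min(vapply(v$signatures, function(s) effective_sd(s$cov), 0)),
    eff_sd_max = max(vapply(v$signatures, function(s) effective_sd(s$cov), 0)))
}

tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "baseline_stats.csv"), row.names = FALSE)
message("baseline descriptive statistics:")
print(tab, row.names = FALSE, digits = 3)
message("the virtual grid hits every target separation to < 1e-10 while ",
        "leaving covariances untouched")
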