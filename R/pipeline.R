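#' Run one simulation scenario
#'
#' The canonical per-run sequence, repeated R times for one cohort and one
#' sampling scenario: randomly pick the K_S "known" sources, draw the
#' labeled nursery-source dataset and the unlabeled mixed-stock dataset by
#' parametric bootstrap, fit the unconditional mixture at the true K
#' (initialization pipeline + EM), optionally run BIC model selection over
#' the K ladder, match components to true sources, and record the run.
#' Every run derives its own child seeds, so the whole scenario is a pure
#' function of `(arguments, seed)` and runs are independently reproducible.
#'
#' @param set A [signature_set()]: the cohort's true baseline.
#' @param K_S Number of sources sampled for the nursery dataset (0..K).
#' @param R Number of resampling runs.
#' @param n_nursery Observations per known source (study design: 25).
#' @param n_mixed Mixed-stock sample size (study design: 100).
#' @param m Mixing proportions, randomly allocated to sources each run.
#' @param controls An [em_controls()] list (its `seed` is overridden per
#'   run).
#' @param seed Scenario base seed.
#' @param select_k Also run model selection each run (for the K metrics)?
#' @param K_max Top of the model-selection ladder.
#' @param criterion Selection criterion, `"BIC"` or `"AIC"`.
#' @param keep_records Keep the full per-run records (set `FALSE` to return
#'   only the summary when memory matters).
#' @return List with `summary` (an `evaluation_summary` row), `records`
#'   (list of `run_record` or `NULL`), `n_failed`, `failures` (messages),
#'   and the echoed design fields.
#' @export
run_scenario <- function(set, K_S, R = 100L, n_nursery = 25L, n_mixed = 100L,
                         m = c(0.1, 0.2, 0.3, 0.4), controls = em_controls(),
                         seed = 1L, select_k = FALSE, K_max = 8L,
                         criterion = "BIC", keep_records = TRUE) {
  ids <- set_sources(set)
  K_true <- length(ids)
  if (K_S < 0L || K_S > K_true) stop("K_S must be between 0 and K")
  records <- vector("list", R)
  failures <- character(0)
  for (r in seq_len(R)) {
    rs <- child_seed(seed, 11L, r)
    rec <- tryCatch({
      set.seed(child_seed(rs, 1L))
      sampled <- if (K_S) sort(sample(ids, K_S)) else character(0)
      labeled <- draw_nursery_dataset(set, sampled, n_nursery,
                                      seed = child_seed(rs, 2L))
      md <- draw_mixed_dataset(set, m, n_mixed, seed = child_seed(rs, 3L))
      md$truth$sampled_sources <- sampled
      ctl <- controls
      ctl$seed <- child_seed(rs, 4L)
      K_hat <- NA_integer_; dbic <- NA_real_; fit <- NULL
      if (select_k) {
        sel <- estimate_k(labeled, md$table, K_S = K_S, K_max = K_max,
                          controls = ctl, criterion = criterion)
        K_hat <- sel$K_hat
        dbic <- sel$delta_bic
        fit <- sel$fits[[as.character(K_true)]]   # reuse the true-K rung
      }
      if (is.null(fit)) fit <- fit_mixture(labeled, md$table, K_true, ctl)
      make_run_record(fit, md$truth, K_hat = K_hat, delta_bic = dbic)
    }, error = function(e) e)
    if (inherits(rec, "error")) failures <- c(failures, conditionMessage(rec))
    else records[[r]] <- rec
  }
  records <- records[!vapply(records, is.null, TRUE)]
  if (length(records) < 2L)
    stop("scenario failed: fewer than 2 successful runs (",
         paste(utils::head(failures, 3), collapse = "; "), ")")
  smry <- summarize_scenario(records, true_mu = set_centroids(set),
                             K_true = K_true, n_failed = length(failures))
  list(summary = smry, records = if (keep_records) records else NULL,
       n_failed = length(failures), failures = failures,
       cohort_id = set$cohort_id, K_S = as.integer(K_S), R = as.integer(R),
       seed = seed)
}

#' Run a grid of scenarios and write summary tables
#'
#' Executes every scenario configuration from [build_scenario_grid()] and
#' writes (i) a wide per-scenario summary CSV and (ii) a long-format metric
#' table (`scenario, cohort, K_S, separation, metric, value, R_effective`)
#' under `out_dir`. Deterministic given the grid's embedded seeds.
#'
#' @param scenarios List of `scenario_config` (see [build_scenario_grid()]).
#' @param out_dir Output directory (created if missing).
#' @param controls An [em_controls()] list.
#' @param select_k Run model selection inside every run?
#' @param K_max,criterion Passed to [run_scenario()].
#' @param verbose Print one progress line per scenario?
#' @return Invisibly, the wide summary data frame (also written to
#'   `summary.csv`; the long table goes to `metrics_long.csv`).
#' @export
run_experiment <- function(scenarios, out_dir, controls = em_controls(),
                           select_k = FALSE, K_max = 8L, criterion = "BIC",
                           verbose = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    res <- run_scenario(sc$set, sc$K_S, R = sc$R, n_nursery = sc$n_nursery,
                        n_mixed = sc$n_mixed, m = sc$m, controls = controls,
                        seed = sc$seed, select_k = select_k, K_max = K_max,
                        criterion = criterion, keep_records = FALSE)
    sep <- average_separation(sc$set)
    row <- cbind(data.frame(scenario = i, cohort = sc$cohort_id,
                            K_S = sc$K_S, separation = sep, R = sc$R),
                 res$summary)
    rows[[i]] <- row
    if (verbose)
      message(sprintf("[%d/%d] %s K_S=%d: BI_p=%.3f SE_p=%.3f BI_theta=%.3f",
                      i, length(scenarios), sc$cohort_id, sc$K_S,
                      row$BI_p, row$SE_p, row$BI_theta))
  }
  wide <- do.call(rbind, rows)
  utils::write.csv(wide, file.path(out_dir, "summary.csv"), row.names = FALSE)
  metrics <- c("BI_p", "SE_p", "BI_theta", "SE_theta", "BI_K", "SE_K",
               "delta_bic_mean")
  long <- do.call(rbind, lapply(seq_len(nrow(wide)), function(i)
    data.frame(scenario = wide$scenario[i], cohort = wide$cohort[i],
               K_S = wide$K_S[i], separation = wide$separation[i],
               metric = metrics, value = as.numeric(wide[i, metrics]),
               R_effective = wide$R_effective[i])))
  utils::write.csv(long, file.path(out_dir, "metrics_long.csv"),
                   row.names = FALSE)
  invisible(wide)
}

#' Fit the mixture model to user-supplied data
#'
#' Single-fit mode for real datasets: standardizes nursery-source and
#' mixed-stock tables on their pooled per-variable statistics (returned so
#' further data can be mapped to the same scale), then runs the
#' initialization + EM pipeline at a fixed K, or the model-selection ladder
#' when `K = "auto"`.
#'
#' @param nursery Labeled observation table, or `NULL` (no baseline
#'   sampling).
#' @param mixed Unlabeled observation table (non-empty).
#' @param K Integer number of components, or `"auto"` for BIC selection
#'   over max(1, K_S)..`K_max`.
#' @param controls An [em_controls()] list.
#' @param K_max,criterion Model-selection settings for `K = "auto"`.
#' @param standardize Standardize the pooled data first (default `TRUE`;
#'   set `FALSE` if the tables are already on a common standardized scale).
#' @return List with `fit` (a `mixture_fit`), `selection` (a
#'   `selection_result` or `NULL`) and `transform` (`center`, `scale`, or
#'   `NULL`).
#' @export
fit_single <- function(nursery = NULL, mixed, K = "auto",
                       controls = em_controls(), K_max = 8L,
                       criterion = "BIC", standardize = TRUE) {
  if (!nrow(mixed)) stop("mixed-stock table is empty")
  panel <- obs_panel(mixed)
  if (is.null(nursery)) nursery <- empty_observation_table(panel)
  mism <- c(setdiff(obs_panel(nursery), panel), setdiff(panel, obs_panel(nursery)))
  if (length(mism))
    stop("panel mismatch between nursery and mixed tables: ",
         paste(unique(mism), collapse = ", "))
  transform <- NULL
  if (standardize) {
    pooled <- rbind(nursery[c("specimen_id", "cohort", "source", panel)],
                    mixed[c("specimen_id", "cohort", "source", panel)])
    attr(pooled, "panel") <- panel
    std <- standardize(pooled, panel)
    transform <- list(center = std$center, scale = std$scale)
    nursery <- apply_standardization(nursery, std$center, std$scale)
    mixed <- apply_standardization(mixed, std$center, std$scale)
  }
  if (identical(K, "auto")) {
    sel <- estimate_k(nursery, mixed, K_max = K_max, controls = controls,
                      criterion = criterion, panel = panel)
    list(fit = sel$fits[[as.character(sel$K_hat)]], selection = sel,
         transform = transform)
  } else {
    list(fit = fit_mixture(nursery, mixed, as.integer(K), controls, panel),
         selection = NULL, transform = transform)
  }
}
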