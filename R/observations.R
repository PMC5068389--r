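#' Build an observation table
#'
#' The package's tabular data container: one row per fish, with a specimen
#' id, cohort label, an optional nursery-source label (`NA` for mixed-stock
#' fish of unknown origin) and the J panel variables. Plain data frame; the
#' panel is recorded in the `"panel"` attribute.
#'
#' @param X Numeric matrix or data frame of measurements (rows = fish).
#' @param cohort Cohort label(s), recycled.
#' @param source Source label(s) or `NA`, recycled.
#' @param panel Variable names; defaults to `colnames(X)` or the standard
#'   seven-element panel.
#' @param specimen_id Optional ids; autogenerated when missing.
#' @return Data frame with columns `specimen_id`, `cohort`, `source`, panel.
#' @export
observation_table <- function(X, cohort = NA_character_, source = NA_character_,
                              panel = NULL, specimen_id = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(panel))
    panel <- if (!is.null(colnames(X))) colnames(X)
             else if (ncol(X) == 7L) default_panel()
             else paste0("V", seq_len(ncol(X)))
  if (length(panel) != ncol(X)) stop("panel length does not match data")
  if (is.null(specimen_id))
    specimen_id <- if (n) paste0("obs", seq_len(n)) else character(0)
  out <- data.frame(specimen_id = as.character(specimen_id),
                    cohort = rep_len(as.character(cohort), n),
                    source = rep_len(as.character(source), n),
                    stringsAsFactors = FALSE)
  for (j in seq_along(panel)) out[[panel[j]]] <- as.numeric(X[, j])
  attr(out, "panel") <- as.character(panel)
  out
}

# empty table with a valid header for a given panel
empty_observation_table <- function(panel) {
  observation_table(matrix(numeric(0), 0L, length(panel),
                           dimnames = list(NULL, panel)), panel = panel)
}

#' Panel of an observation table
#'
#' @param table Observation data frame.
#' @return Character vector of panel variable names (the non-id numeric
#'   columns when no `"panel"` attribute is present).
#' @export
obs_panel <- function(table) {
  p <- attr(table, "panel")
  if (!is.null(p)) return(p)
  setdiff(names(table), c("specimen_id", "cohort", "source"))
}

# numeric matrix of the panel columns
obs_matrix <- function(table, panel = obs_panel(table)) {
  miss <- setdiff(panel, names(table))
  if (length(miss)) stop("missing panel columns: ", paste(miss, collapse = ", "))
  as.matrix(table[, panel, drop = FALSE])
}

#' Read / write observation tables
#'
#' CSV (or TSV, by extension) with header `specimen_id, cohort, source`
#' followed by the panel columns; an empty `source` field marks a
#' mixed-stock fish of unknown origin.
#'
#' @param path File path (`.tsv`/`.txt` are read tab-separated).
#' @param table Observation data frame to write.
#' @return `read_observations()` returns an observation data frame;
#'   `write_observations()` returns `path` invisibly.
#' @export
read_observations <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("specimen_id", "cohort", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  panel <- setdiff(names(df), need)
  observation_table(as.matrix(df[, panel, drop = FALSE]),
                    cohort = df$cohort, source = df$source,
                    panel = panel, specimen_id = df$specimen_id)
}

#' @rdname read_observations
#' @export
write_observations <- function(table, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write signature sets
#'
#' Two companion CSVs: a statistics file with columns
#' `source_id, cohort_id, n, mu_1..mu_J` and a covariance file with the
#' flattened J x J entries per source (`source_id, cov_1_1, cov_1_2, ...`,
#' row-major). Full double precision is preserved.
#'
#' @param set A [signature_set()].
#' @param mu_path,cov_path Paths for the two files.
#' @return `write_signature_set()` returns the paths invisibly;
#'   `read_signature_set()` returns a `signature_set`.
#' @export
write_signature_set <- function(set, mu_path, cov_path) {
  J <- length(set$panel)
  mu_df <- do.call(rbind, lapply(set$signatures, function(s)
    data.frame(source_id = s$source_id, cohort_id = s$cohort_id, n = s$n,
               t(stats::setNames(s$mu, paste0("mu_", seq_len(J)))))))
  cov_df <- do.call(rbind, lapply(set$signatures, function(s) {
    v <- as.numeric(t(s$cov))
    nm <- paste0("cov_", rep(seq_len(J), each = J), "_", rep(seq_len(J), J))
    data.frame(source_id = s$source_id, t(stats::setNames(v, nm)))
  }))
  utils::write.csv(format(mu_df, digits = 17, trim = TRUE), mu_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(format(cov_df, digits = 17, trim = TRUE), cov_path, row.names = FALSE, quote = FALSE)
  invisible(c(mu_path, cov_path))
}

#' @rdname write_signature_set
#' @param panel Optional panel names for the rebuilt set.
#' @export
read_signature_set <- function(mu_path, cov_path, panel = NULL) {
  mu_df <- utils::read.csv(mu_path, stringsAsFactors = FALSE)
  cov_df <- utils::read.csv(cov_path, stringsAsFactors = FALSE)
  J <- sum(grepl("^mu_", names(mu_df)))
  sigs <- lapply(seq_len(nrow(mu_df)), function(i) {
    sid <- mu_df$source_id[i]
    crow <- cov_df[cov_df$source_id == sid, , drop = FALSE]
    if (nrow(crow) != 1L) stop("covariance rows missing for source ", sid)
    cv <- matrix(as.numeric(crow[1, -1]), J, J, byrow = TRUE)
    nursery_signature(sid, as.numeric(mu_df[i, paste0("mu_", seq_len(J))]),
                      (cv + t(cv)) / 2, cohort_id = mu_df$cohort_id[i],
                      n = mu_df$n[i])
  })
  signature_set(sigs, panel = panel)
}
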