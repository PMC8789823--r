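# Per-condition summary tables. The cell is the unit of replication:
# track-level quantities only ever feed a per-cell metric, and the SE
# is computed across cells.

#' Summarize per-cell metrics by condition
#'
#' @param metrics data.frame with columns `cell_id`, `condition` and
#'   one or more numeric metric columns.
#' @return data.frame `condition, metric, mean, se, n_cells`; the SE
#'   is `NA` when a condition has a single cell.
#' @export
summarize_conditions <- function(metrics) {
  if (!all(c("cell_id", "condition") %in% names(metrics)))
    stop("metrics needs cell_id and condition columns")
  tab <- unique(metrics[c("cell_id", "condition")])
  if (anyDuplicated(tab$cell_id))
    stop("a cell_id is assigned to more than one condition")
  value_cols <- setdiff(names(metrics), c("cell_id", "condition"))
  if (!length(value_cols)) stop("no metric columns")
  out <- do.call(rbind, lapply(split(metrics, metrics$condition),
                               function(d) {
    do.call(rbind, lapply(value_cols, function(v) {
      x <- d[[v]]
      n <- sum(!is.na(x))
      data.frame(condition = d$condition[1], metric = v,
                 mean = mean(x, na.rm = TRUE),
                 se = if (n >= 2) stats::sd(x, na.rm = TRUE) / sqrt(n)
                      else NA_real_,
                 n_cells = n, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Write a run manifest
#'
#' Records the configuration hash, seed and package version next to a
#' set of stage outputs so a summary table can be traced to its run.
#'
#' @param path output JSON path.
#' @param config the configuration used (any list).
#' @param seed the run seed.
#' @param extra optional named list merged into the manifest.
#' @export
write_manifest <- function(path, config = NULL, seed = NULL,
                           extra = list()) {
  manifest <- c(list(
    package = "sptkit",
    version = as.character(utils::packageVersion("sptkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = if (!is.null(config))
      substr(digest_string(paste(utils::capture.output(utils::str(config)),
                                 collapse = "\n")), 1, 16)),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

# tiny polynomial rolling hash; avoids a dependency for a cosmetic
# run fingerprint
digest_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
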