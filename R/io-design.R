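#' Read a series design table
#'
#' Tab-separated with header columns `sample_id, series_id, condition,
#' pair_id, dose_mM, hours` (and optionally `cell_type`). Each series is a
#' paired case/control experiment: conditions are `control` / `metformin`,
#' every series must have equal numbers of each, and within a series each
#' `pair_id` appears exactly once per condition.
#'
#' @param path Path to the design TSV.
#' @return A validated data.frame of class `series_design`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  series_design(d)
}

#' Validate a series design data.frame
#'
#' @param d data.frame with the columns documented in [read_design()].
#' @return `d` with class `series_design` prepended.
#' @export
series_design <- function(d) {
  need <- c("sample_id", "series_id", "condition", "pair_id", "dose_mM", "hours")
  if (!all(need %in% names(d)))
    stop("design lacks columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  if (!all(d$condition %in% c("control", "metformin")))
    stop("condition must be 'control' or 'metformin'")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in design")
  for (s in unique(d$series_id)) {
    ds <- d[d$series_id == s, ]
    tab <- table(ds$condition)
    if (length(tab) != 2 || tab[["control"]] != tab[["metformin"]])
      stop("series ", s, ": unequal numbers of control and metformin samples")
    pc <- table(ds$pair_id, ds$condition)
    if (any(pc != 1))
      stop("series ", s, ": each pair_id must appear once per condition")
  }
  class(d) <- c("series_design", "data.frame")
  d
}

#' Write a series design table
#' @param design A [series_design()] data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  write.table(as.data.frame(design), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split a design by series
#' @param design A [series_design()] data.frame.
#' @return Named list of per-series design data.frames.
#' @export
split_design <- function(design) {
  split(as.data.frame(design), design$series_id)
}
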