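#' Expression tensor: samples x transcripts x inferential replicates
#'
#' The statistical substrate for differential expression and correlation:
#' point-estimate counts and TPM per transcript and sample, plus `G`
#' inferential (Gibbs/bootstrap style) replicate count matrices expressing
#' quantification uncertainty. `G = 0` means no replicates are available and
#' downstream code falls back to the point estimates.
#'
#' @param counts numeric matrix, transcripts x samples.
#' @param tpm numeric matrix, same shape as `counts`.
#' @param lengths numeric vector of transcript lengths (bp).
#' @param infreps `NULL`, or a 3-d array transcripts x samples x G.
#' @return An object of class `expression_tensor`.
#' @export
expression_tensor <- function(counts, tpm, lengths, infreps = NULL) {
  counts <- as.matrix(counts)
  tpm <- as.matrix(tpm)
  stopifnot(identical(dim(counts), dim(tpm)),
            length(lengths) == nrow(counts),
            !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("negative counts")
  if (!is.null(infreps)) {
    stopifnot(length(dim(infreps)) == 3,
              dim(infreps)[1] == nrow(counts),
              dim(infreps)[2] == ncol(counts))
    dimnames(infreps)[1:2] <- dimnames(counts)
  }
  structure(list(counts = counts, tpm = tpm,
                 lengths = setNames(as.numeric(lengths), rownames(counts)),
                 infreps = infreps),
            class = "expression_tensor")
}

#' @export
print.expression_tensor <- function(x, ...) {
  cat("expression_tensor:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples,", n_infreps(x), "inferential replicates\n")
  invisible(x)
}

#' Number of inferential replicates in a tensor
#' @param tensor An [expression_tensor()].
#' @return Integer, 0 when no replicates are stored.
#' @export
n_infreps <- function(tensor) {
  if (is.null(tensor$infreps)) 0L else dim(tensor$infreps)[3]
}

#' Subset an expression tensor by sample
#' @param tensor An [expression_tensor()].
#' @param samples Character vector of sample IDs (column names).
#' @return An [expression_tensor()] restricted to those samples.
#' @export
tensor_samples <- function(tensor, samples) {
  stopifnot(all(samples %in% colnames(tensor$counts)))
  expression_tensor(tensor$counts[, samples, drop = FALSE],
                    tensor$tpm[, samples, drop = FALSE],
                    tensor$lengths,
                    if (!is.null(tensor$infreps))
                      tensor$infreps[, samples, , drop = FALSE])
}

#' Read a quantification directory into an expression tensor
#'
#' Two dialects are supported. `"salmon"` expects one subdirectory per
#' sample, each containing a `quant.sf` table with columns
#' `Name, Length, EffectiveLength, TPM, NumReads` (counts are `NumReads`)
#' and, optionally, a plain-text `inf_reps.tsv` whose first column is
#' `Name` followed by one column per inferential replicate. `"plain_table"`
#' expects one `<sample>.tsv` file per sample with columns
#' `transcript_id, length, counts, tpm` plus optional `rep1..repG` columns.
#'
#' Samples missing replicate tables yield `G = 0` with a warning; downstream
#' statistics then use the point estimates. Inconsistent transcript sets
#' across samples are an error naming the offending samples.
#'
#' @param dir Directory containing the per-sample quantifications.
#' @param dialect `"salmon"` or `"plain_table"`.
#' @return An [expression_tensor()] with samples in sorted order.
#' @export
read_quant <- function(dir, dialect = c("salmon", "plain_table")) {
  dialect <- match.arg(dialect)
  if (!dir.exists(dir)) stop("quantification directory not found: ", dir)
  if (dialect == "salmon") {
    samples <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
    if (!length(samples)) stop("no sample subdirectories in ", dir)
    parts <- lapply(samples, function(s) .read_salmon_sample(file.path(dir, s)))
  } else {
    files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = FALSE))
    if (!length(files)) stop("no per-sample .tsv tables in ", dir)
    samples <- sub("\\.tsv$", "", files)
    parts <- lapply(files, function(f) .read_plain_sample(file.path(dir, f)))
  }
  names(parts) <- samples

  ids <- parts[[1]]$ids
  bad <- samples[!vapply(parts, function(p) identical(p$ids, ids), logical(1))]
  if (length(bad))
    stop("transcript sets differ across samples; offenders: ",
         paste(bad, collapse = ", "))

  G <- vapply(parts, function(p) ncol(p$reps) %||% 0L, integer(1))
  if (any(G == 0) && any(G > 0)) {
    warning("samples without inferential replicates: ",
            paste(samples[G == 0], collapse = ", "),
            "; falling back to point estimates (G = 0)")
    G[] <- 0L
  }
  if (length(unique(G[G > 0])) > 1)
    stop("inconsistent replicate counts across samples: ",
         paste(unique(G), collapse = ", "))

  counts <- vapply(parts, function(p) p$counts, numeric(length(ids)))
  tpm <- vapply(parts, function(p) p$tpm, numeric(length(ids)))
  dimnames(counts) <- dimnames(tpm) <- list(ids, samples)
  infreps <- NULL
  if (all(G > 0)) {
    infreps <- array(NA_real_, c(length(ids), length(samples), G[[1]]),
                     dimnames = list(ids, samples, NULL))
    for (j in seq_along(samples)) infreps[, j, ] <- parts[[j]]$reps
  }
  expression_tensor(counts, tpm, parts[[1]]$lengths, infreps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_salmon_sample <- function(sdir) {
  qf <- file.path(sdir, "quant.sf")
  if (!file.exists(qf)) stop("missing quant.sf in ", sdir)
  q <- read.delim(qf, stringsAsFactors = FALSE)
  need <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  if (!all(need %in% names(q)))
    stop("quant.sf in ", sdir, " lacks columns: ",
         paste(setdiff(need, names(q)), collapse = ", "))
  ord <- order(q$Name)
  q <- q[ord, ]
  reps <- NULL
  rf <- file.path(sdir, "inf_reps.tsv")
  if (file.exists(rf)) {
    r <- read.delim(rf, stringsAsFactors = FALSE)
    r <- r[match(q$Name, r$Name), , drop = FALSE]
    reps <- as.matrix(r[, setdiff(names(r), "Name"), drop = FALSE])
    storage.mode(reps) <- "double"
  }
  list(ids = q$Name, counts = q$NumReads, tpm = q$TPM,
       lengths = q$Length, reps = reps)
}

.read_plain_sample <- function(path) {
  q <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "length", "counts", "tpm")
  if (!all(need %in% names(q)))
    stop("plain table ", path, " lacks columns: ",
         paste(setdiff(need, names(q)), collapse = ", "))
  q <- q[order(q$transcript_id), ]
  repcols <- grep("^rep[0-9]+$", names(q), value = TRUE)
  reps <- NULL
  if (length(repcols)) {
    reps <- as.matrix(q[, repcols, drop = FALSE])
    storage.mode(reps) <- "double"
  }
  list(ids = q$transcript_id, counts = q$counts, tpm = q$tpm,
       lengths = q$length, reps = reps)
}

#' Write one sample of an expression tensor as a Salmon-format directory
#'
#' Writes `quant.sf` (and `inf_reps.tsv` when replicates are present) for
#' each sample of the tensor under `dir/<sample>/`, the layout [read_quant()]
#' consumes with `dialect = "salmon"`. Effective length is written equal to
#' length.
#'
#' @param tensor An [expression_tensor()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_quant <- function(tensor, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  G <- n_infreps(tensor)
  # 17 significant digits so doubles survive the text round-trip bit-exact
  fmt <- function(x) sprintf("%.17g", x)
  for (s in colnames(tensor$counts)) {
    sdir <- file.path(dir, s)
    dir.create(sdir, showWarnings = FALSE)
    q <- data.frame(Name = rownames(tensor$counts),
                    Length = fmt(tensor$lengths),
                    EffectiveLength = fmt(tensor$lengths),
                    TPM = fmt(tensor$tpm[, s]),
                    NumReads = fmt(tensor$counts[, s]))
    write.table(q, file.path(sdir, "quant.sf"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (G > 0) {
      r <- data.frame(Name = rownames(tensor$counts),
                      apply(matrix(tensor$infreps[, s, ], ncol = G), 2, fmt))
      names(r)[-1] <- paste0("rep", seq_len(G))
      write.table(r, file.path(sdir, "inf_reps.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
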