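# Internal coordinate convention: 0-based half-open [start, end).
# GTF files are 1-based inclusive; conversion happens only in read_gtf /
# write_gtf so that all interval arithmetic (the cis window in particular)
# is done in half-open coordinates.

.BIOTYPES <- c("lncRNA", "protein_coding", "other")

.collapse_biotype <- function(x) {
  x <- as.character(x)
  out <- rep("other", length(x))
  out[x == "lncRNA"] <- "lncRNA"
  out[x == "protein_coding"] <- "protein_coding"
  out
}

#' Construct a transcript annotation
#'
#' Bundles a gene table and a transcript table into a `tx_annotation`
#' object, the coordinate substrate for the cis window screen and the
#' transcript-to-gene dictionary used throughout the pipeline.
#'
#' Coordinates are 0-based half-open. Every transcript must link to a known
#' gene, intervals must be non-empty, and transcript IDs must be unique.
#' Versioned IDs (e.g. `"ENST00000604514.1"`) are kept verbatim and matched
#' on the full versioned string.
#'
#' @param genes data.frame with columns `gene_id`, `gene_name`, `biotype`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `transcript_name`, `biotype`, `chrom`, `start`, `end`, `strand`.
#' @return An object of class `tx_annotation`: a list with elements `genes`
#'   and `transcripts`.
#' @export
tx_annotation <- function(genes, transcripts) {
  gcols <- c("gene_id", "gene_name", "biotype", "chrom", "start", "end", "strand")
  tcols <- c("transcript_id", "gene_id", "transcript_name", "biotype",
             "chrom", "start", "end", "strand")
  stopifnot(all(gcols %in% names(genes)), all(tcols %in% names(transcripts)))
  genes <- as.data.frame(genes)[, gcols]
  transcripts <- as.data.frame(transcripts)[, tcols]
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicate transcript_id in annotation: ",
         paste(unique(transcripts$transcript_id[duplicated(transcripts$transcript_id)]),
               collapse = ", "))
  if (any(genes$start >= genes$end) || any(transcripts$start >= transcripts$end))
    stop("empty or inverted interval (require start < end in half-open coordinates)")
  missing <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(missing))
    stop("transcripts reference unknown gene_id: ", paste(missing, collapse = ", "))
  rownames(genes) <- NULL
  rownames(transcripts) <- NULL
  structure(list(genes = genes, transcripts = transcripts),
            class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat("tx_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts\n")
  tab <- table(x$transcripts$biotype)
  cat("  transcript biotypes:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Transcript-to-gene dictionary
#'
#' @param annotation A [tx_annotation()] object.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `gene_name`, `biotype` (transcript-level).
#' @export
tx2gene <- function(annotation) {
  tx <- annotation$transcripts
  g <- annotation$genes
  data.frame(transcript_id = tx$transcript_id,
             gene_id = tx$gene_id,
             gene_name = g$gene_name[match(tx$gene_id, g$gene_id)],
             biotype = tx$biotype,
             stringsAsFactors = FALSE)
}

#' Read a GTF annotation
#'
#' Parses a GENCODE-dialect GTF into gene and transcript records,
#' converting the file's 1-based inclusive coordinates to the internal
#' 0-based half-open convention. Biotype is taken from the transcript-level
#' `transcript_type` attribute when present, else the gene-level
#' `gene_type`; anything other than `lncRNA`/`protein_coding` collapses to
#' `"other"`.
#'
#' @param path Path to a GTF file.
#' @param feature_filter Character vector of feature types to read
#'   (default gene and transcript rows; exon rows are ignored).
#' @return A [tx_annotation()] object.
#' @export
read_gtf <- function(path, feature_filter = c("gene", "transcript")) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  .validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type %in% feature_filter, , drop = FALSE]
  if (!nrow(df)) stop("no gene/transcript features in GTF: ", path)

  pick <- function(d, col) if (col %in% names(d)) as.character(d[[col]]) else rep(NA_character_, nrow(d))

  gd <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(
    gene_id = pick(gd, "gene_id"),
    gene_name = ifelse(is.na(pick(gd, "gene_name")), pick(gd, "gene_id"), pick(gd, "gene_name")),
    biotype = .collapse_biotype(pick(gd, "gene_type")),
    chrom = as.character(gd$seqnames),
    start = gd$start - 1L,       # to 0-based half-open
    end = gd$end,
    strand = as.character(gd$strand),
    stringsAsFactors = FALSE)

  td <- df[df$type == "transcript", , drop = FALSE]
  tx_bt <- pick(td, "transcript_type")
  gene_bt <- pick(td, "gene_type")
  tx_bt[is.na(tx_bt)] <- gene_bt[is.na(tx_bt)]
  transcripts <- data.frame(
    transcript_id = pick(td, "transcript_id"),
    gene_id = pick(td, "gene_id"),
    transcript_name = ifelse(is.na(pick(td, "transcript_name")),
                             pick(td, "transcript_id"), pick(td, "transcript_name")),
    biotype = .collapse_biotype(tx_bt),
    chrom = as.character(td$seqnames),
    start = td$start - 1L,
    end = td$end,
    strand = as.character(td$strand),
    stringsAsFactors = FALSE)

  missing <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(missing))
    stop("GTF transcript(s) reference unknown gene_id: ",
         paste(missing, collapse = ", "))
  tx_annotation(genes, transcripts)
}

# Cheap structural validation so malformed attribute blocks are reported
# with a line number (rtracklayer's own errors do not carry one).
.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 9)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields, got ",
           length(fields))
    if (!grepl("gene_id \"[^\"]+\"", fields[9]))
      stop("malformed GTF attribute block at line ", i,
           ": missing gene_id \"...\"")
  }
  invisible(TRUE)
}

#' Write a GTF annotation
#'
#' Inverse of [read_gtf()]: writes gene and transcript rows, converting
#' internal 0-based half-open coordinates back to GTF's 1-based inclusive
#' convention. Round-trips through [read_gtf()] are lossless for all fields
#' the records carry.
#'
#' @param annotation A [tx_annotation()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  t <- annotation$transcripts
  gr_g <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand,
    type = "gene", source = "isolnc",
    gene_id = g$gene_id, gene_name = g$gene_name, gene_type = g$biotype)
  gmatch <- match(t$gene_id, g$gene_id)
  gr_t <- GenomicRanges::GRanges(
    seqnames = t$chrom,
    ranges = IRanges::IRanges(start = t$start + 1L, end = t$end),
    strand = t$strand,
    type = "transcript", source = "isolnc",
    gene_id = t$gene_id, gene_name = g$gene_name[gmatch],
    gene_type = g$biotype[gmatch],
    transcript_id = t$transcript_id, transcript_name = t$transcript_name,
    transcript_type = t$biotype)
  gr <- suppressWarnings(c(gr_g, gr_t))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
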