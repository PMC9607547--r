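#' Cis screen configuration
#'
#' @param window_bp Flanking window around the focal gene (default 1 Mb,
#'   the median human TAD length that motivates the cis range).
#' @param r_min Correlation cutoff: a pair passes when the combined
#'   Pearson r exceeds this (default 0.8).
#' @param p_max P-value cutoff for the combined correlation test
#'   (default 0.01).
#' @param combine_rule How per-series correlations are combined:
#'   `"median_across_series"` (median r, Fisher-combined p; the default —
#'   series differ in cell type and depth, and pooling their samples would
#'   manufacture correlation from between-series offsets) or
#'   `"pooled_samples"`.
#' @return An object of class `cis_config`.
#' @export
cis_config <- function(window_bp = 1e6, r_min = 0.8, p_max = 0.01,
                       combine_rule = c("median_across_series",
                                        "pooled_samples")) {
  stopifnot(window_bp > 0, r_min > 0, r_min <= 1, p_max > 0, p_max < 1)
  structure(list(window_bp = as.numeric(window_bp), r_min = r_min,
                 p_max = p_max, combine_rule = match.arg(combine_rule)),
            class = "cis_config")
}

# Gene lookup for a transcript; errors when unknown.
.focal_gene <- function(transcript_id, annotation) {
  tx <- annotation$transcripts
  i <- match(transcript_id, tx$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  g <- annotation$genes
  j <- match(tx$gene_id[i], g$gene_id)
  if (is.na(j)) stop("unknown gene for transcript: ", transcript_id)
  g[j, ]
}

#' Transcripts of genes within the flanking window
#'
#' Returns all transcripts (any biotype, excluding the focal transcript
#' itself) whose gene interval overlaps the half-open window
#' `[gene.start - window_bp, gene.end + window_bp)` around the focal
#' transcript's gene, on the same chromosome. The window is anchored on
#' gene intervals, not transcripts, and strand is ignored. Distance is the
#' gap between nearest gene edges (0 for overlapping or touching genes).
#'
#' @param focal_transcript_id Transcript ID present in the annotation.
#' @param annotation A [tx_annotation()].
#' @param config A [cis_config()].
#' @return data.frame of neighbour transcripts with an added
#'   `distance_bp` column (per their gene).
#' @export
neighbors_within_window <- function(focal_transcript_id, annotation,
                                    config = cis_config()) {
  fg <- .focal_gene(focal_transcript_id, annotation)
  g <- annotation$genes
  W <- config$window_bp
  same <- g$chrom == fg$chrom & g$gene_id != fg$gene_id
  # half-open window [fg$start - W, fg$end + W): gene [s, e) overlaps iff
  # s < fg$end + W and e > fg$start - W
  hit <- same & g$start < fg$end + W & g$end > fg$start - W
  gh <- g[hit, , drop = FALSE]
  dist <- pmax(gh$start - fg$end, fg$start - gh$end, 0)
  tx <- annotation$transcripts
  keep <- tx$gene_id %in% gh$gene_id & tx$transcript_id != focal_transcript_id
  out <- tx[keep, , drop = FALSE]
  out$distance_bp <- dist[match(out$gene_id, gh$gene_id)]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with t-test p-value
#'
#' `r` is the sample Pearson coefficient; the p-value comes from the
#' two-sided t test `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return List with elements `r` and `p` (both `NA` with a warning for
#'   degenerate input).
#' @export
pearson_with_pvalue <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

# Fisher's method over per-series p-values.
.fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  pchisq(-2 * sum(log(pmax(p, 1e-300))), df = 2 * length(p),
         lower.tail = FALSE)
}

#' Windowed cis co-expression screen
#'
#' For each selected lncRNA isoform, correlates its TPM with the TPM of
#' every transcript of genes inside the flanking window, per series, and
#' combines across series (median r with Fisher-combined p by default).
#' A pair passes when `r_combined > r_min` and `p_combined < p_max`.
#' Series with fewer than 3 samples, or with zero variance in either
#' transcript, are excluded from the combination.
#'
#' @param selected Character vector of focal (lncRNA) transcript IDs.
#' @param tensors Named list of per-series [expression_tensor()]s.
#' @param annotation A [tx_annotation()].
#' @param config A [cis_config()].
#' @param de_tables Optional named list of per-series [run_de()] tables;
#'   when given, candidate partners are restricted to transcripts DE in at
#'   least one series (the screen between the shared isoforms and the
#'   other differentially expressed transcripts).
#' @return data.frame of `CisPair` rows: `lnc_transcript_id`,
#'   `partner_transcript_id`, `genomic_distance_bp`, per-series r columns,
#'   `r_combined`, `p_combined`, `passes`.
#' @export
screen_cis <- function(selected, tensors, annotation, config = cis_config(),
                       de_tables = NULL) {
  dets <- NULL
  if (!is.null(de_tables)) {
    dets <- unique(unlist(lapply(de_tables, function(t)
      t$transcript_id[t$is_DE])))
  }
  rows <- list()
  for (focal in selected) {
    nb <- neighbors_within_window(focal, annotation, config)
    if (!is.null(dets)) nb <- nb[nb$transcript_id %in% dets, , drop = FALSE]
    if (!nrow(nb)) next
    for (i in seq_len(nrow(nb))) {
      partner <- nb$transcript_id[i]
      rs <- ps <- setNames(rep(NA_real_, length(tensors)), names(tensors))
      xs <- list(); ys <- list()
      for (sid in names(tensors)) {
        tpm <- tensors[[sid]]$tpm
        if (!(focal %in% rownames(tpm)) || !(partner %in% rownames(tpm)))
          next
        x <- tpm[focal, ]; y <- tpm[partner, ]
        if (length(x) < 3) next
        if (sd(x) == 0 || sd(y) == 0) next
        cp <- pearson_with_pvalue(x, y)
        rs[sid] <- cp$r; ps[sid] <- cp$p
        xs[[sid]] <- x; ys[[sid]] <- y
      }
      if (all(is.na(rs))) next
      if (config$combine_rule == "median_across_series") {
        r_comb <- median(rs, na.rm = TRUE)
        p_comb <- .fisher_combine(ps)
      } else {
        cp <- pearson_with_pvalue(unlist(xs), unlist(ys))
        r_comb <- cp$r; p_comb <- cp$p
      }
      row <- data.frame(lnc_transcript_id = focal,
                        partner_transcript_id = partner,
                        genomic_distance_bp = nb$distance_bp[i],
                        stringsAsFactors = FALSE)
      for (sid in names(tensors)) row[[paste0("r_", sid)]] <- rs[[sid]]
      row$r_combined <- r_comb
      row$p_combined <- p_comb
      row$passes <- !is.na(r_comb) && !is.na(p_comb) &&
        r_comb > config$r_min && p_comb < config$p_max
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows))
    return(data.frame(lnc_transcript_id = character(),
                      partner_transcript_id = character(),
                      genomic_distance_bp = numeric(),
                      r_combined = numeric(), p_combined = numeric(),
                      passes = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count DE transcripts in each selected isoform's window
#'
#' For each selected lncRNA isoform, the number of distinct transcripts
#' that are DE in at least one series and whose gene lies within the
#' flanking window (transcript-level counting: three DE isoforms of one
#' neighbouring gene count as 3).
#'
#' @param selected Character vector of focal transcript IDs.
#' @param de_tables Named list of per-series [run_de()] tables.
#' @param annotation A [tx_annotation()].
#' @param config A [cis_config()].
#' @return Named integer vector, one count per selected transcript.
#' @export
count_neighbor_dets <- function(selected, de_tables, annotation,
                                config = cis_config()) {
  dets <- unique(unlist(lapply(de_tables, function(t)
    t$transcript_id[t$is_DE])))
  vapply(setNames(selected, selected), function(focal) {
    nb <- neighbors_within_window(focal, annotation, config)
    sum(nb$transcript_id %in% dets)
  }, integer(1))
}
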