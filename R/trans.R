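#' Trans enrichment configuration
#'
#' @param weight_exponent Exponent on |ranking value| in the weighted KS
#'   running sum (default 1; 0 gives the classic unweighted statistic).
#' @param n_perm Gene-label permutations for the null (default 10000).
#' @param seed Integer seed for the permutation draws.
#' @param padj_max Reporting cutoff on BH-adjusted p-values (default 1e-3;
#'   a stricter 1e-4 mirrors the tighter end of the reporting range).
#' @param min_series Minimum number of series in which a set must be
#'   significant to be reported (default 2 independent experiments).
#' @param min_set_size,max_set_size Size filters applied to the
#'   set/profile intersection.
#' @param collapse Transcript-to-gene collapse rule for rankings:
#'   `"max_abs"` (keep the strongest isoform signal, default) or
#'   `"mean"`.
#' @return An object of class `trans_config`.
#' @export
trans_config <- function(weight_exponent = 1, n_perm = 10000, seed = 1,
                         padj_max = 1e-3, min_series = 2,
                         min_set_size = 5, max_set_size = 500,
                         collapse = c("max_abs", "mean")) {
  stopifnot(padj_max > 0, padj_max < 1, n_perm >= 100)
  structure(list(weight_exponent = weight_exponent,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 padj_max = padj_max, min_series = as.integer(min_series),
                 min_set_size = as.integer(min_set_size),
                 max_set_size = as.integer(max_set_size),
                 collapse = match.arg(collapse)),
            class = "trans_config")
}

#' Correlation-ranked profiles for a focal isoform
#'
#' Within each series, the Pearson correlation of the focal isoform's TPM
#' with every protein-coding transcript's TPM; transcript values are
#' collapsed to gene symbols (maximal absolute correlation by default, so
#' the strongest isoform signal is preserved), and a combined profile is
#' the per-gene median across series. Zero-variance transcripts are
#' dropped; series missing the focal isoform are skipped with a warning.
#'
#' @param focal Focal transcript ID.
#' @param tensors Named list of per-series [expression_tensor()]s.
#' @param annotation A [tx_annotation()].
#' @param config A [trans_config()] (for the collapse rule).
#' @return List with `per_series` (named list of named gene-level
#'   correlation vectors), `combined` (per-gene median across series) and
#'   `focal`.
#' @export
build_ranking <- function(focal, tensors, annotation,
                          config = trans_config()) {
  t2g <- tx2gene(annotation)
  pc <- t2g[t2g$biotype == "protein_coding" & t2g$transcript_id != focal, ]
  per_series <- list()
  for (sid in names(tensors)) {
    tpm <- tensors[[sid]]$tpm
    if (!(focal %in% rownames(tpm))) {
      warning("focal isoform ", focal, " absent from series ", sid,
              "; skipped")
      next
    }
    ids <- intersect(pc$transcript_id, rownames(tpm))
    x <- tpm[focal, ]
    if (sd(x) == 0) next
    Y <- t(tpm[ids, , drop = FALSE])
    keep <- apply(Y, 2, sd) > 0
    if (!any(keep)) next
    r <- suppressWarnings(as.numeric(cor(x, Y[, keep, drop = FALSE])))
    names(r) <- ids[keep]
    gene <- pc$gene_name[match(names(r), pc$transcript_id)]
    per_series[[sid]] <- .collapse_to_gene(r, gene, config$collapse)
  }
  genes <- unique(unlist(lapply(per_series, names)))
  combined <- vapply(genes, function(gn) {
    median(unlist(lapply(per_series, function(v) v[gn])), na.rm = TRUE)
  }, numeric(1))
  list(per_series = per_series, combined = combined, focal = focal)
}

.collapse_to_gene <- function(values, gene, rule) {
  sp <- split(values, gene)
  vapply(sp, function(v) {
    if (rule == "max_abs") v[which.max(abs(v))] else mean(v)
  }, numeric(1))
}

# Core weighted KS running-sum extremum on a sorted profile.
# v: values sorted decreasing; idx: sorted positions of the set members.
.es_core <- function(v, idx, exponent) {
  N <- length(v); k <- length(idx)
  w <- abs(v[idx])^exponent
  NR <- sum(w)
  if (NR == 0) { w[] <- 1; NR <- k }
  dec <- if (N > k) 1 / (N - k) else 0
  tops <- cumsum(w) / NR - (idx - seq_len(k)) * dec
  bottoms <- tops - w / NR
  maxt <- max(tops); minb <- min(bottoms)
  # positive extrema win magnitude ties; the comparison allows for
  # summation-order rounding (ties are exactly rational when both extrema
  # sit at weight-free positions of the running sum)
  if (maxt >= -minb - 1e-12) {
    j <- which.max(tops)
    list(es = maxt, extremum_at = idx[j], leading = seq_len(j),
         tops = tops, bottoms = bottoms)
  } else {
    j <- which.min(bottoms)
    list(es = minb, extremum_at = idx[j], leading = j:k,
         tops = tops, bottoms = bottoms)
  }
}

#' Weighted KS enrichment score
#'
#' Genes are sorted by decreasing ranking value; the running sum
#' increments by `|value|^weight_exponent / sum(|value|^weight_exponent)`
#' at member genes and decrements by `1 / (N - n_set)` at non-members.
#' The enrichment score is the extremum of largest magnitude (positive
#' extrema win exact-magnitude ties), and the leading edge contains the
#' members up to (positive ES) or after (negative ES) the extremum. Rank
#' ties are broken by gene name for determinism.
#'
#' @param profile Named numeric vector: gene-level ranking values.
#' @param gene_set Character vector of gene symbols.
#' @param weight_exponent See [trans_config()].
#' @return List with `es`, `leading_edge` (gene names), `hit_ranks`
#'   (positions of the members in the sorted profile), `tops` and
#'   `bottoms` (running-sum values at each member, after/before its
#'   increment). `NULL` when the set does not intersect the profile.
#' @export
enrichment_score <- function(profile, gene_set, weight_exponent = 1) {
  stopifnot(!is.null(names(profile)), all(is.finite(profile)))
  ord <- order(-profile, names(profile))
  v <- profile[ord]
  idx <- which(names(v) %in% unique(gene_set))
  if (!length(idx)) return(NULL)
  core <- .es_core(v, idx, weight_exponent)
  list(es = core$es,
       leading_edge = names(v)[idx[core$leading]],
       hit_ranks = idx, tops = core$tops, bottoms = core$bottoms)
}

#' Permutation-normalised enrichment over a set collection
#'
#' Null enrichment scores come from random gene-label draws of matching
#' set size (the ranking substrate is a correlation profile, so gene
#' permutation — not sample permutation — is the appropriate null).
#' P-values are add-one and two-tailed through the sign-matched null arm:
#' `p = (1 + #\{same-sign null with |ES_null| >= |ES|\}) /
#' (1 + #same-sign null)`. NES divides ES by the mean |null ES| of the
#' matching arm, so `sign(NES) = sign(ES)`; sets whose matching arm has
#' fewer than 10 draws get `NES = NA` and are flagged. BH adjustment is
#' across all tested sets in the call.
#'
#' @param profile Named numeric gene-level ranking vector (one series, or
#'   the combined profile).
#' @param sets A [gene_set_collection()] or named list of gene vectors.
#' @param config A [trans_config()].
#' @param series_id Label recorded in the output rows.
#' @param focal Focal transcript ID recorded in the output rows.
#' @return data.frame with one row per tested set: `set_name`, `size`,
#'   `es`, `nes`, `pvalue`, `padj`, `nes_defined`, `leading_edge`
#'   (semicolon-joined), `series_id`, `focal_transcript_id`.
#' @export
permutation_nes <- function(profile, sets, config = trans_config(),
                            series_id = "combined", focal = NA_character_) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  stopifnot(is.list(sets), !is.null(names(sets)))
  ord <- order(-profile, names(profile))
  v <- profile[ord]
  N <- length(v)
  members <- lapply(sets, function(s) which(names(v) %in% unique(s)))
  sizes <- lengths(members)
  keep <- sizes >= config$min_set_size & sizes <= config$max_set_size
  members <- members[keep]; sizes <- sizes[keep]
  if (!length(members))
    return(data.frame(set_name = character(), size = integer(),
                      es = numeric(), nes = numeric(), pvalue = numeric(),
                      padj = numeric(), nes_defined = logical(),
                      leading_edge = character(), series_id = character(),
                      focal_transcript_id = character(),
                      stringsAsFactors = FALSE))
  # null ES cached per set size; sizes processed in sorted order so the
  # result is invariant to the order of the input sets
  set.seed(config$seed)
  null_by_size <- list()
  for (k in sort(unique(sizes))) {
    null_by_size[[as.character(k)]] <- vapply(seq_len(config$n_perm),
      function(i) .es_core(v, sort(sample.int(N, k)), config$weight_exponent)$es,
      numeric(1))
  }
  rows <- lapply(names(members), function(nm) {
    idx <- members[[nm]]
    core <- .es_core(v, idx, config$weight_exponent)
    null <- null_by_size[[as.character(length(idx))]]
    arm <- if (core$es >= 0) null[null >= 0] else null[null < 0]
    p <- (1 + sum(abs(arm) >= abs(core$es))) / (1 + length(arm))
    nes_ok <- length(arm) >= 10
    nes <- if (nes_ok) core$es / mean(abs(arm)) else NA_real_
    data.frame(set_name = nm, size = length(idx), es = core$es, nes = nes,
               pvalue = p, padj = NA_real_, nes_defined = nes_ok,
               leading_edge = paste(names(v)[idx[core$leading]],
                                    collapse = ";"),
               series_id = series_id, focal_transcript_id = focal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}

#' Trans enrichment across all series
#'
#' Builds the per-series correlation rankings for a focal isoform and runs
#' the permutation enrichment within each series.
#'
#' @param focal Focal transcript ID.
#' @param tensors Named list of per-series [expression_tensor()]s.
#' @param annotation A [tx_annotation()].
#' @param sets A [gene_set_collection()].
#' @param config A [trans_config()].
#' @return data.frame of [permutation_nes()] rows across series.
#' @export
run_trans <- function(focal, tensors, annotation, sets,
                      config = trans_config()) {
  rk <- build_ranking(focal, tensors, annotation, config)
  rows <- lapply(names(rk$per_series), function(sid)
    permutation_nes(rk$per_series[[sid]], sets, config,
                    series_id = sid, focal = focal))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-series enrichment report
#'
#' Keeps sets significant (`padj <= padj_max`) in at least `min_series`
#' series, flags sets whose significant NES signs disagree across series,
#' and returns the per-series NES matrix alongside.
#'
#' @param results data.frame of [run_trans()] / [permutation_nes()] rows
#'   (possibly several series and focal isoforms).
#' @param config A [trans_config()].
#' @return List with `kept` (per-set summary: `set_name`,
#'   `focal_transcript_id`, `n_signif`, `discordant`) and `nes_matrix`
#'   (data.frame, sets x series).
#' @export
report_trans <- function(results, config = trans_config()) {
  if (!nrow(results))
    return(list(kept = data.frame(set_name = character(),
                                  focal_transcript_id = character(),
                                  n_signif = integer(),
                                  discordant = logical()),
                nes_matrix = data.frame()))
  keykept <- list()
  for (key in unique(paste(results$focal_transcript_id, results$set_name,
                           sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    rr <- results[results$focal_transcript_id == parts[1] &
                  results$set_name == parts[2], ]
    sig <- rr[!is.na(rr$padj) & rr$padj <= config$padj_max, ]
    if (nrow(sig) >= config$min_series) {
      keykept[[key]] <- data.frame(
        set_name = parts[2], focal_transcript_id = parts[1],
        n_signif = nrow(sig),
        discordant = length(unique(sign(sig$nes[!is.na(sig$nes)]))) > 1,
        stringsAsFactors = FALSE)
    }
  }
  kept <- if (length(keykept)) do.call(rbind, keykept) else
    data.frame(set_name = character(), focal_transcript_id = character(),
               n_signif = integer(), discordant = logical())
  rownames(kept) <- NULL
  series <- sort(unique(results$series_id))
  sets <- unique(results$set_name)
  nes <- data.frame(set_name = sets, stringsAsFactors = FALSE)
  for (sid in series) {
    rr <- results[results$series_id == sid, ]
    nes[[sid]] <- rr$nes[match(sets, rr$set_name)]
  }
  list(kept = kept, nes_matrix = nes)
}
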