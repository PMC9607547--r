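#' Differential expression configuration
#'
#' Thresholds and permutation settings for the per-series nonparametric
#' differential transcript expression test. The call rule is the raw
#' p-value against `alpha` together with the absolute log2 fold-change
#' gate `lfc_min` (Benjamini-Hochberg q-values are reported but not used
#' for the call).
#'
#' @param alpha Significance threshold on the raw permutation p-value
#'   (default 0.05).
#' @param lfc_min Absolute log2 fold-change threshold (default 0.5; the
#'   call requires `|log2FC| > lfc_min`).
#' @param pseudocount Pseudocount added to group means in the fold-change
#'   estimator (default 5).
#' @param n_perm Number of label permutations for the pooled null
#'   (default 1000).
#' @param paired Paired analysis (default `TRUE`: the series are paired
#'   case/control designs); set `FALSE` for an unpaired rank-sum test.
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `de_config`.
#' @export
de_config <- function(alpha = 0.05, lfc_min = 0.5, pseudocount = 5,
                      n_perm = 1000, paired = TRUE, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, lfc_min >= 0, pseudocount > 0)
  structure(list(alpha = alpha, lfc_min = lfc_min, pseudocount = pseudocount,
                 n_perm = as.integer(n_perm), paired = isTRUE(paired),
                 seed = as.integer(seed)),
            class = "de_config")
}

#' Median-of-ratios count scaling
#'
#' Divides each sample's counts (and each of its inferential replicates)
#' by a size factor computed as the median ratio to the geometric-mean
#' pseudo-reference over transcripts with nonzero counts in all samples.
#' When no transcript is nonzero in every sample, falls back to
#' total-count scaling with a warning. TPM values are left untouched.
#'
#' @param tensor An [expression_tensor()] with at least two samples.
#' @return The scaled tensor; size factors are attached as attribute
#'   `"size_factors"`.
#' @export
scale_counts <- function(tensor) {
  counts <- tensor$counts
  if (ncol(counts) < 2) stop("need at least 2 samples to scale")
  idx <- rowSums(counts == 0) == 0
  if (!any(idx)) {
    warning("no transcript with nonzero counts in all samples; ",
            "falling back to total-count scaling")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
  } else {
    ref <- exp(rowMeans(log(counts[idx, , drop = FALSE])))
    sf <- apply(counts[idx, , drop = FALSE], 2,
                function(cc) median(cc / ref))
  }
  out <- tensor
  out$counts <- sweep(counts, 2, sf, "/")
  if (!is.null(tensor$infreps)) {
    out$infreps <- sweep(tensor$infreps, 2, sf, "/")
  }
  attr(out, "size_factors") <- sf
  out
}

# Within-row ranks (ties averaged) via pairwise column comparisons;
# fast for the small sample counts per series.
.row_ranks <- function(X) {
  S <- ncol(X)
  R <- matrix(0, nrow(X), S, dimnames = dimnames(X))
  for (j in seq_len(S)) {
    less <- rowSums(X < X[, j])
    eq <- rowSums(X == X[, j])
    R[, j] <- less + (eq + 1) / 2
  }
  R
}

# Signed ranks of within-pair differences: sign(d) * rank(|d|) with zero
# differences excluded from the ranking (their entry is 0).
.signed_ranks <- function(D) {
  A <- abs(D)
  nz <- A > 0
  S <- ncol(D)
  R <- matrix(0, nrow(D), S)
  for (j in seq_len(S)) {
    less <- rowSums(nz * (A < A[, j]))
    eq <- rowSums(nz * (A == A[, j]))
    R[, j] <- nz[, j] * (less + (eq + 1) / 2)
  }
  sign(D) * R
}

# One inferential-replicate slice as a matrix (robust to 1-transcript
# tensors, where plain [ , , g] indexing would drop to a vector).
.slice <- function(infreps, g) {
  s <- infreps[, , g, drop = FALSE]
  dim(s) <- dim(infreps)[1:2]
  dimnames(s) <- dimnames(infreps)[1:2]
  s
}

.slices_of <- function(tensor) {
  G <- n_infreps(tensor)
  if (G > 0) lapply(seq_len(G), function(g) .slice(tensor$infreps, g))
  else list(tensor$counts)
}

# Align a per-series design with a tensor's columns and return the pieces
# the rank statistics need.
.de_layout <- function(tensor, design) {
  ds <- as.data.frame(design)
  if (length(unique(ds$series_id)) != 1)
    stop("design must describe a single series; use split_design()")
  if (!all(ds$sample_id %in% colnames(tensor$counts)))
    stop("design samples missing from tensor: ",
         paste(setdiff(ds$sample_id, colnames(tensor$counts)), collapse = ", "))
  ds <- ds[order(ds$pair_id, ds$condition), ]
  list(ds = ds,
       met = ds$sample_id[ds$condition == "metformin"],
       ctl = ds$sample_id[ds$condition == "control"],
       pairs = unique(ds$pair_id))
}

# Average over inferential replicates of the rank structure the statistic
# and its permutation null share. paired: mean signed-rank matrix
# (transcripts x pairs); unpaired: mean rank matrix (transcripts x samples)
# plus the sample/condition layout. Falls back to point estimates at G=0.
.rank_summary <- function(tensor, design, paired) {
  lay <- .de_layout(tensor, design)
  slices <- .slices_of(tensor)
  if (paired) {
    # within-pair differences ordered by pair
    ctl_of <- lay$ds$sample_id[match(paste(lay$pairs, "control"),
                                     paste(lay$ds$pair_id, lay$ds$condition))]
    met_of <- lay$ds$sample_id[match(paste(lay$pairs, "metformin"),
                                     paste(lay$ds$pair_id, lay$ds$condition))]
    M <- 0
    for (Y in slices)
      M <- M + .signed_ranks(Y[, met_of, drop = FALSE] -
                             Y[, ctl_of, drop = FALSE])
    M <- M / length(slices)
    list(paired = TRUE, M = M, n_pairs = length(lay$pairs), lay = lay)
  } else {
    samp <- lay$ds$sample_id
    R <- 0
    for (Y in slices) R <- R + .row_ranks(Y[, samp, drop = FALSE])
    R <- R / length(slices)
    list(paired = FALSE, R = R, samp = samp,
         is_met = lay$ds$condition[match(samp, lay$ds$sample_id)] == "metformin",
         lay = lay)
  }
}

.stat_from_summary <- function(rs) {
  if (rs$paired) {
    rowSums(rs$M) / 2
  } else {
    n1 <- sum(rs$is_met); S <- length(rs$samp)
    rowSums(rs$R[, rs$is_met, drop = FALSE]) - n1 * (S + 1) / 2
  }
}

#' Rank statistic over inferential replicates
#'
#' For each transcript, the mean over the `G` inferential replicates of a
#' centred rank-based two-group statistic on scaled counts: a centred
#' Wilcoxon signed-rank statistic on within-pair differences when
#' `paired`, else a centred Wilcoxon rank-sum (Mann-Whitney) statistic.
#' With no replicates (`G = 0`) the statistic is computed on the point
#' estimates. Swapping condition labels negates the statistic; a
#' transcript constant across samples and replicates scores 0.
#'
#' @param tensor A scaled [expression_tensor()] (see [scale_counts()]).
#' @param design A single-series [series_design()] slice.
#' @param config A [de_config()].
#' @return Named numeric vector of per-transcript statistics.
#' @export
swish_statistic <- function(tensor, design, config = de_config()) {
  rs <- .rank_summary(tensor, design, config$paired)
  setNames(.stat_from_summary(rs), rownames(tensor$counts))
}

#' Pooled permutation p-values
#'
#' Generates null statistics by recomputing the rank statistic under
#' `n_perm` random label permutations — pairs permuted jointly (random
#' within-pair label swaps) when paired, random balanced label
#' reassignments otherwise — and pools the null across all transcripts
#' before computing two-sided add-one p-values
#' `p = (1 + #\{|null| >= |observed|\}) / (1 + N_null)`. Pooling borrows
#' strength across transcripts, without which a three-pair series could
#' never reach small p-values.
#'
#' @param statistics Observed statistics from [swish_statistic()].
#' @param tensor The same scaled tensor.
#' @param design The same single-series design slice.
#' @param config A [de_config()]; `n_perm` must be at least 10.
#' @return Named numeric vector of p-values.
#' @export
permutation_pvalues <- function(statistics, tensor, design,
                                config = de_config()) {
  if (config$n_perm < 10) stop("n_perm must be at least 10")
  rs <- .rank_summary(tensor, design, config$paired)
  set.seed(config$seed)
  P <- config$n_perm
  if (rs$paired) {
    signs <- matrix(sample(c(-1, 1), rs$n_pairs * P, replace = TRUE),
                    rs$n_pairs, P)
    null <- (rs$M %*% signs) / 2
  } else {
    S <- length(rs$samp); n1 <- sum(rs$is_met)
    W <- matrix(0, S, P)
    for (j in seq_len(P)) W[sample.int(S, n1), j] <- 1
    null <- rs$R %*% W - n1 * (S + 1) / 2
  }
  a <- sort(abs(as.numeric(null)))
  N <- length(a)
  obs <- abs(statistics)
  cnt <- N - findInterval(obs, a, left.open = TRUE)
  setNames((1 + cnt) / (1 + N), names(statistics))
}

#' Log2 fold change over inferential replicates
#'
#' The median over inferential replicates of
#' `log2((mean metformin + pseudocount) / (mean control + pseudocount))`
#' on scaled counts; the point estimate when `G = 0`.
#'
#' @inheritParams swish_statistic
#' @return Named numeric vector of per-transcript log2 fold changes.
#' @export
log2fc <- function(tensor, design, config = de_config()) {
  lay <- .de_layout(tensor, design)
  pc <- config$pseudocount
  slices <- .slices_of(tensor)
  lfc <- vapply(slices, function(Y) {
    log2((rowMeans(Y[, lay$met, drop = FALSE]) + pc) /
         (rowMeans(Y[, lay$ctl, drop = FALSE]) + pc))
  }, numeric(nrow(tensor$counts)))
  lfc <- matrix(lfc, nrow = nrow(tensor$counts), ncol = length(slices))
  setNames(apply(lfc, 1, median), rownames(tensor$counts))
}

#' Apply the differential expression call thresholds
#'
#' Sets `is_DE` to `pvalue < alpha AND |log2FC| > lfc_min`, the direction
#' to the fold-change sign for called transcripts (`"none"` otherwise),
#' and attaches Benjamini-Hochberg q-values over the series' p-values
#' (reported, not used for the call).
#'
#' @param results data.frame with at least `pvalue` and `log2FC` columns.
#' @param config A [de_config()].
#' @return `results` with `qvalue`, `is_DE` and `direction` columns.
#' @export
call_de <- function(results, config = de_config()) {
  stopifnot(all(c("pvalue", "log2FC") %in% names(results)))
  results$qvalue <- p.adjust(results$pvalue, method = "BH")
  results$is_DE <- results$pvalue < config$alpha &
    abs(results$log2FC) > config$lfc_min
  results$direction <- ifelse(!results$is_DE, "none",
                              ifelse(results$log2FC > 0, "up", "down"))
  results
}

#' Per-series differential transcript expression
#'
#' Runs the full swish-style analysis for one series: median-of-ratios
#' scaling, the rank statistic averaged over inferential replicates, the
#' pooled permutation null, fold-change estimation and the call
#' thresholds.
#'
#' @param tensor An unscaled [expression_tensor()] for one series.
#' @param design The matching single-series design slice.
#' @param config A [de_config()].
#' @return data.frame with columns `transcript_id`, `statistic`, `log2FC`,
#'   `pvalue`, `qvalue`, `is_DE`, `direction`, `series_id`.
#' @export
run_de <- function(tensor, design, config = de_config()) {
  scaled <- scale_counts(tensor)
  stat <- swish_statistic(scaled, design, config)
  pv <- permutation_pvalues(stat, scaled, design, config)
  fc <- log2fc(scaled, design, config)
  res <- data.frame(transcript_id = names(stat), statistic = as.numeric(stat),
                    log2FC = as.numeric(fc), pvalue = as.numeric(pv),
                    stringsAsFactors = FALSE)
  res <- call_de(res, config)
  res$series_id <- unique(as.data.frame(design)$series_id)
  res
}

#' Differential expression across all series
#'
#' @param tensors Named list of per-series [expression_tensor()]s.
#' @param design A [series_design()] covering the same series.
#' @param config A [de_config()].
#' @return Named list of per-series [run_de()] tables.
#' @export
run_de_all <- function(tensors, design, config = de_config()) {
  sdesign <- split_design(design)
  stopifnot(all(names(tensors) %in% names(sdesign)))
  out <- lapply(names(tensors), function(sid)
    run_de(tensors[[sid]], sdesign[[sid]], config))
  names(out) <- names(tensors)
  out
}
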