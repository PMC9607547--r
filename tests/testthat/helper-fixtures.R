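# Shared fixtures and independent oracles, built in code at test time.

# A small, quick simulated study reused across test files (memoised per
# test-file process).
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed = 3) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- simulation_config(
      seed = seed, n_genes = 80, G_replicates = 20,
      planted_sets = data.frame(set_name = c("SET_POS", "SET_NEG"),
                                size = c(8, 8), shift = c(0.6, -0.6)),
      n_decoy_sets = 2, decoy_set_size = 8)
    .sim_cache[[key]] <- simulate_dataset(cfg)
  }
  .sim_cache[[key]]
}

# Hand-built annotation: focal gene on chr1 at [2e6, 2.01e6) with partner
# genes straddling the 1 Mb window boundary, one overlapping gene, and one
# gene on another chromosome. Coordinates 0-based half-open.
boundary_annotation <- function(window = 1e6) {
  fs <- 2e6; fe <- 2.01e6
  genes <- data.frame(
    gene_id = c("GF", "G_IN", "G_OUT", "G_EDGE", "G_OVL", "G_CHR"),
    gene_name = c("FOCAL", "NEAR", "FAR", "EDGE", "OVL", "OTHER"),
    biotype = c("lncRNA", rep("protein_coding", 5)),
    chrom = c(rep("chr1", 5), "chr2"),
    start = c(fs, fe + window - 1, fe + window + 1, fe + window,
              fs + 5e3, fs),
    end = c(fe, fe + window - 1 + 1e4, fe + window + 1 + 1e4,
            fe + window + 1e4, fs + 6e3, fe),
    strand = "+", stringsAsFactors = FALSE)
  # gaps to the focal gene end: G_IN = window-1 (inside), G_OUT = window+1
  # (outside), G_EDGE = window exactly (outside: half-open window),
  # G_OVL overlaps (distance 0), G_CHR on another chromosome
  genes$start <- as.numeric(genes$start); genes$end <- as.numeric(genes$end)
  tx <- genes
  tx$transcript_id <- paste0("T_", genes$gene_id)
  tx$transcript_name <- paste0(genes$gene_name, "-201")
  tx_annotation(genes, tx[, c("transcript_id", "gene_id", "transcript_name",
                              "biotype", "chrom", "start", "end", "strand")])
}

# A deterministic expression tensor with given TPM rows (counts = TPM).
tensor_from_tpm <- function(tpm_rows, sample_prefix = "s") {
  m <- do.call(rbind, tpm_rows)
  colnames(m) <- paste0(sample_prefix, seq_len(ncol(m)))
  expression_tensor(m, m, lengths = rep(1000, nrow(m)))
}

# A vector with exact Pearson correlation `r` to x (n >= 3).
vector_with_cor <- function(x, r, seed = 1) {
  set.seed(seed)
  e <- rnorm(length(x))
  u <- x - mean(x)
  e <- e - mean(e)
  e <- e - u * sum(e * u) / sum(u * u)      # orthogonalise
  y <- r * u / sqrt(sum(u^2)) + sqrt(1 - r^2) * e / sqrt(sum(e^2))
  y + 10
}

# --- independent oracles -------------------------------------------------

# Median-of-ratios size factors, written directly from the definition.
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(z) all(z > 0))
  ref <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  apply(counts[keep, , drop = FALSE], 2, function(cc) median(cc / ref))
}

# Enumerate the full GSEA running sum position by position.
oracle_es <- function(profile, gene_set, exponent) {
  ord <- order(-profile, names(profile))
  v <- profile[ord]
  hit <- names(v) %in% unique(gene_set)
  w <- abs(v)^exponent
  nr <- sum(w[hit])
  if (nr == 0) { w[] <- 1; nr <- sum(hit) }
  dec <- 1 / (length(v) - sum(hit))
  run <- 0; best <- 0
  for (i in seq_along(v)) {
    run <- if (hit[i]) run + w[i] / nr else run - dec
    # positive extrema win magnitude ties (compared at rounding tolerance)
    if (abs(run) > abs(best) + 1e-12 ||
        (abs(abs(run) - abs(best)) <= 1e-12 && run > best))
      best <- run
  }
  unname(best)
}

# Centred Wilcoxon rank-sum statistic by direct enumeration of ranks.
oracle_ranksum <- function(x_treat, x_ctl) {
  r <- rank(c(x_treat, x_ctl))
  n1 <- length(x_treat); n <- n1 + length(x_ctl)
  sum(r[seq_len(n1)]) - n1 * (n + 1) / 2
}

# Centred Wilcoxon signed-rank statistic (zeros dropped).
oracle_signedrank <- function(d) {
  nz <- d != 0
  if (!any(nz)) return(0)
  r <- rank(abs(d[nz]))
  sum(sign(d[nz]) * r) / 2
}
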