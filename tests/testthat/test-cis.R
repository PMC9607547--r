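test_that("the flanking window honours the boundary at single-bp resolution", {
  ann <- boundary_annotation()
  nb <- neighbors_within_window("T_GF", ann, cis_config())
  ids <- nb$transcript_id
  expect_true("T_G_IN" %in% ids)      # gap = 999,999 bp
  expect_false("T_G_OUT" %in% ids)    # gap = 1,000,001 bp
  expect_false("T_G_EDGE" %in% ids)   # gap = 1,000,000 bp: half-open window
  expect_false("T_G_CHR" %in% ids)    # other chromosome
  expect_false("T_GF" %in% ids)       # never the focal transcript itself
  expect_true("T_G_OVL" %in% ids)
  expect_equal(nb$distance_bp[nb$transcript_id == "T_G_IN"], 1e6 - 1)
  expect_equal(nb$distance_bp[nb$transcript_id == "T_G_OVL"], 0)
  expect_error(neighbors_within_window("nope", ann), "unknown")
})

test_that("the window relation is symmetric and strand-independent", {
  sim <- small_sim()
  ann <- sim$annotation
  cfg <- cis_config(window_bp = 8e5)
  tx <- ann$transcripts
  set.seed(2)
  for (t in sample(tx$transcript_id, 10)) {
    nb <- neighbors_within_window(t, ann, cfg)
    for (p in unique(nb$gene_id)) {
      ptx <- tx$transcript_id[tx$gene_id == p][1]
      back <- neighbors_within_window(ptx, ann, cfg)
      expect_true(tx$gene_id[tx$transcript_id == t][1] %in% back$gene_id)
    }
  }
})

test_that("pearson_with_pvalue matches the closed form and cor.test", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  out <- pearson_with_pvalue(x, y)
  expect_equal(out$r, 10 / sqrt(148))      # direct formula evaluation
  expect_equal(pearson_with_pvalue(x, x)$r, 1)
  expect_equal(pearson_with_pvalue(x, -x)$r, -1)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    ref <- cor.test(a, b)
    got <- pearson_with_pvalue(a, b)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  expect_warning(out <- pearson_with_pvalue(rep(1, 5), x), "variance")
  expect_true(is.na(out$r))
  expect_error(pearson_with_pvalue(1:2, 1:2), "at least 3")
})

test_that("Fisher-combined p-values are uniform under the null", {
  set.seed(6)
  comb <- replicate(800, isolnc:::.fisher_combine(runif(6)))
  expect_gt(suppressWarnings(ks.test(comb, "punif"))$p.value, 0.01)
})

test_that("planted cis pairs pass and decoys beyond the window never appear", {
  sim <- small_sim()
  ct <- sim$truth$cis
  pairs <- screen_cis(unique(ct$focal_tx), sim$tensors, sim$annotation,
                      cis_config())
  key <- paste(pairs$lnc_transcript_id, pairs$partner_transcript_id)
  planted <- paste(ct$focal_tx[ct$in_window], ct$partner_tx[ct$in_window])
  decoys <- paste(ct$focal_tx[!ct$in_window], ct$partner_tx[!ct$in_window])
  expect_true(all(planted %in% key))
  expect_true(all(pairs$passes[key %in% planted]))
  expect_false(any(decoys %in% key))
  # emitted distances never exceed the window
  expect_true(all(pairs$genomic_distance_bp <= 1e6))
  # passes flag is exactly the r/p rule
  expect_equal(pairs$passes,
               pairs$r_combined > 0.8 & pairs$p_combined < 0.01)
})

test_that("the r > 0.8 and p < 0.01 cutoffs gate on both sides", {
  ann <- boundary_annotation()
  x <- as.numeric(1:6)
  mk <- function(r) {
    rows <- list(T_GF = x + 10,
                 T_G_IN = vector_with_cor(x, r),
                 T_G_OUT = x + 10, T_G_EDGE = x + 10,
                 T_G_OVL = rep(1, 6) + (1:6) / 100, T_G_CHR = x)
    tensor_from_tpm(rows)
  }
  run1 <- function(r) {
    tensors <- list(S1 = mk(r))
    screen_cis("T_GF", tensors, ann, cis_config())
  }
  # r straddling 0.8 with p well under 0.01 either way is impossible at
  # n = 6, so check r with six concordant series (Fisher p tiny) instead
  run6 <- function(r) {
    tensors <- lapply(setNames(1:6, paste0("S", 1:6)), function(i) mk(r))
    screen_cis("T_GF", tensors, ann, cis_config())
  }
  below <- run6(0.79); above <- run6(0.81)
  expect_equal(below$r_combined[below$partner_transcript_id == "T_G_IN"],
               0.79, tolerance = 1e-10)
  expect_false(below$passes[below$partner_transcript_id == "T_G_IN"])
  expect_true(above$passes[above$partner_transcript_id == "T_G_IN"])
  # p gate: r fixed above 0.8, single series so Fisher p = the t-test p
  lowp <- run1(0.93)    # p ~ 0.0072 < 0.01
  highp <- run1(0.90)   # p ~ 0.0145 > 0.01
  expect_true(lowp$passes[lowp$partner_transcript_id == "T_G_IN"])
  expect_false(highp$passes[highp$partner_transcript_id == "T_G_IN"])
})

test_that("neighbour DET counts use transcript-level set semantics", {
  genes <- data.frame(
    gene_id = c("GL", "GN"), gene_name = c("L", "N"),
    biotype = c("lncRNA", "protein_coding"), chrom = "chr1",
    start = c(0, 2e5), end = c(1e4, 3e5), strand = "+")
  tx <- data.frame(
    transcript_id = c("TL", "TN1", "TN2", "TN3"),
    gene_id = c("GL", "GN", "GN", "GN"),
    transcript_name = c("L-201", "N-201", "N-202", "N-203"),
    biotype = c("lncRNA", rep("protein_coding", 3)),
    chrom = "chr1", start = c(0, 2e5, 2e5, 2e5),
    end = c(1e4, 3e5, 3e5, 3e5), strand = "+")
  ann <- tx_annotation(genes, tx)
  mk_de <- function(ids) list(S1 = data.frame(
    transcript_id = ids, is_DE = TRUE, stringsAsFactors = FALSE))
  expect_equal(unname(count_neighbor_dets("TL",
    mk_de(c("TN1", "TN2", "TN3")), ann, cis_config())), 3)
  expect_equal(unname(count_neighbor_dets("TL",
    mk_de("TL"), ann, cis_config())), 0)
  # invariant to the order (and duplication across) series tables
  two <- list(S1 = mk_de(c("TN1", "TN2"))$S1, S2 = mk_de(c("TN2", "TN1"))$S1)
  expect_equal(unname(count_neighbor_dets("TL", two, ann, cis_config())), 2)
  expect_equal(unname(count_neighbor_dets("TL", rev(two), ann,
                                          cis_config())), 2)
})
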