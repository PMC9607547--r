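ranking_fixture <- function() {
  # 3 genes; gene B has two isoforms with correlations of opposite sign
  genes <- data.frame(
    gene_id = c("GF", "GA", "GB", "GC"),
    gene_name = c("FOC", "A", "B", "C"),
    biotype = c("lncRNA", rep("protein_coding", 3)),
    chrom = "chr1", start = c(0, 1e5, 2e5, 3e5),
    end = c(1e4, 1.1e5, 2.1e5, 3.1e5), strand = "+")
  tx <- data.frame(
    transcript_id = c("TF", "TA", "TB1", "TB2", "TC"),
    gene_id = c("GF", "GA", "GB", "GB", "GC"),
    transcript_name = paste0(c("FOC", "A", "B", "B", "C"), "-20",
                             c(1, 1, 1, 2, 1)),
    biotype = c("lncRNA", rep("protein_coding", 4)),
    chrom = "chr1", start = c(0, 1e5, 2e5, 2e5, 3e5),
    end = c(1e4, 1.1e5, 2.1e5, 2.1e5, 3.1e5), strand = "+")
  tx_annotation(genes, tx)
}

test_that("rankings use per-series Pearson r collapsed to genes", {
  ann <- ranking_fixture()
  x <- as.numeric(1:8)
  rows <- list(TF = x,
               TA = 2 * x + 3,                         # r = 1
               TB1 = vector_with_cor(x, 0.3, seed = 2),
               TB2 = vector_with_cor(x, -0.9, seed = 3),
               TC = vector_with_cor(x, 0.5, seed = 4))
  tens <- tensor_from_tpm(rows)
  rk <- build_ranking("TF", list(S1 = tens), ann, trans_config())
  r1 <- rk$per_series$S1
  expect_equal(unname(r1["A"]), 1)                 # perfectly correlated gene
  expect_equal(names(which.max(r1)), "A")          # tops the ranking
  expect_equal(unname(r1["B"]), -0.9, tolerance = 1e-10)  # max-|r| collapse
  mean_rk <- build_ranking("TF", list(S1 = tens), ann,
                           trans_config(collapse = "mean"))
  expect_equal(unname(mean_rk$per_series$S1["B"]), (0.3 - 0.9) / 2,
               tolerance = 1e-10)
  # combined profile is the per-gene median across series
  mk <- function(rC) {
    rows$TC <- vector_with_cor(x, rC, seed = 5)
    tensor_from_tpm(rows)
  }
  rk3 <- build_ranking("TF", list(S1 = mk(0.2), S2 = mk(0.4), S3 = mk(0.9)),
                       ann, trans_config())
  expect_equal(unname(rk3$combined["C"]), 0.4, tolerance = 1e-10)
  # lncRNA focal itself never appears in the ranking
  expect_false("FOC" %in% names(r1))
})

test_that("enrichment scores equal the brute-force running sum exactly", {
  set.seed(17)
  for (i in 1:100) {
    N <- sample(5:50, 1)
    profile <- setNames(rnorm(N), paste0("g", sample(1e4, N)))
    k <- sample(2:min(10, N - 1), 1)
    gene_set <- sample(names(profile), k)
    expo <- sample(c(0, 1, 1.5), 1)
    got <- enrichment_score(profile, gene_set, expo)
    # same value up to summation order (cumulative sum vs stepwise loop)
    expect_equal(got$es, oracle_es(profile, gene_set, expo),
                 tolerance = 1e-12)
  }
})

test_that("enrichment scores agree with fgsea's statistic", {
  set.seed(18)
  for (i in 1:25) {
    N <- sample(10, 1) + 20
    profile <- setNames(sort(rnorm(N), decreasing = TRUE),
                        paste0("g", seq_len(N)))
    gene_set <- sample(names(profile), 6)
    got <- enrichment_score(profile, gene_set, 1)
    ref <- fgsea::calcGseaStat(profile,
                               selectedStats = which(names(profile) %in%
                                                       gene_set),
                               gseaParam = 1)
    expect_equal(got$es, ref, tolerance = 1e-12)
  }
})

test_that("limit cases: members at the top give ES = 1; unweighted ES bounded", {
  profile <- setNames(seq(5, 0.1, length.out = 20), paste0("g", 1:20))
  top <- paste0("g", 1:4)
  out <- enrichment_score(profile, top, 1)
  expect_equal(out$es, 1)
  expect_setequal(out$leading_edge, top)
  set.seed(19)
  for (i in 1:30) {
    profile <- setNames(rnorm(30), paste0("g", 1:30))
    es <- enrichment_score(profile, sample(names(profile), 5), 0)$es
    expect_true(es >= -1 && es <= 1)
  }
  # weight 0, N = 4, members at ranks 1 and 3: enumerate the running sum
  p4 <- setNames(c(4, 3, 2, 1), c("a", "b", "c", "d"))
  expect_equal(enrichment_score(p4, c("a", "c"), 0)$es,
               oracle_es(p4, c("a", "c"), 0))
  expect_equal(enrichment_score(p4, c("a", "c"), 0)$es, 0.5)
})

test_that("reversing a symmetric profile mirrors the extremum structure", {
  vals <- c(5, 4, 3, 2, 1)
  profile <- setNames(vals, paste0("g", 1:5))
  rev_profile <- setNames(rev(vals), paste0("g", 1:5))
  for (i in 1:5) {
    set <- paste0("g", c(i, (i %% 5) + 1))
    es_f <- enrichment_score(profile, set, 0)$es
    # same set on the reversed ranking: mirrored positions
    mirrored <- paste0("g", 6 - c(i, (i %% 5) + 1))
    es_r <- enrichment_score(rev_profile, mirrored, 0)$es
    expect_equal(abs(es_f), abs(es_r))
  }
})

test_that("permutation NES keeps the ES sign and is deterministic", {
  sim <- small_sim()
  rk <- build_ranking(sim$truth$focal_tx, sim$tensors["S1"],
                      sim$annotation, trans_config())
  cfg <- trans_config(n_perm = 400, seed = 3)
  res <- permutation_nes(rk$per_series$S1, sim$gene_sets, cfg,
                         series_id = "S1", focal = sim$truth$focal_tx)
  expect_true(all(sign(res$nes[res$nes_defined]) ==
                  sign(res$es[res$nes_defined])))
  expect_true(all(res$padj >= res$pvalue - 1e-15))
  res2 <- permutation_nes(rk$per_series$S1, sim$gene_sets, cfg,
                          series_id = "S1", focal = sim$truth$focal_tx)
  expect_identical(res, res2)
  # invariant to the order of the input sets
  shuffled <- sim$gene_sets$sets[rev(names(sim$gene_sets$sets))]
  res3 <- permutation_nes(rk$per_series$S1, shuffled, cfg,
                          series_id = "S1", focal = sim$truth$focal_tx)
  res3 <- res3[match(res$set_name, res3$set_name), ]
  expect_equal(res$es, res3$es)
  expect_equal(res$pvalue, res3$pvalue)
})

test_that("planted sets are recovered with the right NES signs", {
  sim <- small_sim()
  cfg <- trans_config(n_perm = 2000, seed = 3)
  res <- run_trans(sim$truth$focal_tx, sim$tensors, sim$annotation,
                   sim$gene_sets, cfg)
  pos <- res[res$set_name == "SET_POS", ]
  neg <- res[res$set_name == "SET_NEG", ]
  expect_gte(sum(pos$pvalue < 0.01 & pos$nes > 0, na.rm = TRUE), 2)
  expect_gte(sum(neg$nes < 0, na.rm = TRUE), 4)
})

test_that("random sets give calibrated permutation p-values", {
  set.seed(23)
  profile <- setNames(rnorm(150), paste0("g", 1:150))
  sets <- lapply(1:120, function(i) sample(names(profile), 8))
  names(sets) <- paste0("R", 1:120)
  res <- permutation_nes(profile, sets, trans_config(n_perm = 500, seed = 9))
  expect_gt(suppressWarnings(ks.test(res$pvalue, "punif"))$p.value, 0.01)
})

test_that("the cross-series report applies the two-experiment rule", {
  mk <- function(set, series, padj, nes) data.frame(
    set_name = set, size = 10, es = nes / 2, nes = nes, pvalue = padj / 2,
    padj = padj, nes_defined = TRUE, leading_edge = "",
    series_id = series, focal_transcript_id = "TF",
    stringsAsFactors = FALSE)
  res <- rbind(
    mk("ONE_SERIES", "S1", 1e-5, 2), mk("ONE_SERIES", "S2", 0.5, 1),
    mk("TWO_SERIES", "S1", 1e-5, 2), mk("TWO_SERIES", "S2", 5e-4, 1.8),
    mk("DISCORD", "S1", 1e-5, 2), mk("DISCORD", "S2", 1e-5, -2))
  rep <- report_trans(res, trans_config())
  expect_false("ONE_SERIES" %in% rep$kept$set_name)
  expect_true("TWO_SERIES" %in% rep$kept$set_name)
  expect_false(rep$kept$discordant[rep$kept$set_name == "TWO_SERIES"])
  expect_true(rep$kept$discordant[rep$kept$set_name == "DISCORD"])
  expect_equal(sort(names(rep$nes_matrix)), sort(c("set_name", "S1", "S2")))
  # empty input exits cleanly
  empty <- report_trans(res[0, ], trans_config())
  expect_equal(nrow(empty$kept), 0)
})
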