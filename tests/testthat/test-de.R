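make_tensor <- function(counts, G = 0) {
  counts <- as.matrix(counts)
  rownames(counts) <- paste0("T", seq_len(nrow(counts)))
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  infreps <- NULL
  if (G > 0) {
    infreps <- array(rep(counts, G), c(dim(counts), G),
                     dimnames = c(dimnames(counts), list(NULL)))
  }
  expression_tensor(counts, counts, rep(1000, nrow(counts)), infreps)
}

design_3v3 <- function() {
  series_design(data.frame(
    sample_id = paste0("s", 1:6), series_id = "S1",
    condition = rep(c("control", "metformin"), 3),
    pair_id = rep(paste0("p", 1:3), each = 2),
    dose_mM = 10, hours = 24))
}

test_that("size factors match the median-of-ratios definition", {
  # identical samples -> all factors 1
  t1 <- make_tensor(matrix(rep(c(5, 10, 20), 4), ncol = 4))
  expect_equal(unname(attr(scale_counts(t1), "size_factors")), rep(1, 4))

  # sample B = 2 x sample A -> factors proportional to (1, 2)
  a <- c(4, 8, 100, 3)
  t2 <- make_tensor(cbind(a, 2 * a))
  sf <- attr(scale_counts(t2), "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)

  # random matrix: agree with the direct brute-force computation and with
  # DESeq2's implementation (up to a common scale)
  set.seed(42)
  m <- matrix(rnbinom(20 * 50, mu = 50, size = 5), nrow = 50)
  m[m == 0] <- 1
  t3 <- make_tensor(m)
  sf <- attr(scale_counts(t3), "size_factors")
  expect_equal(unname(sf), unname(oracle_size_factors(m)), tolerance = 1e-12)
  # DESeq2 takes the median on the log-ratio scale, which differs from the
  # plain ratio median only when the median interpolates two values
  sf_deseq <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf / sf[1]), unname(sf_deseq / sf_deseq[1]),
               tolerance = 0.01)

  # scaling divides counts and all inferential replicates
  t4 <- make_tensor(cbind(a, 2 * a), G = 3)
  sc <- scale_counts(t4)
  expect_equal(sc$infreps[, 2, 1], sc$infreps[, 1, 1], tolerance = 1e-12)
})

test_that("no common nonzero transcript falls back to total-count scaling", {
  m <- rbind(c(10, 0), c(0, 10))
  expect_warning(sc <- scale_counts(make_tensor(m)), "total-count")
  expect_equal(unname(attr(sc, "size_factors")), c(1, 1))
})

test_that("unpaired statistic hits the enumerated extreme and matches the oracle", {
  # metformin counts all greater than control in every replicate:
  # the centred rank-sum must equal the enumerated maximum 9 - 9/2 = 4.5
  cnt <- rbind(c(1, 10, 2, 20, 3, 30))
  tens <- make_tensor(cnt, G = 5)
  cfg <- de_config(paired = FALSE)
  s <- swish_statistic(tens, design_3v3(), cfg)
  expect_equal(unname(s), 4.5)
  expect_equal(unname(s),
               oracle_ranksum(c(10, 20, 30), c(1, 2, 3)))

  # random data agree with the direct rank enumeration per transcript
  set.seed(7)
  m <- matrix(rnbinom(60, mu = 30, size = 2), nrow = 10)
  tens2 <- make_tensor(m)
  s2 <- swish_statistic(tens2, design_3v3(), cfg)
  met <- c(2, 4, 6); ctl <- c(1, 3, 5)
  for (i in 1:10)
    expect_equal(unname(s2[i]), oracle_ranksum(m[i, met], m[i, ctl]))
})

test_that("paired statistic matches the signed-rank oracle", {
  set.seed(8)
  m <- matrix(rnbinom(60, mu = 30, size = 2), nrow = 10)
  tens <- make_tensor(m)
  s <- swish_statistic(tens, design_3v3(), de_config(paired = TRUE))
  for (i in 1:10) {
    d <- m[i, c(2, 4, 6)] - m[i, c(1, 3, 5)]
    expect_equal(unname(s[i]), oracle_signedrank(d))
  }
})

test_that("label swap negates the statistic; constant transcripts score 0", {
  sim <- small_sim()
  tens <- scale_counts(sim$tensors$S1)
  des <- split_design(sim$design)$S1
  for (paired in c(TRUE, FALSE)) {
    cfg <- de_config(paired = paired)
    s <- swish_statistic(tens, des, cfg)
    swapped <- des
    swapped$condition <- ifelse(swapped$condition == "control",
                                "metformin", "control")
    expect_equal(unname(swish_statistic(tens, series_design(swapped), cfg)),
                 unname(-s))
  }
  flat <- make_tensor(matrix(7, 1, 6), G = 3)
  expect_equal(unname(swish_statistic(flat, design_3v3())), 0)
  expect_equal(unname(swish_statistic(flat, design_3v3(),
                                      de_config(paired = FALSE))), 0)
})

test_that("pooled permutation p-values follow the add-one formula", {
  set.seed(9)
  tens <- make_tensor(matrix(rnbinom(5 * 6, mu = 30, size = 2), nrow = 5))
  des <- design_3v3()
  cfg <- de_config(n_perm = 40, paired = FALSE, seed = 2)
  N <- 5 * 40   # pooled null size: transcripts x permutations
  # observed beyond every null value -> minimal attainable p
  p_big <- permutation_pvalues(c(a = 1e9), tens, des, cfg)
  expect_equal(unname(p_big), 1 / (1 + N))
  # observed 0 -> every |null| >= 0 -> p = 1
  p_zero <- permutation_pvalues(c(a = 0), tens, des, cfg)
  expect_equal(unname(p_zero), 1)
  # monotone nonincreasing in |observed|
  p_seq <- permutation_pvalues(setNames(c(0.5, 1.5, 3, 4.49), letters[1:4]),
                               tens, des, cfg)
  expect_true(all(diff(unname(p_seq)) <= 0))
  expect_error(permutation_pvalues(c(a = 1), tens, des,
                                   de_config(n_perm = 5)), "n_perm")
})

test_that("log2 fold change uses the pseudocount and replicate median", {
  # group means 20 vs 10, pseudocount 5 -> log2(25/15)
  cnt <- rbind(c(10, 20, 10, 20, 10, 20))
  tens <- make_tensor(cnt)
  expect_equal(unname(log2fc(tens, design_3v3())), log2(25 / 15))
  # identical groups -> 0
  same <- make_tensor(rbind(c(9, 9, 9, 9, 9, 9)), G = 4)
  expect_equal(unname(log2fc(same, design_3v3())), 0)
})

test_that("planted log2FC = 2 is estimated within 0.3 at high expression", {
  cfg <- simulation_config(
    seed = 21, n_series = 1, n_pairs_per_series = 50, n_genes = 30,
    G_replicates = 0, de_expression_range = c(300, 600),
    planted_de = data.frame(n = 2, log2FC = c(2), k_series = 1),
    planted_cis = data.frame(rho = numeric(), distance = numeric()),
    planted_sets = data.frame(set_name = character(), size = integer(),
                              shift = numeric()))
  sim <- simulate_dataset(cfg)
  sid <- sim$truth$de$series_id[1]
  tens <- scale_counts(sim$tensors[[sid]])
  fc <- log2fc(tens, split_design(sim$design)[[sid]])
  expect_lt(max(abs(fc[sim$truth$de$transcript_id] - 2)), 0.3)
})

test_that("the DE call applies p < alpha AND |log2FC| > lfc_min", {
  res <- data.frame(
    transcript_id = paste0("T", 1:6),
    pvalue = c(0.04, 0.04, 0.06, 0.05, 0.04, 0.04),
    log2FC = c(0.6, -0.6, 3.0, 3.0, 0.5, 0.501))
  out <- call_de(res, de_config())
  expect_equal(out$is_DE, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$direction,
               c("up", "down", "none", "none", "none", "up"))
  # BH q-values are monotone nondecreasing in p
  ord <- order(out$pvalue)
  expect_true(all(diff(out$qvalue[ord]) >= -1e-15))
  expect_true(all(out$qvalue >= out$pvalue))
})

test_that("G = 0 tensors fall back to point-estimate statistics", {
  set.seed(10)
  m <- matrix(rnbinom(60, mu = 40, size = 3), nrow = 10)
  with_reps <- make_tensor(m, G = 4)   # replicates identical to counts
  without <- make_tensor(m)
  for (paired in c(TRUE, FALSE)) {
    cfg <- de_config(paired = paired)
    expect_equal(swish_statistic(with_reps, design_3v3(), cfg),
                 swish_statistic(without, design_3v3(), cfg))
  }
})
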