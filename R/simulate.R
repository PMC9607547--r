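#' Simulation configuration
#'
#' Defines the synthetic study: six paired case/control series of
#' triplicates with Gibbs-style inferential replicates, negative-binomial
#' counts, and planted signal at all three levels the pipeline screens for
#' (differential lncRNA isoforms shared across series, cis-correlated
#' transcript pairs inside a 1 Mb window with decoys beyond it, and gene
#' sets whose members track a focal isoform's expression).
#'
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @param n_series Number of case/control series (default 6).
#' @param n_pairs_per_series Pairs per series (default 3, i.e. paired
#'   triplicates).
#' @param n_genes Number of simulated genes (default 250).
#' @param isoforms_per_gene Integer range `c(min, max)` of isoforms drawn
#'   uniformly per gene.
#' @param frac_lncRNA Fraction of (non-planted) genes given lncRNA biotype.
#' @param G_replicates Inferential replicates per sample (default 100).
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param mean_log_expression Named vector `c(mu, sigma)`: natural-log mean
#'   and sd of baseline expression.
#' @param uncertainty_cv Coefficient of variation of the multiplicative
#'   gamma noise that generates inferential replicates; 0 makes every
#'   replicate equal the point-estimate counts.
#' @param pair_sd Log-scale sd of the per-(pair, transcript) baseline
#'   offset shared by the two samples of a pair (gives the paired design
#'   statistical meaning).
#' @param corr_sd Log-scale sd of the latent per-sample factors that drive
#'   planted cis correlations.
#' @param trans_focal_sd Log-scale sd of the latent factor on the
#'   trans-acting focal isoform (smaller than `corr_sd`: set members
#'   inherit the focal's whole deviation, so a large own-factor is not
#'   needed and would mask the focal's condition effect in a three-pair
#'   series).
#' @param depth_sd Log-scale sd of per-sample sequencing-depth factors.
#' @param member_sd Log-scale sd of the idiosyncratic noise added to
#'   planted gene-set members.
#' @param chrom_length Length (bp) of each simulated chromosome.
#' @param planted_de data.frame with columns `n`, `log2FC`, `k_series`:
#'   each row plants `n` lncRNA isoforms at that fold change in a random
#'   subset of `k_series` series. The default mirrors a six-series study in
#'   which one isoform is up in all six series, a few are altered in five
#'   or four, and the rest are series-specific.
#' @param de_expression_range Baseline-mean range (counts) for planted DE
#'   isoforms ("moderate expression"), drawn log-uniformly.
#' @param planted_cis data.frame with columns `rho`, `distance`: each row
#'   plants a focal lncRNA / protein-coding partner pair at that edge
#'   distance with latent correlation `rho`, plus a decoy partner with the
#'   same correlation placed `decoy_distance` away.
#' @param decoy_distance Distance (bp) of decoy partners (default 1.5 Mb,
#'   beyond the 1 Mb screen window).
#' @param cis_expression_range Baseline-mean range for cis-pair transcripts.
#' @param planted_sets data.frame with columns `set_name`, `size`, `shift`:
#'   gene sets whose member genes inherit `shift` times the focal isoform's
#'   expression deviation (negative shifts give inversely correlated sets).
#' @param n_decoy_sets,decoy_set_size Unrelated gene sets added to the
#'   collection.
#' @param keep_latent Store the latent factor draws for validation.
#' @return A validated object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_series = 6,
                              n_pairs_per_series = 3,
                              n_genes = 400,
                              isoforms_per_gene = c(1, 3),
                              frac_lncRNA = 0.3,
                              G_replicates = 100,
                              nb_dispersion = 0.02,
                              mean_log_expression = c(mu = 4, sigma = 1.2),
                              uncertainty_cv = 0.2,
                              pair_sd = 0.1,
                              corr_sd = 0.5,
                              trans_focal_sd = 0.2,
                              depth_sd = 0.25,
                              member_sd = 0.3,
                              chrom_length = 3e8,
                              planted_de = data.frame(
                                n = c(1, 2, 1, 3, 3, 10, 10),
                                log2FC = c(2, 2, -2, 2, -2, 2, -2),
                                k_series = c(6, 5, 5, 4, 4, 1, 1)),
                              de_expression_range = c(50, 400),
                              planted_cis = data.frame(
                                rho = c(0.95, 0.95),
                                distance = c(5e5, 5e5)),
                              decoy_distance = 1.5e6,
                              cis_expression_range = c(150, 600),
                              planted_sets = data.frame(
                                set_name = c("PLANT_SET_UP_A", "PLANT_SET_UP_B",
                                             "PLANT_SET_DOWN_A"),
                                size = c(15, 15, 15),
                                shift = c(0.6, 0.6, -0.6)),
                              n_decoy_sets = 4,
                              decoy_set_size = 15,
                              keep_latent = FALSE) {
  cfg <- list(seed = as.integer(seed), n_series = as.integer(n_series),
              n_pairs_per_series = as.integer(n_pairs_per_series),
              n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              frac_lncRNA = frac_lncRNA, G_replicates = as.integer(G_replicates),
              nb_dispersion = nb_dispersion,
              mean_log_expression = mean_log_expression,
              uncertainty_cv = uncertainty_cv, pair_sd = pair_sd,
              corr_sd = corr_sd, trans_focal_sd = trans_focal_sd,
              depth_sd = depth_sd, member_sd = member_sd,
              chrom_length = chrom_length,
              planted_de = planted_de,
              de_expression_range = de_expression_range,
              planted_cis = planted_cis, decoy_distance = decoy_distance,
              cis_expression_range = cis_expression_range,
              planted_sets = planted_sets,
              n_decoy_sets = as.integer(n_decoy_sets),
              decoy_set_size = as.integer(decoy_set_size),
              keep_latent = isTRUE(keep_latent))
  if (cfg$n_genes < 2) stop("n_genes must be >= 2")
  if (cfg$frac_lncRNA < 0 || cfg$frac_lncRNA > 1)
    stop("frac_lncRNA must be in [0, 1]")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (cfg$uncertainty_cv < 0) stop("uncertainty_cv must be >= 0")
  if (nrow(cfg$planted_de)) {
    if (any(cfg$planted_de$log2FC == 0)) stop("planted log2FC must be nonzero")
    if (any(cfg$planted_de$k_series < 1 | cfg$planted_de$k_series > cfg$n_series))
      stop("planted k_series out of range 1..n_series")
  }
  if (nrow(cfg$planted_cis)) {
    if (any(cfg$planted_cis$rho <= -1 | cfg$planted_cis$rho >= 1))
      stop("planted cis rho must be in (-1, 1)")
    if (any(cfg$planted_cis$distance <= 0)) stop("cis distance must be positive")
  }
  if (nrow(cfg$planted_sets) && any(abs(cfg$planted_sets$shift) >= 1))
    stop("planted set shift must be in (-1, 1)")
  structure(cfg, class = "sim_config")
}

#' Null simulation configuration
#'
#' A [simulation_config()] with no planted signal of any kind: the global
#' null used to check the calibration of the differential expression test.
#'
#' @param seed,... Passed to [simulation_config()].
#' @return A `sim_config` with empty `planted_de`, `planted_cis` and
#'   `planted_sets`.
#' @export
null_simulation_config <- function(seed = 1, ...) {
  simulation_config(
    seed = seed,
    planted_de = data.frame(n = integer(), log2FC = numeric(),
                            k_series = integer()),
    planted_cis = data.frame(rho = numeric(), distance = numeric()),
    planted_sets = data.frame(set_name = character(), size = integer(),
                              shift = numeric()),
    ...)
}

#' Simulate a transcript annotation
#'
#' Genes are placed on a few chromosomes with inter-gene gaps short enough
#' that most genes have neighbours inside a 1 Mb window. Planted cis pairs
#' occupy dedicated blocks on the first chromosome: the partner gene's
#' nearest edge sits exactly at the requested distance from the focal gene,
#' and a decoy partner lies at `decoy_distance` (beyond the screen window)
#' by construction. Each gene gets 1 or more isoforms, the first spanning
#' the gene; biotypes are assigned per `frac_lncRNA` (cis focal genes are
#' always lncRNA, partners and decoys protein-coding).
#'
#' @param config A [simulation_config()].
#' @return A [tx_annotation()] with attribute `"cis_layout"`, a data.frame
#'   mapping each planted pair to its focal/partner/decoy genes and
#'   transcripts.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_cis <- nrow(config$planted_cis)
  needed <- 3 * n_cis
  if (config$n_genes < needed + 2)
    stop("n_genes too small for the planted cis layout")
  max_reach <- if (n_cis) max(config$planted_cis$distance, config$decoy_distance) else 0
  if (n_cis && (n_cis * (max_reach + 4e6) > config$chrom_length))
    stop("requested cis distance impossible on configured chromosome length")

  genes <- list(); txs <- list()
  gid <- 0L; tid <- 0L; n_lnc <- 0L; n_pcg <- 0L
  add_gene <- function(chrom, start, len, biotype, name, n_iso) {
    gid <<- gid + 1L
    gene_id <- sprintf("SIMG%05d.1", gid)
    g <- data.frame(gene_id = gene_id, gene_name = name, biotype = biotype,
                    chrom = chrom, start = start, end = start + len,
                    strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    tt <- vector("list", n_iso)
    for (k in seq_len(n_iso)) {
      tid <<- tid + 1L
      if (k == 1) { s <- start; e <- start + len } else {
        s <- start + floor(0.3 * len * runif(1))
        e <- start + len - floor(0.3 * len * runif(1))
      }
      tt[[k]] <- data.frame(
        transcript_id = sprintf("SIMT%05d.1", tid), gene_id = gene_id,
        transcript_name = sprintf("%s-%d", name, 200 + k),
        biotype = biotype, chrom = chrom, start = s, end = e,
        strand = g$strand, stringsAsFactors = FALSE)
    }
    genes[[length(genes) + 1L]] <<- g
    txs[[length(txs) + 1L]] <<- do.call(rbind, tt)
    g
  }

  layout <- NULL
  if (n_cis) {
    cursor <- 1e6
    rows <- vector("list", n_cis)
    for (i in seq_len(n_cis)) {
      d <- config$planted_cis$distance[i]
      lf <- round(runif(1, 5e3, 2e4)); lp <- round(runif(1, 5e3, 2e4))
      ld <- round(runif(1, 5e3, 2e4))
      fg <- add_gene("chr1", cursor, lf, "lncRNA", sprintf("CISLNC%02d", i), 1L)
      pg <- add_gene("chr1", fg$end + d, lp, "protein_coding",
                     sprintf("CISPCG%02d", i), 1L)
      dg <- add_gene("chr1", fg$end + config$decoy_distance, ld,
                     "protein_coding", sprintf("CISDEC%02d", i), 1L)
      rows[[i]] <- data.frame(
        pair = i,
        focal_gene = fg$gene_id, focal_tx = txs[[length(txs) - 1L]]$transcript_id[1],
        partner_gene = pg$gene_id, partner_tx = txs[[length(txs)]]$transcript_id[1],
        decoy_gene = dg$gene_id, decoy_tx = NA_character_,
        rho = config$planted_cis$rho[i], distance = d,
        decoy_distance = config$decoy_distance, stringsAsFactors = FALSE)
      # transcript ids above: partner added second-to-last? fix after loop
      cursor <- dg$end + 4e6
      if (cursor > config$chrom_length)
        stop("requested cis distance impossible on configured chromosome length")
    }
    layout <- do.call(rbind, rows)
  }

  n_rest <- config$n_genes - needed
  chroms <- c("chr2", "chr3")
  per_chrom <- ceiling(n_rest / length(chroms))
  ci <- 0L
  for (ch in chroms) {
    cursor <- 1e5
    for (j in seq_len(min(per_chrom, n_rest - ci))) {
      len <- round(runif(1, 2e3, 3e4))
      bt <- if (runif(1) < config$frac_lncRNA) "lncRNA" else "protein_coding"
      if (bt == "lncRNA") { n_lnc <- n_lnc + 1L; nm <- sprintf("LNC%04d", n_lnc) }
      else { n_pcg <- n_pcg + 1L; nm <- sprintf("PCG%04d", n_pcg) }
      n_iso <- sample(seq(config$isoforms_per_gene[1],
                          config$isoforms_per_gene[2]), 1)
      add_gene(ch, cursor, len, bt, nm, n_iso)
      cursor <- cursor + len + round(runif(1, 2e4, 6e5))
      if (cursor > config$chrom_length)
        stop("simulated genes exceed configured chromosome length")
    }
    ci <- ci + min(per_chrom, n_rest - ci)
    if (ci >= n_rest) break
  }

  ann <- tx_annotation(do.call(rbind, genes), do.call(rbind, txs))
  if (!is.null(layout)) {
    # resolve transcript ids for the single-isoform cis genes
    tx <- ann$transcripts
    layout$focal_tx <- tx$transcript_id[match(layout$focal_gene, tx$gene_id)]
    layout$partner_tx <- tx$transcript_id[match(layout$partner_gene, tx$gene_id)]
    layout$decoy_tx <- tx$transcript_id[match(layout$decoy_gene, tx$gene_id)]
    attr(ann, "cis_layout") <- layout
  }
  ann
}

#' Simulate the series design table
#'
#' @param config A [simulation_config()].
#' @return A [series_design()] data.frame for `n_series` paired series with
#'   cell type, dose and sampling-time metadata.
#' @export
simulate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cells <- rep_len(c("HeSC", "A549", "786-O", "Panc-1", "PrimaryHep", "HeSC"),
                   config$n_series)
  doses <- rep_len(c(50, 32, 25, 10, 10, 5), config$n_series)
  hours <- rep_len(c(24, 48, 24, 24, 48, 24), config$n_series)
  rows <- list()
  for (s in seq_len(config$n_series)) {
    sid <- sprintf("S%d", s)
    for (p in seq_len(config$n_pairs_per_series)) {
      for (cond in c("control", "metformin")) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_p%d_%s", sid, p,
                              ifelse(cond == "control", "ctl", "met")),
          series_id = sid, condition = cond,
          pair_id = sprintf("%s_p%d", sid, p),
          dose_mM = doses[s], hours = hours[s], cell_type = cells[s],
          stringsAsFactors = FALSE)
      }
    }
  }
  series_design(do.call(rbind, rows))
}

# Resolve which transcripts carry planted differential expression.
# Instances are ordered by decreasing series membership (ups before downs
# within a tier); the top instance is the trans-acting focal isoform and
# cis focal transcripts take the following >=4-series slots so that the
# downstream screens target them.
.assign_planted_de <- function(config, ann) {
  pd <- config$planted_de
  if (!nrow(pd)) return(NULL)
  inst <- pd[rep(seq_len(nrow(pd)), pd$n), c("log2FC", "k_series")]
  inst <- inst[order(-inst$k_series, -sign(inst$log2FC)), ]
  rownames(inst) <- NULL
  layout <- attr(ann, "cis_layout")
  tx <- ann$transcripts
  reserved <- if (!is.null(layout))
    c(layout$focal_tx, layout$partner_tx, layout$decoy_tx) else character()
  eligible <- tx$transcript_id[tx$biotype == "lncRNA" &
                               !(tx$transcript_id %in% reserved)]
  inst$transcript_id <- NA_character_
  i <- 1L
  if (!is.null(layout)) {
    high <- which(inst$k_series >= 4)
    want <- head(setdiff(high, 1L), nrow(layout))
    if (length(want) < nrow(layout))
      warning("not enough >=4-series DE slots for cis focal transcripts; ",
              "cis focals will not all be selectable by commonality")
    inst$transcript_id[want] <- layout$focal_tx[seq_along(want)]
  }
  open <- which(is.na(inst$transcript_id))
  if (length(open) > length(eligible))
    stop("not enough lncRNA transcripts to plant differential expression")
  inst$transcript_id[open] <- sample(eligible, length(open))
  inst
}

#' Simulate counts, TPM and inferential replicates with planted signal
#'
#' Baseline per-transcript means are log-normal; counts are negative
#' binomial around a per-sample log-mean that adds (i) a per-(pair,
#' transcript) baseline offset shared by the two samples of a pair, (ii) a
#' per-sample sequencing-depth factor (cancelled by TPM and removed by
#' count scaling downstream), (iii) the planted condition effect
#' (`2^log2FC` on metformin samples of the targeted series), and (iv)
#' latent per-sample factors that create the planted correlations: cis
#' partners (and their beyond-window decoys) carry a `rho`-correlated copy
#' of the focal gene's latent factor plus the focal's condition effect,
#' and planted set members inherit `shift` times the focal isoform's whole
#' deviation plus idiosyncratic noise. Inferential replicates resample each
#' count with multiplicative gamma noise of coefficient of variation
#' `uncertainty_cv`; TPM is computed from counts and transcript lengths.
#'
#' @param annotation A [simulate_annotation()] result (its `"cis_layout"`
#'   attribute, when present, drives the cis planting).
#' @param design A [series_design()] data.frame.
#' @param config A [simulation_config()].
#' @return List with elements `tensors` (named list of
#'   [expression_tensor()], one per series), `truth` (ground-truth lists:
#'   `de`, `cis`, `sets`), and `gene_sets` (a [gene_set_collection()]
#'   containing the planted and decoy sets).
#' @export
simulate_counts <- function(annotation, design, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  tx <- annotation$transcripts
  g <- annotation$genes
  Tn <- nrow(tx)
  lens <- tx$end - tx$start
  mu0 <- config$mean_log_expression[["mu"]]
  sd0 <- config$mean_log_expression[["sigma"]]
  b <- rnorm(Tn, mu0, sd0)
  names(b) <- tx$transcript_id
  layout <- attr(annotation, "cis_layout")
  if (nrow(config$planted_cis) && is.null(layout))
    stop("config plants cis pairs but annotation has no cis_layout; ",
         "use simulate_annotation() with the same config")

  inst <- .assign_planted_de(config, annotation)
  if (!is.null(inst)) {
    b[inst$transcript_id] <- runif(nrow(inst),
                                   log(config$de_expression_range[1]),
                                   log(config$de_expression_range[2]))
    series_ids <- unique(design$series_id)
    inst$series <- lapply(inst$k_series,
                          function(k) sort(sample(series_ids, k)))
  }
  if (!is.null(layout)) {
    cis_tx <- c(layout$focal_tx, layout$partner_tx, layout$decoy_tx)
    b[cis_tx] <- runif(length(cis_tx), log(config$cis_expression_range[1]),
                       log(config$cis_expression_range[2]))
  }

  # trans focal = top planted instance (maximal series membership, up)
  focal_tx <- if (!is.null(inst)) inst$transcript_id[1] else NA_character_

  # planted set membership: single-isoform protein-coding genes outside
  # the cis layout (so the planted gene-level signal is not diluted by
  # unrelated sibling isoforms); decoy sets from the remaining
  # protein-coding genes
  sets <- list(); set_truth <- NULL
  iso_n <- table(tx$gene_id)
  first_iso <- tx[!duplicated(tx$gene_id), ]
  first_iso$gene_name <- g$gene_name[match(first_iso$gene_id, g$gene_id)]
  all_pc <- first_iso[first_iso$biotype == "protein_coding", ]
  pc_pool <- all_pc[iso_n[all_pc$gene_id] == 1, ]
  if (!is.null(layout))
    pc_pool <- pc_pool[!(pc_pool$gene_id %in%
                         c(layout$partner_gene, layout$decoy_gene)), ]
  member_tx <- character(); member_shift <- numeric()
  if (nrow(config$planted_sets) && !is.na(focal_tx)) {
    need <- sum(config$planted_sets$size)
    if (need > nrow(pc_pool))
      stop("not enough single-isoform protein-coding genes for the ",
           "planted gene sets")
    picked <- sample(nrow(pc_pool), need)
    off <- 0L
    for (j in seq_len(nrow(config$planted_sets))) {
      sz <- config$planted_sets$size[j]
      rows <- pc_pool[picked[(off + 1):(off + sz)], ]
      off <- off + sz
      nm <- config$planted_sets$set_name[j]
      sets[[nm]] <- rows$gene_name
      member_tx <- c(member_tx, rows$transcript_id)
      member_shift <- c(member_shift,
                        rep(config$planted_sets$shift[j], sz))
      set_truth <- rbind(set_truth, data.frame(
        set_name = nm, focal_tx = focal_tx,
        shift = config$planted_sets$shift[j], stringsAsFactors = FALSE))
    }
    b[member_tx] <- runif(length(member_tx), log(50), log(400))
    pool_left <- setdiff(all_pc$gene_name, unlist(sets))
    for (j in seq_len(config$n_decoy_sets)) {
      sz <- min(config$decoy_set_size, length(pool_left))
      if (sz < 3) break
      sets[[sprintf("DECOY_SET_%02d", j)]] <- sample(pool_left, sz)
    }
  }
  gene_sets <- if (length(sets)) gene_set_collection(sets) else NULL

  ln2 <- log(2)
  sdesign <- split_design(design)
  tensors <- list(); latents <- list()
  de_truth <- NULL
  for (sid in names(sdesign)) {
    ds <- sdesign[[sid]]
    ds <- ds[order(ds$pair_id, ds$condition), ]
    n <- nrow(ds)
    is_met <- ds$condition == "metformin"
    logmu <- matrix(b, Tn, n)
    # pair offsets (shared within a pair, independent across transcripts)
    for (p in unique(ds$pair_id)) {
      o <- rnorm(Tn, 0, config$pair_sd)
      logmu[, ds$pair_id == p] <- logmu[, ds$pair_id == p] + o
    }
    # sequencing depth
    depth <- rnorm(n, 0, config$depth_sd)
    logmu <- sweep(logmu, 2, depth, "+")
    # planted condition effects (and per-transcript effect bookkeeping)
    delta <- setNames(numeric(Tn), tx$transcript_id)
    if (!is.null(inst)) {
      here <- vapply(inst$series, function(ss) sid %in% ss, logical(1))
      for (k in which(here)) delta[inst$transcript_id[k]] <- inst$log2FC[k] * ln2
    }
    # latent factors
    zstore <- list()
    if (!is.null(layout)) {
      for (i in seq_len(nrow(layout))) {
        zf <- rnorm(n); rho <- layout$rho[i]
        zp <- rho * zf + sqrt(1 - rho^2) * rnorm(n)
        zd <- rho * zf + sqrt(1 - rho^2) * rnorm(n)
        dlt <- delta[layout$focal_tx[i]]
        logmu[match(layout$focal_tx[i], tx$transcript_id), ] <-
          logmu[match(layout$focal_tx[i], tx$transcript_id), ] +
          config$corr_sd * zf
        logmu[match(layout$partner_tx[i], tx$transcript_id), ] <-
          logmu[match(layout$partner_tx[i], tx$transcript_id), ] +
          config$corr_sd * zp + dlt * is_met
        logmu[match(layout$decoy_tx[i], tx$transcript_id), ] <-
          logmu[match(layout$decoy_tx[i], tx$transcript_id), ] +
          config$corr_sd * zd + dlt * is_met
        zstore[[paste0("cis", i)]] <- cbind(zf = zf, zp = zp, zd = zd)
      }
    }
    if (length(member_tx)) {
      zt <- rnorm(n)
      fdev <- config$trans_focal_sd * zt + delta[focal_tx] * is_met
      fi <- match(focal_tx, tx$transcript_id)
      logmu[fi, ] <- logmu[fi, ] + config$trans_focal_sd * zt
      mi <- match(member_tx, tx$transcript_id)
      for (k in seq_along(mi)) {
        logmu[mi[k], ] <- logmu[mi[k], ] + member_shift[k] * fdev +
          config$member_sd * rnorm(n)
      }
      zstore[["trans_focal"]] <- zt
    }
    # condition effect applied to the planted transcripts themselves
    didx <- which(delta != 0)
    if (length(didx))
      logmu[didx, is_met] <- logmu[didx, is_met] + delta[didx]

    counts <- matrix(rnbinom(Tn * n, mu = exp(logmu),
                             size = 1 / config$nb_dispersion), Tn, n)
    dimnames(counts) <- list(tx$transcript_id, ds$sample_id)
    rate <- counts / lens
    tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
    tpm[is.nan(tpm)] <- 0
    infreps <- NULL
    if (config$G_replicates > 0) {
      G <- config$G_replicates
      infreps <- array(NA_real_, c(Tn, n, G),
                       dimnames = list(tx$transcript_id, ds$sample_id, NULL))
      if (config$uncertainty_cv == 0) {
        for (gi in seq_len(G)) infreps[, , gi] <- counts
      } else {
        shp <- 1 / config$uncertainty_cv^2
        for (gi in seq_len(G))
          infreps[, , gi] <- counts *
            matrix(rgamma(Tn * n, shape = shp, rate = shp), Tn, n)
      }
    }
    tensors[[sid]] <- expression_tensor(counts, tpm, lens, infreps)
    if (config$keep_latent) latents[[sid]] <- zstore
    if (!is.null(inst)) {
      here <- which(vapply(inst$series, function(ss) sid %in% ss, logical(1)))
      if (length(here))
        de_truth <- rbind(de_truth, data.frame(
          series_id = sid, transcript_id = inst$transcript_id[here],
          log2FC = inst$log2FC[here],
          direction = ifelse(inst$log2FC[here] > 0, "up", "down"),
          biotype = tx$biotype[match(inst$transcript_id[here],
                                     tx$transcript_id)],
          stringsAsFactors = FALSE))
    }
  }

  cis_truth <- NULL
  if (!is.null(layout)) {
    cis_truth <- rbind(
      data.frame(focal_tx = layout$focal_tx, partner_tx = layout$partner_tx,
                 rho = layout$rho, distance = layout$distance,
                 in_window = TRUE, stringsAsFactors = FALSE),
      data.frame(focal_tx = layout$focal_tx, partner_tx = layout$decoy_tx,
                 rho = layout$rho, distance = layout$decoy_distance,
                 in_window = FALSE, stringsAsFactors = FALSE))
  }
  truth <- list(de = de_truth, cis = cis_truth, sets = set_truth,
                focal_tx = focal_tx)
  out <- list(tensors = tensors, truth = truth, gene_sets = gene_sets)
  if (config$keep_latent) out$latents <- latents
  out
}

#' Simulate a complete study
#'
#' Convenience wrapper: annotation, design, counts/truth and gene sets
#' from one config.
#'
#' @param config A [simulation_config()].
#' @return List with `annotation`, `design`, `tensors`, `truth`,
#'   `gene_sets` (and `latents` when `keep_latent`).
#' @export
simulate_dataset <- function(config) {
  ann <- simulate_annotation(config)
  design <- simulate_design(config)
  sim <- simulate_counts(ann, design, config)
  c(list(annotation = ann, design = design), sim)
}

#' Write a simulated study as an on-disk fixture
#'
#' Writes the GTF annotation, GMT gene sets, design TSV, per-series
#' Salmon-format quantification directories and a ground-truth JSON under
#' `dir` — the same layout the readers ([read_gtf()], [read_gmt()],
#' [read_design()], [read_quant()]) consume.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  if (!is.null(sim$gene_sets))
    write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_design(sim$design, file.path(dir, "design.tsv"))
  qdir <- file.path(dir, "quant")
  for (sid in names(sim$tensors))
    write_quant(sim$tensors[[sid]], file.path(qdir, sid))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
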