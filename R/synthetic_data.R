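# Seeded generator for synthetic regulatory genomics inputs: an annotation
# with intronic miRNAs, TF binding peaks planted in promoter windows, HOT
# loci, binned binding-signal matrices coupled to expression through planted
# regulator signs, conserved and decoy miRNA seed sites, a PPI scaffold, and
# recorded ground truth for every planted structure.
#
# One seed drives everything; the annotation and the regulome draw from
# fixed sub-streams (seed, seed + 1) so partial reruns are reproducible.

#' Parameters of the synthetic regulome
#'
#' Defaults describe a desk-scale study: 1,000 genes, a panel of 20 assayed
#' TFs and 60 miRNAs (mirroring the order of magnitude of a ~20-TF /
#' ~160-miRNA ChIP-seq compendium at reduced scale), 8 tissues, a 7-stage
#' developmental time course, 40% intronic miRNAs with sense probability
#' 0.8.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_genes,n_tfs,n_mirnas Entity counts; TFs are a flagged subset of
#'   genes.
#' @param n_tissues Number of tissues for the specificity profiles (>= 2).
#' @param stages Developmental stage labels (the expression conditions).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param fraction_intronic Fraction of miRNAs embedded in a host intron.
#' @param sense_probability Probability an intronic miRNA lies on the host's
#'   strand.
#' @param tf_signs Optional +1/-1 vector of true regulator signs (default
#'   alternating).
#' @param target_mu,target_size Negative-binomial parameters of per-TF gene
#'   target counts (`target_mu = 0` gives zero targets).
#' @param mirna_target_mu Mean per-TF miRNA target count.
#' @param mirna_gene_mu Mean per-miRNA gene target count.
#' @param tf_weight Sampling weight of TF genes as targets (creates TF->TF
#'   and miRNA->TF edges).
#' @param peak_jitter_sd SD (bp) of peak-center placement noise around the
#'   target TSS, truncated to the default promoter window.
#' @param peak_halfwidth Peak half-width in bp.
#' @param background_peaks_per_tf Non-target peaks placed uniformly per TF.
#' @param n_hot_loci,hot_tf_count HOT loci: positions where `hot_tf_count`
#'   distinct TFs stack peaks in a 400-bp window (default panel-sized: 16).
#' @param beta Planted binding->expression effect size (sign times `beta`
#'   times promoter signal is added to target expression).
#' @param expression_sigma Log-normal expression noise SD.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline expression.
#' @param conservation_p5 Probability a true seed site is conserved in the
#'   two extra species (all true sites pass the 3-species filter).
#' @param decoy_sites Number of under-conserved decoy sites.
#' @param ppi_mean_degree Mean degree of the random PPI scaffold.
#' @param essential_fraction Fraction of genes flagged essential.
#' @param tissue_specific_fraction Fraction of genes with tissue-restricted
#'   expression.
#' @param planted_ffl,planted_feedback,planted_co_ppi Numbers of planted
#'   feed-forward loops, TF<->miRNA composite feedback loops, and
#'   miRNA-represses-both-PPI-partners instances.
#' @return List of class `simulation_params`.
#' @export
simulation_params <- function(seed = 1L, n_genes = 1000L, n_tfs = 20L,
                              n_mirnas = 60L, n_tissues = 8L,
                              stages = c("EE", "LE", "L1", "L2", "L3", "L4", "YA"),
                              chrom_lengths = c(chrI = 4e6, chrII = 4e6, chrIII = 4e6),
                              fraction_intronic = 0.4,
                              sense_probability = 0.8,
                              tf_signs = NULL,
                              target_mu = 40, target_size = 5,
                              mirna_target_mu = 5,
                              mirna_gene_mu = 25,
                              tf_weight = 5,
                              peak_jitter_sd = 200,
                              peak_halfwidth = 150L,
                              background_peaks_per_tf = 30L,
                              n_hot_loci = 5L, hot_tf_count = NULL,
                              beta = 3,
                              expression_sigma = 0.25,
                              baseline_meanlog = 3, baseline_sdlog = 0.8,
                              conservation_p5 = 0.7,
                              decoy_sites = 120L,
                              ppi_mean_degree = 4,
                              essential_fraction = 0.15,
                              tissue_specific_fraction = 0.3,
                              planted_ffl = 0L, planted_feedback = 0L,
                              planted_co_ppi = 0L) {
  if (is.null(hot_tf_count)) hot_tf_count <- min(n_tfs, 16L)
  p <- as.list(environment())
  with(p, {
    stopifnot(n_genes > 0, n_tfs >= 0, n_tfs <= n_genes, n_mirnas >= 0,
              n_tissues >= 2,
              fraction_intronic >= 0, fraction_intronic <= 1,
              sense_probability >= 0, sense_probability <= 1,
              conservation_p5 >= 0, conservation_p5 <= 1,
              peak_halfwidth >= 1, target_mu >= 0, mirna_gene_mu >= 0)
  })
  if (!is.null(p$tf_signs) && length(p$tf_signs) != n_tfs) {
    stop("tf_signs must have one entry per TF")
  }
  structure(p, class = "simulation_params")
}

#' Simulate a genome annotation
#'
#' Genes and intergenic pre-miRNAs are placed sequentially along the
#' chromosomes with at least 2.5 kb between entities, so default promoter
#' windows never collide by construction. Each gene carries 1-2 transcripts
#' with three exons and a 200-bp 3'UTR at its 3' end. A
#' `fraction_intronic` share of the miRNAs is embedded wholly inside an
#' intron of a (>= 5 kb) host gene, at least 1.6 kb from both gene ends so
#' the miRNA's promoter window stays clear of the host's; embedding is on
#' the host strand with probability `sense_probability`. TFs are a random
#' flagged subset of genes.
#'
#' @param params A [simulation_params()] object.
#' @return A [genome_annotation()].
#' @export
simulate_annotation <- function(params) {
  set.seed(params$seed)
  n_intronic <- round(params$fraction_intronic * params$n_mirnas)
  n_intergenic <- params$n_mirnas - n_intronic
  host_idx <- if (n_intronic > 0) sample(params$n_genes, n_intronic) else integer(0)
  gene_len <- round(stats::runif(params$n_genes, 2500, 6000))
  gene_len[host_idx] <- round(stats::runif(n_intronic, 5000, 6000))
  # one placement stream of genes + intergenic miRNA slots, >= 2.5 kb apart
  ent <- data.frame(
    kind = c(rep("gene", params$n_genes), rep("mirna", n_intergenic)),
    idx = c(seq_len(params$n_genes), seq_len(n_intergenic)),
    len = c(gene_len,
            if (n_intergenic) sample(80:120, n_intergenic, replace = TRUE) else integer(0)),
    stringsAsFactors = FALSE)
  ent <- ent[sample(nrow(ent)), , drop = FALSE]
  gaps <- 2500 + round(stats::rexp(nrow(ent), 1 / 1000))
  chroms <- names(params$chrom_lengths)
  ci <- 1L
  pos <- 1000L
  ent$chrom <- NA_character_
  ent$start <- NA_integer_
  for (i in seq_len(nrow(ent))) {
    while (pos + ent$len[i] + 1000 > params$chrom_lengths[ci]) {
      ci <- ci + 1L
      if (ci > length(chroms)) {
        stop("genome too small for the requested entity count")
      }
      pos <- 1000L
    }
    ent$chrom[i] <- chroms[ci]
    ent$start[i] <- as.integer(pos)
    pos <- pos + ent$len[i] + gaps[i]
  }
  ent$strand <- sample(c("+", "-"), nrow(ent), replace = TRUE)
  ge <- ent[ent$kind == "gene", , drop = FALSE]
  ge <- ge[order(ge$idx), , drop = FALSE]
  gene_id <- sprintf("g%04d", seq_len(params$n_genes))
  is_tf <- rep(FALSE, params$n_genes)
  if (params$n_tfs > 0) is_tf[sample(params$n_genes, params$n_tfs)] <- TRUE
  genes <- data.frame(gene_id = gene_id, chrom = ge$chrom, start = ge$start,
                      end = ge$start + ge$len, strand = ge$strand,
                      is_tf = is_tf, stringsAsFactors = FALSE)
  # transcripts: all genes have .t1 spanning the gene; ~20% add a .t2 with a
  # 200 bp shorter 5' end
  two_tx <- stats::runif(params$n_genes) < 0.2
  tx <- function(tag, shift5) {
    d <- genes
    shift <- ifelse(d$strand == "+", shift5, 0L)
    shrink <- ifelse(d$strand == "-", shift5, 0L)
    data.frame(transcript_id = paste0(d$gene_id, tag),
               gene_id = d$gene_id, chrom = d$chrom,
               start = d$start + shift, end = d$end - shrink,
               strand = d$strand, stringsAsFactors = FALSE)
  }
  t1 <- tx(".t1", 0L)
  t2 <- tx(".t2", 200L)[two_tx, , drop = FALSE]
  transcripts <- rbind(t1, t2)
  # exon skeleton at fixed fractions of the gene span; introns are
  # (0.15, 0.5) and (0.6, 0.9) of the length
  exon_rows <- function(txd) {
    g <- genes[match(txd$gene_id, genes$gene_id), ]
    L <- g$end - g$start
    b1 <- g$start + round(0.15 * L)
    b2 <- g$start + round(0.50 * L)
    b3 <- g$start + round(0.60 * L)
    b4 <- g$start + round(0.90 * L)
    rbind(
      data.frame(transcript_id = txd$transcript_id, chrom = txd$chrom,
                 start = pmax(txd$start, g$start), end = b1,
                 stringsAsFactors = FALSE),
      data.frame(transcript_id = txd$transcript_id, chrom = txd$chrom,
                 start = b2, end = b3, stringsAsFactors = FALSE),
      data.frame(transcript_id = txd$transcript_id, chrom = txd$chrom,
                 start = b4, end = pmin(txd$end, g$end),
                 stringsAsFactors = FALSE))
  }
  exons <- rbind(exon_rows(t1), if (nrow(t2)) exon_rows(t2))
  # 3'UTR: terminal 200 bp of the 3'-most exon
  utr_for <- function(txd) {
    data.frame(transcript_id = txd$transcript_id, chrom = txd$chrom,
               start = ifelse(txd$strand == "+", txd$end - 200L, txd$start),
               end = ifelse(txd$strand == "+", txd$end, txd$start + 200L),
               stringsAsFactors = FALSE)
  }
  utr3 <- rbind(utr_for(t1), if (nrow(t2)) utr_for(t2))
  # intronic miRNAs: inside intron 2, >= 1.6 kb from either gene end
  mirnas <- data.frame(mirna_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), stringsAsFactors = FALSE)
  if (n_intronic > 0) {
    hg <- genes[host_idx, , drop = FALSE]
    L <- hg$end - hg$start
    mlen <- sample(80:120, n_intronic, replace = TRUE)
    lo <- hg$start + pmax(round(0.60 * L) + 10L, 1600L)
    hi <- hg$start + pmin(round(0.90 * L) - 10L, L - 1700L) - mlen
    if (any(hi < lo)) stop("host genes too short for intronic embedding")
    mstart <- lo + floor(stats::runif(n_intronic) * (hi - lo + 1))
    sense <- stats::runif(n_intronic) < params$sense_probability
    mirnas <- rbind(mirnas, data.frame(
      mirna_id = sprintf("mir-%03d", seq_len(n_intronic)),
      chrom = hg$chrom, start = as.integer(mstart),
      end = as.integer(mstart + mlen),
      strand = ifelse(sense, hg$strand, ifelse(hg$strand == "+", "-", "+")),
      stringsAsFactors = FALSE))
  }
  if (n_intergenic > 0) {
    me <- ent[ent$kind == "mirna", , drop = FALSE]
    me <- me[order(me$idx), , drop = FALSE]
    mirnas <- rbind(mirnas, data.frame(
      mirna_id = sprintf("mir-%03d", n_intronic + seq_len(n_intergenic)),
      chrom = me$chrom, start = me$start, end = me$start + me$len,
      strand = me$strand, stringsAsFactors = FALSE))
  }
  genome_annotation(genes, transcripts, exons, utr3, mirnas)
}

# negative-binomial count, at least 1 unless mu is 0
.nb_count <- function(n, mu, size) {
  if (mu == 0) return(rep(0L, n))
  stats::rnbinom(n, mu = mu, size = size) + 1L
}

#' Simulate the full regulome around an annotation
#'
#' Plants true TF->gene / TF->miRNA / miRNA->gene edges and realises them as
#' observable data: one ChIP peak per TF edge whose center falls inside the
#' target's default promoter window (jitter truncated to the window), plus
#' uniform background peaks and stacked HOT loci; binned binding-signal
#' matrices; stage expression where each TF's targets are shifted by
#' `sign * beta * promoter signal` in the TF's own assay stage (so the
#' planted sign is recoverable); tissue expression; a conserved seed-site
#' table with under-conserved decoys; a random PPI scaffold; essentiality
#' flags; and requested planted motif instances. Truth tables for every
#' planted structure are returned for parameter-recovery tests.
#'
#' @param annotation Result of [simulate_annotation()] (same params).
#' @param params The same [simulation_params()].
#' @return List of class `regulome_sim`; see fields in the source. Key
#'   elements: `tf_edges`, `mirna_edges` (truth), `peaksets`, `signal`,
#'   `expr_tx_stage`, `expr_gene_stage`, `expr_tissue`, `sites`, `ppi`,
#'   `essential`, `tf_signs`, `tf_conditions`, `planted`, `hot_loci`.
#' @export
simulate_regulome <- function(annotation, params) {
  if (params$hot_tf_count > params$n_tfs) {
    stop("hot_tf_count cannot exceed the number of assayed TFs")
  }
  set.seed(params$seed + 1L)
  genes <- annotation$genes
  tf_ids <- genes$gene_id[genes$is_tf]
  gene_ids <- genes$gene_id
  mirna_ids <- annotation$mirnas$mirna_id
  n_tfs <- length(tf_ids)
  signs <- if (is.null(params$tf_signs)) {
    rep(c(1L, -1L), length.out = n_tfs)
  } else as.integer(params$tf_signs)
  names(signs) <- tf_ids
  stages <- params$stages
  conditions <- stats::setNames(
    stages[(seq_len(n_tfs) - 1L) %% length(stages) + 1L], tf_ids)

  w_gene <- ifelse(genes$is_tf, params$tf_weight, 1)
  # --- true TF edges ---------------------------------------------------------
  tf_edges <- list()
  for (tf in tf_ids) {
    ng <- .nb_count(1, params$target_mu, params$target_size)
    tg <- if (ng > 0) sample(gene_ids, min(ng, length(gene_ids)),
                             prob = w_gene) else character(0)
    nm <- if (length(mirna_ids)) .nb_count(1, params$mirna_target_mu,
                                           params$target_size) else 0L
    tm <- if (nm > 0) sample(mirna_ids, min(nm, length(mirna_ids))) else character(0)
    tf_edges[[tf]] <- data.frame(
      tf_id = tf,
      target_id = c(tg, tm),
      target_type = rep(c("gene", "mirna"), c(length(tg), length(tm))),
      stringsAsFactors = FALSE)
  }
  tf_edges <- do.call(rbind, c(tf_edges, list(make.row.names = FALSE)))
  if (is.null(tf_edges)) {
    tf_edges <- data.frame(tf_id = character(), target_id = character(),
                           target_type = character(), stringsAsFactors = FALSE)
  }
  # --- true miRNA edges ------------------------------------------------------
  mirna_edges <- list()
  for (m in mirna_ids) {
    n <- .nb_count(1, params$mirna_gene_mu, 3)
    tg <- if (n > 0) sample(gene_ids, min(n, length(gene_ids)),
                            prob = ifelse(genes$is_tf, 3, 1)) else character(0)
    if (length(tg)) {
      mirna_edges[[m]] <- data.frame(mirna_id = m, gene_id = tg,
                                     stringsAsFactors = FALSE)
    }
  }
  mirna_edges <- do.call(rbind, c(mirna_edges, list(make.row.names = FALSE)))
  if (is.null(mirna_edges)) {
    mirna_edges <- data.frame(mirna_id = character(), gene_id = character(),
                              stringsAsFactors = FALSE)
  }
  # --- planted motifs --------------------------------------------------------
  planted <- list(ffl = NULL, feedback = NULL, co_ppi = NULL)
  extra_ppi <- NULL
  non_tf_genes <- gene_ids[!genes$is_tf]
  if (params$planted_ffl > 0) {
    if (n_tfs < 2) stop("planting FFLs needs at least 2 TFs")
    k <- params$planted_ffl
    ta <- tf_ids[(seq_len(k) - 1L) %% n_tfs + 1L]
    tb <- tf_ids[seq_len(k) %% n_tfs + 1L]
    gg <- sample(non_tf_genes, k)
    planted$ffl <- data.frame(tf_a = ta, tf_b = tb, gene = gg,
                              stringsAsFactors = FALSE)
    tf_edges <- rbind(tf_edges,
                      data.frame(tf_id = c(ta, ta, tb),
                                 target_id = c(tb, gg, gg),
                                 target_type = "gene",
                                 stringsAsFactors = FALSE))
  }
  if (params$planted_feedback > 0 && length(mirna_ids)) {
    k <- params$planted_feedback
    tfp <- tf_ids[(seq_len(k) - 1L) %% n_tfs + 1L]
    mp <- mirna_ids[(seq_len(k) - 1L) %% length(mirna_ids) + 1L]
    planted$feedback <- data.frame(tf = tfp, mirna = mp,
                                   stringsAsFactors = FALSE)
    tf_edges <- rbind(tf_edges,
                      data.frame(tf_id = tfp, target_id = mp,
                                 target_type = "mirna", stringsAsFactors = FALSE))
    mirna_edges <- rbind(mirna_edges,
                         data.frame(mirna_id = mp, gene_id = tfp,
                                    stringsAsFactors = FALSE))
  }
  if (params$planted_co_ppi > 0 && length(mirna_ids)) {
    k <- params$planted_co_ppi
    mp <- mirna_ids[(seq_len(k) - 1L) %% length(mirna_ids) + 1L]
    g1 <- sample(non_tf_genes, k)
    g2 <- sample(setdiff(non_tf_genes, g1), k)
    planted$co_ppi <- data.frame(mirna = mp, gene_a = g1, gene_b = g2,
                                 stringsAsFactors = FALSE)
    mirna_edges <- rbind(mirna_edges,
                         data.frame(mirna_id = rep(mp, 2),
                                    gene_id = c(g1, g2),
                                    stringsAsFactors = FALSE))
    extra_ppi <- data.frame(a = g1, b = g2, stringsAsFactors = FALSE)
  }
  tf_edges <- unique(tf_edges)
  mirna_edges <- unique(mirna_edges)

  # --- peaks -----------------------------------------------------------------
  tr <- annotation$transcripts
  t1 <- tr[endsWith(tr$transcript_id, ".t1"), ]
  anchor_tss <- stats::setNames(t1$tss, t1$gene_id)
  anchor_strand <- stats::setNames(t1$strand, t1$gene_id)
  anchor_chrom <- stats::setNames(t1$chrom, t1$gene_id)
  mi <- annotation$mirnas
  anchor_tss[mi$mirna_id] <- mi$start5
  anchor_strand[mi$mirna_id] <- mi$strand
  anchor_chrom[mi$mirna_id] <- mi$chrom
  hw <- params$peak_halfwidth
  hot_loci <- NULL
  if (params$n_hot_loci > 0 && n_tfs > 0) {
    hchrom <- sample(names(params$chrom_lengths), params$n_hot_loci,
                     replace = TRUE,
                     prob = params$chrom_lengths / sum(params$chrom_lengths))
    hpos <- floor(stats::runif(params$n_hot_loci) *
                    (params$chrom_lengths[hchrom] - 1000)) + 300L
    hot_loci <- data.frame(chrom = hchrom, start = as.integer(hpos),
                           end = as.integer(hpos + 400L),
                           stringsAsFactors = FALSE)
  }
  hot_tfs <- tf_ids[seq_len(min(params$hot_tf_count, n_tfs))]
  peaksets <- list()
  for (tf in tf_ids) {
    ed <- tf_edges[tf_edges$tf_id == tf, , drop = FALSE]
    u <- round(stats::rnorm(nrow(ed), 0, params$peak_jitter_sd))
    u <- pmax(pmin(u, 499L), -1000L)  # truncate to the default window
    tss <- anchor_tss[ed$target_id]
    str <- anchor_strand[ed$target_id]
    center <- as.integer(ifelse(str == "+", tss + u, tss - u))
    df <- data.frame(chrom = unname(anchor_chrom[ed$target_id]),
                     center = center, stringsAsFactors = FALSE)
    nb <- params$background_peaks_per_tf
    if (nb > 0) {
      bchrom <- sample(names(params$chrom_lengths), nb, replace = TRUE,
                       prob = params$chrom_lengths / sum(params$chrom_lengths))
      bcent <- floor(stats::runif(nb) * (params$chrom_lengths[bchrom] - 2000)) + 1000L
      df <- rbind(df, data.frame(chrom = bchrom, center = as.integer(bcent),
                                 stringsAsFactors = FALSE))
    }
    df$start <- pmax(df$center - hw, 0L)
    df$end <- df$center + hw
    df$score <- round(stats::rgamma(nrow(df), 2, 1) * 10, 2)
    if (!is.null(hot_loci) && tf %in% hot_tfs) {
      df <- rbind(df, data.frame(chrom = hot_loci$chrom,
                                 center = hot_loci$start + 200L,
                                 start = hot_loci$start, end = hot_loci$end,
                                 score = 50, stringsAsFactors = FALSE))
    }
    peaksets[[tf]] <- peak_set(df[, c("chrom", "start", "end", "center", "score")],
                               tf_id = tf, condition = conditions[tf])
  }

  # --- binned binding signal -------------------------------------------------
  n_tx <- nrow(tr)
  bins <- 40L
  # TSS-centred peak over a broad enrichment: bound promoters are co-elevated
  # across the whole +-2 kb, as in empirical TSS-proximal binding profiles
  bell <- 0.25 + exp(-((seq_len(bins) - 20.5)^2) / (2 * 16))
  signal <- list()
  strength_by_tf <- list()
  for (tf in tf_ids) {
    m <- matrix(stats::rgamma(n_tx * bins, shape = 0.3, rate = 2),
                nrow = n_tx, dimnames = list(tr$transcript_id, NULL))
    tg_genes <- tf_edges$target_id[tf_edges$tf_id == tf &
                                     tf_edges$target_type == "gene"]
    tgt_tx <- tr$transcript_id[tr$gene_id %in% tg_genes]
    if (length(tgt_tx)) {
      strength <- stats::rgamma(length(tgt_tx), shape = 4, rate = 0.8)
      names(strength) <- tgt_tx
      m[tgt_tx, ] <- m[tgt_tx, , drop = FALSE] +
        outer(strength, bell)
      strength_by_tf[[tf]] <- strength
    }
    signal[[tf]] <- structure(m, class = c("binned_signal", class(m)),
                              tf_id = tf, flank = 2000L, bin_bp = 100L)
  }

  # --- stage expression ------------------------------------------------------
  baseline <- stats::rlnorm(n_tx, params$baseline_meanlog, params$baseline_sdlog)
  expr_tx <- matrix(baseline, nrow = n_tx, ncol = length(stages)) *
    exp(matrix(stats::rnorm(n_tx * length(stages), 0, params$expression_sigma),
               nrow = n_tx))
  dimnames(expr_tx) <- list(tr$transcript_id, stages)
  # promoter signal = mean over the bins covering -1 kb .. +500 bp
  promoter_bins <- 11:25
  for (tf in tf_ids) {
    st <- strength_by_tf[[tf]]
    if (is.null(st)) next
    psig <- rowMeans(signal[[tf]][names(st), promoter_bins, drop = FALSE])
    expr_tx[names(st), conditions[tf]] <-
      pmax(expr_tx[names(st), conditions[tf]] + signs[tf] * params$beta * psig, 0)
  }
  gene_of_tx <- stats::setNames(tr$gene_id, tr$transcript_id)
  expr_gene <- rowsum(expr_tx, group = gene_of_tx[rownames(expr_tx)])
  expr_mirna <- matrix(stats::rlnorm(length(mirna_ids) * length(stages), 2, 1),
                       nrow = length(mirna_ids),
                       dimnames = list(mirna_ids, stages))

  # --- tissue expression -----------------------------------------------------
  n_t <- params$n_tissues
  tissues <- paste0("tissue", seq_len(n_t))
  specific <- stats::runif(length(gene_ids)) < params$tissue_specific_fraction
  shape <- matrix(1, nrow = length(gene_ids), ncol = n_t)
  if (any(specific)) {
    pick <- sample(n_t, sum(specific), replace = TRUE)
    shape[cbind(which(specific), pick)] <- 8
  }
  expr_tissue <- matrix(stats::rgamma(length(gene_ids) * n_t, shape = shape,
                                      rate = 1 / 20),
                        nrow = length(gene_ids),
                        dimnames = list(gene_ids, tissues))

  # --- miRNA seed sites ------------------------------------------------------
  species <- c("C.elegans", "C.briggsae", "C.remanei", "C.brenneri", "C.japonica")
  utr <- annotation$utr3
  utr1 <- utr[endsWith(utr$transcript_id, ".t1"), ]
  utr_of_gene <- utr1[match(paste0(gene_ids, ".t1"), utr1$transcript_id), ]
  mk_sites <- function(mirna, gene, conserved5) {
    u <- utr_of_gene[match(gene, gene_ids), ]
    off <- floor(stats::runif(length(gene)) * pmax(u$end - u$start - 8L, 1L))
    data.frame(mirna_id = mirna, transcript_id = u$transcript_id,
               chrom = u$chrom, start = u$start + off, end = u$start + off + 7L,
               `C.elegans` = TRUE, `C.briggsae` = TRUE, `C.remanei` = TRUE,
               `C.brenneri` = conserved5, `C.japonica` = conserved5,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  sites <- NULL
  if (nrow(mirna_edges)) {
    c5 <- stats::runif(nrow(mirna_edges)) < params$conservation_p5
    sites <- mk_sites(mirna_edges$mirna_id, mirna_edges$gene_id, c5)
  }
  if (params$decoy_sites > 0 && length(mirna_ids)) {
    dm <- sample(mirna_ids, params$decoy_sites, replace = TRUE)
    dg <- sample(gene_ids, params$decoy_sites, replace = TRUE)
    decoy <- mk_sites(dm, dg, FALSE)
    decoy$`C.remanei` <- FALSE  # conserved in 2 species only: fails both filters
    sites <- rbind(sites, decoy)
  }
  if (is.null(sites)) {
    sites <- data.frame(mirna_id = character(), transcript_id = character(),
                        chrom = character(), start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
    for (sp in species) sites[[sp]] <- logical(0)
  }

  # --- PPI scaffold, essentiality -------------------------------------------
  n_ppi <- round(params$ppi_mean_degree * length(gene_ids) / 2)
  ppi <- data.frame(a = sample(gene_ids, n_ppi, replace = TRUE),
                    b = sample(gene_ids, n_ppi, replace = TRUE),
                    stringsAsFactors = FALSE)
  ppi <- ppi[ppi$a != ppi$b, , drop = FALSE]
  swap <- ppi$a > ppi$b
  tmp <- ppi$a[swap]; ppi$a[swap] <- ppi$b[swap]; ppi$b[swap] <- tmp
  ppi <- unique(ppi)
  if (!is.null(extra_ppi)) ppi <- unique(rbind(ppi, extra_ppi))
  essential <- stats::setNames(
    stats::runif(length(gene_ids)) < params$essential_fraction, gene_ids)

  structure(list(
    annotation = annotation, params = params,
    tf_ids = tf_ids, tf_signs = signs, tf_conditions = conditions,
    tf_edges = tf_edges, mirna_edges = mirna_edges,
    peaksets = peaksets, signal = signal,
    expr_tx_stage = expr_tx, expr_gene_stage = expr_gene,
    expr_mirna_stage = expr_mirna, expr_tissue = expr_tissue,
    sites = sites, ppi = ppi, essential = essential,
    hot_loci = hot_loci, planted = planted), class = "regulome_sim")
}

#' Simulate annotation and regulome in one call
#' @param params A [simulation_params()].
#' @return A `regulome_sim` bundle (includes its annotation).
#' @export
simulate_study <- function(params = simulation_params()) {
  ann <- simulate_annotation(params)
  simulate_regulome(ann, params)
}

#' Write a simulated study to disk in the package's exchange formats
#'
#' Emits the full fixture set: GFF3 annotation, one narrowPeak file per TF,
#' TSV expression matrices, the seed-site table, PPI pairs and essentiality
#' flags.
#'
#' @param sim A [simulate_study()] bundle.
#' @param outdir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotation = file.path(outdir, "annotation.gff3"))
  write_annotation(sim$annotation, paths["annotation"])
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  for (tf in names(sim$peaksets)) {
    p <- file.path(outdir, "peaks", paste0(tf, ".narrowPeak"))
    write_peaks(sim$peaksets[[tf]], p)
    paths[paste0("peaks_", tf)] <- p
  }
  tabs <- list(expr_tx_stage = sim$expr_tx_stage,
               expr_gene_stage = sim$expr_gene_stage,
               expr_tissue = sim$expr_tissue)
  for (nm in names(tabs)) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    write_expression(tabs[[nm]], p)
    paths[nm] <- p
  }
  paths["sites"] <- file.path(outdir, "mirna_sites.tsv")
  write_site_table(sim$sites, paths["sites"])
  paths["ppi"] <- file.path(outdir, "ppi.tsv")
  utils::write.table(sim$ppi, paths["ppi"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["essential"] <- file.path(outdir, "essential.tsv")
  utils::write.table(
    data.frame(id = names(sim$essential), essential = sim$essential),
    paths["essential"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
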