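# End-to-end orchestration: one configuration drives simulate -> call
# targets -> classify signs -> build network -> hierarchy -> motifs -> host
# network, with a JSON manifest of every artifact; a parameter sweep over
# the 2x2x2 grid of analysis choices; and edge-removal robustness checks of
# the motif analysis.

# run the core analysis (target calling through network assembly) for one
# parameter combination
.analyse_network <- function(sim, window_preset = "default",
                             hot_mode = "keep", conservation = 3,
                             hot = NULL) {
  win <- promoter_window(window_preset)
  if (hot_mode != "keep" && is.null(hot)) {
    hot <- detect_hot_regions(sim$peaksets,
                              threshold = hot_auto_threshold(length(sim$tf_ids)))
  }
  tf_called <- call_tf_targets(sim$peaksets, sim$annotation, win,
                               hot = hot, hot_mode = hot_mode)
  mi_called <- filter_conserved_sites(sim$sites, sim$annotation,
                                      min_species = conservation)
  assemble_network(tf_called, mi_called, sim$ppi, sim$annotation)
}

#' Run the full integrated-network pipeline
#'
#' Takes a configuration (a list, or a path to a YAML file with the same
#' structure), validates it up front, runs every stage, writes all artifacts
#' under `outdir` and returns a manifest. The configuration holds either a
#' `simulation` block (arguments to [simulation_params()]) or an `inputs`
#' block with paths (`annotation`, `peaks` = directory of
#' `<tf>.narrowPeak` files, `expression`, `sites`, `ppi`); analysis knobs:
#' `window` (preset), `hot_mode`, `conservation` (3/5), `consistency_cutoff`,
#' `n_null`, `q`, `seed`.
#'
#' @param config List or YAML path.
#' @param outdir Output directory.
#' @return The manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs) {
    stop("config must contain a 'simulation' block or an 'inputs' block")
  }
  if (has_inputs) {
    need <- unlist(config$inputs[c("annotation", "expression", "sites", "ppi")])
    missing <- need[!file.exists(need)]
    if (length(missing)) {
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    }
  }
  cfg <- utils::modifyList(
    list(window = "default", hot_mode = "exclude_overlap", conservation = 3,
         consistency_cutoff = 0.7, n_null = 100L, q = 100L, seed = 1L),
    config[setdiff(names(config), c("simulation", "inputs"))])
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (has_sim) {
    params <- do.call(simulation_params,
                      utils::modifyList(list(seed = cfg$seed),
                                        as.list(config$simulation)))
    sim <- simulate_study(params)
  } else {
    ann <- read_annotation(config$inputs$annotation)
    pk_files <- list.files(config$inputs$peaks, full.names = TRUE)
    peaksets <- lapply(pk_files, function(f) {
      read_peaks(f, tf_id = sub("\\..*$", "", basename(f)))
    })
    names(peaksets) <- vapply(peaksets, attr, "", "tf_id")
    sim <- list(annotation = ann, peaksets = peaksets,
                tf_ids = names(peaksets),
                sites = read_site_table(config$inputs$sites),
                ppi = read_edge_pairs(config$inputs$ppi),
                expr_tx_stage = read_expression(config$inputs$expression),
                signal = NULL, tf_conditions = NULL, essential = NULL,
                expr_tissue = NULL)
  }
  hot <- detect_hot_regions(sim$peaksets,
                            threshold = hot_auto_threshold(length(sim$tf_ids)))
  network <- .analyse_network(sim, cfg$window, cfg$hot_mode,
                              cfg$conservation, hot = hot)
  # sign classification needs the binned-signal matrices
  if (!is.null(sim$signal)) {
    calls <- lapply(sim$tf_ids, function(tf) {
      classify_regulator(sim$signal[[tf]], sim$expr_tx_stage,
                         condition = sim$tf_conditions[[tf]],
                         consistency_cutoff = cfg$consistency_cutoff)
    })
    network <- assign_edge_signs(network, calls)
    signs_df <- data.frame(
      tf_id = vapply(calls, `[[`, "", "tf_id"),
      class = vapply(calls, `[[`, "", "class"),
      consistency = vapply(calls, `[[`, 0, "consistency"),
      mean_r = vapply(calls, `[[`, 0, "mean_r"), stringsAsFactors = FALSE)
    utils::write.table(signs_df, file.path(outdir, "signs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_network(network, file.path(outdir, "network.tsv"))
  utils::write.table(as.data.frame(hot), file.path(outdir, "hot_regions.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  # hierarchy over the assayed-TF core
  tftf <- network$edges[network$edges$type == "TF->TF", , drop = FALSE]
  hier <- build_core_hierarchy(tftf, universe = intersect(
    sim$tf_ids, network$nodes$id[network$nodes$type == "TF"]))
  mi_tf <- network$edges[network$edges$type == "miRNA->TF", , drop = FALSE]
  hier <- place_mirnas(hier, mi_tf,
                       mirnas = network$nodes$id[network$nodes$type == "miRNA"])
  utils::write.table(hier$tf_layers, file.path(outdir, "tf_layers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hier$mirna_layers, file.path(outdir, "mirna_layers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # motifs
  set.seed(cfg$seed)
  enr <- motif_enrichment(network, size = 3, signed = FALSE,
                          n_null = cfg$n_null, q = cfg$q)
  utils::write.table(enr, file.path(outdir, "motifs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # degree statistics
  deg <- degree_statistics(network)
  # host network
  pairs <- find_host_pairs(sim$annotation)
  mi_called <- filter_conserved_sites(sim$sites, sim$annotation,
                                      min_species = cfg$conservation)
  host <- build_host_network(pairs, mi_called)
  utils::write.table(pairs, file.path(outdir, "host_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(host, file.path(outdir, "host_network.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # specificity scores
  if (!is.null(sim$expr_tissue)) {
    sc <- specificity_scores(sim$expr_tissue)
    utils::write.table(sc, file.path(outdir, "tsps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config = cfg,
    seed = cfg$seed,
    counts = list(
      nodes = nrow(network$nodes),
      edges_by_type = as.list(table(network$edges$type)),
      ppi = nrow(network$ppi),
      hot_regions = nrow(hot),
      host_pairs = nrow(pairs),
      host_edges = nrow(host),
      tf_layers = as.list(table(hier$tf_layers$layer)),
      strand_bias_p = if (nrow(pairs)) {
        strand_bias_test(sum(pairs$orientation == "sense"), nrow(pairs))
      } else NULL),
    degree_fits = lapply(deg$fits, function(f) f[c("ok", "lambda", "r_squared")]),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Sweep the 2x2x2 grid of analysis choices
#'
#' Runs target calling and network assembly for every combination of
#' promoter window (default/strict), HOT handling (keep/exclude_overlap)
#' and conservation stringency (3/5 species), and tabulates the edge counts
#' of the resulting 8 integrated networks. Optionally adds the z-score of
#' the plain feed-forward loop from a (smaller) motif analysis per network.
#'
#' @param sim A [simulate_study()] bundle.
#' @param with_motifs Also compute the FFL z-score per network (slower).
#' @param n_null,q,seed Motif-analysis settings when `with_motifs`.
#' @return Data frame with one row per combination.
#' @export
run_sweep <- function(sim, with_motifs = FALSE, n_null = 50L, q = 20L,
                      seed = 1L) {
  hot <- detect_hot_regions(sim$peaksets,
                            threshold = hot_auto_threshold(length(sim$tf_ids)))
  grid <- expand.grid(window = c("default", "strict"),
                      hot_mode = c("keep", "exclude_overlap"),
                      conservation = c(3, 5), stringsAsFactors = FALSE)
  ffl_label <- canonical_label(
    data.frame(id = c("a", "b", "g"), type = c("TF", "TF", "gene")),
    data.frame(source = c("a", "a", "b"), target = c("b", "g", "g"), sign = 1))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    net <- .analyse_network(sim, grid$window[i], grid$hot_mode[i],
                            grid$conservation[i], hot = hot)
    tb <- table(factor(net$edges$type, levels = .edge_types))
    row <- data.frame(grid[i, ], n_nodes = nrow(net$nodes),
                      n_tf_gene = as.integer(tb["TF->gene"] + tb["TF->TF"]),
                      n_tf_mirna = as.integer(tb["TF->miRNA"]),
                      n_mirna_gene = as.integer(tb["miRNA->gene"] + tb["miRNA->TF"]),
                      n_edges = nrow(net$edges), stringsAsFactors = FALSE)
    if (with_motifs) {
      set.seed(seed)
      enr <- motif_enrichment(net, size = 3, signed = FALSE,
                              n_null = n_null, q = q)
      row$ffl_z <- if (ffl_label %in% enr$label) {
        enr$z[enr$label == ffl_label]
      } else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Robustness of motif enrichment to random edge removal
#'
#' Removes a fraction of regulatory edges uniformly at random, recomputes
#' the motif enrichment, and reports which originally significant motifs
#' (z > 2 and empirical p <= 0.05) stay significant.
#'
#' @param network An [integrated_network()].
#' @param fractions Removal fractions in (0, 1) (defaults 1/5/10/20/30%).
#' @param n_rep Replicates per fraction.
#' @param n_null,q Motif-analysis settings.
#' @param seed Seed.
#' @return List with `baseline` (the enrichment table) and `stability`
#'   (data frame: fraction, replicate, retained fraction of significant
#'   motifs, mean |z| of those motifs).
#' @export
robustness_check <- function(network, fractions = c(0.01, 0.05, 0.1, 0.2, 0.3),
                             n_rep = 5L, n_null = 50L, q = 20L, seed = 1L) {
  if (any(fractions >= 1) || any(fractions < 0)) {
    stop("removal fractions must lie in [0, 1)")
  }
  # each replicate runs under a derived seed; a 0% "removal" therefore
  # reproduces the baseline enrichment exactly
  derive <- function(f, r) as.integer(seed + 131L * r + round(1e4 * f))
  run_one <- function(f, r) {
    set.seed(derive(f, r))
    e <- network$edges
    keep <- sort(sample(nrow(e), round((1 - f) * nrow(e))))
    sub <- network
    sub$edges <- e[keep, , drop = FALSE]
    used <- unique(c(sub$edges$source, sub$edges$target, sub$ppi$a, sub$ppi$b))
    sub$nodes <- sub$nodes[sub$nodes$id %in% used, , drop = FALSE]
    motif_enrichment(sub, size = 3, signed = FALSE, n_null = n_null, q = q)
  }
  base <- run_one(0, 1L)
  sig <- base$label[!is.na(base$z) & base$z > 2 & base$p_emp <= 0.05]
  rows <- list()
  for (f in fractions) {
    for (r in seq_len(n_rep)) {
      enr <- run_one(f, r)
      still <- enr$label[!is.na(enr$z) & enr$z > 2 & enr$p_emp <= 0.05]
      zsig <- enr$z[enr$label %in% sig & !is.na(enr$z)]
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, replicate = r,
        retained = if (length(sig)) mean(sig %in% still) else NA_real_,
        mean_abs_z = if (length(zsig)) mean(abs(zsig)) else NA_real_)
    }
  }
  list(baseline = base, n_significant = length(sig),
       stability = do.call(rbind, rows))
}
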