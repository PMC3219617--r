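# Assembly of the integrated regulatory network: conservation filtering of
# miRNA seed sites, the gene-universe restriction, degree statistics and
# regulator target-overlap tests.

.edge_types <- c("TF->gene", "TF->TF", "TF->miRNA", "miRNA->gene", "miRNA->TF")

#' Construct an integrated regulatory network
#'
#' Nodes are typed (`TF`, `gene`, `miRNA`); directed regulatory edges are
#' typed by their endpoint classes and carry a sign in `{-1, 0, +1}` (0 =
#' unsigned/ambiguous). Undirected PPI edges live in a separate table and are
#' never counted in regulatory degrees. Self-loops are permitted only as
#' `TF->TF` auto-regulation.
#'
#' @param nodes Data frame `id`, `type`.
#' @param edges Data frame `source`, `target`, `type`, `sign`.
#' @param ppi Data frame `a`, `b` (undirected, de-duplicated).
#' @param gene_universe Optional character vector: the eligible gene universe
#'   used for overlap statistics (defaults to all gene/TF nodes).
#' @return Object of class `integrated_network`.
#' @export
integrated_network <- function(nodes, edges, ppi = NULL,
                               gene_universe = NULL) {
  if (is.null(ppi)) ppi <- data.frame(a = character(), b = character(),
                                      stringsAsFactors = FALSE)
  nodes <- unique(nodes)
  if (anyDuplicated(nodes$id)) stop("node ids must map to a unique type")
  if (nrow(edges)) {
    if (!all(edges$type %in% .edge_types)) stop("unknown edge type")
    unknown <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(unknown)) {
      stop("edges reference unknown node ids: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    key <- paste(edges$type, edges$source, edges$target)
    if (anyDuplicated(key)) stop("duplicate edges of the same type")
    self <- edges$source == edges$target
    if (any(self & edges$type != "TF->TF")) {
      stop("self-loops are only allowed as TF->TF auto-regulation")
    }
  }
  if (is.null(edges$sign)) edges$sign <- 0L
  if (is.null(gene_universe)) {
    gene_universe <- nodes$id[nodes$type %in% c("gene", "TF")]
  }
  rownames(nodes) <- rownames(edges) <- rownames(ppi) <- NULL
  structure(list(nodes = nodes, edges = edges, ppi = ppi,
                 gene_universe = gene_universe),
            class = "integrated_network")
}

#' @export
print.integrated_network <- function(x, ...) {
  cat("integrated_network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "regulatory edges,", nrow(x$ppi), "PPI edges\n")
  if (nrow(x$edges)) print(table(x$edges$type))
  invisible(x)
}

#' Filter miRNA seed sites by cross-species conservation
#'
#' A site passes when it is conserved in every species of the required set:
#' the 3-species set by default, or the stricter 5-species set. A gene is a
#' target of a miRNA if at least one transcript of the gene carries at least
#' one passing site in its 3'UTR; gene-level edges are de-duplicated.
#'
#' @param sites Site table (see [read_site_table()]); one logical column per
#'   species.
#' @param annotation A [genome_annotation()] (maps transcripts to genes).
#' @param min_species 3 (default) or 5.
#' @param species_sets Named list with elements `"3"` and `"5"` giving the
#'   species column names for each mode.
#' @return Data frame `mirna_id`, `gene_id`.
#' @export
filter_conserved_sites <- function(sites, annotation, min_species = 3,
                                   species_sets = list(
                                     "3" = c("C.elegans", "C.briggsae", "C.remanei"),
                                     "5" = c("C.elegans", "C.briggsae", "C.remanei",
                                             "C.brenneri", "C.japonica"))) {
  if (!min_species %in% c(3, 5)) stop("min_species must be 3 or 5")
  need <- species_sets[[as.character(min_species)]]
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("site table lacks species columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(sites)) {
    return(data.frame(mirna_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  pass <- Reduce(`&`, lapply(need, function(sp) sites[[sp]] %in% TRUE))
  hits <- sites[pass, c("mirna_id", "transcript_id"), drop = FALSE]
  gene_of <- stats::setNames(annotation$transcripts$gene_id,
                             annotation$transcripts$transcript_id)
  hits$gene_id <- unname(gene_of[hits$transcript_id])
  if (anyNA(hits$gene_id)) stop("site table references unknown transcripts")
  out <- unique(hits[, c("mirna_id", "gene_id")])
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the integrated network from edge lists
#'
#' The eligible gene universe contains the genes for which both inputs to the
#' analysis exist: an annotated TSS (so TF targets are callable) and at least
#' one annotated 3'UTR (so miRNA sites are predictable). Regulatory edges
#' touching genes outside the universe are dropped, with counts recorded in
#' attribute `dropped`. Edges into genes flagged as TFs are typed `TF->TF` /
#' `miRNA->TF`.
#'
#' @param tf_edges Data frame `tf_id`, `target_id`, `target_type`
#'   (`"gene"`/`"mirna"`) as produced by [call_tf_targets()].
#' @param mirna_edges Data frame `mirna_id`, `gene_id` as produced by
#'   [filter_conserved_sites()].
#' @param ppi_edges Data frame of undirected gene pairs (`a`, `b`), or NULL.
#' @param annotation A [genome_annotation()].
#' @return An [integrated_network()].
#' @export
assemble_network <- function(tf_edges, mirna_edges, ppi_edges, annotation) {
  genes <- annotation$genes
  with_utr <- unique(annotation$transcripts$gene_id[
    annotation$transcripts$transcript_id %in% annotation$utr3$transcript_id])
  with_tss <- unique(annotation$transcripts$gene_id)
  universe <- intersect(with_tss, with_utr)
  is_tf <- stats::setNames(genes$is_tf, genes$gene_id)
  mirna_ids <- annotation$mirnas$mirna_id
  node_type <- function(id) {
    ifelse(id %in% mirna_ids, "miRNA",
           ifelse(is_tf[id] %in% TRUE, "TF", "gene"))
  }
  dropped <- c(tf = 0L, mirna = 0L)
  edges <- data.frame(source = character(), target = character(),
                      type = character(), sign = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(tf_edges) && nrow(tf_edges)) {
    keep <- tf_edges$target_type == "mirna" | tf_edges$target_id %in% universe
    dropped["tf"] <- sum(!keep)
    te <- unique(tf_edges[keep, , drop = FALSE])
    type <- ifelse(te$target_type == "mirna", "TF->miRNA",
                   ifelse(is_tf[te$target_id] %in% TRUE, "TF->TF", "TF->gene"))
    edges <- rbind(edges, data.frame(source = te$tf_id, target = te$target_id,
                                     type = type, sign = 0L,
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(mirna_edges) && nrow(mirna_edges)) {
    keep <- mirna_edges$gene_id %in% universe
    dropped["mirna"] <- sum(!keep)
    me <- unique(mirna_edges[keep, , drop = FALSE])
    type <- ifelse(is_tf[me$gene_id] %in% TRUE, "miRNA->TF", "miRNA->gene")
    edges <- rbind(edges, data.frame(source = me$mirna_id, target = me$gene_id,
                                     type = type, sign = -1L,
                                     stringsAsFactors = FALSE))
  }
  ppi <- NULL
  if (!is.null(ppi_edges) && nrow(ppi_edges)) {
    pe <- ppi_edges[ppi_edges$a %in% universe & ppi_edges$b %in% universe, ,
                    drop = FALSE]
    swap <- pe$a > pe$b
    tmp <- pe$a[swap]; pe$a[swap] <- pe$b[swap]; pe$b[swap] <- tmp
    ppi <- unique(pe[pe$a != pe$b, c("a", "b"), drop = FALSE])
  }
  ids <- unique(c(edges$source, edges$target,
                  if (!is.null(ppi)) c(ppi$a, ppi$b)))
  nodes <- data.frame(id = ids, type = node_type(ids), stringsAsFactors = FALSE)
  if (length(dropped) && any(dropped > 0)) {
    message(sprintf("assemble_network: dropped %d TF edge(s) and %d miRNA edge(s) outside the gene universe",
                    dropped["tf"], dropped["mirna"]))
  }
  net <- integrated_network(nodes, edges, ppi,
                            gene_universe = intersect(universe, ids))
  attr(net, "dropped") <- dropped
  net
}

#' Degree histograms, exponential fits and miRNA in/out correlation
#'
#' Reports the four regulatory degree histograms (regulatory TFs per gene,
#' regulatory TFs per miRNA, regulatory miRNAs per gene, targets per miRNA),
#' an exponential fit `count ~ exp(-lambda k)` per histogram via
#' [fit_exponential()], and the Pearson correlation between miRNA in-degree
#' (regulatory TFs) and out-degree (targets). Histograms cover every node of
#' the relevant class, including zero-degree nodes.
#'
#' @param network An [integrated_network()].
#' @return List of class `degree_report` with `histograms`, `fits`,
#'   `mirna_inout`.
#' @export
degree_statistics <- function(network) {
  e <- network$edges
  nd <- network$nodes
  genes <- nd$id[nd$type %in% c("gene", "TF")]
  mirnas <- nd$id[nd$type == "miRNA"]
  count_over <- function(ids, targets) {
    tab <- table(factor(targets, levels = ids))
    table(as.integer(tab))
  }
  hist_list <- list(
    tfs_per_gene = count_over(genes, e$target[e$type %in% c("TF->gene", "TF->TF")]),
    tfs_per_mirna = count_over(mirnas, e$target[e$type == "TF->miRNA"]),
    mirnas_per_gene = count_over(genes, e$target[e$type %in% c("miRNA->gene", "miRNA->TF")]),
    targets_per_mirna = count_over(mirnas, e$source[e$type %in% c("miRNA->gene", "miRNA->TF")])
  )
  fits <- lapply(hist_list, function(h) {
    fit_exponential(as.integer(names(h)), as.integer(h))
  })
  m_in <- table(factor(e$source[e$type %in% c("miRNA->gene", "miRNA->TF")],
                       levels = mirnas))
  m_tf <- table(factor(e$target[e$type == "TF->miRNA"], levels = mirnas))
  inout <- list(r = NA_real_, p = NA_real_)
  if (length(mirnas) >= 3 &&
      stats::sd(as.integer(m_in)) > 0 && stats::sd(as.integer(m_tf)) > 0) {
    ct <- stats::cor.test(as.integer(m_tf), as.integer(m_in))
    inout <- list(r = unname(ct$estimate), p = ct$p.value)
  }
  structure(list(histograms = hist_list, fits = fits, mirna_inout = inout),
            class = "degree_report")
}

#' Pairwise target-overlap tests between regulators
#'
#' For every unordered pair of regulators of the requested classes, reports
#' the sizes of their target sets, the overlap, the upper-tail hypergeometric
#' p-value over the network's target universe, and Benjamini-Hochberg
#' q-values across all pairs in the matrix. Self-pairs are excluded;
#' regulators without targets give p = 1 and are flagged.
#'
#' @param network An [integrated_network()].
#' @param class_pair One of `"TFxTF"`, `"TFxmiRNA"`, `"miRNAxmiRNA"`.
#' @param target_type `"gene"` (protein-coding targets; universe = gene
#'   universe) or `"mirna"` (shared target miRNAs; universe = miRNA nodes).
#' @return Data frame, one row per regulator pair.
#' @export
target_overlap_matrix <- function(network,
                                  class_pair = c("TFxmiRNA", "TFxTF", "miRNAxmiRNA"),
                                  target_type = c("gene", "mirna")) {
  class_pair <- match.arg(class_pair)
  target_type <- match.arg(target_type)
  e <- network$edges
  nd <- network$nodes
  if (target_type == "gene") {
    universe <- network$gene_universe
    etypes_tf <- c("TF->gene", "TF->TF")
    etypes_mi <- c("miRNA->gene", "miRNA->TF")
  } else {
    universe <- nd$id[nd$type == "miRNA"]
    etypes_tf <- "TF->miRNA"
    etypes_mi <- character()
  }
  targets_of <- function(class) {
    etys <- if (class == "TF") etypes_tf else etypes_mi
    sub <- e[e$type %in% etys, , drop = FALSE]
    regs <- nd$id[nd$type == if (class == "TF") "TF" else "miRNA"]
    regs <- intersect(regs, unique(e$source))
    sets <- split(sub$target, factor(sub$source, levels = regs))
    lapply(sets, unique)
  }
  classes <- switch(class_pair,
                    TFxTF = c("TF", "TF"),
                    TFxmiRNA = c("TF", "miRNA"),
                    miRNAxmiRNA = c("miRNA", "miRNA"))
  sets_a <- targets_of(classes[1])
  sets_b <- targets_of(classes[2])
  same <- classes[1] == classes[2]
  if (same) {
    if (length(sets_a) < 2) stop("need at least 2 regulators of each class")
    pairs <- t(utils::combn(names(sets_a), 2))
  } else {
    if (length(sets_a) < 1 || length(sets_b) < 1) {
      stop("need at least 1 regulator of each class")
    }
    pairs <- as.matrix(expand.grid(names(sets_a), names(sets_b),
                                   stringsAsFactors = FALSE))
  }
  u <- length(universe)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (a == b) return(NULL)
    ta <- intersect(sets_a[[a]], universe)
    tb <- intersect(sets_b[[b]], universe)
    ov <- length(intersect(ta, tb))
    flagged <- length(ta) == 0 || length(tb) == 0
    p <- if (flagged) 1 else hypergeom_upper_tail(ov, length(ta), length(tb), u)
    data.frame(regulator_a = a, regulator_b = b, n_a = length(ta),
               n_b = length(tb), overlap = ov, p = p, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no regulator pairs to test")
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
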