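# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as brute-force enumerations, independent of the code
# paths they validate.

# ---- tiny annotation built by hand -----------------------------------------

# one + strand and one - strand gene, one intronic miRNA, one intergenic
tiny_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chrI",
    start = c(10000L, 40000L), end = c(16000L, 46000L),
    strand = c("+", "-"), is_tf = c(TRUE, FALSE), stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript_id = c("gA.t1", "gB.t1"), gene_id = c("gA", "gB"),
    chrom = "chrI", start = c(10000L, 40000L), end = c(16000L, 46000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = rep(c("gA.t1", "gB.t1"), each = 2),
    chrom = "chrI",
    start = c(10000L, 14000L, 40000L, 44000L),
    end = c(11000L, 16000L, 41000L, 46000L), stringsAsFactors = FALSE)
  utr3 <- data.frame(
    transcript_id = c("gA.t1", "gB.t1"), chrom = "chrI",
    start = c(15800L, 40000L), end = c(16000L, 40200L),
    stringsAsFactors = FALSE)
  mirnas <- data.frame(
    mirna_id = c("mir-i", "mir-x"), chrom = "chrI",
    start = c(12000L, 70000L), end = c(12100L, 70100L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  genome_annotation(genes, transcripts, exons, utr3, mirnas)
}

# a peak set from centers only
peaks_at <- function(centers, tf_id, chrom = "chrI", halfwidth = 150L,
                     condition = "NA") {
  peak_set(data.frame(chrom = chrom, start = centers - halfwidth,
                      end = centers + halfwidth, center = centers,
                      score = 1, stringsAsFactors = FALSE),
           tf_id = tf_id, condition = condition)
}

# small typed network from compact edge specs: list of c(src, tgt, type, sign)
make_net <- function(edge_list, node_types, ppi = NULL) {
  edges <- do.call(rbind, lapply(edge_list, function(e) {
    data.frame(source = e[[1]], target = e[[2]], type = e[[3]],
               sign = as.integer(if (length(e) >= 4) e[[4]] else 0L),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        type = character(), sign = integer(),
                        stringsAsFactors = FALSE)
  }
  nodes <- data.frame(id = names(node_types), type = unname(node_types),
                      stringsAsFactors = FALSE)
  integrated_network(nodes, edges, ppi)
}

# random typed network: node types assigned, directed regulatory edges
# sampled respecting type constraints; signs random in signed mode
random_typed_network <- function(n_nodes, n_edges, signed = FALSE) {
  types <- sample(c("TF", "miRNA", "gene"), n_nodes, replace = TRUE,
                  prob = c(0.3, 0.3, 0.4))
  ids <- sprintf("n%02d", seq_len(n_nodes))
  names(types) <- ids
  tfs <- ids[types == "TF"]
  mirnas <- ids[types == "miRNA"]
  genes <- ids[types == "gene"]
  cand <- rbind(
    if (length(tfs)) expand.grid(s = tfs, t = c(tfs, mirnas, genes),
                                 stringsAsFactors = FALSE),
    if (length(mirnas)) expand.grid(s = mirnas, t = c(tfs, genes),
                                    stringsAsFactors = FALSE))
  cand <- cand[cand$s != cand$t, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  take <- cand[sample(nrow(cand), min(n_edges, nrow(cand))), , drop = FALSE]
  type_of_edge <- function(s, t) {
    st <- types[s]; tt <- types[t]
    ifelse(st == "TF",
           ifelse(tt == "TF", "TF->TF", ifelse(tt == "miRNA", "TF->miRNA", "TF->gene")),
           ifelse(tt == "TF", "miRNA->TF", "miRNA->gene"))
  }
  edges <- data.frame(source = take$s, target = take$t,
                      type = type_of_edge(take$s, take$t),
                      sign = if (signed) sample(c(-1L, 1L), nrow(take), TRUE)
                             else 0L,
                      stringsAsFactors = FALSE)
  edges$sign[edges$type %in% c("miRNA->gene", "miRNA->TF")] <- -1L
  integrated_network(data.frame(id = ids, type = unname(types),
                                stringsAsFactors = FALSE), edges)
}

# ---- independent oracles ----------------------------------------------------

# exhaustive hypergeometric upper tail from binomial coefficients
oracle_hyper_tail <- function(ov, a, b, u) {
  ks <- ov:min(a, b)
  sum(choose(a, ks) * choose(u - a, b - ks)) / choose(u, b)
}

# exhaustive binomial upper tail at p0 = 1/2
oracle_binom_tail_half <- function(k, n) {
  sum(choose(n, k:n)) / 2^n
}

# brute-force typed/signed motif census over all node triples; labels are
# built by an independent string-permutation canonicalisation
oracle_census3 <- function(network, signed = FALSE) {
  ids <- network$nodes$id
  types <- setNames(network$nodes$type, ids)
  e <- network$edges
  e <- e[e$source != e$target, , drop = FALSE]
  if (signed) e <- e[e$sign != 0, , drop = FALSE]
  ekey <- paste(e$source, e$target)
  esign <- setNames(ifelse(e$sign > 0, "+", "-"), ekey)
  lab_of <- function(trip) {
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    cands <- vapply(perms, function(p) {
      nd <- trip[p]
      tok <- character(0)
      for (i in 1:3) for (j in 1:3) {
        if (i == j) next
        k <- paste(nd[i], nd[j])
        if (k %in% ekey) {
          tok <- c(tok, paste0(i, ">", j, if (signed) esign[[k]] else ""))
        }
      }
      paste0(paste(substr(sub("miRNA", "M", sub("gene", "G", sub("TF", "T", types[nd]))), 1, 1),
                   collapse = ","), "|", paste(tok, collapse = ","))
    }, "")
    min(cands)
  }
  if (length(ids) < 3) return(table(character(0)))
  # undirected adjacency matrix; a node triple is connected iff at least two
  # of its three unordered pairs are adjacent
  n <- length(ids)
  U <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  U[cbind(e$source, e$target)] <- TRUE
  U <- U | t(U)
  trips <- combn(n, 3)
  npairs <- U[cbind(trips[1, ], trips[2, ])] +
    U[cbind(trips[1, ], trips[3, ])] +
    U[cbind(trips[2, ], trips[3, ])]
  conn <- which(npairs >= 2)
  labs <- vapply(conn, function(i) lab_of(ids[trips[, i]]), "")
  table(labs)
}

# exact two-group rank-sum distribution by full enumeration (independent of
# the package's combn-based path: recursion over subset sums is avoided;
# uses explicit index subsets)
oracle_ranksum_two_sided <- function(xs, ys) {
  r <- rank(c(xs, ys))
  n1 <- length(xs); n <- length(r)
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  subs <- combn(n, n1)
  ws <- apply(subs, 2, function(ix) sum(r[ix]))
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# default small simulation used across tests
small_sim <- function(seed = 7, ...) {
  p <- simulation_params(seed = seed, n_genes = 120, n_tfs = 8, n_mirnas = 20,
                         background_peaks_per_tf = 5, n_hot_loci = 2,
                         hot_tf_count = 7, decoy_sites = 30, ...)
  simulate_study(p)
}
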