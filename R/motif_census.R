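# Exact census of 2- and 3-node typed (and optionally signed) subgraphs of
# the regulatory network, enrichment against stratified degree-preserving
# rewiring nulls, and composite motifs involving the PPI scaffold.
#
# Canonical labels: a connected subgraph on k nodes is encoded, for each of
# the k! node orderings, as the digit sequence (node types, then directed
# edge slots in row-major pair order); the canonical form is the minimum over
# orderings, so isomorphic subgraphs share a label. Node type letters are
# T (TF), M (miRNA), G (gene); edge tokens are "i>j" with a +/- suffix in
# signed mode.

.type_code <- c(TF = 1L, miRNA = 2L, gene = 3L)
.type_letter <- c("T", "M", "G")

.perms3 <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
# base slot index of the ordered pair (i, j) among the 6 off-diagonal pairs
.pair_slot <- local({
  p <- matrix(0L, 3, 3)
  p[1, 2] <- 1L; p[1, 3] <- 2L; p[2, 1] <- 3L
  p[2, 3] <- 4L; p[3, 1] <- 5L; p[3, 2] <- 6L
  p
})

# canonical integers for a batch of triples.
# ty: n x 3 type codes; ec: n x 6 edge codes in base slot order
# (1>2, 1>3, 2>1, 2>3, 3>1, 3>2); codes 0 = none, 1 = +/unsigned, 2 = -.
.canon3 <- function(ty, ec) {
  pw <- 4^(8:0)
  best <- NULL
  for (r in seq_len(6)) {
    p <- .perms3[r, ]
    v <- ty[, p[1]] * pw[1] + ty[, p[2]] * pw[2] + ty[, p[3]] * pw[3] +
      ec[, .pair_slot[p[1], p[2]]] * pw[4] +
      ec[, .pair_slot[p[1], p[3]]] * pw[5] +
      ec[, .pair_slot[p[2], p[1]]] * pw[6] +
      ec[, .pair_slot[p[2], p[3]]] * pw[7] +
      ec[, .pair_slot[p[3], p[1]]] * pw[8] +
      ec[, .pair_slot[p[3], p[2]]] * pw[9]
    best <- if (is.null(best)) v else pmin(best, v)
  }
  best
}

.canon2 <- function(ty, ec) {
  # ty: n x 2; ec: n x 2 (slots 1>2, 2>1)
  v1 <- ty[, 1] * 64 + ty[, 2] * 16 + ec[, 1] * 4 + ec[, 2]
  v2 <- ty[, 2] * 64 + ty[, 1] * 16 + ec[, 2] * 4 + ec[, 1]
  pmin(v1, v2)
}

.decode_label <- function(v, size, signed) {
  sign_chr <- if (signed) c("+", "-") else c("", "")
  vapply(v, function(x) {
    if (size == 3) {
      d <- integer(9)
      for (k in 9:1) { d[k] <- x %% 4; x <- x %/% 4 }
      types <- .type_letter[d[1:3]]
      slots <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
      ed <- d[4:9]
    } else {
      d <- integer(4)
      for (k in 4:1) { d[k] <- x %% 4; x <- x %/% 4 }
      types <- .type_letter[d[1:2]]
      slots <- list(c(1, 2), c(2, 1))
      ed <- d[3:4]
    }
    tok <- character(0)
    for (k in seq_along(ed)) {
      if (ed[k] > 0) {
        tok <- c(tok, sprintf("%d>%d%s", slots[[k]][1], slots[[k]][2],
                              sign_chr[ed[k]]))
      }
    }
    paste0(paste(types, collapse = ","), "|", paste(tok, collapse = ","))
  }, "")
}

# integer node indexing plus edge-code lookup for a network
.census_prep <- function(network, signed) {
  ids <- network$nodes$id
  n <- length(ids)
  tyc <- unname(.type_code[network$nodes$type])
  e <- network$edges
  e <- e[e$source != e$target, , drop = FALSE]  # self-loops counted separately
  n_excl <- 0L
  if (signed) {
    n_excl <- sum(e$sign == 0L)
    e <- e[e$sign != 0L, , drop = FALSE]
  }
  si <- match(e$source, ids)
  ti <- match(e$target, ids)
  code <- if (signed) ifelse(e$sign > 0, 1L, 2L) else rep(1L, nrow(e))
  key <- (si - 1) * n + (ti - 1)
  list(ids = ids, n = n, tyc = tyc, si = si, ti = ti,
       key = key, code = code, n_excluded = n_excl)
}

.edge_code_at <- function(prep, from, to) {
  idx <- match((from - 1) * prep$n + (to - 1), prep$key)
  ifelse(is.na(idx), 0L, prep$code[idx])
}

# candidate connected triples: every connected triple has a node adjacent to
# the two others in the underlying undirected graph
.connected_triples <- function(prep) {
  und <- unique(data.frame(a = c(prep$si, prep$ti), b = c(prep$ti, prep$si)))
  adj <- split(und$b, und$a)
  chunks <- lapply(names(adj), function(vch) {
    nb <- unique(adj[[vch]])
    if (length(nb) < 2) return(NULL)
    cmb <- utils::combn(nb, 2)
    cbind(as.integer(vch), t(cmb))
  })
  tri <- do.call(rbind, chunks)
  if (is.null(tri) || !nrow(tri)) return(matrix(integer(), ncol = 3))
  a <- pmin(tri[, 1], tri[, 2], tri[, 3])
  c_ <- pmax(tri[, 1], tri[, 2], tri[, 3])
  b <- tri[, 1] + tri[, 2] + tri[, 3] - a - c_
  key <- (a * prep$n + b) * prep$n + c_
  keep <- !duplicated(key)
  cbind(a[keep], b[keep], c_[keep])
}

#' Canonical label of a small typed subgraph
#'
#' Returns the canonical (node-permutation-invariant) label of a connected
#' subgraph on 2 or 3 typed nodes with typed/signed directed edges.
#' Isomorphic subgraphs map to identical labels; non-isomorphic ones to
#' distinct labels. Label grammar: node type letters (`T`, `M`, `G`) in
#' canonical order, then edge tokens `i>j` (1-based positions, `+`/`-`
#' suffix in signed mode).
#'
#' @param nodes Data frame `id`, `type` (2 or 3 rows).
#' @param edges Data frame `source`, `target`, `sign`.
#' @param signed Encode edge signs in the label.
#' @return A single label string.
#' @examples
#' canonical_label(
#'   data.frame(id = c("a", "b", "g"), type = c("TF", "TF", "gene")),
#'   data.frame(source = c("a", "a", "b"), target = c("b", "g", "g"),
#'              sign = c(1, 1, 1)))
#' @export
canonical_label <- function(nodes, edges, signed = FALSE) {
  k <- nrow(nodes)
  if (!k %in% c(2, 3)) stop("canonical_label covers subgraphs on 2 or 3 nodes")
  if (is.null(edges$sign)) edges$sign <- 1L
  tyc <- unname(.type_code[nodes$type])
  if (anyNA(tyc)) stop("node types must be TF, miRNA or gene")
  si <- match(edges$source, nodes$id)
  ti <- match(edges$target, nodes$id)
  if (anyNA(si) || anyNA(ti)) stop("edges reference nodes outside the subgraph")
  code_at <- function(i, j) {
    hit <- which(si == i & ti == j)
    if (!length(hit)) return(0L)
    if (signed) { if (edges$sign[hit[1]] > 0) 1L else 2L } else 1L
  }
  # connectivity of the underlying undirected graph
  und <- unique(cbind(pmin(si, ti), pmax(si, ti)))
  und <- und[und[, 1] != und[, 2], , drop = FALSE]
  if ((k == 2 && nrow(und) < 1) || (k == 3 && nrow(und) < 2)) {
    stop("subgraph is not connected")
  }
  if (k == 3) {
    ec <- matrix(c(code_at(1, 2), code_at(1, 3), code_at(2, 1),
                   code_at(2, 3), code_at(3, 1), code_at(3, 2)), nrow = 1)
    v <- .canon3(matrix(tyc, nrow = 1), ec)
  } else {
    ec <- matrix(c(code_at(1, 2), code_at(2, 1)), nrow = 1)
    v <- .canon2(matrix(tyc, nrow = 1), ec)
  }
  .decode_label(v, k, signed)
}

#' Exact typed/signed subgraph census
#'
#' Enumerates every connected node pair (`size = 2`) or triple (`size = 3`)
#' of the regulatory network exactly (no sampling) and counts canonical
#' labels. Each unordered node set is counted once. TF auto-regulation
#' self-loops are not part of the 3-node census (see
#' [count_autoregulation()]); in signed mode, edges with sign 0 (ambiguous
#' regulators) are excluded and their number recorded in the
#' `n_excluded_edges` attribute.
#'
#' @param network An [integrated_network()].
#' @param size 2 or 3.
#' @param signed Distinguish edge signs in motif labels.
#' @param sample_triples For very large networks: count only this many
#'   uniformly sampled connected triples and scale counts up by the
#'   inverse sampling fraction (Horvitz-Thompson); counts then become
#'   non-integer estimates. NULL (default) enumerates exactly.
#' @return Data frame `label`, `count`, sorted by decreasing count, with
#'   attributes `n_subgraphs` (total connected sets counted) and
#'   `n_excluded_edges`.
#' @export
census <- function(network, size = 3, signed = FALSE, sample_triples = NULL) {
  if (!size %in% c(2, 3)) stop("census size must be 2 or 3")
  prep <- .census_prep(network, signed)
  if (size == 3) {
    tri <- .connected_triples(prep)
    scale_up <- 1
    if (!is.null(sample_triples) && nrow(tri) > sample_triples) {
      keep <- sample.int(nrow(tri), sample_triples)
      scale_up <- nrow(tri) / sample_triples
      tri <- tri[keep, , drop = FALSE]
    }
    if (!nrow(tri)) {
      out <- data.frame(label = character(), count = integer(),
                        stringsAsFactors = FALSE)
      attr(out, "n_subgraphs") <- 0L
      attr(out, "n_excluded_edges") <- prep$n_excluded
      return(out)
    }
    ty <- cbind(prep$tyc[tri[, 1]], prep$tyc[tri[, 2]], prep$tyc[tri[, 3]])
    ec <- cbind(.edge_code_at(prep, tri[, 1], tri[, 2]),
                .edge_code_at(prep, tri[, 1], tri[, 3]),
                .edge_code_at(prep, tri[, 2], tri[, 1]),
                .edge_code_at(prep, tri[, 2], tri[, 3]),
                .edge_code_at(prep, tri[, 3], tri[, 1]),
                .edge_code_at(prep, tri[, 3], tri[, 2]))
    v <- .canon3(ty, ec)
  } else {
    scale_up <- 1
    pr <- unique(cbind(pmin(prep$si, prep$ti), pmax(prep$si, prep$ti)))
    if (!nrow(pr)) {
      out <- data.frame(label = character(), count = integer(),
                        stringsAsFactors = FALSE)
      attr(out, "n_subgraphs") <- 0L
      attr(out, "n_excluded_edges") <- prep$n_excluded
      return(out)
    }
    ty <- cbind(prep$tyc[pr[, 1]], prep$tyc[pr[, 2]])
    ec <- cbind(.edge_code_at(prep, pr[, 1], pr[, 2]),
                .edge_code_at(prep, pr[, 2], pr[, 1]))
    v <- .canon2(ty, ec)
  }
  tab <- table(v)
  cnt <- as.numeric(tab) * scale_up
  if (scale_up == 1) cnt <- as.integer(cnt)
  out <- data.frame(label = .decode_label(as.numeric(names(tab)), size, signed),
                    count = cnt, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_subgraphs") <- length(v) * scale_up
  attr(out, "n_excluded_edges") <- prep$n_excluded
  out
}

#' Count TF auto-regulation loops
#'
#' Self-loops are the one-node motif; they are excluded from the 2/3-node
#' census and counted here, split into positive (PAR) and negative (NAR)
#' auto-regulation by edge sign.
#'
#' @param network An [integrated_network()].
#' @return List `n`, `par`, `nar`, `tfs` (data frame `tf_id`, `sign`).
#' @export
count_autoregulation <- function(network) {
  e <- network$edges
  self <- e[e$source == e$target & e$type == "TF->TF", , drop = FALSE]
  list(n = nrow(self), par = sum(self$sign > 0), nar = sum(self$sign < 0),
       tfs = data.frame(tf_id = self$source, sign = self$sign,
                        stringsAsFactors = FALSE))
}

#' Degree-preserving stratified rewiring null
#'
#' Maslov-Sneppen double-edge swaps applied independently within each edge
#' stratum: the edge type (`TF->gene`, `TF->TF`, `TF->miRNA`, `miRNA->gene`,
#' `miRNA->TF`), additionally split by sign when `signed = TRUE`, so that
#' every node keeps its per-type (and per-sign) in- and out-degrees exactly.
#' `q * |E_stratum|` swaps are attempted per stratum; swaps that would
#' create duplicates (within the edge type) or self-loops are rejected.
#' Strata with fewer than 2 edges cannot be rewired and are flagged in the
#' `skipped_strata` attribute. PPI edges are never rewired.
#'
#' @param network An [integrated_network()].
#' @param q Attempted swaps per edge (default 100).
#' @param signed Preserve per-sign degrees separately.
#' @param only_types Optional character vector restricting rewiring to these
#'   edge types (others left untouched), e.g. miRNA strata only.
#' @return A rewired [integrated_network()]; randomness follows R's RNG
#'   (use `set.seed()` for reproducibility).
#' @export
rewire_null <- function(network, q = 100L, signed = FALSE, only_types = NULL) {
  e <- network$edges
  if (!nrow(e)) return(network)
  ids <- network$nodes$id
  si <- match(e$source, ids)
  ti <- match(e$target, ids)
  stratum <- if (signed) paste(e$type, e$sign) else e$type
  if (!is.null(only_types)) {
    # frozen edges get singleton strata so they are never touched
    frozen <- !(e$type %in% only_types)
    stratum[frozen] <- paste0(".frozen", seq_len(nrow(e)))[frozen]
  }
  # locale-independent stratum codes so draws are reproducible everywhere
  slev <- sort(unique(stratum), method = "radix")
  sf <- match(stratum, slev)
  tf_ <- match(e$type, .edge_types)
  res <- cpp_rewire_strata(si, ti, sf, tf_, as.integer(q))
  e$source <- ids[res$src]
  e$target <- ids[res$tgt]
  network$edges <- e
  skipped <- slev[res$skipped_strata]
  attr(network, "skipped_strata") <-
    if (is.null(only_types)) skipped else setdiff(skipped, stratum[frozen])
  network
}

#' Motif enrichment against an ensemble of rewired networks
#'
#' Runs the exact census on the real network and on `n_null` stratified
#' rewiring nulls, and reports for every label observed anywhere: the real
#' count `n_real`, the null mean and sd, `z = (n_real - mean) / sd` (NA when
#' the null sd is 0), and the add-one empirical p-value
#' `(1 + #\{null >= n_real\}) / (n_null + 1)`, which can never be 0. Labels
#' absent from the real network but present in nulls appear with
#' `n_real = 0`, exposing depletion.
#'
#' @param network An [integrated_network()].
#' @param size Motif size, 2 or 3.
#' @param signed Signed census and sign-stratified nulls.
#' @param n_null Number of null networks (default 1000).
#' @param q Attempted swaps per edge for each null.
#' @param seed Optional seed for reproducibility.
#' @return Data frame `label`, `n_real`, `null_mean`, `null_sd`, `z`,
#'   `p_emp`, sorted by decreasing z.
#' @export
motif_enrichment <- function(network, size = 3, signed = FALSE,
                             n_null = 1000L, q = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  real <- census(network, size, signed)
  real_counts <- stats::setNames(real$count, real$label)
  null_list <- vector("list", n_null)
  for (i in seq_len(n_null)) {
    null_list[[i]] <- census(rewire_null(network, q = q, signed = signed),
                             size, signed)
  }
  labels <- Reduce(union, c(list(real$label),
                            lapply(null_list, function(d) d$label)))
  nullmat <- matrix(0L, nrow = length(labels), ncol = n_null,
                    dimnames = list(labels, NULL))
  for (i in seq_len(n_null)) {
    d <- null_list[[i]]
    nullmat[d$label, i] <- d$count
  }
  n_real <- ifelse(labels %in% names(real_counts),
                   real_counts[labels], 0L)
  mu <- rowMeans(nullmat)
  sdv <- apply(nullmat, 1, stats::sd)
  z <- ifelse(sdv > 0, (n_real - mu) / sdv, NA_real_)
  p_emp <- (1 + rowSums(nullmat >= matrix(n_real, nrow = length(labels),
                                          ncol = n_null))) / (n_null + 1)
  out <- data.frame(label = labels, n_real = as.integer(n_real),
                    null_mean = mu, null_sd = sdv, z = z, p_emp = p_emp,
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$z), -Inf, out$z), out$label), ]
  rownames(out) <- NULL
  out
}

#' Composite motifs built on the PPI scaffold and feedback/auto-regulation
#'
#' Three composite counts with permutation p-values (add-one empirical):
#' \describe{
#'   \item{co_mirna_ppi}{Incidences of a miRNA repressing both endpoints of
#'     a PPI edge. Null: rewire the miRNA target strata only, PPI fixed.}
#'   \item{feedback_loops}{Unordered (TF, miRNA) pairs connected in both
#'     directions (TF->miRNA and miRNA->TF composite feedback loops).
#'     Null: rewire both strata.}
#'   \item{autoregulation}{TF->TF self-loops, split into PAR/NAR by sign.
#'     Null: permute the target slots of the TF->TF edges.}
#' }
#'
#' @param network An [integrated_network()] (with PPI edges for the first
#'   test; otherwise that test is skipped and flagged).
#' @param n_null Number of permutations (default 100).
#' @param q Swaps per edge for the rewiring nulls.
#' @param seed Optional seed.
#' @return List with one element per test: `count`, `p_emp`, plus
#'   `par`/`nar` for auto-regulation; skipped tests carry `skipped = TRUE`.
#' @export
composite_ppi_motifs <- function(network, n_null = 100L, q = 100L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- network$edges
  count_co <- function(net) {
    ee <- net$edges
    tgt <- ee[ee$type %in% c("miRNA->gene", "miRNA->TF"), , drop = FALSE]
    sets <- split(tgt$source, tgt$target)
    p <- net$ppi
    if (!nrow(p)) return(0L)
    sum(vapply(seq_len(nrow(p)), function(i) {
      length(intersect(sets[[p$a[i]]], sets[[p$b[i]]]))
    }, integer(1)))
  }
  count_fb <- function(net) {
    ee <- net$edges
    down <- ee[ee$type == "TF->miRNA", c("source", "target")]
    up <- ee[ee$type == "miRNA->TF", c("source", "target")]
    length(intersect(paste(down$source, down$target),
                     paste(up$target, up$source)))
  }
  out <- list()
  if (nrow(network$ppi)) {
    real <- count_co(network)
    nulls <- vapply(seq_len(n_null), function(i) {
      count_co(rewire_null(network, q = q,
                           only_types = c("miRNA->gene", "miRNA->TF")))
    }, integer(1))
    out$co_mirna_ppi <- list(count = real,
                             null_mean = mean(nulls),
                             p_emp = (1 + sum(nulls >= real)) / (n_null + 1))
  } else {
    out$co_mirna_ppi <- list(count = NA_integer_, p_emp = NA_real_,
                             skipped = TRUE)
  }
  real_fb <- count_fb(network)
  nulls_fb <- vapply(seq_len(n_null), function(i) {
    count_fb(rewire_null(network, q = q,
                         only_types = c("TF->miRNA", "miRNA->TF")))
  }, integer(1))
  out$feedback_loops <- list(count = real_fb,
                             null_mean = mean(nulls_fb),
                             p_emp = (1 + sum(nulls_fb >= real_fb)) / (n_null + 1))
  auto <- count_autoregulation(network)
  tftf <- e[e$type == "TF->TF", , drop = FALSE]
  nulls_ar <- vapply(seq_len(n_null), function(i) {
    sum(tftf$source == sample(tftf$target))
  }, integer(1))
  out$autoregulation <- list(count = auto$n, par = auto$par, nar = auto$nar,
                             null_mean = mean(nulls_ar),
                             p_emp = (1 + sum(nulls_ar >= auto$n)) / (n_null + 1))
  out
}
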