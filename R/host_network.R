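# Intronic miRNA / host-gene analysis: containment detection, strand-bias
# test, and the miRNA -> host-gene intra-regulation network.

#' Find intronic miRNA / host-gene pairs
#'
#' A miRNA is intronic in a gene when its pre-miRNA hairpin lies entirely
#' within the gene's span and intersects no exon of any transcript of that
#' gene (the strictest isoform handling: one overlapping exon in any isoform
#' disqualifies the pair). Orientation is `sense` when the strands match.
#' A miRNA contained in more than one gene yields one row per host, flagged
#' ambiguous.
#'
#' @param annotation A [genome_annotation()] with exon structure.
#' @return Data frame `mirna_id`, `host_gene_id`, `orientation`
#'   (`sense`/`antisense`), `ambiguous`.
#' @export
find_host_pairs <- function(annotation) {
  mi <- annotation$mirnas
  g <- annotation$genes
  empty <- data.frame(mirna_id = character(), host_gene_id = character(),
                      orientation = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(mi) || !nrow(g)) return(empty)
  mi_gr <- GenomicRanges::GRanges(mi$chrom,
                                  IRanges::IRanges(mi$start + 1L, mi$end))
  g_gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1L, g$end))
  within <- GenomicRanges::findOverlaps(mi_gr, g_gr, type = "within")
  if (!length(within)) return(empty)
  ex <- annotation$exons
  tr_gene <- stats::setNames(annotation$transcripts$gene_id,
                             annotation$transcripts$transcript_id)
  ex_gene <- unname(tr_gene[ex$transcript_id])
  rows <- lapply(seq_along(within), function(k) {
    i <- S4Vectors::queryHits(within)[k]
    j <- S4Vectors::subjectHits(within)[k]
    gid <- g$gene_id[j]
    gex <- ex[ex_gene == gid & ex$chrom == mi$chrom[i], , drop = FALSE]
    # overlap with any exon of any isoform of the host disqualifies
    if (nrow(gex) && any(gex$start < mi$end[i] & gex$end > mi$start[i])) {
      return(NULL)
    }
    data.frame(mirna_id = mi$mirna_id[i], host_gene_id = gid,
               orientation = if (mi$strand[i] == g$strand[j]) "sense" else "antisense",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$ambiguous <- out$mirna_id %in% out$mirna_id[duplicated(out$mirna_id)]
  out <- out[order(out$mirna_id, out$host_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-sided exact binomial strand-bias test
#'
#' Tests whether intragenic miRNAs favour the sense strand of their host
#' beyond the symmetric null: `p = P[X >= n_sense]` with
#' `X ~ Binomial(n_total, 0.5)`, evaluated exactly in log space.
#'
#' @param n_sense Number of sense-oriented pairs.
#' @param n_total Total number of intragenic miRNAs.
#' @return The one-sided p-value.
#' @export
strand_bias_test <- function(n_sense, n_total) {
  if (n_total == 0) stop("strand bias undefined for zero intragenic miRNAs")
  if (n_sense < 0 || n_sense > n_total) stop("n_sense must lie in [0, n_total]")
  binomial_upper_tail(n_sense, n_total, 0.5)
}

#' Build the miRNA -> host-gene intra-regulation network
#'
#' Restricted to sense-oriented pairs (antisense miRNAs are not assumed
#' co-transcribed with the host). A directed edge `m_a -> host(m_b)` exists
#' when the host gene of miRNA `m_b` is a predicted target of `m_a`;
#' `a == b` is auto-regulation (a miRNA repressing its own host). All edges
#' are repressive (sign -1).
#'
#' @param pairs Host pairs from [find_host_pairs()]; only rows with
#'   `orientation == "sense"` are used.
#' @param mirna_gene_edges Data frame `mirna_id`, `gene_id` of predicted
#'   miRNA targets.
#' @return Data frame `mirna_id`, `host_gene_id`, `host_of` (the miRNA whose
#'   host is targeted), `auto` (logical), `sign`.
#' @export
build_host_network <- function(pairs, mirna_gene_edges) {
  sense <- pairs[pairs$orientation == "sense", , drop = FALSE]
  empty <- data.frame(mirna_id = character(), host_gene_id = character(),
                      host_of = character(), auto = logical(),
                      sign = integer(), stringsAsFactors = FALSE)
  if (!nrow(sense)) return(empty)
  tkey <- paste(mirna_gene_edges$mirna_id, mirna_gene_edges$gene_id)
  rows <- expand.grid(a = sense$mirna_id, b = sense$mirna_id,
                      stringsAsFactors = FALSE)
  host_of_b <- stats::setNames(sense$host_gene_id, sense$mirna_id)
  rows$host <- unname(host_of_b[rows$b])
  hit <- paste(rows$a, rows$host) %in% tkey
  rows <- rows[hit, , drop = FALSE]
  if (!nrow(rows)) return(empty)
  out <- data.frame(mirna_id = rows$a, host_gene_id = rows$host,
                    host_of = rows$b, auto = rows$a == rows$b,
                    sign = -1L, stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$mirna_id, out$host_gene_id, out$host_of), , drop = FALSE]
  rownames(out) <- NULL
  out
}
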