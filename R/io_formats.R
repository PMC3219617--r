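# Readers and writers for the external formats (GFF3 annotation, BED-like
# peaks, TSV expression/site/PPI tables, edge-list networks) and the shared
# coordinate model. All internal coordinates are 0-based half-open, matching
# BED; GFF3's 1-based inclusive coordinates are converted on read and write.

# ---- annotation -------------------------------------------------------------

#' Construct a genome annotation object
#'
#' Tables use 0-based half-open coordinates. The TSS is the strand-aware
#' 5' end: `start` for `+` features, `end - 1` for `-` features. Tables are
#' sorted deterministically so that identical annotations compare equal
#' regardless of input order.
#'
#' @param genes Data frame: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `is_tf` (logical).
#' @param transcripts Data frame: `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param exons Data frame: `transcript_id`, `chrom`, `start`, `end`.
#' @param utr3 Data frame: `transcript_id`, `chrom`, `start`, `end` (3'UTR
#'   intervals).
#' @param mirnas Data frame: `mirna_id`, `chrom`, `start`, `end`, `strand`
#'   (pre-miRNA hairpin loci).
#' @return An object of class `genome_annotation` with derived `tss` columns.
#' @export
genome_annotation <- function(genes, transcripts, exons, utr3, mirnas) {
  stopifnot(all(genes$end > genes$start), all(genes$start >= 0))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (anyDuplicated(transcripts$transcript_id)) stop("duplicate transcript ids")
  if (anyDuplicated(mirnas$mirna_id)) stop("duplicate miRNA ids")
  missing_parent <- setdiff(transcripts$gene_id, genes$gene_id)
  if (length(missing_parent)) {
    stop("transcripts reference unknown genes: ",
         paste(utils::head(missing_parent, 5), collapse = ", "))
  }
  if (is.null(genes$is_tf)) genes$is_tf <- FALSE
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  transcripts$tss <- ifelse(transcripts$strand == "+",
                            transcripts$start, transcripts$end - 1)
  mirnas$start5 <- ifelse(mirnas$strand == "+", mirnas$start, mirnas$end - 1)
  ord <- function(d, id) d[order(d$chrom, d$start, d[[id]]), , drop = FALSE]
  ann <- list(
    genes = ord(genes, "gene_id"),
    transcripts = ord(transcripts, "transcript_id"),
    exons = exons[order(exons$transcript_id, exons$start), , drop = FALSE],
    utr3 = utr3[order(utr3$transcript_id, utr3$start), , drop = FALSE],
    mirnas = ord(mirnas, "mirna_id")
  )
  ann <- lapply(ann, function(d) { rownames(d) <- NULL; d })
  structure(ann, class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:",
      nrow(x$genes), "genes (", sum(x$genes$is_tf), "TFs ),",
      nrow(x$transcripts), "transcripts,",
      nrow(x$mirnas), "pre-miRNAs\n")
  invisible(x)
}

.gff_feature_types <- c("gene", "mRNA", "exon", "three_prime_UTR", "pre_miRNA")

#' Read a GFF3 annotation file
#'
#' Recognised feature types are `gene`, `mRNA`, `exon`, `three_prime_UTR`
#' and `pre_miRNA` (the dialect used here for pre-miRNA hairpins); records of
#' other types are ignored with a warning that reports how many were skipped.
#' 1-based inclusive GFF coordinates become 0-based half-open internally.
#' A gene attribute `is_tf=1` marks transcription factors.
#'
#' @param path Path to a GFF3 file.
#' @return A [genome_annotation()] object.
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body)) {
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != 9)
    if (length(bad)) {
      stop(sprintf("malformed GFF line %d: expected 9 columns, found %d",
                   body[bad[1]], nf[bad[1]]))
    }
    st <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
    en <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    bad <- which(is.na(st) | is.na(en) | en < st)
    if (length(bad)) {
      stop(sprintf("malformed GFF line %d: invalid interval", body[bad[1]]))
    }
  }
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent", "is_tf")))
  unknown <- !(as.character(gff$type) %in% .gff_feature_types)
  if (any(unknown)) {
    warning(sprintf("ignored %d record(s) of unrecognised feature type(s): %s",
                    sum(unknown),
                    paste(unique(gff$type[unknown]), collapse = ", ")))
    gff <- gff[!unknown, , drop = FALSE]
  }
  gff$parent1 <- vapply(gff$Parent, function(p) {
    if (length(p)) as.character(p[[1]]) else NA_character_
  }, "")
  pick <- function(type) gff[as.character(gff$type) == type, , drop = FALSE]
  g <- pick("gene")
  genes <- data.frame(
    gene_id = as.character(g$ID), chrom = as.character(g$seqid),
    start = g$start - 1L, end = as.integer(g$end),
    strand = as.character(g$strand),
    is_tf = !is.na(g$is_tf) & g$is_tf %in% c("1", "true", "TRUE"),
    stringsAsFactors = FALSE)
  tr <- pick("mRNA")
  transcripts <- data.frame(
    transcript_id = as.character(tr$ID), gene_id = tr$parent1,
    chrom = as.character(tr$seqid),
    start = tr$start - 1L, end = as.integer(tr$end),
    strand = as.character(tr$strand), stringsAsFactors = FALSE)
  ex <- pick("exon")
  exons <- data.frame(
    transcript_id = ex$parent1, chrom = as.character(ex$seqid),
    start = ex$start - 1L, end = as.integer(ex$end), stringsAsFactors = FALSE)
  ut <- pick("three_prime_UTR")
  utr3 <- data.frame(
    transcript_id = ut$parent1, chrom = as.character(ut$seqid),
    start = ut$start - 1L, end = as.integer(ut$end), stringsAsFactors = FALSE)
  mi <- pick("pre_miRNA")
  mirnas <- data.frame(
    mirna_id = as.character(mi$ID), chrom = as.character(mi$seqid),
    start = mi$start - 1L, end = as.integer(mi$end),
    strand = as.character(mi$strand), stringsAsFactors = FALSE)
  genome_annotation(genes, transcripts, exons, utr3, mirnas)
}

#' Write an annotation as GFF3
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates
#' are converted back to GFF3's 1-based inclusive convention, so a
#' read -> write -> read round trip is the identity.
#'
#' @param ann A [genome_annotation()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  row9 <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tintregnet\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start + 1L, end, strand, attrs)
  }
  g <- ann$genes
  out <- c("##gff-version 3",
           row9(g$chrom, "gene", g$start, g$end, g$strand,
                sprintf("ID=%s%s", g$gene_id,
                        ifelse(g$is_tf, ";is_tf=1", ""))))
  tr <- ann$transcripts
  if (nrow(tr)) {
    out <- c(out, row9(tr$chrom, "mRNA", tr$start, tr$end, tr$strand,
                       sprintf("ID=%s;Parent=%s", tr$transcript_id, tr$gene_id)))
    strand_of <- stats::setNames(tr$strand, tr$transcript_id)
    ex <- ann$exons
    if (nrow(ex)) {
      out <- c(out, row9(ex$chrom, "exon", ex$start, ex$end,
                         unname(strand_of[ex$transcript_id]),
                         sprintf("Parent=%s", ex$transcript_id)))
    }
    ut <- ann$utr3
    if (nrow(ut)) {
      out <- c(out, row9(ut$chrom, "three_prime_UTR", ut$start, ut$end,
                         unname(strand_of[ut$transcript_id]),
                         sprintf("Parent=%s", ut$transcript_id)))
    }
  }
  mi <- ann$mirnas
  if (nrow(mi)) {
    out <- c(out, row9(mi$chrom, "pre_miRNA", mi$start, mi$end, mi$strand,
                       sprintf("ID=%s", mi$mirna_id)))
  }
  writeLines(out, path)
  invisible(path)
}

# ---- peaks ------------------------------------------------------------------

#' Construct a peak set
#'
#' @param peaks Data frame with `chrom`, `start`, `end`, `center`, `score`
#'   (0-based half-open intervals; `center` inside the interval).
#' @param tf_id Assayed factor identifier.
#' @param condition Condition label, e.g. a developmental stage.
#' @return Object of class `peak_set`.
#' @export
peak_set <- function(peaks, tf_id, condition = "NA") {
  if (nrow(peaks)) {
    stopifnot(all(peaks$end > peaks$start),
              all(peaks$center >= peaks$start & peaks$center < peaks$end),
              all(peaks$score >= 0))
  }
  rownames(peaks) <- NULL
  structure(peaks, class = c("peak_set", "data.frame"),
            tf_id = tf_id, condition = condition)
}

#' Read peaks from a BED or narrowPeak file
#'
#' BED coordinates are already 0-based half-open and are kept as-is. For
#' 10-column narrowPeak input with a non-negative summit offset (column 10)
#' the peak center is `start + offset`; otherwise the interval midpoint
#' `floor((start + end) / 2)`. An empty file yields an empty peak set.
#'
#' @param path Path to a BED3+ / narrowPeak file.
#' @inheritParams peak_set
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, tf_id, condition = "NA") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(peak_set(data.frame(chrom = character(), start = integer(),
                               end = integer(), center = integer(),
                               score = numeric()), tf_id, condition))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 columns", which(nf < 3)[1]))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.integer(vapply(fields, `[`, "", 2L))
  end <- as.integer(vapply(fields, `[`, "", 3L))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) stop(sprintf("malformed BED line %d: end <= start", bad[1]))
  score <- if (all(nf >= 5)) {
    s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    ifelse(is.na(s), 0, s)
  } else rep(0, length(start))
  center <- floor((start + end) / 2)
  if (all(nf >= 10)) {
    off <- suppressWarnings(as.integer(vapply(fields, `[`, "", 10L)))
    use <- !is.na(off) & off >= 0
    center[use] <- start[use] + off[use]
  }
  peak_set(data.frame(chrom = chrom, start = start, end = end,
                      center = center, score = score,
                      stringsAsFactors = FALSE), tf_id, condition)
}

#' Write a peak set as narrowPeak-like BED
#'
#' Ten columns; the summit offset column preserves the peak center so a
#' write -> read round trip keeps centers.
#'
#' @param ps A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(ps, path) {
  if (!nrow(ps)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s_peak%d\t%g\t.\t0\t-1\t-1\t%d",
                   ps$chrom, ps$start, ps$end, attr(ps, "tf_id"),
                   seq_len(nrow(ps)), ps$score, ps$center - ps$start)
  writeLines(lines, path)
  invisible(path)
}

# ---- simple TSV tables ------------------------------------------------------

#' Read an expression matrix from TSV
#'
#' First column holds entity ids, the header row holds condition labels.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with entity rownames.
#' @export
read_expression <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         row.names = 1, stringsAsFactors = FALSE)
  m <- as.matrix(d)
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
  m
}

#' Write an expression matrix as TSV
#' @param expr Numeric matrix with rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(id = rownames(expr), expr, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA seed-site table from TSV
#'
#' Columns: `mirna_id`, `transcript_id`, `chrom`, `start`, `end`, then one
#' logical column per species carrying the conservation flag of each site.
#'
#' @param path Path to a TSV file.
#' @return Data frame; species columns are logical.
#' @export
read_site_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  fixed <- c("mirna_id", "transcript_id", "chrom", "start", "end")
  if (!all(fixed %in% names(d))) stop("site table missing required columns")
  for (sp in setdiff(names(d), fixed)) d[[sp]] <- as.logical(d[[sp]])
  d
}

#' Write a miRNA seed-site table as TSV
#' @param sites Site table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column edge list (e.g. PPI) from TSV
#' @param path Path to a headered two-column TSV.
#' @return Data frame with columns `a`, `b`.
#' @export
read_edge_pairs <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(d[, 1:2], c("a", "b"))
}

#' Read an id -> logical flag table (e.g. essentiality) from TSV
#' @param path Path to a headered two-column TSV.
#' @return Named logical vector.
#' @export
read_flags <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(as.logical(d[, 2]), d[, 1])
}

# ---- network edge lists -----------------------------------------------------

#' Write an integrated network as a TSV edge list
#'
#' One row per edge with columns `source_id`, `source_type`, `target_id`,
#' `target_type`, `edge_type`, `sign` (0 for unsigned edges, including PPI).
#' Rows are sorted by (edge_type, source, target) so output is deterministic.
#'
#' @param network An [integrated_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  ty <- stats::setNames(network$nodes$type, network$nodes$id)
  reg <- network$edges
  rows <- data.frame(
    source_id = reg$source, source_type = unname(ty[reg$source]),
    target_id = reg$target, target_type = unname(ty[reg$target]),
    edge_type = reg$type, sign = reg$sign, stringsAsFactors = FALSE)
  if (nrow(network$ppi)) {
    rows <- rbind(rows, data.frame(
      source_id = network$ppi$a, source_type = unname(ty[network$ppi$a]),
      target_id = network$ppi$b, target_type = unname(ty[network$ppi$b]),
      edge_type = "PPI", sign = 0L, stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$edge_type, rows$source_id, rows$target_id), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an integrated network from a TSV edge list
#'
#' Inverse of [write_network()]; node set is reconstructed from edge
#' endpoints.
#'
#' @param path Path to an edge-list TSV.
#' @return An [integrated_network()].
#' @export
read_network <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  nodes <- unique(rbind(
    data.frame(id = d$source_id, type = d$source_type, stringsAsFactors = FALSE),
    data.frame(id = d$target_id, type = d$target_type, stringsAsFactors = FALSE)))
  is_ppi <- d$edge_type == "PPI"
  edges <- data.frame(source = d$source_id[!is_ppi], target = d$target_id[!is_ppi],
                      type = d$edge_type[!is_ppi], sign = as.integer(d$sign[!is_ppi]),
                      stringsAsFactors = FALSE)
  ppi <- data.frame(a = d$source_id[is_ppi], b = d$target_id[is_ppi],
                    stringsAsFactors = FALSE)
  integrated_network(nodes, edges, ppi)
}
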