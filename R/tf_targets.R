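# TF target calling: strand-aware promoter windows anchored at the TSS (or at
# the 5' end of a pre-miRNA hairpin), membership decided by the peak CENTER,
# with optional detection and exclusion of highly occupied target (HOT)
# regions where many distinct factors pile up.

#' Promoter window definition
#'
#' The default (1000 bp upstream, 500 bp downstream of the TSS) reflects the
#' observation that most promoter-proximal binding signal falls in that
#' 1.5 kb; `strict` (500/300) trades sensitivity for specificity and
#' `relaxed` (2000/500) the reverse.
#'
#' @param preset `"default"`, `"strict"` or `"relaxed"`, or `NULL` when
#'   giving explicit distances.
#' @param upstream,downstream Distances in bp (used when `preset` is NULL).
#' @return List with `upstream`, `downstream`.
#' @export
promoter_window <- function(preset = "default", upstream = NULL,
                            downstream = NULL) {
  if (!is.null(preset)) {
    w <- switch(preset,
                default = c(1000L, 500L),
                strict = c(500L, 300L),
                relaxed = c(2000L, 500L),
                stop("unknown promoter window preset: ", preset))
    upstream <- w[1]; downstream <- w[2]
  }
  if (upstream < 0 || downstream < 0 || upstream + downstream <= 0) {
    stop("invalid promoter window")
  }
  list(upstream = as.integer(upstream), downstream = as.integer(downstream))
}

# Strand-aware promoter interval, 0-based half-open. For a + strand anchor t
# the window is [t - up, t + down); for - strand, the mirror image
# [t - down + 1, t + up + 1).
.window_bounds <- function(tss, strand, window) {
  up <- window$upstream; down <- window$downstream
  start <- ifelse(strand == "+", tss - up, tss - down + 1L)
  end <- ifelse(strand == "+", tss + down, tss + up + 1L)
  data.frame(start = start, end = end)
}

#' Detect highly occupied target (HOT) regions
#'
#' A genomic position is HOT-covered when peaks of at least `threshold`
#' distinct factors overlap the `window_bp`-wide window centered on it;
#' maximal runs of HOT-covered positions are merged into intervals. Multiple
#' conditions of the same factor count once ("bound by N factors" counts
#' factors, not experiments).
#'
#' @param peaksets List of [peak_set()] objects (possibly several per TF).
#' @param window_bp Window size in bp (default 400).
#' @param threshold Minimum number of distinct factors (default 15).
#' @return Object of class `hot_regions`: data frame `chrom`, `start`, `end`,
#'   `occupancy` (max distinct-TF occupancy inside the interval), with the
#'   detection parameters as attributes.
#' @export
detect_hot_regions <- function(peaksets, window_bp = 400L, threshold = 15L) {
  if (threshold < 1) stop("threshold must be at least 1")
  if (!length(peaksets)) stop("need at least one peak set")
  half <- floor(window_bp / 2)
  tfs <- vapply(peaksets, attr, "", "tf_id")
  by_tf <- split(peaksets, tfs)
  # per TF: union of peaks across conditions, extended so that a position p
  # is covered iff some peak overlaps the window centered on p; the reduced
  # per-TF ranges are disjoint, so pooled coverage counts distinct TFs
  per_tf <- lapply(by_tf, function(sets) {
    df <- do.call(rbind, lapply(sets, function(ps) {
      as.data.frame(ps)[, c("chrom", "start", "end"), drop = FALSE]
    }))
    if (!nrow(df)) return(NULL)
    GenomicRanges::reduce(GenomicRanges::GRanges(
      df$chrom,
      IRanges::IRanges(start = pmax(df$start - half + 2L, 1L),
                       end = df$end + half)))
  })
  per_tf <- per_tf[!vapply(per_tf, is.null, logical(1))]
  cov_total <- if (length(per_tf)) {
    GenomicRanges::coverage(do.call(c, unname(per_tf)))
  } else NULL
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      occupancy = integer(), stringsAsFactors = FALSE)
  if (is.null(cov_total)) {
    return(structure(empty, class = c("hot_regions", "data.frame"),
                     window_bp = window_bp, threshold = threshold))
  }
  out <- empty
  for (chr in names(cov_total)) {
    sl <- IRanges::slice(cov_total[[chr]], lower = threshold)
    if (!length(sl)) next
    out <- rbind(out, data.frame(
      chrom = chr,
      start = IRanges::start(sl) - 1L,
      end = IRanges::end(sl),
      occupancy = as.integer(IRanges::viewMaxs(sl)),
      stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hot_regions", "data.frame"),
            window_bp = window_bp, threshold = threshold)
}

#' Occupancy-fraction HOT threshold for a smaller TF panel
#'
#' Scales the canonical 15-of-22 occupancy fraction to a panel of
#' `n_tfs` assayed factors: `ceiling(0.68 * n_tfs)`.
#'
#' @param n_tfs Number of assayed factors.
#' @return Integer threshold.
#' @export
hot_auto_threshold <- function(n_tfs) {
  as.integer(ceiling(0.68 * n_tfs))
}

# drop peaks according to the HOT handling mode
.filter_hot <- function(peaks, hot, hot_mode) {
  if (hot_mode == "keep" || !nrow(peaks)) return(peaks)
  if (!nrow(hot)) return(peaks)
  hot_gr <- GenomicRanges::GRanges(hot$chrom,
                                   IRanges::IRanges(hot$start + 1L, hot$end))
  q <- if (hot_mode == "exclude_overlap") {
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(peaks$start + 1L, peaks$end))
  } else {
    GenomicRanges::GRanges(peaks$chrom,
                           IRanges::IRanges(peaks$center + 1L, peaks$center + 1L))
  }
  drop <- IRanges::overlapsAny(q, hot_gr)
  peaks[!drop, , drop = FALSE]
}

#' Call TF target genes and miRNAs from binding peaks
#'
#' A gene is a target of the factor when the center of at least one peak lies
#' in the strand-aware promoter window of at least one of the gene's
#' transcripts; a miRNA is a target when a peak center lies in the same
#' window anchored at the strand-aware 5' end of its pre-miRNA hairpin.
#' Edges are de-duplicated across transcripts and across the factor's
#' conditions (union). HOT handling: `exclude_overlap` removes any peak whose
#' interval overlaps a HOT region, `exclude_center` removes peaks whose
#' center falls in one, `keep` uses all peaks.
#'
#' @param peaksets A [peak_set()] or list of them (one factor, possibly
#'   several conditions; or several factors).
#' @param annotation A [genome_annotation()].
#' @param window A [promoter_window()].
#' @param hot A `hot_regions` object, or NULL.
#' @param hot_mode `"keep"`, `"exclude_overlap"` or `"exclude_center"`.
#' @return Data frame `tf_id`, `target_id`, `target_type` in {gene, mirna}.
#' @export
call_tf_targets <- function(peaksets, annotation,
                            window = promoter_window("default"),
                            hot = NULL,
                            hot_mode = c("keep", "exclude_overlap",
                                         "exclude_center")) {
  hot_mode <- match.arg(hot_mode)
  if (hot_mode != "keep" && is.null(hot)) {
    stop("hot_mode '", hot_mode, "' requires a hot_regions object")
  }
  if (inherits(peaksets, "peak_set")) peaksets <- list(peaksets)
  tr <- annotation$transcripts
  wins_tr <- .window_bounds(tr$tss, tr$strand, window)
  mi <- annotation$mirnas
  wins_mi <- .window_bounds(mi$start5, mi$strand, window)
  anchors <- data.frame(
    chrom = c(tr$chrom, mi$chrom),
    start = c(wins_tr$start, wins_mi$start),
    end = c(wins_tr$end, wins_mi$end),
    target_id = c(tr$gene_id, mi$mirna_id),
    target_type = rep(c("gene", "mirna"), c(nrow(tr), nrow(mi))),
    stringsAsFactors = FALSE)
  win_gr <- GenomicRanges::GRanges(
    anchors$chrom, IRanges::IRanges(anchors$start + 1L, anchors$end))
  out <- list()
  for (ps in peaksets) {
    peaks <- .filter_hot(as.data.frame(ps), hot, hot_mode)
    if (!nrow(peaks)) next
    pt <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$center + 1L, peaks$center + 1L))
    hits <- GenomicRanges::findOverlaps(pt, win_gr)
    if (!length(hits)) next
    idx <- unique(S4Vectors::subjectHits(hits))
    out[[length(out) + 1L]] <- data.frame(
      tf_id = attr(ps, "tf_id"),
      target_id = anchors$target_id[idx],
      target_type = anchors$target_type[idx],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(tf_id = character(), target_id = character(),
                      target_type = character(), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$tf_id, res$target_type, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
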