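# Activator/repressor classification. Binding signal around each transcript's
# TSS is summarised in 40 strand-aware 100-bp bins spanning -2 kb..+2 kb; the
# per-bin Pearson correlation with transcript expression, taken across
# transcripts, gives a correlation profile whose consistent sign classifies
# the factor. TF out-edges inherit the factor's sign; miRNA regulation is
# always repressive.

#' Binned binding signal around transcript TSSs
#'
#' Divides the strand-aware region from `flank` bp upstream to `flank` bp
#' downstream of every transcript's TSS into bins of `bin_bp` (40 bins of
#' 100 bp by default; bin 1 is always the most upstream). Each read
#' contributes `overlap / read_length` to a bin, so a read fully inside one
#' bin adds 1 and one straddling two bins splits proportionally. Windows
#' extending past a chromosome start are clipped (positions below 0 get no
#' signal).
#'
#' @param reads Data frame `chrom`, `start`, `end` of signal intervals
#'   (0-based half-open).
#' @param annotation A [genome_annotation()].
#' @param tf_id Factor identifier stored on the result.
#' @param flank Half-width of the window in bp (default 2000).
#' @param bin_bp Bin width in bp (default 100).
#' @return Matrix transcripts x bins (class `binned_signal`), rownames =
#'   transcript ids, with `tf_id` attribute.
#' @export
binned_signal <- function(reads, annotation, tf_id, flank = 2000L,
                          bin_bp = 100L) {
  tr <- annotation$transcripts
  n_bins <- as.integer(2L * flank / bin_bp)
  m <- matrix(0, nrow = nrow(tr), ncol = n_bins,
              dimnames = list(tr$transcript_id, NULL))
  if (nrow(reads)) {
    # genomic bin intervals; bins are numbered 5'->3' so they run backwards
    # along the genome for minus-strand transcripts
    b <- rep(seq_len(n_bins), times = nrow(tr))
    ti <- rep(seq_len(nrow(tr)), each = n_bins)
    plus <- tr$strand[ti] == "+"
    bstart <- ifelse(plus,
                     tr$tss[ti] - flank + (b - 1L) * bin_bp,
                     tr$tss[ti] + flank - b * bin_bp + 1L)
    bend <- bstart + bin_bp
    keep <- bend > 0
    bin_gr <- GenomicRanges::GRanges(
      tr$chrom[ti][keep],
      IRanges::IRanges(pmax(bstart[keep], 0L) + 1L, bend[keep]))
    read_gr <- GenomicRanges::GRanges(
      reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end))
    hits <- GenomicRanges::findOverlaps(read_gr, bin_gr)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(read_gr)[qi], IRanges::ranges(bin_gr)[si]))
      wgt <- ov / IRanges::width(read_gr)[qi]
      tloc <- ti[keep][si]
      bloc <- b[keep][si]
      key <- (tloc - 1L) * n_bins + bloc
      agg <- rowsum(wgt, key)
      k <- as.integer(rownames(agg))
      m[cbind((k - 1L) %/% n_bins + 1L, (k - 1L) %% n_bins + 1L)] <- agg[, 1]
    }
  }
  structure(m, class = c("binned_signal", class(m)), tf_id = tf_id,
            flank = flank, bin_bp = bin_bp)
}

#' Classify a factor as activator, repressor or ambiguous
#'
#' For each bin, the Pearson correlation `r_b` between that bin's signal and
#' (by default log2-transformed) transcript expression is computed across
#' transcripts. Consistency is the larger of the fraction of defined `r_b`
#' that are positive or negative; bins with zero signal variance are dropped
#' from the denominator. The factor is classified by the sign of the mean
#' correlation when consistency reaches the cutoff, otherwise `ambiguous`.
#'
#' @param signal A [binned_signal()] matrix (transcripts x bins).
#' @param expr Expression matrix (transcripts x conditions).
#' @param condition Column of `expr` matched to the binding experiment.
#' @param consistency_cutoff Minimum fraction of same-signed bins (default
#'   0.7).
#' @param log_transform Apply `log2(x + 1)` to expression first (default
#'   TRUE, appropriate for the dynamic range of RNA-seq levels).
#' @return List of class `sign_call`: `tf_id`, `class` (`"positive"`,
#'   `"negative"`, `"ambiguous"`), `consistency`, `mean_r`, `r_bins`,
#'   `n_transcripts`.
#' @export
classify_regulator <- function(signal, expr, condition,
                               consistency_cutoff = 0.7,
                               log_transform = TRUE) {
  if (!condition %in% colnames(expr)) {
    stop("condition '", condition, "' not found in expression matrix")
  }
  common <- intersect(rownames(signal), rownames(expr))
  if (length(common) < 10) {
    stop("need at least 10 transcripts with both signal and expression")
  }
  s <- signal[common, , drop = FALSE]
  y <- expr[common, condition]
  if (log_transform) y <- log2(y + 1)
  if (stats::sd(y) == 0) {
    stop("zero-variance expression vector for condition '", condition, "'")
  }
  r <- vapply(seq_len(ncol(s)), function(b) {
    x <- s[, b]
    if (stats::sd(x) == 0) NA_real_ else stats::cor(x, y)
  }, numeric(1))
  defined <- !is.na(r)
  if (!any(defined)) {
    consistency <- NA_real_
    cls <- "ambiguous"
  } else {
    consistency <- max(mean(r[defined] > 0), mean(r[defined] < 0))
    cls <- if (consistency >= consistency_cutoff) {
      if (mean(r[defined]) > 0) "positive" else "negative"
    } else "ambiguous"
  }
  structure(list(tf_id = attr(signal, "tf_id"), class = cls,
                 consistency = consistency,
                 mean_r = if (any(defined)) mean(r[defined]) else NA_real_,
                 r_bins = r, n_transcripts = length(common)),
            class = "sign_call")
}

#' @export
print.sign_call <- function(x, ...) {
  cat(sprintf("sign_call: %s -> %s (consistency %.2f, mean r %.3f, %d transcripts)\n",
              x$tf_id, x$class,
              ifelse(is.na(x$consistency), NA, x$consistency),
              ifelse(is.na(x$mean_r), NA, x$mean_r), x$n_transcripts))
  invisible(x)
}

#' Export per-TF bin-correlation profiles as a table
#'
#' One row per (TF, bin) with the bin correlation, suitable for plotting the
#' correlation-profile figure underlying the classification.
#'
#' @param sign_calls List of [classify_regulator()] results.
#' @return Data frame `tf_id`, `bin`, `r`, `class`.
#' @export
sign_profiles <- function(sign_calls) {
  do.call(rbind, lapply(sign_calls, function(sc) {
    data.frame(tf_id = sc$tf_id, bin = seq_along(sc$r_bins), r = sc$r_bins,
               class = sc$class, stringsAsFactors = FALSE)
  }))
}

#' Propagate regulator classes to edge signs
#'
#' Every out-edge of a classified factor gets that factor's sign (+1
#' positive, -1 negative, 0 ambiguous; ambiguous edges are excluded from
#' signed motif analysis downstream). All miRNA regulatory edges are signed
#' -1: miRNAs repress their targets. PPI edges stay unsigned.
#'
#' @param network An [integrated_network()].
#' @param sign_calls List of [classify_regulator()] results (or a data frame
#'   with columns `tf_id`, `class`) covering every TF with out-edges.
#' @return The network with the `sign` column filled in.
#' @export
assign_edge_signs <- function(network, sign_calls) {
  if (is.data.frame(sign_calls)) {
    cls <- stats::setNames(sign_calls$class, sign_calls$tf_id)
  } else {
    cls <- stats::setNames(vapply(sign_calls, `[[`, "", "class"),
                           vapply(sign_calls, `[[`, "", "tf_id"))
  }
  e <- network$edges
  tf_src <- e$type %in% c("TF->gene", "TF->TF", "TF->miRNA")
  need <- unique(e$source[tf_src])
  missing <- setdiff(need, names(cls))
  if (length(missing)) {
    stop("no sign call for TF(s) with out-edges: ",
         paste(missing, collapse = ", "))
  }
  sign_of <- c(positive = 1L, negative = -1L, ambiguous = 0L)
  e$sign[tf_src] <- unname(sign_of[cls[e$source[tf_src]]])
  e$sign[e$type %in% c("miRNA->gene", "miRNA->TF")] <- -1L
  network$edges <- e
  network
}
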