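# Regulatory hierarchy: a three-layer TF core built from TF->TF edges
# (self-loops ignored), four miRNA layers slotted around it, and per-layer
# property statistics.

#' Build the three-layer TF core hierarchy
#'
#' Bucket rules, applied to TF->TF edges with self-loops ignored (a factor
#' regulating only itself is "not regulated by any other TF"):
#' top = not regulated by any other TF; bottom = regulates no other TF,
#' among the remaining factors; middle = everything else, i.e. factors that
#' both regulate and are regulated. Unregulated isolated factors land in the
#' top layer (the "unregulated" rule takes precedence). Factors regulated
#' only from the middle still go to the middle bucket so that the assignment
#' is total. Any digraph is layerable under these rules; empty layers are
#' permitted.
#'
#' @param tf_edges Data frame `source`, `target` of TF->TF regulatory edges.
#' @param universe Optional character vector of factors to assign (defaults
#'   to all factors appearing in `tf_edges`).
#' @return Object of class `hierarchy`: list with `tf_layers` (data frame
#'   `tf_id`, `layer` in {top, middle, bottom}) and an empty `mirna_layers`.
#' @export
build_core_hierarchy <- function(tf_edges, universe = NULL) {
  e <- tf_edges[tf_edges$source != tf_edges$target, , drop = FALSE]
  if (is.null(universe)) {
    universe <- sort(unique(c(tf_edges$source, tf_edges$target)))
  }
  has_in <- universe %in% e$target
  has_out <- universe %in% e$source
  layer <- ifelse(!has_in, "top", ifelse(!has_out, "bottom", "middle"))
  structure(list(
    tf_layers = data.frame(tf_id = universe, layer = layer,
                           stringsAsFactors = FALSE),
    mirna_layers = data.frame(mirna_id = character(), layer = integer(),
                              stringsAsFactors = FALSE)),
    class = "hierarchy")
}

#' Insert miRNAs into the hierarchy as four layers
#'
#' Sequential set-difference assignment: layer 1 holds the miRNAs regulating
#' at least one top-layer TF (top priority even if they also regulate lower
#' layers); of the rest, layer 2 those regulating a middle TF; of the rest,
#' layer 3 those regulating a bottom TF; layer 4 the remainder, which only
#' have incoming regulatory edges.
#'
#' @param core A [build_core_hierarchy()] result.
#' @param mirna_tf_edges Data frame `source` (miRNA), `target` (TF) of
#'   miRNA->TF edges.
#' @param mirnas Character vector of all miRNAs to place (defaults to the
#'   sources of `mirna_tf_edges`).
#' @return The hierarchy with `mirna_layers` filled (`layer` in 1..4).
#' @export
place_mirnas <- function(core, mirna_tf_edges, mirnas = NULL) {
  if (is.null(mirnas)) mirnas <- sort(unique(mirna_tf_edges$source))
  lay_of <- stats::setNames(core$tf_layers$layer, core$tf_layers$tf_id)
  regulates <- function(ms, tf_layer) {
    tfs <- names(lay_of)[lay_of == tf_layer]
    ms %in% mirna_tf_edges$source[mirna_tf_edges$target %in% tfs]
  }
  remaining <- mirnas
  assignment <- stats::setNames(rep(4L, length(mirnas)), mirnas)
  for (i in seq_along(c("top", "middle", "bottom"))) {
    tf_layer <- c("top", "middle", "bottom")[i]
    hit <- remaining[regulates(remaining, tf_layer)]
    assignment[hit] <- i
    remaining <- setdiff(remaining, hit)
  }
  core$mirna_layers <- data.frame(mirna_id = mirnas,
                                  layer = unname(assignment[mirnas]),
                                  stringsAsFactors = FALSE)
  core
}

#' @export
print.hierarchy <- function(x, ...) {
  tl <- table(factor(x$tf_layers$layer, levels = c("top", "middle", "bottom")))
  cat("hierarchy: TFs", paste(names(tl), as.integer(tl), collapse = ", "))
  if (nrow(x$mirna_layers)) {
    ml <- table(factor(x$mirna_layers$layer, levels = 1:4))
    cat("; miRNA layers", paste(names(ml), as.integer(ml), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Per-layer property statistics for the TF hierarchy
#'
#' For each TF layer: group size, mean PPI degree, mean number of regulatory
#' miRNAs, mean tissue-specificity score, and the fraction of essential
#' factors. Cross-layer comparisons: Kruskal-Wallis p across the three
#' layers and pairwise two-sided rank-sum p per property (computed only when
#' every layer contributes at least one value); essentiality gets a
#' bottom-vs-top Fisher exact test.
#'
#' @param hierarchy A [place_mirnas()]/[build_core_hierarchy()] result.
#' @param network An [integrated_network()] (for miRNA->TF in-degrees).
#' @param ppi_edges Data frame `a`, `b` of undirected PPI pairs, or NULL.
#' @param tsps_scores Named numeric vector of tissue-specificity scores.
#' @param essential Named logical vector of essentiality flags.
#' @return List of class `layer_report` with `summary` (per-layer means),
#'   `tests` (per-property Kruskal-Wallis and pairwise rank-sum p),
#'   `essential_fisher`.
#' @export
layer_property_report <- function(hierarchy, network, ppi_edges = NULL,
                                  tsps_scores = NULL, essential = NULL) {
  lay <- hierarchy$tf_layers
  tfs <- lay$tf_id
  layers <- c("top", "middle", "bottom")
  props <- list()
  if (!is.null(ppi_edges) && nrow(ppi_edges)) {
    deg <- table(factor(c(ppi_edges$a, ppi_edges$b), levels = tfs))
    props$ppi_degree <- stats::setNames(as.numeric(deg), tfs)
  }
  if (!is.null(network)) {
    e <- network$edges
    nmi <- table(factor(e$target[e$type == "miRNA->TF"], levels = tfs))
    props$n_reg_mirnas <- stats::setNames(as.numeric(nmi), tfs)
  }
  if (!is.null(tsps_scores)) {
    props$tsps <- stats::setNames(as.numeric(tsps_scores[tfs]), tfs)
  }
  if (!is.null(essential)) {
    props$essential <- stats::setNames(as.numeric(essential[tfs]), tfs)
  }
  groups_of <- function(vals) {
    lapply(layers, function(l) {
      v <- vals[lay$tf_id[lay$layer == l]]
      v[!is.na(v)]
    })
  }
  summary_df <- do.call(rbind, lapply(layers, function(l) {
    ids <- lay$tf_id[lay$layer == l]
    row <- data.frame(layer = l, n = length(ids), stringsAsFactors = FALSE)
    for (p in names(props)) {
      v <- props[[p]][ids]
      row[[paste0("mean_", p)]] <- if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }
    row
  }))
  tests <- lapply(props, function(vals) {
    g <- groups_of(vals)
    names(g) <- layers
    if (any(lengths(g) == 0)) {
      return(list(kruskal_p = NA_real_, pairwise = NULL,
                  skipped = "property missing for an entire layer"))
    }
    if (all(lengths(g) < 2)) {
      return(list(kruskal_p = NA_real_, pairwise = NULL,
                  skipped = "too few factors per layer"))
    }
    pw <- utils::combn(layers, 2, function(pr) {
      data.frame(a = pr[1], b = pr[2],
                 p = ranksum(g[[pr[1]]], g[[pr[2]]]),
                 stringsAsFactors = FALSE)
    }, simplify = FALSE)
    list(kruskal_p = kruskal_p(g), pairwise = do.call(rbind, pw),
         skipped = NA_character_)
  })
  fisher <- NULL
  if (!is.null(essential)) {
    top_ids <- lay$tf_id[lay$layer == "top"]
    bot_ids <- lay$tf_id[lay$layer == "bottom"]
    et <- essential[top_ids]; eb <- essential[bot_ids]
    et <- et[!is.na(et)]; eb <- eb[!is.na(eb)]
    if (length(et) && length(eb)) {
      tab <- matrix(c(sum(eb), sum(!eb), sum(et), sum(!et)), nrow = 2)
      fisher <- stats::fisher.test(tab, alternative = "greater")$p.value
    }
  }
  structure(list(summary = summary_df, tests = tests,
                 essential_fisher = fisher),
            class = "layer_report")
}
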