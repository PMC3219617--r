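# Shared statistical kernels: specificity scores, exact tail probabilities,
# exponential degree-distribution fits and rank tests.

#' Tissue/stage specificity score of one expression profile
#'
#' Relative entropy (Kullback-Leibler divergence) of a gene's fractional
#' expression across `K` conditions against the uniform null `q_i = 1/K`.
#' A score of 0 means perfectly uniform expression; the maximum, `log2(K)`
#' (for the default base 2), is reached when all expression falls in a single
#' condition.
#'
#' @param x Non-negative expression values, one per tissue or stage (`K >= 2`).
#' @param base Logarithm base; base 2 gives scores in bits.
#' @return A single non-negative score.
#' @examples
#' tsps(rep(5, 8))          # uniform -> 0
#' tsps(c(1, rep(0, 7)))    # point mass over 8 tissues -> 3 bits
#' @export
tsps <- function(x, base = 2) {
  if (length(x) < 2) {
    stop("specificity needs at least 2 conditions")
  }
  if (anyNA(x) || any(x < 0)) {
    stop("expression values must be non-negative and non-missing")
  }
  s <- sum(x)
  if (s == 0) {
    stop("all-zero expression row: specificity score undefined")
  }
  p <- x / s
  k <- length(x)
  # 0 * log(0) := 0
  sum(ifelse(p > 0, p * log(p * k, base = base), 0))
}

#' Specificity scores for every row of an expression matrix
#'
#' All-zero rows are flagged rather than scored.
#'
#' @param expr Numeric matrix, rows = entities, columns = conditions.
#' @param base Logarithm base passed to [tsps()].
#' @return Data frame with columns `id`, `score`, `n_conditions`, `flagged`.
#' @export
specificity_scores <- function(expr, base = 2) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("specificity needs at least 2 conditions")
  ok <- rowSums(expr) > 0 & !apply(expr, 1, anyNA)
  score <- rep(NA_real_, nrow(expr))
  if (any(ok)) {
    score[ok] <- apply(expr[ok, , drop = FALSE], 1, tsps, base = base)
  }
  data.frame(
    id = if (is.null(rownames(expr))) as.character(seq_len(nrow(expr))) else rownames(expr),
    score = score,
    n_conditions = ncol(expr),
    flagged = !ok,
    stringsAsFactors = FALSE
  )
}

#' Upper-tail hypergeometric probability P[X >= overlap]
#'
#' Probability of drawing at least `overlap` marked elements when `size_b`
#' elements are drawn without replacement from a universe of size `universe`
#' containing `size_a` marked elements. Evaluated in log space so that very
#' small tails do not underflow.
#'
#' @param overlap Observed overlap count.
#' @param size_a,size_b Sizes of the two sets.
#' @param universe Universe size.
#' @return The tail probability, in (0, 1].
#' @export
hypergeom_upper_tail <- function(overlap, size_a, size_b, universe) {
  if (size_a > universe || size_b > universe) {
    stop("set sizes cannot exceed the universe")
  }
  if (overlap > min(size_a, size_b)) {
    stop("overlap cannot exceed the smaller set size")
  }
  if (overlap <= 0) return(1)
  exp(stats::phyper(overlap - 1, size_a, universe - size_a, size_b,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Upper-tail binomial probability P[X >= k]
#'
#' Exact log-space evaluation; no normal approximation, so tails of the
#' order of 1e-60 (as arise in miRNA strand-bias tests) are representable.
#'
#' @param k Observed count of successes.
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @param log_p Return the natural log of the tail probability (tails far
#'   below the double-precision floor, around 1e-308, are only representable
#'   this way).
#' @return The tail probability in (0, 1], or its log.
#' @export
binomial_upper_tail <- function(k, n, p0 = 0.5, log_p = FALSE) {
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  lp <- if (k == 0) 0 else stats::pbinom(k - 1, n, p0, lower.tail = FALSE,
                                         log.p = TRUE)
  if (log_p) lp else exp(lp)
}

#' Fit an exponential decay to a degree histogram
#'
#' Fits `count ~ exp(-lambda * degree)` by least squares of `ln(count)` on
#' degree over occupied bins (count > 0; no pseudocounts). By default the fit
#' is weighted by the bin counts, which keeps sparsely occupied tail bins
#' (where `ln(count)` is dominated by sampling noise) from dragging the slope.
#'
#' @param degrees Integer degrees (bin positions).
#' @param counts Non-negative counts per degree.
#' @param weighted Weight each bin by its count (default) or fit unweighted.
#' @return List with `ok` (logical; FALSE when fewer than 3 occupied bins),
#'   `lambda` (decay rate, positive for a decaying histogram), `r_squared`
#'   (computed on the log scale, weighted consistently with the fit),
#'   `n_bins` (occupied bins used), and `reason` when skipped.
#' @export
fit_exponential <- function(degrees, counts, weighted = TRUE) {
  if (length(degrees) != length(counts)) stop("degrees/counts length mismatch")
  keep <- counts > 0
  k <- as.numeric(degrees[keep])
  cnt <- as.numeric(counts[keep])
  if (length(unique(k)) < 3) {
    return(list(ok = FALSE, lambda = NA_real_, r_squared = NA_real_,
                n_bins = length(k), reason = "fewer than 3 occupied degree bins"))
  }
  y <- log(cnt)
  w <- if (weighted) cnt else rep(1, length(cnt))
  fit <- stats::lm(y ~ k, weights = w)
  fitted_y <- stats::fitted(fit)
  wmean <- sum(w * y) / sum(w)
  ss_res <- sum(w * (y - fitted_y)^2)
  ss_tot <- sum(w * (y - wmean)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  list(ok = TRUE, lambda = -unname(stats::coef(fit)[2]), r_squared = r2,
       n_bins = length(k), reason = NA_character_)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration of the rank-sum distribution (over all subset
#' assignments of the pooled mid-ranks, so ties are handled exactly) when both
#' samples have at most `exact_max` observations; otherwise the normal
#' approximation with tie correction. The two-sided exact p is the symmetric
#' tail `P[|W - E(W)| >= |w - E(W)|]`.
#'
#' @param xs,ys Numeric samples, each non-empty.
#' @param exact_max Largest per-sample size for which the exact distribution
#'   is enumerated.
#' @return Two-sided p-value in (0, 1].
#' @export
ranksum <- function(xs, ys, exact_max = 10) {
  if (length(xs) == 0 || length(ys) == 0) stop("rank-sum test needs non-empty samples")
  n1 <- length(xs)
  n2 <- length(ys)
  n <- n1 + n2
  r <- rank(c(xs, ys))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    cmb <- utils::combn(n, n1)
    ws <- colSums(matrix(r[cmb], nrow = n1))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  } else {
    tie <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- (w - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  min(p, 1)
}

#' Kruskal-Wallis p-value across groups
#'
#' Thin wrapper over [stats::kruskal.test()] for a list of numeric samples.
#'
#' @param groups List of numeric vectors.
#' @return The Kruskal-Wallis p-value, or `NA` if fewer than 2 non-empty
#'   groups are supplied.
#' @export
kruskal_p <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) return(NA_real_)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) return(1)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  stats::kruskal.test(vals, g)$p.value
}
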