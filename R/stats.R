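# The statistical layer used throughout the pipeline: Mann-Whitney U with an
# exact small-sample branch, Benjamini-Hochberg adjustment, effect sizes
# (log2 fold change of means, Cohen's d), significance labels and Pearson
# correlation matrices over per-motif amino-acid counts.

#' Mann-Whitney U test (two-sided)
#'
#' U is the rank-sum statistic for `x`
#' (\eqn{U = \sum rank(x) - n_1(n_1+1)/2}). With `method = "auto"` the p-value
#' is exact (full enumeration of the permutation distribution of U) when
#' `length(x) + length(y) <= 12` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used. The
#' exact two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y Numeric samples (non-empty).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return list with `statistic` (U for `x`), `p` and `method` used.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("mann_whitney_u: empty sample")
  comb <- c(x, y)
  r <- rank(comb)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(comb) > 0L
  use_exact <- switch(method,
                      auto = (n1 + n2 <= 12L) && !ties,
                      exact = TRUE,
                      normal = FALSE)
  if (use_exact) {
    if (ties) stop("exact Mann-Whitney p is not defined with ties")
    p <- mwu_exact_p(U, n1, n2)
    return(list(statistic = U, p = p, method = "exact"))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(comb)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) stop("mann_whitney_u: zero variance (all values tied)")
  z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-z))
  list(statistic = U, p = p, method = "normal")
}

# Exact two-sided p from the full permutation distribution of U (no ties).
# Only depends on ranks, so it is computed over rank subsets.
mwu_exact_p <- function(U, n1, n2) {
  N <- n1 + n2
  subsets <- utils::combn(N, n1)
  us <- colSums(subsets) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(us <= U), mean(us >= U)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in input order, monotone in p-value rank and capped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of adjusted values (same length and order).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("bh_adjust: p-values must be in (0,1]")
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Log2 fold change of sample means
#'
#' @param x,y Numeric samples; both means must be strictly positive.
#' @return `log2(mean(x) / mean(y))`. A non-positive mean raises a condition
#'   of class `rg_nonpositive_mean`, signalling the caller to fall back to
#'   [cohens_d()].
#' @export
log2fc_of_means <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  if (mx <= 0 || my <= 0) {
    stop(structure(class = c("rg_nonpositive_mean", "error", "condition"),
                   list(message = "non-positive mean; use Cohen's d",
                        call = sys.call())))
  }
  log2(mx / my)
}

#' Cohen's d effect size
#'
#' Difference of means divided by the pooled standard deviation with
#' \eqn{(n_1-1),(n_2-1)} weighting.
#'
#' @param x,y Numeric samples of length at least 2 each.
#' @return Numeric d (sign follows `mean(x) - mean(y)`).
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("cohens_d: need at least 2 values per sample")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("cohens_d: pooled standard deviation is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Effect size with automatic fallback
#'
#' Uses the log2 fold change of means where both means are positive, else
#' Cohen's d.
#'
#' @param x,y Numeric samples.
#' @return list with `effect` and `effect_kind`
#'   (`"log2fc"` or `"cohens_d"`).
#' @export
effect_size <- function(x, y) {
  tryCatch(list(effect = log2fc_of_means(x, y), effect_kind = "log2fc"),
           rg_nonpositive_mean = function(e) {
             list(effect = cohens_d(x, y), effect_kind = "cohens_d")
           })
}

#' Significance star label for a p-value
#'
#' `scheme = "conventional"` uses the cuts 0.05 / 0.01 / 0.001 / 0.0001;
#' `scheme = "printed"` uses 0.5 / 0.1 / 0.01 / 0.001. A p-value exactly at a
#' cut receives the less-significant label (strict inequality).
#'
#' @param p Numeric p-value(s).
#' @param scheme `"conventional"` (default) or `"printed"`, or a numeric
#'   vector of strictly decreasing thresholds.
#' @return Character label(s): `"ns"`, `"*"`, `"**"`, `"***"` or `"****"`.
#' @export
significance_label <- function(p, scheme = "conventional") {
  thresholds <- if (is.numeric(scheme)) {
    scheme
  } else {
    switch(match.arg(scheme, c("conventional", "printed")),
           conventional = c(0.05, 0.01, 0.001, 0.0001),
           printed = c(0.5, 0.1, 0.01, 0.001))
  }
  stopifnot(all(diff(thresholds) < 0))
  labels <- c("ns", "*", "**", "***", "****")[seq_len(length(thresholds) + 1L)]
  vapply(p, function(pp) labels[sum(pp < thresholds) + 1L], character(1))
}

#' Pearson correlation matrix over per-motif amino-acid counts
#'
#' @param counts Numeric matrix, one row per motif, one column per amino
#'   acid (at least 3 rows).
#' @return Symmetric correlation matrix with unit diagonal; cells involving a
#'   constant column are `NA` and the affected column names are attached as
#'   attribute `constant_columns`.
#' @export
pearson_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 3L) stop("pearson_matrix: need at least 3 motifs")
  sds <- apply(counts, 2L, stats::sd)
  constant <- colnames(counts)[sds == 0]
  r <- suppressWarnings(stats::cor(counts))
  attr(r, "constant_columns") <- constant
  r
}
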