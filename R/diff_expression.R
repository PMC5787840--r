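#' Pseudocounted fold change
#'
#' `FC = (mean_a + c) / (mean_b + c)`. The pseudocount guards zero means so
#' the ratio is always finite; `0 vs 0` gives `FC = 1`.
#'
#' @param mean_a,mean_b Non-negative normalized group means (vectorized).
#' @param pseudocount Positive constant added to both means; default 0.5.
#' @return List with components `fc` and `log2fc`.
#' @export
fold_change <- function(mean_a, mean_b, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("'pseudocount' must be > 0")
  if (any(mean_a < 0) || any(mean_b < 0)) stop("means must be non-negative")
  fc <- (mean_a + pseudocount) / (mean_b + pseudocount)
  list(fc = fc, log2fc = log2(fc))
}

#' Method-of-moments NB dispersion
#'
#' Per-gene dispersion `alpha` in the parameterization
#' `Var = mu + alpha * mu^2`, estimated on size-factor-corrected counts by
#' pooling the within-group moments:
#' `alpha = max(0, (s2_pooled - mu_bar) / mu_bar^2)`. Optionally shrunk
#' halfway (on the log scale of `alpha + eps`) toward a lowess trend of the
#' raw estimates over log mean, which stabilizes the very noisy per-gene
#' moments available at n = 3.
#'
#' @param counts Raw count matrix (genes x samples).
#' @param group Factor/vector of group labels, length `ncol(counts)`; within
#'   each group at least 2 replicates.
#' @param size_factors Per-sample size factors (default all 1).
#' @param shrink Shrink toward the mean-dispersion trend? Default `TRUE`;
#'   needs >= 20 genes with positive means, otherwise raw estimates are
#'   returned.
#' @return Data frame: `gene_id`, `alpha` (the working, possibly shrunk,
#'   value), `alpha_raw`, `degenerate` (all-zero gene).
#' @export
estimate_dispersion <- function(counts, group, size_factors = NULL,
                                shrink = TRUE) {
  counts <- as_gene_matrix(counts)
  group <- as.factor(group)
  if (length(group) != ncol(counts))
    stop("'group' must have one label per sample")
  if (any(table(group) < 2L))
    stop("each group needs >= 2 replicates")
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  z <- sweep(counts, 2L, size_factors, "/")

  lv <- levels(group)
  means <- vapply(lv, function(g) rowMeans(z[, group == g, drop = FALSE]),
                  numeric(nrow(z)))
  vars <- vapply(lv, function(g)
    apply(z[, group == g, drop = FALSE], 1L, stats::var),
    numeric(nrow(z)))
  means <- matrix(means, nrow = nrow(z))
  vars <- matrix(vars, nrow = nrow(z))
  ns <- as.vector(table(group)[lv])
  # pooled within-group variance; grand mean = mean of group means
  s2 <- as.vector(vars %*% (ns - 1L)) / sum(ns - 1L)
  mu <- rowMeans(means)
  degenerate <- mu == 0
  # moment estimate kept signed until the very end: truncating before the
  # trend fit would bias the trend upward for genes at or near Poisson
  mom <- ifelse(degenerate, 0, (s2 - mu) / mu^2)
  alpha_raw <- pmax(0, mom)

  alpha <- alpha_raw
  ok <- !degenerate
  if (shrink && sum(ok) >= 20L) {
    # arithmetic-scale trend: the raw MoM estimate is roughly unbiased but
    # extremely noisy at n = 3, so a 50/50 blend with the fitted trend keeps
    # per-gene signal without letting chance zeros wipe out the variance
    fit <- stats::lowess(log(mu[ok]), mom[ok], f = 0.5)
    trend <- stats::approx(fit$x, fit$y, xout = log(mu[ok]),
                           rule = 2, ties = mean)$y
    alpha[ok] <- pmax(0.5 * mom[ok] + 0.5 * pmax(trend, 0), 0)
  }
  data.frame(gene_id = rownames(counts), alpha = alpha,
             alpha_raw = alpha_raw, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

as_gene_matrix <- function(x) {
  if (inherits(x, "expr_matrix")) x <- x$values
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  x
}

#' Negative-binomial Wald test between two sample groups
#'
#' Per gene, compares the normalized group means with a Wald statistic on the
#' log-mean difference. Under `Var(K) = mu + alpha * mu^2`, the delta-method
#' variance of the log of a group mean over n replicates is
#' `(1/mu + alpha) / n`; the two group variances add, the statistic is
#' referred to a standard normal and the two-sided p-value is
#' Benjamini-Hochberg adjusted within the table. Genes with zero counts in
#' both groups get `p = 1` and direction `none`.
#'
#' @param x Raw-count gene-level [expr_matrix()] or matrix.
#' @param group_a,group_b Disjoint, non-empty character vectors of sample ids
#'   (>= 2 each). `log2fc` and `direction` refer to a over b.
#' @param size_factors Per-sample size factors for all samples in `x`
#'   (default: cpm factors computed from `x` itself).
#' @param dispersion Optional data frame from [estimate_dispersion()]
#'   (matched by `gene_id`); by default estimated from these two groups.
#' @param alpha Significance level used only to label `direction`
#'   (default 0.05, on the adjusted q-value).
#' @param pseudocount Pseudocount for the reported fold change.
#' @return Data frame with class `de_result`: `gene_id`, `mean_a`, `mean_b`,
#'   `log2fc`, `p_value`, `q_value`, `direction` (`up`/`down`/`none`).
#' @export
test_two_groups <- function(x, group_a, group_b, size_factors = NULL,
                            dispersion = NULL, alpha = 0.05,
                            pseudocount = 0.5) {
  values <- as_gene_matrix(x)
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs >= 2 replicates")
  missing_s <- setdiff(c(group_a, group_b), colnames(values))
  if (length(missing_s))
    stop("samples not in matrix: ", paste(missing_s, collapse = ", "))
  if (is.null(size_factors)) {
    size_factors <- size_factors(values, "cpm")
  }
  if (is.null(names(size_factors))) {
    if (length(size_factors) != ncol(values))
      stop("'size_factors' must be named or cover every sample in 'x'")
    names(size_factors) <- colnames(values)
  }
  sf <- size_factors[c(group_a, group_b)]
  sub <- values[, c(group_a, group_b), drop = FALSE]
  grp <- rep(c("a", "b"), c(length(group_a), length(group_b)))
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(sub, grp, size_factors = sf)
  }
  alph <- dispersion$alpha[match(rownames(values), dispersion$gene_id)]
  alph[is.na(alph)] <- 0

  z <- sweep(sub, 2L, sf, "/")
  mean_a <- rowMeans(z[, grp == "a", drop = FALSE])
  mean_b <- rowMeans(z[, grp == "b", drop = FALSE])
  na <- sum(grp == "a"); nb <- sum(grp == "b")

  l2fc <- fold_change(mean_a, mean_b, pseudocount)$log2fc
  # variance floor via pseudocount so zero means do not zero the SE out
  va <- (1 / pmax(mean_a, pseudocount) + alph) / na
  vb <- (1 / pmax(mean_b, pseudocount) + alph) / nb
  w <- (log(mean_a + pseudocount) - log(mean_b + pseudocount)) / sqrt(va + vb)
  p <- 2 * stats::pnorm(-abs(w))
  p[mean_a == 0 & mean_b == 0] <- 1
  p <- pmin(p, 1)
  q <- adjust_fdr(p)

  direction <- rep("none", length(p))
  direction[q < alpha & l2fc > 0] <- "up"
  direction[q < alpha & l2fc < 0] <- "down"
  res <- data.frame(gene_id = rownames(values), mean_a = mean_a,
                    mean_b = mean_b, log2fc = l2fc, p_value = p,
                    q_value = q, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; order-preserving, `q >= p`, `q` in `[0, 1]`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
adjust_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Write a differential-expression table
#' @param de A `de_result` from [test_two_groups()].
#' @param path Output TSV path.
#' @export
write_de_table <- function(de, path) {
  write_tsv_strict(as.data.frame(de), path)
  invisible(path)
}
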