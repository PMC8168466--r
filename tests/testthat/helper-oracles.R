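# Independent brute-force oracles, deliberately coded apart from the package's
# computation paths.

# Partial correlation: explicit normal-equations regression of x and y on the
# controls (intercept included), then the textbook Pearson formula on the two
# residual vectors.
oracle_pcor <- function(x, y, D = NULL) {
  n <- length(x)
  X <- cbind(rep(1, n))
  if (!is.null(D)) X <- cbind(X, t(rbind(D)))
  XtX <- t(X) %*% X
  rx <- x - X %*% solve(XtX, t(X) %*% x)
  ry <- y - X %*% solve(XtX, t(X) %*% y)
  oracle_pearson(as.vector(rx), as.vector(ry))
}

# Textbook Pearson correlation written out longhand.
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  den <- sqrt(sum((a - ma)^2)) * sqrt(sum((b - mb)^2))
  num / den
}

# Benjamini-Hochberg step-up, naive per-element definition:
# q_i = min(1, min over j with p_j >= p_i of m * p_j / rank(p_j)),
# with maximal ranks for ties.
oracle_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    ranks <- vapply(cand, function(pj) sum(p <= pj), numeric(1))
    min(1, min(m * cand / ranks))
  }, numeric(1))
}

# Student-t two-sided tail probability through the incomplete-beta identity,
# independent of stats::pt's use inside the package.
oracle_t_pvalue <- function(t, df) {
  x <- df / (df + t^2)
  stats::pbeta(x, df / 2, 0.5)
}
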