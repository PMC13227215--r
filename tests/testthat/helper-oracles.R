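# Independent brute-force oracles used across test files. These stay
# deliberately naive (loops, closed forms) so they check the package's
# vectorized implementations from a different direction.

# median-of-ratios size factors, plain loops, rescaled to geomean 1
oracleSizeFactors <- function(k) {
  ref <- which(apply(k, 1, function(r) all(r > 0)))
  geo <- vapply(ref, function(g) prod(k[g, ])^(1 / ncol(k)), 1.0)
  s <- vapply(seq_len(ncol(k)), function(j)
    median(k[ref, j] / geo), 1.0)
  s / prod(s)^(1 / length(s))
}

# weighted least squares by explicit normal equations
oracleWLS <- function(X, y, w) {
  XtWX <- t(X) %*% diag(w) %*% X
  V <- solve(XtWX)
  beta <- V %*% t(X) %*% diag(w) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  list(beta = drop(beta), V = V,
       sigma = sqrt(sum(w * res^2) / df), df = df)
}

# per-pair leading-logFC distance, naive sort-and-average
oracleLeadingDist <- function(expr, top) {
  n <- ncol(expr)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dif <- sort(abs(expr[, i] - expr[, j]), decreasing = TRUE)[seq_len(top)]
    d[i, j] <- sqrt(mean(dif^2))
  }
  d
}

# Procrustes RMS after optimal rotation/reflection/translation
procrustesRMS <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  sv <- svd(t(B) %*% A)
  R <- sv$u %*% t(sv$v)
  sc <- sum(sv$d) / sum(B^2)
  sqrt(mean((A - sc * B %*% R)^2))
}

# naive average-linkage agglomeration on a distance matrix, returning
# the sorted vector of merge heights
oracleAvgLinkHeights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# chi-square statistic of a 2x2 table, sum((O-E)^2/E), no correction
oracleChi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# a small NB count matrix with a fixed dispersion trend and no effects
nbNullCounts <- function(nGenes, nSamples, logMeanRange = c(1, 10),
                         a0 = 0.05, a1 = 2, seed = 1) {
  set.seed(seed)
  mu <- 2^runif(nGenes, logMeanRange[1], logMeanRange[2])
  alpha <- a0 + a1 / mu
  matrix(rnbinom(nGenes * nSamples, mu = mu, size = rep(1 / alpha, nSamples)),
         nGenes, nSamples,
         dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                         sprintf("s%03d", seq_len(nSamples))))
}
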