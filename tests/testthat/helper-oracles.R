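# Independent oracles, coded as plainly as possible so they stay
# structurally different from the package implementations.

# brute-force AUC: enumerate all presence x absence pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# textbook weighted kappa via explicit double loops
oracle_kappa <- function(m, weighting = "none") {
  k <- nrow(m) - 1
  p <- m / sum(m)
  ri <- unname(rowSums(p)); cj <- unname(colSums(p))
  po <- 0; pe <- 0
  for (i in 0:k) for (j in 0:k) {
    w <- switch(weighting,
                none = as.numeric(i == j),
                linear = 1 - abs(i - j) / k,
                quadratic = 1 - (i - j)^2 / k^2)
    po <- po + w * p[i + 1, j + 1]
    pe <- pe + w * ri[i + 1] * cj[j + 1]
  }
  (po - pe) / (1 - pe)
}

# Pearson chi-square by direct observed/expected arithmetic
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# brute-force quarter precipitation: scan all 12 wraparound windows
oracle_wettest_quarter <- function(prec) {
  best <- -Inf
  for (s in 1:12) {
    idx <- ((s - 1):(s + 1)) %% 12 + 1
    best <- max(best, sum(prec[idx]))
  }
  best
}

# brute-force nearest predicted-cell-center distance
oracle_nearest_distance <- function(point, surface) {
  g <- surface$consensus
  nr <- nrow(g$values); s <- g$cell_size
  best <- Inf
  for (r in seq_len(nr)) for (c in seq_len(ncol(g$values))) {
    v <- g$values[r, c]
    if (is.na(v) || v < 1) next
    cx <- g$origin[1] + (c - 0.5) * s
    cy <- g$origin[2] + (nr - r + 0.5) * s
    best <- min(best, sqrt((cx - point[1])^2 + (cy - point[2])^2))
  }
  best
}

# one-predictor logistic regression by hand-rolled IRLS
oracle_irls_logistic <- function(x, y, iters = 50) {
  b <- c(0, 0)
  X <- cbind(1, x)
  for (i in seq_len(iters)) {
    eta <- X %*% b
    mu <- 1 / (1 + exp(-eta))
    w <- as.vector(mu * (1 - mu))
    z <- eta + (y - mu) / pmax(w, 1e-12)
    b <- solve(crossprod(X, w * X), crossprod(X, w * z))
  }
  as.vector(b)
}
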