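# Minimal multivariate adaptive regression splines learner.
#
# Forward stepwise selection of mirrored hinge pairs max(0, x - k) /
# max(0, k - x) with knots at marginal quantiles, greedily adding the basis
# function giving the largest squared-error reduction (computed against the
# current orthonormalized basis, so each step is one matrix product), then
# backward pruning by the classical GCV criterion with the conventional
# penalty of 3 effective parameters per basis function. Final coefficients
# are refit through a binomial-link GLM on the pruned basis so scores land
# in (0, 1).

.mars_basis <- function(X, knots_per_var = 5L) {
  cols <- list(); info <- list()
  for (j in seq_len(ncol(X))) {
    ks <- unique(stats::quantile(X[, j], probs = seq_len(knots_per_var) /
                                   (knots_per_var + 1), names = FALSE))
    for (k in ks) {
      cols[[length(cols) + 1L]] <- pmax(0, X[, j] - k)
      info[[length(info) + 1L]] <- c(var = j, knot = k, dir = 1)
      cols[[length(cols) + 1L]] <- pmax(0, k - X[, j])
      info[[length(info) + 1L]] <- c(var = j, knot = k, dir = -1)
    }
  }
  list(B = do.call(cbind, cols), info = info)
}

.mars_gcv <- function(rss, n, nterms, penalty = 3) {
  eff <- 1 + penalty * nterms          # intercept + penalized basis terms
  rss / (n * (1 - min(eff, n - 1) / n)^2)
}

mars_fit <- function(X, y, max_terms = 21L, knots_per_var = 5L, penalty = 3) {
  X <- as.matrix(X); n <- nrow(X)
  cand <- .mars_basis(X, knots_per_var)
  B <- cand$B
  keep <- apply(B, 2L, stats::sd) > 0
  B <- B[, keep, drop = FALSE]; info <- cand$info[keep]
  # standardize candidates for numerically stable Gram-Schmidt
  Bs <- scale(B)
  yc <- y - mean(y)
  Q <- NULL                 # orthonormal basis of selected columns
  sel <- integer()
  rss <- sum(yc^2)
  gcv <- .mars_gcv(rss, n, 0L, penalty)
  res <- yc
  for (step in seq_len(min(max_terms, ncol(Bs)))) {
    R <- Bs
    if (!is.null(Q)) R <- Bs - Q %*% (crossprod(Q, Bs))
    nrm2 <- colSums(R^2)
    score <- drop(crossprod(R, res))^2 / pmax(nrm2, 1e-10)
    score[nrm2 < 1e-8] <- -Inf
    score[sel] <- -Inf
    best <- which.max(score)
    if (!is.finite(score[best]) || score[best] <= 0) break
    new_rss <- rss - score[best]
    new_gcv <- .mars_gcv(new_rss, n, length(sel) + 1L, penalty)
    q <- R[, best] / sqrt(nrm2[best])
    Q <- cbind(Q, q)
    res <- res - q * drop(crossprod(q, res))
    sel <- c(sel, best)
    rss <- new_rss
    gcv <- new_gcv
  }
  if (!length(sel)) stop("MARS: no informative basis function found")
  # backward pruning by GCV on exact least-squares refits
  current <- sel
  best_set <- current
  best_gcv <- .mars_rss_gcv(Bs, yc, current, n, penalty)
  while (length(current) > 1L) {
    gcvs <- vapply(seq_along(current), function(i)
      .mars_rss_gcv(Bs, yc, current[-i], n, penalty), 0.0)
    i <- which.min(gcvs)
    current <- current[-i]
    if (gcvs[i] <= best_gcv) { best_gcv <- gcvs[i]; best_set <- current }
  }
  sel <- best_set
  dat <- data.frame(y = y, Bs[, sel, drop = FALSE])
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat,
                                     family = stats::binomial()))
  structure(list(info = info[sel],
                 center = attr(Bs, "scaled:center")[sel],
                 scl = attr(Bs, "scaled:scale")[sel],
                 glm = fit, nvars = ncol(X),
                 varnames = colnames(X)), class = "sdm_mars")
}

.mars_rss_gcv <- function(Bs, yc, idx, n, penalty) {
  if (!length(idx)) return(.mars_gcv(sum(yc^2), n, 0L, penalty))
  f <- stats::lm.fit(cbind(1, Bs[, idx, drop = FALSE]), yc)
  .mars_gcv(sum(f$residuals^2), n, length(idx), penalty)
}

predict.sdm_mars <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$varnames, drop = FALSE])
  B <- vapply(seq_along(object$info), function(i) {
    inf <- object$info[[i]]
    raw <- if (inf["dir"] > 0) pmax(0, X[, inf["var"]] - inf["knot"]) else
      pmax(0, inf["knot"] - X[, inf["var"]])
    (raw - object$center[i]) / object$scl[i]
  }, numeric(nrow(X)))
  B <- matrix(B, nrow = nrow(X))
  colnames(B) <- names(stats::coef(object$glm))[-1]
  dat <- as.data.frame(B)
  as.numeric(stats::predict(object$glm, newdata = dat, type = "response"))
}
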