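#' Stack binary SDM maps into a consensus surface
#'
#' The consensus score of a cell is the number of algorithms (0-5) whose
#' dichotomized prediction marks it suitable. A cell is nodata if any input
#' map is nodata there.
#'
#' @param binaries list of 1-5 congruent 0/1 `sdm_grid`s.
#' @return object of class `ensemble_surface`: fields `consensus` (integer
#'   grid), `binaries`, `k`.
#' @export
stack_consensus <- function(binaries) {
  if (!length(binaries) || length(binaries) > 5L)
    stop("between 1 and 5 binary grids required")
  if (is.null(names(binaries)))
    names(binaries) <- paste0("m", seq_along(binaries))
  viol <- congruence_check(structure(binaries, class = "layer_stack"))
  viol <- viol[viol$kind != "nodata_mask", , drop = FALSE]
  if (nrow(viol)) stop("incongruent binary grids")
  for (nm in names(binaries)) {
    v <- binaries[[nm]]$values
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop("non-binary values in grid ", nm)
  }
  ref <- binaries[[1]]
  tot <- Reduce(`+`, lapply(binaries, function(g) g$values))
  structure(list(consensus = raster_grid(tot, ref$cell_size, ref$origin),
                 binaries = binaries, k = length(binaries)),
            class = "ensemble_surface")
}

#' @export
print.ensemble_surface <- function(x, ...) {
  cat(sprintf("<ensemble_surface> k = %d models\n", x$k))
  print(area_by_consensus(x))
  invisible(x)
}

#' Suitable area by consensus score
#'
#' @param surface an `ensemble_surface`.
#' @return data.frame with `score` (0..k), `area_sqkm`, `percent` of the
#'   non-nodata area; percents sum to 100.
#' @export
area_by_consensus <- function(surface) {
  g <- surface$consensus
  cell_sqkm <- g$cell_size^2 / 1e6
  counts <- vapply(0:surface$k, function(sc)
    sum(g$values == sc, na.rm = TRUE), 0L)
  area <- counts * cell_sqkm
  data.frame(score = 0:surface$k, area_sqkm = area,
             percent = 100 * area / sum(area))
}

#' Construct an agreement table from a cell matrix
#'
#' Rows index the consensus score of method B (conventionally the
#' convenience-sample map), columns that of method A (the standard-survey
#' map); entries are areas in sq km.
#'
#' @param cells nonnegative (k+1)x(k+1) matrix of areas.
#' @param unit area unit label (informational).
#' @return object of class `agreement_table` (the matrix, with dimnames
#'   `0..k` and a `unit` attribute).
#' @export
agreement_table <- function(cells, unit = "sqkm") {
  cells <- as.matrix(cells)
  if (nrow(cells) != ncol(cells)) stop("agreement table must be square")
  if (any(cells < 0)) stop("negative cell area")
  k <- nrow(cells) - 1L
  dimnames(cells) <- list(convenience = 0:k, standard = 0:k)
  structure(cells, unit = unit, class = c("agreement_table", "matrix"))
}

#' Cross-tabulate two consensus surfaces by area
#'
#' `cells[b, a]` is the total area where surface B scores `b` and surface A
#' scores `a`; cells nodata in either surface are excluded.
#'
#' @param surface_a,surface_b congruent `ensemble_surface`s (A = standard in
#'   the columns, B = convenience in the rows).
#' @return an [agreement_table()] in sq km.
#' @export
cross_tabulate <- function(surface_a, surface_b) {
  ga <- surface_a$consensus; gb <- surface_b$consensus
  if (!identical(dim(ga$values), dim(gb$values)) ||
      !isTRUE(all.equal(ga$cell_size, gb$cell_size)) ||
      !isTRUE(all.equal(ga$origin, gb$origin)))
    stop("incongruent surfaces")
  k <- max(surface_a$k, surface_b$k)
  ok <- !is.na(ga$values) & !is.na(gb$values)
  counts <- table(factor(gb$values[ok], levels = 0:k),
                  factor(ga$values[ok], levels = 0:k))
  agreement_table(unclass(counts) * ga$cell_size^2 / 1e6)
}

.kappa_weights <- function(k, weighting) {
  i <- matrix(0:k, k + 1L, k + 1L)
  j <- t(i)
  switch(weighting,
         none = (i == j) * 1.0,
         linear = 1 - abs(i - j) / k,
         quadratic = 1 - (i - j)^2 / k^2,
         stop("unknown weighting: ", weighting))
}

#' Cohen's kappa from an agreement table
#'
#' With cell proportions `p_ij`, observed weighted agreement
#' `Po = sum(w_ij p_ij)` and chance agreement `Pe = sum(w_ij p_i. p_.j)`,
#' kappa = (Po - Pe) / (1 - Pe). Weights: `none` is the identity (plain
#' Cohen's kappa), `linear` is `1 - |i-j|/k`, `quadratic` is
#' `1 - (i-j)^2/k^2`. Kappa is invariant to rescaling all cells, so areas
#' and proportions give the same value.
#'
#' @param table an [agreement_table()] (or plain square matrix).
#' @param weighting `"none"`, `"linear"`, or `"quadratic"`.
#' @return list with `kappa`, `po`, `pe`, `weighting`.
#' @export
cohen_kappa <- function(table, weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  m <- unclass(as.matrix(table))
  if (sum(m) <= 0) stop("empty agreement table")
  p <- m / sum(m)
  k <- nrow(p) - 1L
  w <- .kappa_weights(k, weighting)
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (isTRUE(all.equal(pe, 1)))
    stop("degenerate table: chance agreement equals 1")
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, weighting = weighting)
}

#' Large-sample (Fleiss-Cohen-Everitt) standard error of weighted kappa
#'
#' Evaluates the classical asymptotic variance of the estimated (weighted)
#' kappa on the table's cell proportions, with the supplied number of
#' independently classified units as the divisor. For map comparison the
#' units are pixels; pixel-level independence is an assumption the caller
#' accepts (a caveat, since neighboring cells are spatially correlated).
#'
#' @inheritParams cohen_kappa
#' @param n_units number of classified units (e.g. pixel count), > 0.
#' @return list with `se` and `ci95 = kappa +/- 1.96 se`.
#' @export
kappa_se_fleiss <- function(table, weighting = c("none", "linear", "quadratic"),
                            n_units) {
  weighting <- match.arg(weighting)
  if (!(is.numeric(n_units) && length(n_units) == 1L && n_units > 0))
    stop("n_units must be a positive number")
  m <- unclass(as.matrix(table))
  p <- m / sum(m)
  k <- nrow(p) - 1L
  w <- .kappa_weights(k, weighting)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi_, pj_))
  kap <- (po - pe) / (1 - pe)
  wbar_i <- as.vector(w %*% pj_)     # expected weight given row i
  wbar_j <- as.vector(pi_ %*% w)     # expected weight given column j
  term <- (w * (1 - pe) - outer(wbar_i, rep(1, k + 1L)) * (1 - po) -
             outer(rep(1, k + 1L), wbar_j) * (1 - po))^2
  var_hat <- (sum(p * term) - (po * pe - 2 * pe + po)^2) /
    (n_units * (1 - pe)^4)
  se <- sqrt(max(var_hat, 0))
  list(se = se, ci95 = c(kap - 1.96 * se, kap + 1.96 * se))
}

#' Landis-Koch style interpretation of kappa
#'
#' Below 0: no agreement; 0 to 0.20 (inclusive): slight; above 0.20 to 0.40:
#' fair; above 0.40: moderate or better.
#'
#' @param kappa kappa value (<= 1).
#' @return character label.
#' @export
interpret_kappa <- function(kappa) {
  if (kappa > 1) stop("kappa cannot exceed 1")
  if (kappa < 0) "no agreement"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else "moderate or better"
}

#' Full kappa estimate with SE, CI and label
#'
#' @inheritParams kappa_se_fleiss
#' @return list of class `kappa_estimate`: `kappa`, `weighting`,
#'   `standard_error`, `ci95`, `n_units`, `label`.
#' @export
kappa_estimate <- function(table, weighting = c("none", "linear", "quadratic"),
                           n_units) {
  weighting <- match.arg(weighting)
  pt <- cohen_kappa(table, weighting)
  se <- kappa_se_fleiss(table, weighting, n_units)
  structure(list(kappa = pt$kappa, weighting = weighting,
                 standard_error = se$se, ci95 = se$ci95, n_units = n_units,
                 label = interpret_kappa(pt$kappa)),
            class = "kappa_estimate")
}

#' @export
print.kappa_estimate <- function(x, ...) {
  cat(sprintf("kappa (%s) = %.4f, SE = %.4f, 95%% CI [%.4f, %.4f] -- %s\n",
              x$weighting, x$kappa, x$standard_error, x$ci95[1], x$ci95[2],
              x$label))
  invisible(x)
}

#' Proportion of positive points by consensus score
#'
#' For each consensus score 0..k, the fraction of all points falling on
#' cells of that score whose status is `presence` (denominators include
#' absence and background records). Points on nodata cells are dropped with
#' a message.
#'
#' @param points an [occurrence_set()].
#' @param surface an `ensemble_surface`.
#' @return data.frame with `score`, `n_points`, `n_positive`, `proportion`.
#' @export
proportion_positive_by_score <- function(points, surface) {
  sc <- extract_at(surface$consensus, points$x, points$y)
  drop <- is.na(sc)
  if (any(drop))
    message(sum(drop), " point(s) on nodata cells or outside the extent dropped")
  sc <- sc[!drop]
  pos <- points$status[!drop] == "presence"
  out <- data.frame(score = 0:surface$k)
  out$n_points <- vapply(out$score, function(s) sum(sc == s), 0L)
  out$n_positive <- vapply(out$score, function(s) sum(pos[sc == s]), 0L)
  out$proportion <- ifelse(out$n_points > 0, out$n_positive / out$n_points,
                           NA_real_)
  out
}

#' Pearson chi-square association test
#'
#' Thin wrapper over the classical Pearson X^2 = sum (O-E)^2/E with
#' df = (rows-1)(cols-1); no continuity correction.
#'
#' @param counts matrix of nonnegative counts.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_association <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ct$expected <= 0)) stop("expected counts must be positive")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
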