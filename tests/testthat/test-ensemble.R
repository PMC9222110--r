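# helpers ----------------------------------------------------------------

bin_grid <- function(m, cs = 100) raster_grid(m, cs)

# build an ensemble surface directly from 0/1 matrices
surface_from <- function(..., cs = 100) {
  stack_consensus(lapply(list(...), bin_grid, cs = cs))
}

# an ensemble surface whose consensus equals a given integer matrix
surface_with_consensus <- function(cons, cs = 100) {
  k <- 5L
  mats <- lapply(seq_len(k), function(i) (cons >= i) * 1.0)
  surface_from_list(mats, cs)
}
surface_from_list <- function(mats, cs = 100) {
  stack_consensus(lapply(mats, bin_grid, cs = cs))
}

test_that("consensus is the cell-wise sum of binary maps, with nodata contagion", {
  ones <- matrix(1, 2, 2); zeros <- matrix(0, 2, 2)
  expect_true(all(surface_from(ones, ones, ones, ones, ones)$consensus$values == 5))
  expect_true(all(surface_from(zeros, zeros, zeros, zeros, zeros)$consensus$values == 0))
  a <- matrix(c(1, 0, 1, 0), 2, 2); b <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(surface_from(a, b)$consensus$values, a + b)
  withna <- a; withna[1, 1] <- NA
  expect_true(is.na(surface_from(withna, b)$consensus$values[1, 1]))
  expect_error(surface_from(matrix(2, 2, 2)), "non-binary")
})

test_that("areas by consensus score count cells at the 1-ha convention", {
  cons <- matrix(0L, 10, 10); cons[1:25] <- 5L
  s <- surface_with_consensus(cons)
  tab <- area_by_consensus(s)
  expect_equal(tab$area_sqkm[tab$score == 5], 0.25)
  expect_equal(tab$percent[tab$score == 5], 25)
  expect_equal(sum(tab$percent), 100)
  uni <- surface_with_consensus(matrix(3L, 4, 4))
  expect_equal(area_by_consensus(uni)$percent[4], 100)
})

test_that("cross-tabulation matches exhaustive cell-by-cell counting", {
  set.seed(71)
  ca <- matrix(sample(0:5, 9, TRUE), 3, 3)
  cb <- matrix(sample(0:5, 9, TRUE), 3, 3)
  sa <- surface_with_consensus(ca); sb <- surface_with_consensus(cb)
  tab <- cross_tabulate(sa, sb)
  for (i in 0:5) for (j in 0:5)
    expect_equal(tab[i + 1, j + 1], sum(cb == i & ca == j) * 0.01)
  # identical surfaces give a strictly diagonal table
  d <- cross_tabulate(sa, sa)
  expect_equal(sum(d) - sum(diag(d)), 0)
  # all-0 vs all-5 concentrates in one off-diagonal cell
  z <- surface_with_consensus(matrix(0L, 3, 3))
  f <- surface_with_consensus(matrix(5L, 3, 3))
  t2 <- cross_tabulate(z, f)
  expect_equal(t2[6, 1], 0.09)
  expect_equal(sum(t2), 0.09)
  # marginals equal the per-surface area tables
  expect_equal(unname(colSums(tab)), area_by_consensus(sa)$area_sqkm)
  expect_equal(unname(rowSums(tab)), area_by_consensus(sb)$area_sqkm)
})

test_that("kappa has its textbook fixed points", {
  d <- agreement_table(diag(c(5, 3, 9, 1, 2, 7)))
  for (w in c("none", "linear", "quadratic"))
    expect_equal(cohen_kappa(d, w)$kappa, 1)
  # rank-one table (cells = outer product of marginals): Po = Pe, kappa = 0
  r <- c(0.3, 0.1, 0.2, 0.15, 0.05, 0.2); cj <- c(0.25, 0.25, 0.1, 0.1, 0.1, 0.2)
  expect_equal(cohen_kappa(agreement_table(outer(r, cj)), "none")$kappa, 0)
  expect_error(cohen_kappa(agreement_table(matrix(0, 6, 6))), "empty")
  one_cat <- matrix(0, 6, 6); one_cat[1, 1] <- 10
  expect_error(cohen_kappa(agreement_table(one_cat)), "degenerate")
})

test_that("kappa agrees with an independent double-loop oracle and is scale-free", {
  t3 <- load_agreement_fixture("table3")
  t4 <- load_agreement_fixture("table4")
  for (w in c("none", "linear", "quadratic")) {
    expect_equal(cohen_kappa(t3, w)$kappa, oracle_kappa(unclass(t3), w))
    expect_equal(cohen_kappa(t4, w)$kappa, oracle_kappa(unclass(t4), w))
    scaled <- agreement_table(unclass(t3) * 137.5)
    expect_equal(cohen_kappa(scaled, w)$kappa, cohen_kappa(t3, w)$kappa)
  }
})

test_that("all weightings coincide on a 2-category table", {
  m <- agreement_table(matrix(c(30, 10, 5, 55), 2, 2))
  ks <- vapply(c("none", "linear", "quadratic"),
               function(w) cohen_kappa(m, w)$kappa, 0.0)
  expect_equal(unname(ks[2]), unname(ks[1]))
  expect_equal(unname(ks[3]), unname(ks[1]))
})

test_that("Fleiss standard errors scale as 1/sqrt(n) and match the bootstrap", {
  m <- agreement_table(matrix(c(45, 10, 5,
                                8, 60, 12,
                                4, 14, 42), 3, 3, byrow = TRUE))
  s1 <- kappa_se_fleiss(m, "none", n_units = 200)
  s2 <- kappa_se_fleiss(m, "none", n_units = 400)
  expect_equal(s1$se / sqrt(2), s2$se)
  # ci95 arithmetic
  k <- cohen_kappa(m, "none")$kappa
  expect_equal(s1$ci95, c(k - 1.96 * s1$se, k + 1.96 * s1$se))

  # multinomial bootstrap oracle, both weightings
  p <- unclass(m) / sum(m)
  set.seed(81)
  for (w in c("none", "linear")) {
    boot <- replicate(2000, {
      draw <- matrix(stats::rmultinom(1, 200, as.vector(p)), 3, 3)
      if (sum(diag(draw)) == 200) NA_real_ else
        cohen_kappa(agreement_table(draw), w)$kappa
    })
    se_boot <- stats::sd(boot, na.rm = TRUE)
    se_an <- kappa_se_fleiss(m, w, n_units = 200)$se
    expect_lt(abs(se_an - se_boot) / se_boot, 0.15)
  }
})

test_that("agreement labels follow the published thresholds", {
  expect_equal(interpret_kappa(-0.1), "no agreement")
  expect_equal(interpret_kappa(0), "slight")
  expect_equal(interpret_kappa(0.060), "slight")
  expect_equal(interpret_kappa(0.20), "slight")
  expect_equal(interpret_kappa(0.35), "fair")
  expect_equal(interpret_kappa(0.40), "fair")
  expect_equal(interpret_kappa(0.41), "moderate or better")
  expect_error(interpret_kappa(1.2), "exceed")
})

test_that("proportion positive by score counts hand-checkable configurations", {
  cons <- matrix(rep(0:5, each = 2), 2, 6)   # columns scored 0..5
  s <- surface_with_consensus(cons)
  cen_x <- (seq_len(6) - 0.5) * 100
  # 12 points: one presence and one background per score column
  occ <- occurrence_set(data.frame(
    id = as.character(1:12),
    x = rep(cen_x, each = 2),
    y = rep(c(150, 50), 6),
    species = "t",
    status = rep(c("presence", "background"), 6),
    source = "convenience", year = 2000))
  pp <- proportion_positive_by_score(occ, s)
  expect_equal(pp$n_points, rep(2L, 6))
  expect_equal(pp$proportion, rep(0.5, 6))

  # all presences on score 5, all background on score 0
  occ2 <- occurrence_set(data.frame(
    id = as.character(1:4),
    x = c(550, 550, 50, 50), y = c(150, 50, 150, 50),
    species = "t",
    status = c("presence", "presence", "background", "background"),
    source = "convenience", year = 2000))
  pp2 <- proportion_positive_by_score(occ2, s)
  expect_equal(pp2$proportion[c(1, 6)], c(0, 1))
})

test_that("proportion positive rises with consensus when suitability drives both", {
  for (s in 1:5) {
    sc <- sdm_scenario(seed = 200 + s, shape = c(80, 80), convenience_n = 2000,
                       bias_strength = 0, positional_error_mean = 0,
                       positional_error_max = 0)
    st <- simulate_environment(sc)
    # consensus surface built from suitability itself: score = how many of 5
    # fixed thresholds the cell clears, a monotone transform of suitability
    qs <- stats::quantile(st$suitability$values, seq(0.15, 0.95, length.out = 5))
    mats <- lapply(qs, function(q) (st$suitability$values >= q) * 1.0)
    surf <- surface_from_list(mats)
    pres <- simulate_convenience_sample(st, sc)
    bkg <- sample_background(st$stack, pres, ratio = 2, seed = s)
    common <- c("id", "x", "y", "species", "status", "source", "year")
    occ <- occurrence_set(rbind(as.data.frame(pres)[common],
                                as.data.frame(bkg)[common]))
    pp <- proportion_positive_by_score(occ, surf)
    expect_true(all(diff(pp$proportion) >= 0),
                info = paste("seed", 200 + s))
  }
})

test_that("chi-square association reproduces hand arithmetic", {
  m <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  res <- chi_square_association(m)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$statistic, oracle_chisq(m))
  expect_equal(res$df, 1)
  four_by_two <- matrix(c(5, 15, 10, 10, 8, 12, 2, 18), 4, 2, byrow = TRUE)
  expect_equal(chi_square_association(four_by_two)$df, 3)
  prop <- matrix(c(10, 20, 20, 40), 2, 2, byrow = TRUE)
  expect_equal(chi_square_association(prop)$statistic, 0)
  expect_error(chi_square_association(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})

test_that("shuffling one surface pushes kappa into its own confidence band at 0", {
  covered <- 0L
  for (s in 1:5) {
    set.seed(300 + s)
    ca <- matrix(sample(0:5, 900, TRUE, prob = c(0.3, 0.2, 0.15, 0.15, 0.1, 0.1)),
                 30, 30)
    cb <- matrix(sample(as.vector(ca)), 30, 30)   # paired structure destroyed
    tab <- cross_tabulate(surface_with_consensus(ca), surface_with_consensus(cb))
    est <- kappa_estimate(tab, "none", n_units = 900)
    if (est$ci95[1] <= 0 && 0 <= est$ci95[2]) covered <- covered + 1L
  }
  expect_gte(covered, 4L)
})
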