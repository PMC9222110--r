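# small helpers used across the engine tests -----------------------------

toy_stack <- function(seed = 1, n = 16) {
  set.seed(seed)
  layer_stack(p1 = raster_grid(matrix(rnorm(n), sqrt(n)), 100),
              p2 = raster_grid(matrix(rnorm(n), sqrt(n)), 100))
}

# a linearly separable table: label follows the sign of x1
separable_table <- function(n = 60, seed = 2) {
  set.seed(seed)
  x1 <- c(runif(n / 2, 1, 2), runif(n / 2, -2, -1))
  x2 <- rnorm(n)
  structure(data.frame(id = as.character(seq_len(n)),
                       label = rep(c(1L, 0L), each = n / 2),
                       x1 = x1, x2 = x2),
            class = c("training_table", "data.frame"))
}

test_that("training tables read the cell under each reported point", {
  stk <- toy_stack()
  g <- stk$p1
  cen <- cell_centers(g)
  occ <- occurrence_set(data.frame(
    id = c("a", "b", "c"),
    x = c(cen$x[2], cen$x[3], 1e6),          # last point outside the extent
    y = c(cen$y[1], cen$y[4], 0),
    species = "t", status = c("presence", "absence", "presence"),
    source = "standard", year = 2016))
  expect_message(tab <- build_training_table(stk, occ), "dropped")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$p1, c(g$values[1, 2], g$values[4, 3]))
  expect_equal(tab$label, c(1L, 0L))
  expect_equal(attr(tab, "n_dropped"), 1L)
})

test_that("single-class and empty tables are rejected", {
  stk <- toy_stack()
  cen <- cell_centers(stk$p1)
  occ <- occurrence_set(data.frame(id = "a", x = cen$x[1], y = cen$y[1],
                                   species = "t", status = "presence",
                                   source = "standard", year = 2016))
  expect_error(build_training_table(stk, occ), "single label class")
})

test_that("AUC matches brute-force pair enumeration, including ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(auc(c(0.9, 0.4, 0.35, 0.8), c(1, 0, 1, 0)),
               oracle_auc(c(0.9, 0.4, 0.35, 0.8), c(1, 0, 1, 0)))
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))      # both classes guaranteed
    scores <- round(runif(n), 2)                  # rounded -> frequent ties
    expect_equal(auc(scores, labels), oracle_auc(scores, labels))
  }
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("correlated-variable reduction follows the greedy rule", {
  set.seed(31)
  n <- 40
  a <- rnorm(n)
  y <- as.integer(a + rnorm(n, sd = 0.5) > 0)
  tab <- structure(data.frame(id = as.character(1:n), label = y,
                              a = a, b = 2 * a + 1, c = rnorm(n)),
                   class = c("training_table", "data.frame"))
  # cor(a, b) = 1, AUC(a) = AUC(b) (monotone transform) -> tie drops "b"
  expect_equal(reduce_variables(tab, 0.7), c("a", "c"))

  tab2 <- tab; tab2$b <- -a   # AUC(b) = 1 - AUC(a) < AUC(a): b loses outright
  expect_equal(reduce_variables(tab2, 0.7), c("a", "c"))

  # all pairwise |r| under the cutoff: identity
  set.seed(32)
  tab3 <- structure(data.frame(id = as.character(1:n), label = y,
                               u = rnorm(n), v = rnorm(n), w = rnorm(n)),
                    class = c("training_table", "data.frame"))
  expect_equal(reduce_variables(tab3, 0.7), c("u", "v", "w"))

  # constant predictors fall out first
  tab4 <- tab3; tab4$z <- 1
  expect_message(out <- reduce_variables(tab4, 0.7), "constant")
  expect_equal(out, c("u", "v", "w"))
})

test_that("stratified folds are deterministic, balanced, and class-complete", {
  y <- rep(c(1L, 0L), c(30, 70))
  f1 <- make_cv_folds(y, k = 10, seed = 3)
  f2 <- make_cv_folds(y, k = 10, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_cv_folds(y, k = 10, seed = 4)))
  expect_equal(sort(unique(f1)), 1:10)
  expect_equal(as.vector(table(f1[y == 1])), rep(3L, 10))
  expect_equal(as.vector(table(f1[y == 0])), rep(7L, 10))
  sizes <- table(f1)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(make_cv_folds(rep(c(1L, 0L), c(5, 95)), k = 10), "smaller k")
})

test_that("every algorithm separates the separable toy table", {
  tab <- separable_table()
  folds <- make_cv_folds(tab$label, k = 5, seed = 1)
  for (alg in c("LR", "BRT", "RF", "MARS", "MaxEnt")) {
    fit <- fit_sdm(alg, tab, c("x1", "x2"), folds,
                   hyperparameters = if (alg == "BRT") list(nrounds = 80) else list())
    train_scores <- fit$predictor(tab[, c("x1", "x2")])
    expect_equal(auc(train_scores, tab$label), 1, info = alg)
    # every fold separates perfectly; pooled scores from different folds may
    # interleave marginally for the boosted trees
    expect_equal(fit$cv_metrics$fold_auc, rep(1, 5), info = alg)
    expect_gte(fit$cv_metrics$pooled_auc, 0.99)
    expect_gt(fit$threshold, 0); expect_lt(fit$threshold, 1)
  }
})

test_that("permuted labels give near-chance held-out AUC for every algorithm", {
  set.seed(41)
  n <- 200
  tab <- structure(data.frame(id = as.character(1:n),
                              label = sample(rep(c(1L, 0L), each = n / 2)),
                              x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n)),
                   class = c("training_table", "data.frame"))
  folds <- make_cv_folds(tab$label, k = 5, seed = 2)
  hp <- list(BRT = list(nrounds = 60), MaxEnt = list(nfolds = 3),
             MARS = list(max_terms = 10, knots_per_var = 3))
  for (alg in c("LR", "BRT", "RF", "MARS", "MaxEnt")) {
    cv <- crossvalidate(alg, tab, c("x1", "x2", "x3"), folds,
                        hyperparameters = if (alg %in% names(hp)) hp[[alg]] else list())
    expect_gte(cv$pooled_auc, 0.35)
    expect_lte(cv$pooled_auc, 0.65)
  }
})

test_that("the LR adapter agrees with an independent IRLS fit to 6 decimals", {
  set.seed(51)
  n <- 80
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 + 1.2 * x))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  tab <- structure(data.frame(id = as.character(1:n), label = y, x = x,
                              dummy = rnorm(n)),
                   class = c("training_table", "data.frame"))
  folds <- make_cv_folds(tab$label, k = 4, seed = 1)
  fit <- fit_sdm("LR", tab, "x", folds)
  b <- oracle_irls_logistic(x, y)
  newx <- data.frame(x = c(-1, 0, 0.5, 2))
  expect_equal(fit$predictor(newx),
               as.vector(plogis(b[1] + b[2] * newx$x)),
               tolerance = 1e-6)
})

test_that("threshold selection balances sensitivity and specificity", {
  tau <- select_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(tau, 0.5)
  # complete overlap: both extreme candidates tie, higher sensitivity wins
  tau2 <- select_threshold(c(0.6, 0.6), c(1, 0))
  expect_lt(tau2, 0.6)
  # exhaustive-scan optimality on random inputs
  set.seed(61)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    scores <- round(runif(n), 2)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    tau <- select_threshold(scores, labels)
    d_at <- function(t) abs(mean(scores[labels == 1] >= t) -
                              mean(scores[labels == 0] < t))
    grid_t <- sort(unique(c(scores - 1e-6, scores + 1e-6, tau)))
    expect_lte(d_at(tau), min(vapply(grid_t, d_at, 0.0)) + 1e-12)
  }
})

test_that("surfaces honor the fitted score function and nodata cells", {
  tab <- separable_table()
  folds <- make_cv_folds(tab$label, k = 5, seed = 1)
  fit <- fit_sdm("LR", tab, c("x1", "x2"), folds)
  v1 <- matrix(c(1.5, -1.5, 0.3, NA), 2, 2)
  v2 <- matrix(c(0, 0, 0, 0), 2, 2)
  stk <- layer_stack(x1 = raster_grid(v1, 100), x2 = raster_grid(v2, 100))
  surf <- predict_surface(fit, stk)
  expect_true(is.na(surf$values[2, 2]))
  expect_equal(surf$values[1, 1],
               fit$predictor(data.frame(x1 = 1.5, x2 = 0)))
  # constant stack -> constant surface
  stc <- layer_stack(x1 = raster_grid(matrix(1, 3, 3), 100),
                     x2 = raster_grid(matrix(0, 3, 3), 100))
  sc <- predict_surface(fit, stc)
  expect_equal(max(sc$values) - min(sc$values), 0)
  expect_error(predict_surface(fit, layer_stack(x1 = stc$x1)), "x2")
})

test_that("fold assignments are shared verbatim across algorithms", {
  tab <- separable_table(n = 40, seed = 5)
  folds <- make_cv_folds(tab$label, k = 4, seed = 9)
  cvs <- lapply(c("LR", "RF"), function(a)
    crossvalidate(a, tab, c("x1", "x2"), folds))
  expect_identical(cvs[[1]]$folds, cvs[[2]]$folds)
  expect_identical(cvs[[1]]$folds, folds)
})

test_that("LR recovers the generating coefficient signs on unbiased synthetic data", {
  hits <- 0L
  for (s in 1:5) {
    sc <- sdm_scenario(seed = 100 + s, shape = c(50, 50), n_transects = 2000,
                       bias_strength = 0)
    st <- simulate_environment(sc)
    occ <- simulate_standard_survey(st, sc)
    tab <- build_training_table(st$stack, occ)
    folds <- make_cv_folds(tab$label, k = 4, seed = 1)
    fit <- fit_sdm("LR", tab, paste0("env", 1:4), folds)
    base <- data.frame(env1 = 0, env2 = 0, env3 = 0, env4 = 0)
    sign_of <- vapply(1:4, function(j) {
      up <- base; up[[j]] <- 1
      sign(fit$predictor(up) - fit$predictor(base))
    }, 0.0)
    truth <- sign(c(1.5, -1.0, 0.8, 0.5))
    if (all(sign_of == truth)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
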