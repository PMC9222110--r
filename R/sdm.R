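#' Build a model training table from a stack and occurrence records
#'
#' One row per record: label 1 for presences, 0 for absences/background, plus
#' the predictor values read from the cell containing the *reported*
#' coordinates (half-open cell convention, see [locate_cells()]). Records
#' outside the extent or on nodata cells are dropped with a message.
#'
#' @param stack a `layer_stack` of predictor grids.
#' @param occurrences an [occurrence_set()].
#' @return data.frame of class `training_table` with columns `id`, `label`
#'   and one column per layer; attributes `provenance` and `n_dropped`.
#' @export
build_training_table <- function(stack, occurrences) {
  vals <- lapply(stack, extract_at, x = occurrences$x, y = occurrences$y)
  pred <- as.data.frame(vals)
  ok <- stats::complete.cases(pred)
  n_dropped <- sum(!ok)
  if (n_dropped)
    message(n_dropped, " record(s) outside the extent or on nodata cells dropped")
  tab <- cbind(data.frame(id = occurrences$id,
                          label = as.integer(occurrences$status == "presence")),
               pred)[ok, , drop = FALSE]
  if (!nrow(tab)) stop("zero usable rows")
  if (length(unique(tab$label)) < 2L)
    stop("training table contains a single label class")
  rownames(tab) <- NULL
  attr(tab, "provenance") <- occurrences$source[1]
  attr(tab, "n_dropped") <- n_dropped
  class(tab) <- c("training_table", "data.frame")
  tab
}

.predictor_names <- function(table) setdiff(names(table), c("id", "label"))

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation; tied score pairs contribute 1/2.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = presence).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Greedy correlation-based variable reduction
#'
#' Constant predictors are removed first (with a message). Then, while any
#' pair of remaining predictors has absolute Pearson correlation above the
#' cutoff, the member of the *worst* (most correlated) pair with the lower
#' univariate AUC against the label is dropped; ties drop the later name
#' alphabetically. Survivors are returned in their original column order.
#'
#' @param table a `training_table`.
#' @param correlation_cutoff absolute-correlation threshold (default 0.7).
#' @return character vector of surviving predictor names.
#' @export
reduce_variables <- function(table, correlation_cutoff = 0.7) {
  preds <- .predictor_names(table)
  if (length(preds) < 2L) stop("at least two predictors required")
  X <- as.matrix(table[, preds, drop = FALSE])
  const <- apply(X, 2L, stats::sd) == 0
  if (any(const)) {
    message("dropping constant predictor(s): ",
            paste(preds[const], collapse = ", "))
    preds <- preds[!const]
    X <- X[, preds, drop = FALSE]
  }
  uni <- vapply(preds, function(p) auc(X[, p], table$label), 0.0)
  keep <- preds
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(cm) <- 0
    if (max(cm) <= correlation_cutoff) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    a <- keep[worst[1]]; b <- keep[worst[2]]
    drop_var <- if (uni[a] < uni[b]) a
      else if (uni[b] < uni[a]) b
      else max(a, b)                 # tie: later name alphabetically
    keep <- setdiff(keep, drop_var)
  }
  preds[preds %in% keep]
}

#' Stratified cross-validation folds
#'
#' Folds are created once per (labels, seed) and must be reused across all
#' algorithms so every model sees identical partitions.
#'
#' @param labels 0/1 label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold assignment (1..k) per row.
#' @export
make_cv_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.integer(labels)
  if (min(table(labels)) < k)
    stop("smallest class has fewer rows than k; use a smaller k")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# ---- algorithm adapters ------------------------------------------------
# each adapter consumes (X data.frame, y 0/1) and returns a closure mapping
# a data.frame of predictors to scores in [0, 1]

.default_hyper <- list(
  BRT = list(eta = 0.01, max_depth = 3L, nrounds = NULL, nrounds_max = 500L,
             cv_folds = 5L, subsample = 0.8),
  RF = list(num.trees = 500L),
  MARS = list(max_terms = 21L, knots_per_var = 5L, penalty = 3),
  MaxEnt = list(nlambda = 50L, nfolds = 5L),
  LR = list()
)

.check_degenerate <- function(X, y, algorithm) {
  if (length(unique(y)) < 2L || all(apply(as.matrix(X), 2L, stats::sd) == 0))
    stop("degenerate training data for ", algorithm, ": no variation")
}

.fit_adapter <- function(algorithm, X, y, hp) {
  .check_degenerate(X, y, algorithm)
  switch(algorithm,
    LR = {
      dat <- cbind(data.frame(.y = y), X)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = dat,
                                         family = stats::binomial()))
      function(nd) as.numeric(stats::predict(fit, newdata = nd,
                                             type = "response"))
    },
    BRT = {
      dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
      params <- list(objective = "binary:logistic", eta = hp$eta,
                     max_depth = hp$max_depth, subsample = hp$subsample,
                     nthread = 1L)
      nrounds <- hp$nrounds
      if (is.null(nrounds)) {
        cv <- xgboost::xgb.cv(params = params, data = dm,
                              nrounds = hp$nrounds_max, nfold = hp$cv_folds,
                              early_stopping_rounds = 20L, verbose = 0)
        nrounds <- cv$best_iteration
      }
      fit <- xgboost::xgb.train(params = params, data = dm, nrounds = nrounds)
      vn <- colnames(X)
      function(nd) as.numeric(stats::predict(fit,
        xgboost::xgb.DMatrix(as.matrix(nd[, vn, drop = FALSE]))))
    },
    RF = {
      dat <- cbind(data.frame(.y = factor(y, levels = c(0, 1))), X)
      fit <- ranger::ranger(.y ~ ., data = dat, num.trees = hp$num.trees,
                            probability = TRUE, num.threads = 1L,
                            seed = 1L)
      function(nd) as.numeric(stats::predict(fit, data = nd,
                                             num.threads = 1L)$predictions[, "1"])
    },
    MARS = {
      fit <- mars_fit(as.matrix(X), y, max_terms = hp$max_terms,
                      knots_per_var = hp$knots_per_var, penalty = hp$penalty)
      function(nd) predict.sdm_mars(fit, nd)
    },
    MaxEnt = {
      Xm <- as.matrix(X)
      fit <- glmnet::cv.glmnet(Xm, y, family = "binomial", alpha = 1,
                               nlambda = hp$nlambda, nfolds = hp$nfolds)
      vn <- colnames(Xm)
      function(nd) as.numeric(stats::predict(fit,
        newx = as.matrix(nd[, vn, drop = FALSE]),
        s = "lambda.min", type = "response"))
    },
    stop("unknown algorithm: ", algorithm))
}

#' Cross-validate one algorithm on shared folds
#'
#' Refits the algorithm with each fold held out and collects held-out scores;
#' pooled held-out scores drive AUC and (downstream) threshold selection.
#'
#' @param algorithm one of `"LR"`, `"BRT"`, `"RF"`, `"MARS"`, `"MaxEnt"`.
#' @param table a `training_table`.
#' @param variables predictor names to use.
#' @param folds integer fold vector from [make_cv_folds()].
#' @param hyperparameters named list overriding the documented defaults.
#' @return list with `scores` (pooled held-out, in row order), `fold_auc`,
#'   `pooled_auc`, and `folds`.
#' @export
crossvalidate <- function(algorithm, table, variables, folds,
                          hyperparameters = list()) {
  hp <- utils::modifyList(.default_hyper[[algorithm]], hyperparameters)
  X <- table[, variables, drop = FALSE]
  y <- table$label
  scores <- rep(NA_real_, nrow(table))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      stop("fold ", f, " lacks both classes; use stratified folds / smaller k")
    pred <- .fit_adapter(algorithm, X[tr, , drop = FALSE], y[tr], hp)
    scores[!tr] <- pred(X[!tr, , drop = FALSE])
  }
  fold_auc <- vapply(sort(unique(folds)), function(f)
    auc(scores[folds == f], y[folds == f]), 0.0)
  list(scores = scores, fold_auc = fold_auc,
       pooled_auc = auc(scores, y), folds = folds)
}

#' Select the sensitivity = specificity threshold
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores plus one candidate below the minimum and one above the maximum
#' score. A score is classified suitable when `score >= tau`. The candidate
#' minimizing `|sensitivity - specificity|` wins; ties prefer higher
#' sensitivity, then lower tau.
#'
#' @param scores numeric scores in `[0, 1]` (pooled held-out CV scores by
#'   convention).
#' @param labels 0/1 labels.
#' @return the selected threshold tau.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes required")
  s <- sort(unique(scores))
  # extreme candidates sit strictly below the min / above the max score,
  # inside (0, 1) whenever the scores allow it
  lo <- if (s[1] > 0) s[1] / 2 else s[1] - 0.5
  hi <- if (s[length(s)] < 1) (s[length(s)] + 1) / 2 else s[length(s)] + 0.5
  cands <- c(lo, if (length(s) > 1L) (s[-length(s)] + s[-1]) / 2, hi)
  sens <- vapply(cands, function(t) mean(scores[labels == 1L] >= t), 0.0)
  spec <- vapply(cands, function(t) mean(scores[labels == 0L] < t), 0.0)
  d <- abs(sens - spec)
  ord <- order(d, -sens, cands)
  cands[ord[1]]
}

#' Fit one SDM algorithm end to end
#'
#' Runs shared-fold cross-validation for held-out metrics and the
#' sensitivity = specificity threshold, then refits on all rows for the final
#' score function.
#'
#' @inheritParams crossvalidate
#' @param threshold_source `"cv"` (pooled held-out scores, default) or
#'   `"training"`.
#' @return object of class `fitted_sdm` with fields `algorithm`,
#'   `selected_variables`, `predictor` (score closure), `threshold`,
#'   `cv_metrics`.
#' @export
fit_sdm <- function(algorithm, table, variables = .predictor_names(table),
                    folds = NULL, hyperparameters = list(),
                    threshold_source = c("cv", "training")) {
  threshold_source <- match.arg(threshold_source)
  algorithm <- match.arg(algorithm, c("LR", "BRT", "RF", "MARS", "MaxEnt"))
  if (is.null(folds)) folds <- make_cv_folds(table$label, k = 10L, seed = 1L)
  hp <- utils::modifyList(.default_hyper[[algorithm]], hyperparameters)
  cv <- crossvalidate(algorithm, table, variables, folds, hyperparameters)
  predictor <- .fit_adapter(algorithm, table[, variables, drop = FALSE],
                            table$label, hp)
  thr_scores <- if (threshold_source == "cv") cv$scores else
    predictor(table[, variables, drop = FALSE])
  tau <- select_threshold(thr_scores, table$label)
  sens <- mean(thr_scores[table$label == 1L] >= tau)
  spec <- mean(thr_scores[table$label == 0L] < tau)
  structure(list(algorithm = algorithm, selected_variables = variables,
                 predictor = predictor, threshold = tau,
                 hyperparameters = hp,
                 cv_metrics = list(pooled_auc = cv$pooled_auc,
                                   fold_auc = cv$fold_auc,
                                   sensitivity = sens, specificity = spec,
                                   accuracy = mean((thr_scores >= tau) ==
                                                     (table$label == 1L)))),
            class = "fitted_sdm")
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("<fitted_sdm> %s | %d variables | tau = %.3f | CV AUC = %.3f\n",
              x$algorithm, length(x$selected_variables), x$threshold,
              x$cv_metrics$pooled_auc))
  invisible(x)
}

#' Predict a probability surface from a fitted SDM
#'
#' @param fitted a `fitted_sdm`.
#' @param stack a `layer_stack` containing every selected variable.
#' @return continuous `sdm_grid` of scores in `[0, 1]`; a cell is nodata
#'   wherever any selected layer is nodata.
#' @export
predict_surface <- function(fitted, stack) {
  miss <- setdiff(fitted$selected_variables, names(stack))
  if (length(miss)) stop("stack is missing layer(s): ", paste(miss, collapse = ", "))
  ref <- stack[[fitted$selected_variables[1]]]
  nd <- as.data.frame(lapply(stack[fitted$selected_variables],
                             function(g) as.vector(g$values)))
  ok <- stats::complete.cases(nd)
  out <- rep(NA_real_, nrow(nd))
  if (any(ok)) out[ok] <- fitted$predictor(nd[ok, , drop = FALSE])
  raster_grid(matrix(out, nrow(ref$values), ncol(ref$values)),
              ref$cell_size, ref$origin)
}

#' Binary suitability surface at a fitted threshold
#'
#' @param fitted a `fitted_sdm`.
#' @param stack predictor `layer_stack`.
#' @return 0/1 `sdm_grid`: 1 where score >= threshold.
#' @export
binary_surface <- function(fitted, stack) {
  p <- predict_surface(fitted, stack)
  raster_grid((p$values >= fitted$threshold) * 1.0, p$cell_size, p$origin)
}

#' Fit the five-algorithm ensemble on one training table
#'
#' Creates stratified folds once, fits each algorithm with those shared
#' folds, thresholds every probability surface at its own sensitivity =
#' specificity point, and stacks the binary maps into a 0-5 consensus
#' surface.
#'
#' @param table a `training_table`.
#' @param stack predictor `layer_stack`.
#' @param algorithms subset of the five algorithm names.
#' @param k folds for cross-validation.
#' @param seed fold seed.
#' @param correlation_cutoff passed to [reduce_variables()]; `NULL` skips
#'   reduction.
#' @param hyperparameters named list of per-algorithm overrides.
#' @param threshold_source see [fit_sdm()].
#' @return list of class `sdm_ensemble`: `models`, `surface` (an
#'   `ensemble_surface`), `variables`, `folds`.
#' @export
fit_ensemble <- function(table, stack,
                         algorithms = c("LR", "BRT", "RF", "MARS", "MaxEnt"),
                         k = 10L, seed = 1L, correlation_cutoff = 0.7,
                         hyperparameters = list(),
                         threshold_source = "cv") {
  vars <- if (is.null(correlation_cutoff)) .predictor_names(table) else
    reduce_variables(table, correlation_cutoff)
  folds <- make_cv_folds(table$label, k = k, seed = seed)
  models <- lapply(algorithms, function(a)
    fit_sdm(a, table, vars, folds,
            hyperparameters = if (a %in% names(hyperparameters))
              hyperparameters[[a]] else list(),
            threshold_source = threshold_source))
  names(models) <- algorithms
  binaries <- lapply(models, binary_surface, stack = stack)
  structure(list(models = models, surface = stack_consensus(binaries),
                 variables = vars, folds = folds), class = "sdm_ensemble")
}
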