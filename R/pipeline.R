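#' Load a shipped printed agreement-table fixture
#'
#' The package ships the two published 6x6 standard-vs-convenience area
#' cross-tabulations (sq km) as plain-text fixtures, including their printed
#' TOTAL row and column. Loading recomputes every marginal from the 36 cells
#' and validates it against the printed totals to within 0.5 sq km (printed
#' rounding); any larger mismatch is treated as a transcription fault.
#'
#' @param name `"table3"` (A. americanum) or `"table4"` (I. scapularis).
#' @return an [agreement_table()] with attributes `printed_row_totals`,
#'   `printed_col_totals`, `printed_total`.
#' @export
load_agreement_fixture <- function(name = c("table3", "table4")) {
  name <- match.arg(name)
  file <- system.file("extdata",
                      switch(name,
                             table3 = "table3_a_americanum_agreement_sqkm.csv",
                             table4 = "table4_i_scapularis_agreement_sqkm.csv"),
                      package = "sdmcompare")
  if (!nzchar(file)) stop("fixture not found; is the package installed?")
  raw <- utils::read.csv(file, comment.char = "#", check.names = FALSE)
  rn <- raw[[1]]
  m <- as.matrix(raw[, -1])
  cells <- m[rn != "TOTAL", colnames(m) != "TOTAL", drop = FALSE]
  row_tot <- m[rn != "TOTAL", colnames(m) == "TOTAL"]
  col_tot <- m[rn == "TOTAL", colnames(m) != "TOTAL"]
  grand <- m[rn == "TOTAL", colnames(m) == "TOTAL"]
  if (any(abs(rowSums(cells) - row_tot) > 0.5) ||
      any(abs(colSums(cells) - col_tot) > 0.5) ||
      abs(sum(cells) - grand) > 0.5)
    stop("fixture marginals disagree with printed totals beyond 0.5 sq km ",
         "(transcription fault)")
  out <- agreement_table(unname(cells))
  attr(out, "printed_row_totals") <- unname(row_tot)
  attr(out, "printed_col_totals") <- unname(col_tot)
  attr(out, "printed_total") <- unname(grand)
  out
}

#' Assemble and validate a pipeline configuration
#'
#' A config fully determines a run: the synthetic scenario, the engine
#' settings, the comparison settings, and explicit seeds for every
#' stochastic stage (landscape/survey generation via the scenario seed,
#' background sampling, and fold creation).
#'
#' @param scenario named list of [sdm_scenario()] arguments; must include
#'   `seed`.
#' @param engine named list: `algorithms`, `k`, `correlation_cutoff`,
#'   `background_ratio`, `hyperparameters`, `threshold_source`.
#' @param comparison named list: `weighting` for the kappa comparison.
#' @param seeds named list with integers `background` and `folds`.
#' @param output_dir optional directory for per-stage outputs.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(scenario = list(seed = 1L),
                       engine = list(),
                       comparison = list(),
                       seeds = list(background = 1L, folds = 1L),
                       output_dir = NULL) {
  if (is.null(scenario$seed)) stop("config is missing scenario$seed")
  if (is.null(seeds$background) || is.null(seeds$folds))
    stop("config is missing seeds$background or seeds$folds")
  engine <- utils::modifyList(
    list(algorithms = c("LR", "BRT", "RF", "MARS", "MaxEnt"), k = 10L,
         correlation_cutoff = 0.7, background_ratio = 10L,
         hyperparameters = list(), threshold_source = "cv"), engine)
  comparison <- utils::modifyList(list(weighting = "none"), comparison)
  structure(list(scenario = scenario, engine = engine,
                 comparison = comparison, seeds = seeds,
                 output_dir = output_dir), class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with top-level keys `scenario`, `engine`,
#'   `comparison`, `seeds`, `output_dir`.
#' @return a validated [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(scenario = if (is.null(y$scenario)) list() else y$scenario,
             engine = if (is.null(y$engine)) list() else y$engine,
             comparison = if (is.null(y$comparison)) list() else y$comparison,
             seeds = if (is.null(y$seeds)) list() else y$seeds,
             output_dir = y$output_dir)
}

#' Run the full comparison pipeline on a synthetic scenario
#'
#' Simulates the landscape, runs both survey designs, samples background
#' points for the convenience presences, fits the five-algorithm ensemble
#' for each design on shared folds, stacks the consensus surfaces, and
#' computes the comparison statistics: per-design areas by consensus score,
#' the areal cross-tabulation, the (weighted) kappa with Fleiss SE and CI
#' (with pixel count as the inference unit), proportion-positive curves,
#' and the omission report of convenience presences against the
#' standard-survey ensemble. When `output_dir` is set, per-stage CSVs and a
#' machine-readable JSON summary are written; re-running the same config
#' reproduces them byte for byte.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with elements `scenario`,
#'   `state`, `occurrences`, `ensembles`, `areas`, `agreement`, `kappa`,
#'   `proportion_positive`, `omissions`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scenario <- do.call(sdm_scenario, config$scenario)
  eng <- config$engine
  state <- simulate_environment(scenario)
  std <- simulate_standard_survey(state, scenario)
  conv <- simulate_convenience_sample(state, scenario)
  bkg <- sample_background(state$stack, conv, ratio = eng$background_ratio,
                           seed = config$seeds$background)
  common <- c("id", "x", "y", "species", "status", "source", "year")
  conv_all <- occurrence_set(rbind(as.data.frame(conv)[common],
                                   as.data.frame(bkg)[common]))
  tab_std <- build_training_table(state$stack, std)
  tab_conv <- build_training_table(state$stack, conv_all)
  ens <- lapply(list(standard = tab_std, convenience = tab_conv), function(tb)
    fit_ensemble(tb, state$stack, algorithms = eng$algorithms, k = eng$k,
                 seed = config$seeds$folds,
                 correlation_cutoff = eng$correlation_cutoff,
                 hyperparameters = eng$hyperparameters,
                 threshold_source = eng$threshold_source))
  agreement <- cross_tabulate(ens$standard$surface, ens$convenience$surface)
  n_units <- sum(!is.na(ens$standard$surface$consensus$values) &
                   !is.na(ens$convenience$surface$consensus$values))
  kap <- kappa_estimate(agreement, config$comparison$weighting, n_units)
  prop <- list(standard = proportion_positive_by_score(std,
                 ens$standard$surface),
               convenience = proportion_positive_by_score(conv_all,
                 ens$convenience$surface))
  om <- find_omissions(conv, ens$standard$surface)
  ta <- tryCatch(temporal_association(om$is_omission, om$year),
                 error = function(e) NULL)
  res <- structure(list(
    scenario = scenario, state = state,
    occurrences = list(standard = std, convenience = conv, background = bkg),
    ensembles = ens,
    areas = lapply(ens, function(e) area_by_consensus(e$surface)),
    agreement = agreement, kappa = kap,
    proportion_positive = prop,
    omissions = list(report = om, rates = omission_rates(om),
                     temporal = ta),
    log = list(seeds = c(scenario = scenario$seed,
                         background = config$seeds$background,
                         folds = config$seeds$folds),
               dropped_standard = attr(tab_std, "n_dropped"),
               dropped_convenience = attr(tab_conv, "n_dropped"),
               variables = lapply(ens, `[[`, "variables"))),
    class = "pipeline_result")
  if (!is.null(config$output_dir)) .write_pipeline_outputs(res, config)
  res
}

.write_pipeline_outputs <- function(res, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$output_dir, f)
  utils::write.csv(res$areas$standard, p("areas_standard.csv"),
                   row.names = FALSE)
  utils::write.csv(res$areas$convenience, p("areas_convenience.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(res$agreement)),
                   p("agreement_table.csv"))
  utils::write.csv(as.data.frame(res$omissions$report),
                   p("omissions.csv"), row.names = FALSE)
  summary <- list(
    kappa = res$kappa$kappa, weighting = res$kappa$weighting,
    se = res$kappa$standard_error, ci95 = res$kappa$ci95,
    label = res$kappa$label,
    omission_rate = res$omissions$rates$omission_rate,
    adjacency_rate = res$omissions$rates$adjacency_rate,
    pooled_auc = lapply(res$ensembles, function(e)
      lapply(e$models, function(m) m$cv_metrics$pooled_auc)),
    thresholds = lapply(res$ensembles, function(e)
      lapply(e$models, `[[`, "threshold")),
    seeds = as.list(res$log$seeds))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(NULL)
}
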