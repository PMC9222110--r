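#' Scenario definitions for synthetic landscapes and surveys
#'
#' A scenario fixes everything the generators need: landscape geometry,
#' spatial autocorrelation of the environmental layers, the logistic true
#' suitability model, the designed-survey effort, and the convenience-sample
#' bias and positional-error settings. Defaults emulate the study conditions:
#' 1-ha cells (100 m), 560 transect pairs of ~150 m, presence-only
#' convenience records with geocoding errors averaging a few hundred meters
#' (literature range roughly 200-800 m).
#'
#' @param seed integer; every generator is deterministic given (seed, scenario).
#' @param shape integer (rows, cols) of the landscape.
#' @param cell_size cell edge in meters (100 m = 1 ha cells).
#' @param n_continuous_layers number of autocorrelated continuous predictors.
#' @param autocorrelation_range smoothing scale of the random fields, meters.
#' @param suitability_coefficients named weights on standardized layers.
#' @param suitability_intercept intercept of the logistic true-suitability model.
#' @param n_transects number of standard-survey transects.
#' @param transect_length transect length in meters.
#' @param detection_prob per-visit detection scaling on true suitability.
#' @param convenience_n number of presence-only convenience records.
#' @param bias_strength >= 0; 0 means spatially uniform sampling effort.
#' @param positional_error_mean,positional_error_max target mean and hard
#'   truncation (meters) of the geocoding displacement distribution.
#' @return a validated list of class `sdm_scenario`.
#' @export
sdm_scenario <- function(seed = 1L,
                         shape = c(100L, 100L),
                         cell_size = 100,
                         n_continuous_layers = 6L,
                         autocorrelation_range = 1500,
                         suitability_coefficients = c(env1 = 1.5, env2 = -1.0,
                                                      env3 = 0.8, env4 = 0.5),
                         suitability_intercept = -0.25,
                         n_transects = 560L,
                         transect_length = 150,
                         detection_prob = 1,
                         convenience_n = 178L,
                         bias_strength = 1,
                         positional_error_mean = 200,
                         positional_error_max = 800) {
  sc <- list(seed = as.integer(seed), shape = as.integer(shape),
             cell_size = cell_size, n_continuous_layers = as.integer(n_continuous_layers),
             autocorrelation_range = autocorrelation_range,
             suitability_coefficients = suitability_coefficients,
             suitability_intercept = suitability_intercept,
             n_transects = as.integer(n_transects),
             transect_length = transect_length,
             detection_prob = detection_prob,
             convenience_n = as.integer(convenience_n),
             bias_strength = bias_strength,
             positional_error_mean = positional_error_mean,
             positional_error_max = positional_error_max)
  stopifnot(length(sc$shape) == 2L, all(sc$shape > 0L), sc$cell_size > 0,
            sc$n_continuous_layers > 0L, sc$n_transects > 0L,
            sc$convenience_n > 0L, sc$bias_strength >= 0,
            sc$positional_error_mean <= sc$positional_error_max,
            sc$positional_error_max >= 0, sc$detection_prob >= 0,
            sc$detection_prob <= 1)
  class(sc) <- "sdm_scenario"
  sc
}

#' Occurrence record tables
#'
#' Thin constructor/validator for occurrence sets: point records with a
#' status (`presence`, `absence`, `background`), a source framework
#' (`standard`, `convenience`), a collection year, and optional
#' positional-error metadata (`true_x`, `true_y`, `error_m`, `error_flag`).
#'
#' @param df data.frame with at least columns `id`, `x`, `y`, `species`,
#'   `status`, `source`, `year`.
#' @return `df` with class `occurrence_set` prepended.
#' @export
occurrence_set <- function(df) {
  need <- c("id", "x", "y", "species", "status", "source", "year")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$status %in% c("presence", "absence", "background")))
    stop("invalid status values")
  if (!all(df$source %in% c("standard", "convenience")))
    stop("invalid source values")
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' @export
#' @rdname occurrence_set
#' @param path CSV path.
read_occurrences <- function(path) {
  occurrence_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
#' @rdname occurrence_set
#' @param occ an `occurrence_set`.
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

# Gaussian-kernel smoothing of a matrix with reflection padding (separable).
.smooth_field <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(min(half, n))]), v, rev(v[seq.int(n, by = -1L,
             length.out = min(half, n))]))
    # if the pad is shorter than half (tiny grids), recycle by reflection
    while (length(vp) < n + 2L * half)
      vp <- c(vp[1], vp, vp[length(vp)])
    out <- stats::filter(vp, k, sides = 2L)
    out[(half + 1L):(half + n)]
  }
  m2 <- apply(m, 2L, pad_conv)
  t(apply(t(m2), 2L, pad_conv))
}

#' Simulate a synthetic landscape and its true state
#'
#' Continuous predictors are spatially autocorrelated standardized random
#' fields (white noise smoothed with a Gaussian kernel whose scale matches
#' `autocorrelation_range`). Land cover is a 5-class categorical layer
#' obtained by quantile-binning one further autocorrelated field, shipped
#' both as a categorical `landcover` grid (codes 1-5: forest, grass,
#' wetlands, shrub, other) and as five 0/1 indicator layers. True
#' suitability is `plogis(intercept + sum(coef * layer))`. The relative
#' sampling-effort (bias) surface decays exponentially with distance from a
#' fixed "population center" in the northeast of the map:
#' `exp(-bias_strength * d / max(d))`, so `bias_strength = 0` gives uniform
#' effort.
#'
#' @param scenario a [sdm_scenario()].
#' @return list of class `true_state`: `stack` (a `layer_stack`),
#'   `landcover` (categorical grid), `suitability`, `bias_surface`.
#' @export
simulate_environment <- function(scenario) {
  stopifnot(inherits(scenario, "sdm_scenario"))
  set.seed(scenario$seed)
  nr <- scenario$shape[1]; nc <- scenario$shape[2]; s <- scenario$cell_size
  sigma <- scenario$autocorrelation_range / s / 2
  mkfield <- function() {
    f <- .smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
    (f - mean(f)) / stats::sd(f)
  }
  cont <- lapply(seq_len(scenario$n_continuous_layers), function(i) mkfield())
  names(cont) <- paste0("env", seq_along(cont))
  lc_field <- mkfield()
  lc_codes <- 1:5
  lc_names <- c("forest", "grass", "wetlands", "shrub", "other")
  qs <- stats::quantile(lc_field, probs = seq(0.2, 0.8, by = 0.2))
  lc <- matrix(findInterval(lc_field, qs) + 1L, nr, nc)
  coefs <- scenario$suitability_coefficients
  missing_layers <- setdiff(names(coefs), names(cont))
  if (length(missing_layers))
    stop("suitability coefficient references missing layer(s): ",
         paste(missing_layers, collapse = ", "))
  eta <- matrix(scenario$suitability_intercept, nr, nc)
  for (nm in names(coefs)) eta <- eta + coefs[[nm]] * cont[[nm]]
  suit <- stats::plogis(eta)
  # population center fixed in the upper-right quadrant of the map
  cx <- scenario$cell_size * nc * 0.75
  cy <- scenario$cell_size * nr * 0.75
  xs <- (seq_len(nc) - 0.5) * s
  ys <- (nr - seq_len(nr) + 0.5) * s
  d <- sqrt(outer(ys - cy, xs - cx, function(a, b) a^2 + b^2))
  bias <- exp(-scenario$bias_strength * d / max(d))
  mk <- function(v, ...) raster_grid(v, s, c(0, 0), ...)
  layers <- lapply(cont, mk)
  for (i in seq_along(lc_codes))
    layers[[lc_names[i]]] <- mk((lc == lc_codes[i]) * 1.0)
  structure(list(
    stack = layer_stack(layers),
    landcover = mk(lc, kind = "categorical", codes = lc_codes),
    suitability = mk(suit),
    bias_surface = mk(bias)), class = "true_state")
}

# largest-remainder (Hamilton) apportionment of n among weights w
.largest_remainder <- function(n, w) {
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Simulate a designed (standard) transect survey
#'
#' Transect start cells are stratified across the five land-cover classes in
#' proportion to class area (largest-remainder allocation, then uniform
#' sampling of cells within class without replacement). Each transect is a
#' 150 m segment (scenario `transect_length`) at a uniform random bearing
#' from the start-cell center; its detection probability is the mean true
#' suitability over the cells the segment passes through, times
#' `detection_prob`. Presences and absences are returned with exact
#' coordinates (no positional error).
#'
#' @param state a `true_state` from [simulate_environment()].
#' @param scenario the matching [sdm_scenario()].
#' @param species species label for the records.
#' @return an [occurrence_set()] with `source = "standard"`.
#' @export
simulate_standard_survey <- function(state, scenario, species = "synthetic") {
  set.seed(scenario$seed + 1L)
  lc <- state$landcover
  nr <- nrow(lc$values); nc <- ncol(lc$values); s <- lc$cell_size
  n <- scenario$n_transects
  if (n > nr * nc) stop("n_transects exceeds available cells")
  codes <- lc$codes
  areas <- vapply(codes, function(k) sum(lc$values == k, na.rm = TRUE), 0L)
  alloc <- .largest_remainder(n, areas)
  # if a class has fewer cells than its allocation, spill over to the largest class
  over <- pmax(alloc - areas, 0L)
  alloc <- pmin(alloc, areas)
  alloc[which.max(areas)] <- alloc[which.max(areas)] + sum(over)
  cells <- unlist(lapply(seq_along(codes), function(i) {
    pool <- which(lc$values == codes[i])
    sample(pool, alloc[i])
  }))
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  x0 <- lc$origin[1] + (col - 0.5) * s
  y0 <- lc$origin[2] + (nr - row + 0.5) * s
  theta <- stats::runif(length(cells), 0, 2 * pi)
  # mean suitability over cells intersected by the segment, sampled finely
  step <- s / 4
  ts <- seq(0, scenario$transect_length, by = step)
  p <- vapply(seq_along(cells), function(i) {
    px <- x0[i] + ts * cos(theta[i]); py <- y0[i] + ts * sin(theta[i])
    rc <- locate_cells(state$suitability, px, py)
    ok <- !is.na(rc$row)
    cid <- unique(rc$row[ok] + (rc$col[ok] - 1L) * nr)
    mean(state$suitability$values[cid], na.rm = TRUE)
  }, 0.0)
  hit <- stats::rbinom(length(cells), 1L, pmin(1, p * scenario$detection_prob))
  occurrence_set(data.frame(
    id = sprintf("std%04d", seq_along(cells)),
    x = x0, y = y0, species = species,
    status = ifelse(hit == 1L, "presence", "absence"),
    source = "standard",
    year = sample(2015:2019, length(cells), replace = TRUE),
    stringsAsFactors = FALSE))
}

#' Simulate a presence-only convenience sample
#'
#' Cells are drawn with probability proportional to true suitability times
#' the sampling-bias surface; the true point is placed uniformly within the
#' cell, then displaced isotropically by a geocoding positional error drawn
#' from a log-normal distribution calibrated so its mean falls between
#' `positional_error_mean` and `positional_error_max`, hard-truncated at
#' `positional_error_max` (resampling the magnitude). With
#' `positional_error_max = 0` the reported coordinates equal the true ones.
#' Collection years span the archive eras (pre-1940 through post-1980).
#'
#' @inheritParams simulate_standard_survey
#' @return an [occurrence_set()] with `source = "convenience"` carrying
#'   `true_x`, `true_y` and the realized `error_m`.
#' @export
simulate_convenience_sample <- function(state, scenario, species = "synthetic") {
  set.seed(scenario$seed + 2L)
  suit <- state$suitability; bias <- state$bias_surface
  nr <- nrow(suit$values); s <- suit$cell_size
  w <- as.vector(suit$values * bias$values)
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("zero total sampling weight")
  n <- scenario$convenience_n
  cells <- sample.int(length(w), n, replace = TRUE, prob = w)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  tx <- suit$origin[1] + (col - 1L) * s + stats::runif(n, 0, s)
  ty <- suit$origin[2] + (nrow(suit$values) - row) * s + stats::runif(n, 0, s)
  err <- .positional_error(n, scenario$positional_error_mean,
                           scenario$positional_error_max)
  ang <- stats::runif(n, 0, 2 * pi)
  occurrence_set(data.frame(
    id = sprintf("cnv%04d", seq_len(n)),
    x = tx + err * cos(ang), y = ty + err * sin(ang),
    species = species, status = "presence", source = "convenience",
    year = sample(c(1925:1939, 1940:1959, 1960:1979, 1980:2017), n,
                  replace = TRUE),
    true_x = tx, true_y = ty, error_m = err,
    stringsAsFactors = FALSE))
}

# truncated log-normal positional error; target mean midway between the
# configured mean and max before truncation
.positional_error <- function(n, err_mean, err_max) {
  if (err_max <= 0) return(rep(0, n))
  sdlog <- 0.6
  target <- (err_mean + err_max) / 2
  meanlog <- log(target) - sdlog^2 / 2
  draw <- stats::rlnorm(n, meanlog, sdlog)
  bad <- draw > err_max
  while (any(bad)) {
    draw[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
    bad <- draw > err_max
  }
  draw
}

#' Sample background (pseudo-absence) points
#'
#' Draws exactly `ratio` times the number of presence records, uniformly over
#' non-nodata cells, redrawing any point whose 1-ha cell already contains a
#' presence (the exclusion rule). Points are placed uniformly within their
#' cell.
#'
#' @param stack a `layer_stack` (the first layer defines geometry/nodata).
#' @param presences an `occurrence_set` of presence records.
#' @param ratio background:presence ratio (default 10).
#' @param seed integer seed.
#' @param species species label.
#' @return an [occurrence_set()] of `status = "background"` records.
#' @export
sample_background <- function(stack, presences, ratio = 10L, seed = 1L,
                              species = presences$species[1]) {
  set.seed(seed)
  ref <- stack[[1]]
  nr <- nrow(ref$values); s <- ref$cell_size
  pres <- presences[presences$status == "presence", , drop = FALSE]
  if (!nrow(pres)) stop("no presence records")
  rc <- locate_cells(ref, pres$x, pres$y)
  occupied <- unique(rc$row + (rc$col - 1L) * nr)
  occupied <- occupied[!is.na(occupied)]
  eligible <- which(!is.na(ref$values))
  eligible <- setdiff(eligible, occupied)
  need <- ratio * nrow(pres)
  if (length(eligible) < need)
    stop("eligible cells (", length(eligible), ") fewer than required background count (",
         need, ")")
  cells <- sample(eligible, need, replace = TRUE)
  row <- ((cells - 1L) %% nr) + 1L
  col <- ((cells - 1L) %/% nr) + 1L
  bx <- ref$origin[1] + (col - 1L) * s + stats::runif(need, 0, s)
  by <- ref$origin[2] + (nr - row) * s + stats::runif(need, 0, s)
  occurrence_set(data.frame(
    id = sprintf("bkg%05d", seq_len(need)),
    x = bx, y = by, species = species, status = "background",
    source = pres$source[1],
    year = NA_integer_, stringsAsFactors = FALSE))
}
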