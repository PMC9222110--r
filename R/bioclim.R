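#' Aggregate daily climate series to monthly values
#'
#' Monthly `tmin`/`tmax` are means of the daily values; monthly precipitation
#' is the sum. Series must cover whole months.
#'
#' @param tmin,tmax,prec daily series: numeric vectors, or matrices with one
#'   row per cell and one column per day.
#' @param months integer month-of-year (1-12) for every day.
#' @param days_in_month expected number of days per month; the default is the
#'   non-leap civil calendar.
#' @return list with matrices `tmin`, `tmax` (monthly means, 12 columns) and
#'   `prec` (monthly totals).
#' @export
aggregate_daily_to_monthly <- function(tmin, tmax, prec, months,
                                       days_in_month = c(31, 28, 31, 30, 31, 30,
                                                         31, 31, 30, 31, 30, 31)) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)
  tmin <- as_mat(tmin); tmax <- as_mat(tmax); prec <- as_mat(prec)
  nd <- length(months)
  if (ncol(tmin) != nd || ncol(tmax) != nd || ncol(prec) != nd)
    stop("series length must equal length(months)")
  counts <- tabulate(months, nbins = 12L)
  used <- counts > 0L
  if (any(counts[used] != days_in_month[used]))
    stop("partial months in the daily series")
  if (any(prec < 0, na.rm = TRUE)) stop("negative precipitation")
  if (any(tmax < tmin, na.rm = TRUE)) stop("tmax < tmin in daily series")
  agg <- function(x, f) {
    out <- matrix(NA_real_, nrow(x), 12L)
    for (m in which(used)) out[, m] <- apply(x[, months == m, drop = FALSE], 1L, f)
    out
  }
  list(tmin = agg(tmin, mean), tmax = agg(tmax, mean), prec = agg(prec, sum))
}

# all 12 consecutive 3-month windows with Dec-Jan wraparound; rows = windows
.quarter_windows <- function() {
  t(vapply(1:12, function(s) ((s - 1L):(s + 1L)) %% 12L + 1L, integer(3)))
}

#' Compute the 19 bioclimatic variables from monthly climate
#'
#' Follows the standard bioclim naming: bio1 annual mean temperature, bio2
#' mean diurnal range, bio3 isothermality (100 x bio2/bio7), bio4 temperature
#' seasonality (100 x population SD of monthly means), bio5/bio6 max/min
#' temperature of the warmest/coldest month, bio7 annual range, bio8-bio11
#' mean temperature of the wettest/driest/warmest/coldest quarter, bio12
#' annual precipitation, bio13/bio14 wettest/driest month precipitation,
#' bio15 precipitation seasonality (100 x population SD / (1 + bio12/12)),
#' bio16-bio19 precipitation of the wettest/driest/warmest/coldest quarter.
#' Quarters are all 12 consecutive 3-month windows with December-January
#' wraparound; ties are broken by the earliest starting month. Monthly mean
#' temperature is (tmin + tmax)/2. When bio7 = 0 (no temperature variation)
#' bio3 is undefined and returned as `NA`.
#'
#' @param mc list as returned by [aggregate_daily_to_monthly()]: matrices
#'   `tmin`, `tmax`, `prec` with one row per cell and 12 columns (or plain
#'   length-12 vectors for a single cell).
#' @return matrix with one row per cell and columns `bio1`...`bio19`.
#' @export
compute_bioclim <- function(mc) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L)
  tmin <- as_mat(mc$tmin); tmax <- as_mat(mc$tmax); prec <- as_mat(mc$prec)
  stopifnot(ncol(tmin) == 12L, ncol(tmax) == 12L, ncol(prec) == 12L)
  if (any(tmax < tmin, na.rm = TRUE)) stop("tmax < tmin")
  if (any(prec < 0, na.rm = TRUE)) stop("negative precipitation")
  tavg <- (tmin + tmax) / 2
  n <- nrow(tavg)
  win <- .quarter_windows()
  # per-window quarter summaries: 12 columns, one per starting month
  qprec <- sapply(seq_len(12L), function(w) rowSums(prec[, win[w, ], drop = FALSE]))
  qtemp <- sapply(seq_len(12L), function(w) rowMeans(tavg[, win[w, ], drop = FALSE]))
  qprec <- matrix(qprec, n, 12L); qtemp <- matrix(qtemp, n, 12L)
  pick <- function(score, value, decreasing) {
    # earliest-start tie-break: which.max/min return the first index
    idx <- apply(score, 1L, if (decreasing) which.max else which.min)
    value[cbind(seq_len(n), idx)]
  }
  sd_pop <- function(x) sqrt(rowMeans((x - rowMeans(x))^2))
  out <- matrix(NA_real_, n, 19L,
                dimnames = list(NULL, paste0("bio", 1:19)))
  out[, "bio1"] <- rowMeans(tavg)
  out[, "bio2"] <- rowMeans(tmax - tmin)
  out[, "bio4"] <- 100 * sd_pop(tavg)
  out[, "bio5"] <- apply(tmax, 1L, max)
  out[, "bio6"] <- apply(tmin, 1L, min)
  out[, "bio7"] <- out[, "bio5"] - out[, "bio6"]
  out[, "bio3"] <- ifelse(out[, "bio7"] == 0, NA_real_,
                          100 * out[, "bio2"] / out[, "bio7"])
  out[, "bio8"] <- pick(qprec, qtemp, TRUE)    # wettest quarter
  out[, "bio9"] <- pick(qprec, qtemp, FALSE)   # driest quarter
  out[, "bio10"] <- pick(qtemp, qtemp, TRUE)   # warmest quarter
  out[, "bio11"] <- pick(qtemp, qtemp, FALSE)  # coldest quarter
  out[, "bio12"] <- rowSums(prec)
  out[, "bio13"] <- apply(prec, 1L, max)
  out[, "bio14"] <- apply(prec, 1L, min)
  out[, "bio15"] <- 100 * sd_pop(prec) / (1 + out[, "bio12"] / 12)
  out[, "bio16"] <- pick(qprec, qprec, TRUE)
  out[, "bio17"] <- pick(qprec, qprec, FALSE)
  out[, "bio18"] <- pick(qtemp, qprec, TRUE)   # precip of warmest quarter
  out[, "bio19"] <- pick(qtemp, qprec, FALSE)  # precip of coldest quarter
  out
}

#' Compute bioclim layers from stacks of monthly grids
#'
#' Convenience wrapper applying [compute_bioclim()] cell-wise to 12 congruent
#' monthly grids per variable.
#'
#' @param tmin,tmax,prec lists of 12 congruent `sdm_grid`s each.
#' @return `layer_stack` of 19 grids named `bio1`...`bio19`.
#' @export
bioclim_stack <- function(tmin, tmax, prec) {
  stopifnot(length(tmin) == 12L, length(tmax) == 12L, length(prec) == 12L)
  ref <- tmin[[1]]
  vec <- function(gl) sapply(gl, function(g) as.vector(g$values))
  mc <- list(tmin = vec(tmin), tmax = vec(tmax), prec = vec(prec))
  bio <- compute_bioclim(mc)
  layers <- lapply(colnames(bio), function(nm)
    raster_grid(matrix(bio[, nm], nrow(ref$values), ncol(ref$values)),
                ref$cell_size, ref$origin))
  names(layers) <- colnames(bio)
  layer_stack(layers)
}

#' Per-cell NDVI summaries across composites
#'
#' @param composites list of congruent `sdm_grid`s (>= 1).
#' @return `layer_stack` with layers `ndvimin`, `ndvimean`, `ndvimax`.
#'   Nodata cells are excluded per cell; a cell nodata in every composite
#'   stays nodata.
#' @export
ndvi_summaries <- function(composites) {
  if (!length(composites)) stop("at least one composite required")
  viol <- congruence_check(structure(stats::setNames(composites,
           paste0("c", seq_along(composites))), class = "layer_stack"))
  viol <- viol[viol$kind != "nodata_mask", , drop = FALSE]
  if (nrow(viol)) stop("incongruent composites")
  ref <- composites[[1]]
  a <- sapply(composites, function(g) as.vector(g$values))
  a <- matrix(a, ncol = length(composites))
  f <- function(fun) apply(a, 1L, function(r)
    if (all(is.na(r))) NA_real_ else fun(r, na.rm = TRUE))
  mk <- function(v) raster_grid(matrix(v, nrow(ref$values), ncol(ref$values)),
                                ref$cell_size, ref$origin)
  layer_stack(ndvimin = mk(f(min)), ndvimean = mk(f(mean)), ndvimax = mk(f(max)))
}
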