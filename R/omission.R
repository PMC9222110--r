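#' Classify presence points against a consensus surface
#'
#' A presence whose containing cell has consensus score 0 is an ensemble
#' omission error. Omissions are further classed `adjacent` when any of the
#' 8 neighboring cells has consensus >= 1 (equivalently, the nearest
#' predicted cell center lies within sqrt(2) x cell_size), else `outside`.
#' Presences on nodata cells are flagged and excluded from rates.
#'
#' @param presences an [occurrence_set()]; only `status == "presence"` rows
#'   are used.
#' @param surface an `ensemble_surface`.
#' @param flags optional character vector (recycled) of qualitative
#'   positional-error codes carried through from the input, never inferred.
#' @return data.frame of class `omission_report`: `id`, `x`, `y`, `year`,
#'   `consensus_at_point`, `is_omission`, `nearest_predicted_distance`,
#'   `category`, `flag`; attribute `n_excluded` counts nodata presences.
#' @export
find_omissions <- function(presences, surface, flags = NULL) {
  pres <- presences[presences$status == "presence", , drop = FALSE]
  g <- surface$consensus
  sc <- extract_at(g, pres$x, pres$y)
  excl <- is.na(sc)
  if (any(excl))
    message(sum(excl), " presence(s) on nodata cells excluded from rates")
  pres <- pres[!excl, , drop = FALSE]
  sc <- sc[!excl]
  omit <- sc == 0
  dist <- rep(NA_real_, nrow(pres))
  cat <- ifelse(omit, NA_character_, "inside-prediction")
  if (any(omit)) {
    for (i in which(omit)) {
      dist[i] <- nearest_predicted_distance(c(pres$x[i], pres$y[i]), surface)
      cat[i] <- classify_adjacency(c(pres$x[i], pres$y[i]), surface)
    }
  }
  out <- data.frame(id = pres$id, x = pres$x, y = pres$y,
                    year = pres$year, consensus_at_point = as.integer(sc),
                    is_omission = omit,
                    nearest_predicted_distance = dist,
                    category = cat,
                    flag = if (is.null(flags)) NA_character_ else
                      rep_len(flags, nrow(pres)),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(excl)
  class(out) <- c("omission_report", "data.frame")
  out
}

#' Omission and adjacency rates from an omission report
#'
#' @param report an `omission_report`.
#' @return list with `n`, `n_omission`, `omission_rate`, `n_adjacent`,
#'   `adjacency_rate` (both rates over all classified presences).
#' @export
omission_rates <- function(report) {
  n <- nrow(report)
  list(n = n,
       n_omission = sum(report$is_omission),
       omission_rate = sum(report$is_omission) / n,
       n_adjacent = sum(report$category == "adjacent", na.rm = TRUE),
       adjacency_rate = sum(report$category == "adjacent", na.rm = TRUE) / n)
}

#' Euclidean distance to the nearest predicted cell center
#'
#' @param point numeric (x, y) in meters.
#' @param surface an `ensemble_surface` with at least one cell of consensus
#'   >= 1.
#' @return distance in meters (0 only if the point sits exactly on a
#'   predicted cell's center).
#' @export
nearest_predicted_distance <- function(point, surface) {
  g <- surface$consensus
  idx <- which(!is.na(g$values) & g$values >= 1)
  if (!length(idx)) stop("surface has no predicted (consensus >= 1) cells")
  nr <- nrow(g$values); s <- g$cell_size
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  cx <- g$origin[1] + (col - 0.5) * s
  cy <- g$origin[2] + (nr - row + 0.5) * s
  sqrt(min((cx - point[1])^2 + (cy - point[2])^2))
}

#' Adjacency classification of an omission point
#'
#' @param point numeric (x, y) of a presence whose containing cell has
#'   consensus 0.
#' @param surface an `ensemble_surface`.
#' @return `"adjacent"` if any 8-connected neighbor of the containing cell
#'   has consensus >= 1 (neighbors beyond the grid edge are ignored), else
#'   `"outside"`.
#' @export
classify_adjacency <- function(point, surface) {
  g <- surface$consensus
  rc <- locate_cells(g, point[1], point[2])
  if (is.na(rc$row)) stop("point outside the surface extent")
  if (!is.na(g$values[rc$row, rc$col]) && g$values[rc$row, rc$col] >= 1)
    stop("point is not an omission: consensus >= 1 at its cell")
  nr <- nrow(g$values); nc <- ncol(g$values)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r <- rc$row + dr; c <- rc$col + dc
    if (r < 1L || r > nr || c < 1L || c > nc) next
    v <- g$values[r, c]
    if (!is.na(v) && v >= 1) return("adjacent")
  }
  "outside"
}

#' Era bins for collection years
#'
#' @param year integer years.
#' @return factor with levels `pre-1940`, `1940-1959`, `1960-1979`, `>=1980`.
#' @export
collection_period <- function(year) {
  cut(year, breaks = c(-Inf, 1939, 1959, 1979, Inf),
      labels = c("pre-1940", "1940-1959", "1960-1979", ">=1980"))
}

#' Temporal association of omission errors
#'
#' Builds the 4 x 2 table of collection-period bin by omission status and
#' applies the Pearson association test (3 df when all bins are populated).
#' Empty bins are dropped with a warning and the degrees of freedom reduce
#' accordingly.
#'
#' @param is_omission logical vector.
#' @param year collection year per record.
#' @return list with `table`, `statistic`, `df`, `p_value`.
#' @export
temporal_association <- function(is_omission, year) {
  if (length(is_omission) != length(year)) stop("length mismatch")
  if (length(unique(is_omission)) < 2L)
    stop("both omission outcomes must be present")
  bins <- collection_period(year)
  tab <- table(bins, factor(is_omission, levels = c(FALSE, TRUE),
                            labels = c("inside", "omission")))
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("dropping empty period bin(s): ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  res <- chi_square_association(unclass(tab))
  c(list(table = tab), res)
}
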