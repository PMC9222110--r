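#' Raster grid objects
#'
#' A `sdm_grid` is the spatial substrate of the package: a rectangular matrix
#' of cell values with a cell size in meters, the (x, y) of the lower-left
#' corner of the extent, and `NA` marking nodata cells. Row 1 of the matrix is
#' the *top* row of the map; the y coordinate increases upward. At the study
#' convention of `cell_size = 100` m every cell is 1 ha.
#'
#' @param values numeric (or integer-code) matrix; `NA` is nodata.
#' @param cell_size positive cell edge length in meters.
#' @param origin numeric length-2, (x, y) of the lower-left corner in meters.
#' @param kind `"continuous"` or `"categorical"`.
#' @param codes for categorical grids, the declared set of legal codes. All
#'   non-`NA` values must belong to it.
#' @return an object of class `sdm_grid`.
#' @export
raster_grid <- function(values, cell_size, origin = c(0, 0),
                        kind = c("continuous", "categorical"), codes = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!(is.numeric(cell_size) && length(cell_size) == 1L && cell_size > 0))
    stop("`cell_size` must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be numeric (x, y)")
  if (kind == "categorical") {
    if (is.null(codes)) codes <- sort(unique(as.vector(values[!is.na(values)])))
    bad <- setdiff(unique(as.vector(values[!is.na(values)])), codes)
    if (length(bad))
      stop("categorical grid contains undeclared codes: ", paste(bad, collapse = ", "))
  }
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin), kind = kind, codes = codes),
            class = "sdm_grid")
}

#' @export
print.sdm_grid <- function(x, ...) {
  cat(sprintf("<sdm_grid> %d x %d cells, cell_size %g m, origin (%g, %g), %s\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2], x$kind))
  cat(sprintf("  nodata: %d cells; non-nodata area %.4f sq km\n",
              sum(is.na(x$values)), grid_area_sqkm(x)))
  invisible(x)
}

#' @export
dim.sdm_grid <- function(x) dim(x$values)

#' Non-nodata area of a grid in square kilometers
#'
#' Area = (number of non-nodata cells) x cell_size^2, converted to sq km.
#' @param grid a `sdm_grid`.
#' @return area in sq km.
#' @export
grid_area_sqkm <- function(grid) {
  sum(!is.na(grid$values)) * grid$cell_size^2 / 1e6
}

#' Cell center coordinates
#'
#' @param grid a `sdm_grid`.
#' @return list with vectors `x` (per column) and `y` (per row, row 1 = top).
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); s <- grid$cell_size
  list(x = grid$origin[1] + (seq_len(nc) - 0.5) * s,
       y = grid$origin[2] + (nr - seq_len(nr) + 0.5) * s)
}

#' Locate points on a grid
#'
#' Half-open cell convention: a point with `x` in `[x0 + (c-1) s, x0 + c s)`
#' falls in column `c`, and likewise in y, so a point on a shared corner is
#' assigned to the cell to its upper right. Points outside the extent get `NA`.
#'
#' @param grid a `sdm_grid`.
#' @param x,y point coordinates in meters.
#' @return data.frame with columns `row`, `col` (`NA` when outside the extent).
#' @export
locate_cells <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); s <- grid$cell_size
  col <- floor((x - grid$origin[1]) / s) + 1L
  row_from_bottom <- floor((y - grid$origin[2]) / s) + 1L
  row <- nr - row_from_bottom + 1L
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations
#'
#' @inheritParams locate_cells
#' @return vector of cell values; `NA` for points outside the extent or on
#'   nodata cells.
#' @export
extract_at <- function(grid, x, y) {
  rc <- locate_cells(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- grid$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Layer stacks
#'
#' A named, ordered collection of mutually congruent grids (same shape, cell
#' size, origin). Congruence is checked at construction; nodata masks may
#' differ until the stack is harmonized by the caller.
#'
#' @param ... named `sdm_grid` objects, or a single named list of them.
#' @return object of class `layer_stack` (a named list of grids).
#' @export
layer_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1]], "sdm_grid"))
    layers <- layers[[1]]
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all layers must be named")
  if (!all(vapply(layers, inherits, TRUE, "sdm_grid")))
    stop("all layers must be sdm_grid objects")
  stk <- structure(layers, class = "layer_stack")
  viol <- congruence_check(stk)
  viol <- viol[viol$kind != "nodata_mask", , drop = FALSE]
  if (nrow(viol))
    stop("incongruent layers: ", paste(unique(viol$layer), collapse = ", "))
  stk
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Report congruence violations in a layer stack
#'
#' Compares every layer against the first: shape, cell size, origin, and
#' nodata mask. Reporting only; never throws.
#'
#' @param stack a `layer_stack` or plain named list of `sdm_grid`s.
#' @return data.frame with columns `layer`, `kind`, `detail`; zero rows iff
#'   the stack is fully congruent with identical nodata masks.
#' @export
congruence_check <- function(stack) {
  out <- data.frame(layer = character(), kind = character(), detail = character())
  if (length(stack) < 2L) return(out)
  ref <- stack[[1]]
  for (nm in names(stack)[-1]) {
    g <- stack[[nm]]
    if (!identical(dim(g$values), dim(ref$values))) {
      out <- rbind(out, data.frame(layer = nm, kind = "shape",
        detail = sprintf("%dx%d vs %dx%d", nrow(g$values), ncol(g$values),
                         nrow(ref$values), ncol(ref$values))))
      next  # other comparisons meaningless on a different shape
    }
    if (!isTRUE(all.equal(g$cell_size, ref$cell_size)))
      out <- rbind(out, data.frame(layer = nm, kind = "cell_size",
        detail = sprintf("%g vs %g", g$cell_size, ref$cell_size)))
    if (!isTRUE(all.equal(g$origin, ref$origin)))
      out <- rbind(out, data.frame(layer = nm, kind = "origin",
        detail = sprintf("(%g,%g) vs (%g,%g)", g$origin[1], g$origin[2],
                         ref$origin[1], ref$origin[2])))
    if (!identical(is.na(g$values), is.na(ref$values)))
      out <- rbind(out, data.frame(layer = nm, kind = "nodata_mask",
        detail = sprintf("%d cells differ",
                         sum(is.na(g$values) != is.na(ref$values)))))
  }
  out
}

#' Extent-preserving resampling
#'
#' Continuous grids are resampled by bilinear interpolation at the target cell
#' centers (coordinates outside the source center hull are clamped to the
#' nearest center, i.e. edge values extend outward by half a cell). When some
#' of the four surrounding source cells are nodata the remaining weights are
#' renormalized; a target cell is nodata only where all contributing source
#' cells are nodata. Categorical grids take the majority code over the source
#' cells whose centers fall in each target cell (or the containing source cell
#' when upsampling), ties broken by the lowest code.
#'
#' @param grid a `sdm_grid`.
#' @param target_shape integer (rows, cols) of the output.
#' @param target_cell_size cell size of the output, in meters. The implied
#'   extent must match the source extent to within one source cell.
#' @return resampled `sdm_grid`.
#' @export
resample_grid <- function(grid, target_shape, target_cell_size) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); s <- grid$cell_size
  tr <- as.integer(target_shape[1]); tc <- as.integer(target_shape[2])
  ts <- as.numeric(target_cell_size)
  if (tr <= 0L || tc <= 0L || ts <= 0) stop("non-positive target geometry")
  if (abs(tr * ts - nr * s) > s || abs(tc * ts - nc * s) > s)
    stop("target extent differs from source extent by more than one source cell")
  cen <- cell_centers(grid)
  tx <- grid$origin[1] + (seq_len(tc) - 0.5) * ts
  ty <- grid$origin[2] + (tr - seq_len(tr) + 0.5) * ts   # row 1 = top

  if (grid$kind == "continuous") {
    out <- .bilinear(grid$values, cen$x, cen$y, tx, ty)
  } else {
    out <- .majority_resample(grid$values, grid, tr, tc, ts, tx, ty)
  }
  raster_grid(out, ts, grid$origin, kind = grid$kind, codes = grid$codes)
}

# bilinear interpolation of matrix v (row 1 = top, centers sx/ sy with sy
# decreasing along rows) at the outer grid of points (ty_i, tx_j); NA-aware
# with weight renormalization.
.bilinear <- function(v, sx, sy, tx, ty) {
  nr <- nrow(v); nc <- ncol(v)
  # clamp target coords into the source-center hull
  txc <- pmin(pmax(tx, sx[1]), sx[nc])
  # sy runs from top (largest) down; clamp likewise
  tyc <- pmin(pmax(ty, sy[nr]), sy[1])
  # bracketing column indices
  j0 <- pmin(pmax(findInterval(txc, sx), 1L), nc - if (nc > 1L) 1L else 0L)
  if (nc == 1L) j0 <- rep(1L, length(txc))
  j1 <- pmin(j0 + 1L, nc)
  fx <- if (nc == 1L) rep(0, length(txc)) else (txc - sx[j0]) / (sx[j1] - sx[j0])
  fx[!is.finite(fx)] <- 0
  # rows: use descending y; index in ascending order then flip
  sy_asc <- rev(sy)                       # bottom-to-top
  i0a <- pmin(pmax(findInterval(tyc, sy_asc), 1L), nr - if (nr > 1L) 1L else 0L)
  if (nr == 1L) i0a <- rep(1L, length(tyc))
  i1a <- pmin(i0a + 1L, nr)
  fy <- if (nr == 1L) rep(0, length(tyc)) else
    (tyc - sy_asc[i0a]) / (sy_asc[i1a] - sy_asc[i0a])
  fy[!is.finite(fy)] <- 0
  r0 <- nr - i0a + 1L; r1 <- nr - i1a + 1L  # back to top-based rows

  out <- matrix(NA_real_, length(ty), length(tx))
  for (i in seq_along(ty)) {
    w00 <- (1 - fx) * (1 - fy[i]); w10 <- fx * (1 - fy[i])
    w01 <- (1 - fx) * fy[i];       w11 <- fx * fy[i]
    v00 <- v[cbind(r0[i], j0)]; v10 <- v[cbind(r0[i], j1)]
    v01 <- v[cbind(r1[i], j0)]; v11 <- v[cbind(r1[i], j1)]
    W <- rbind(w00, w10, w01, w11); V <- rbind(v00, v10, v01, v11)
    W[is.na(V)] <- 0; V[is.na(V)] <- 0
    tot <- colSums(W)
    val <- colSums(W * V) / tot
    val[tot == 0] <- NA_real_
    out[i, ] <- val
  }
  out
}

.majority_resample <- function(v, grid, tr, tc, ts, tx, ty) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, tr, tc)
  cen <- cell_centers(grid)
  # target cell index of every source cell center (half-open convention)
  scol <- floor((cen$x - grid$origin[1]) / ts) + 1L
  srow_fb <- floor((cen$y - grid$origin[2]) / ts) + 1L
  srow <- tr - srow_fb + 1L
  scol <- pmin(pmax(scol, 1L), tc); srow <- pmin(pmax(srow, 1L), tr)
  tgt_row <- matrix(srow, nr, nc)
  tgt_col <- matrix(scol, nr, nc, byrow = TRUE)
  idx <- (tgt_col - 1L) * tr + tgt_row      # linear target index per source cell
  vals <- as.vector(v); idxv <- as.vector(idx)
  keep <- !is.na(vals)
  if (any(keep)) {
    tb <- table(idxv[keep], vals[keep])
    codes <- as.numeric(colnames(tb))
    ord <- order(codes)                       # numeric order, not lexical
    tb <- tb[, ord, drop = FALSE]; codes <- codes[ord]
    cells <- as.integer(rownames(tb))
    # majority with lowest-code tie-break: which.max takes the first maximum
    win <- apply(tb, 1L, function(cnt) codes[which.max(cnt)])
    out[cells] <- win
  }
  # upsampling: target cells receiving no source center take the containing source cell
  empty <- which(is.na(out))
  if (length(empty)) {
    er <- ((empty - 1L) %% tr) + 1L; ec <- ((empty - 1L) %/% tr) + 1L
    ex <- grid$origin[1] + (ec - 0.5) * ts
    ey <- grid$origin[2] + (tr - er + 0.5) * ts
    out[empty] <- extract_at(grid, ex, ey)
  }
  out
}

#' Aggregate a fine land-cover grid to five primary classes
#'
#' Maps every fine code to one of exactly five primary codes, then (when
#' `factor > 1`) aggregates blocks of `factor x factor` fine cells by majority
#' vote over the mapped codes. Ties are broken deterministically by the lowest
#' primary code. With `factor = 1` only the code mapping is applied.
#'
#' @param fine categorical `sdm_grid`.
#' @param class_map named numeric vector: names are fine codes (as characters),
#'   values are primary codes. Exactly 5 distinct primary codes are required.
#' @param factor positive integer aggregation factor; grid dimensions must be
#'   divisible by it.
#' @return categorical `sdm_grid` on the five primary codes.
#' @export
aggregate_landcover <- function(fine, class_map, factor = 1L) {
  if (fine$kind != "categorical") stop("`fine` must be a categorical grid")
  primary <- sort(unique(as.numeric(class_map)))
  if (length(primary) != 5L) stop("class_map must target exactly 5 primary codes")
  present <- unique(as.vector(fine$values[!is.na(fine$values)]))
  unmapped <- setdiff(as.character(present), names(class_map))
  if (length(unmapped))
    stop("unmapped fine codes: ", paste(unmapped, collapse = ", "))
  mapped <- fine$values
  mapped[] <- unname(class_map[as.character(fine$values)])
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L)
    return(raster_grid(mapped, fine$cell_size, fine$origin, "categorical", primary))
  nr <- nrow(mapped); nc <- ncol(mapped)
  if (nr %% factor || nc %% factor)
    stop("grid dimensions must be divisible by the aggregation factor")
  tr <- nr %/% factor; tc <- nc %/% factor
  out <- matrix(NA_real_, tr, tc)
  for (i in seq_len(tr)) for (j in seq_len(tc)) {
    blk <- mapped[((i - 1L) * factor + 1L):(i * factor),
                  ((j - 1L) * factor + 1L):(j * factor)]
    blk <- blk[!is.na(blk)]
    if (!length(blk)) next
    cnt <- vapply(primary, function(p) sum(blk == p), 0L)
    out[i, j] <- primary[which.max(cnt)]   # first max -> lowest code
  }
  raster_grid(out, fine$cell_size * factor, fine$origin, "categorical", primary)
}
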