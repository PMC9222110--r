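#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`/
#' `xllcenter`, `yllcorner`/`yllcenter`, `cellsize`, optional `NODATA_value`)
#' followed by `nrows` rows of values, top row first.
#'
#' @param path file path.
#' @param kind passed to [raster_grid()].
#' @param codes passed to [raster_grid()] for categorical grids.
#' @return a `sdm_grid`.
#' @export
read_asc_grid <- function(path, kind = "continuous", codes = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); i <- i + 1L
    } else break
  }
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  if (is.null(ncols) || is.null(nrows)) stop("missing ncols/nrows header")
  cs <- hdr$cellsize
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  nodata <- hdr$nodata_value
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop(sprintf("expected %d values, found %d", nrows * ncols, length(vals)))
  m <- matrix(vals, nrows, ncols, byrow = TRUE)
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  raster_grid(m, cs, c(x0, y0), kind = kind, codes = codes)
}

#' Write an ESRI ASCII grid
#'
#' Values are written at full double precision (`%.15g`) so an ASCII
#' round-trip reproduces them exactly at printed precision.
#'
#' @param grid a `sdm_grid`.
#' @param path output path.
#' @param nodata value substituted for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1L, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read/write single-band TIFF rasters with a world file
#'
#' TIFF values are handled by the `tiff` package; the geometry travels in a
#' plain-text ESRI world file (`.tfw`) next to the image. Values are scaled
#' to the unit interval inside the TIFF and restored on read; the original
#' value range is stored in a `.range` text sidecar. CRS metadata is neither
#' read nor interpreted.
#'
#' @param grid a `sdm_grid`.
#' @param path path ending in `.tif`.
#' @return `path` (write) or a `sdm_grid` (read).
#' @export
write_tif_grid <- function(grid, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  v <- grid$values
  rng <- range(v, na.rm = TRUE)
  span <- if (diff(rng) > 0) diff(rng) else 1
  u <- (v - rng[1]) / span
  u[is.na(u)] <- 0
  mask <- is.na(v) * 1.0
  # values and nodata mask travel as two single-band pages
  tiff::writeTIFF(list(u, mask), path, bits.per.sample = 32L)
  nr <- nrow(v); s <- grid$cell_size
  tfw <- sub("\\.tif$", ".tfw", path)
  writeLines(sprintf("%.10g", c(s, 0, 0, -s,
                                grid$origin[1] + s / 2,
                                grid$origin[2] + (nr - 0.5) * s)), tfw)
  writeLines(sprintf("%.15g", rng), sub("\\.tif$", ".range", path))
  invisible(path)
}

#' @rdname write_tif_grid
#' @param kind,codes passed to [raster_grid()].
#' @export
read_tif_grid <- function(path, kind = "continuous", codes = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  a <- tiff::readTIFF(path, all = TRUE)
  tfw <- as.numeric(readLines(sub("\\.tif$", ".tfw", path)))
  rng <- as.numeric(readLines(sub("\\.tif$", ".range", path)))
  s <- tfw[1]; nr <- nrow(a[[1]])
  x0 <- tfw[5] - s / 2
  y0 <- tfw[6] - (nr - 0.5) * s
  span <- if (diff(rng) > 0) diff(rng) else 1
  v <- a[[1]] * span + rng[1]
  v[a[[2]] > 0.5] <- NA_real_
  raster_grid(v, s, c(x0, y0), kind = kind, codes = codes)
}
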