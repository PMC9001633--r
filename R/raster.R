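# Minimal gridded-raster container and headered-ASCII-grid I/O. Values are
# stored as a matrix with row 1 the southernmost row, aligned on the same
# half-open grid convention as the PAM module.

#' Create a climate raster
#'
#' @param values Numeric matrix, `n_rows x n_cols`, row 1 = southernmost
#'   row, column 1 = westernmost column. `NA` marks no-data cells.
#' @param grid A [grid_spec()] matching the matrix dimensions.
#' @param name Variable name (e.g. `"bio01"`).
#' @return A `climate_raster` object.
#' @export
climate_raster <- function(values, grid, name = "layer") {
  stopifnot(inherits(grid, "grid_spec"),
            is.matrix(values),
            nrow(values) == grid$n_rows,
            ncol(values) == grid$n_cols)
  structure(list(values = values, grid = grid, name = name),
            class = "climate_raster")
}

#' @export
print.climate_raster <- function(x, ...) {
  cat(sprintf("<climate_raster> '%s' %d x %d, range [%g, %g]\n",
              x$name, x$grid$n_rows, x$grid$n_cols,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Extract raster values at point coordinates
#'
#' @param raster A `climate_raster`.
#' @param lon,lat Coordinate vectors (decimal degrees).
#' @return Numeric vector; `NA` for points outside the grid or on no-data
#'   cells.
#' @export
raster_extract <- function(raster, lon, lat) {
  stopifnot(inherits(raster, "climate_raster"))
  g <- raster$grid
  cell <- point_to_cell_(g, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(cell)
  row <- (cell[ok] - 1L) %/% g$n_cols + 1L
  col <- (cell[ok] - 1L) %% g$n_cols + 1L
  out[ok] <- raster$values[cbind(row, col)]
  out
}

#' Read a headered ASCII grid (ESRI format)
#'
#' @param path File with `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#'   `cellsize`, optional `NODATA_value` header lines followed by rows of
#'   values ordered north to south.
#' @param name Variable name for the resulting raster.
#' @return A `climate_raster`.
#' @export
read_ascii_grid <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header incomplete; need ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid has ", length(vals), " values; expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE] # file is north-first
  grid <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$ncols, hdr$nrows,
                    hdr$cellsize)
  climate_raster(m, grid, name = name)
}

#' Write a raster as a headered ASCII grid
#'
#' @param raster A `climate_raster`.
#' @param path Output file path.
#' @param nodata Value used to encode `NA` cells.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "climate_raster"))
  g <- raster$grid
  m <- raster$values
  m[is.na(m)] <- nodata
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  hdr <- c(paste("ncols", g$n_cols), paste("nrows", g$n_rows),
           paste("xllcorner", format(g$lon_min, digits = 12)),
           paste("yllcorner", format(g$lat_min, digits = 12)),
           paste("cellsize", format(g$cell_size, digits = 12)),
           paste("NODATA_value", nodata))
  body <- apply(m, 1, function(r) paste(format(r, digits = 10, trim = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
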