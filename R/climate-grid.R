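#' Climate grid container
#'
#' A stack of environmental layers on a regular lat/lon grid, plus a
#' suitability mask. Layers are matrices with rows running north to south
#' (row 1 = northernmost), the raster convention.
#'
#' @param layers named list of numeric matrices, all with identical
#'   dimensions.
#' @param lat,lon numeric vectors of cell-center coordinates; \code{lat}
#'   descending (length = rows), \code{lon} ascending (length = cols).
#' @param mask logical matrix of the same shape; \code{TRUE} = suitable cell.
#'   Default: all cells suitable.
#' @param scenario free-text tag, conventionally \code{"current"} or
#'   \code{"future"}.
#' @return An object of class \code{climate_grid}.
#' @export
climate_grid <- function(layers, lat, lon, mask = NULL, scenario = "current") {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- dim(layers[[1]])
  for (l in layers) stopifnot(identical(dim(l), dims))
  stopifnot(length(lat) == dims[1], length(lon) == dims[2])
  if (is.unsorted(rev(lat)) || is.unsorted(lon)) {
    stop("lat must be descending and lon ascending (cell centers)")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  stopifnot(identical(dim(mask), dims), is.logical(mask))
  structure(list(layers = layers, lat = lat, lon = lon, mask = mask,
                 scenario = scenario),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid [%s]: %d x %d cells, %d layers (%s), %d suitable\n",
              x$scenario, nrow(x$mask), ncol(x$mask), length(x$layers),
              paste(names(x$layers), collapse = ", "), sum(x$mask)))
  invisible(x)
}

#' Extract unmasked cells as a table
#'
#' @param grid a \code{climate_grid}.
#' @return data.frame with \code{cell} (index into the matrix, column-major),
#'   \code{lat}, \code{lon}, and one column per layer; one row per suitable
#'   cell, ordered by cell index.
#' @export
grid_cells <- function(grid) {
  stopifnot(inherits(grid, "climate_grid"))
  idx <- which(grid$mask)
  rc <- arrayInd(idx, dim(grid$mask))
  out <- data.frame(cell = idx,
                    lat = grid$lat[rc[, 1]],
                    lon = grid$lon[rc[, 2]])
  for (v in names(grid$layers)) out[[v]] <- grid$layers[[v]][idx]
  out
}

#' Read / write a single layer as ESRI ASCII grid
#'
#' Plain-text raster interchange. \code{NODATA} cells become \code{NA} on
#' read; masked cells are written as \code{NODATA}.
#'
#' @param path file path.
#' @param grid a \code{climate_grid} (write) .
#' @param layer layer name to write.
#' @return \code{read_ascii_grid}: a list with \code{values} (matrix),
#'   \code{lat}, \code{lon}; \code{write_ascii_grid}: the path, invisibly.
#' @export
write_ascii_grid <- function(grid, layer, path) {
  stopifnot(inherits(grid, "climate_grid"), layer %in% names(grid$layers))
  m <- grid$layers[[layer]]
  m[!grid$mask] <- NA
  cs <- if (length(grid$lon) > 1) diff(grid$lon)[1] else 1
  if (length(grid$lat) > 1 && abs(abs(diff(grid$lat)[1]) - cs) > 1e-9) {
    stop("ESRI ASCII grids require square cells (lat/lon spacing equal)")
  }
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", min(grid$lon) - cs / 2),
           sprintf("yllcorner %.10g", min(grid$lat) - cs / 2),
           sprintf("cellsize %.10g", cs),
           "NODATA_value -9999")
  m[is.na(m)] <- -9999
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  nodata <- hdr[["nodata_value"]]
  if (!is.null(nodata)) vals[vals == nodata] <- NA
  cs <- hdr[["cellsize"]]
  lon <- hdr[["xllcorner"]] + cs / 2 + cs * (seq_len(hdr[["ncols"]]) - 1)
  lat <- hdr[["yllcorner"]] + cs / 2 + cs * (rev(seq_len(hdr[["nrows"]])) - 1)
  list(values = vals, lat = lat, lon = lon)
}
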