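#' Georeferenced single-band raster surface
#'
#' A minimal in-memory raster: a numeric matrix in the usual raster
#' orientation (row 1 = northern-most row) plus the affine pieces of an ESRI
#' ASCII grid header. Missing cells are stored as `NA`; the `nodata` sentinel
#' is used only when reading and writing files.
#'
#' @param grid numeric matrix (row 1 is the top/north row).
#' @param xll,yll coordinates of the lower-left corner of the grid (map units).
#' @param cellsize cell edge length in map units (default 70, the working
#'   resolution of the landscape surfaces).
#' @param nodata sentinel written to file for missing cells.
#' @param crs free-text coordinate reference label, carried as metadata only.
#' @return an object of class `raster_surface`.
#' @export
raster_surface <- function(grid, xll = 0, yll = 0, cellsize = 70,
                           nodata = -9999, crs = "unspecified") {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("`grid` must be a numeric matrix")
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("`cellsize` must be a positive number")
  structure(
    list(grid = grid, xll = xll, yll = yll, cellsize = cellsize,
         nodata = nodata, crs = crs),
    class = "raster_surface")
}

#' @export
print.raster_surface <- function(x, ...) {
  v <- x$grid[is.finite(x$grid)]
  cat(sprintf("raster_surface: %d x %d cells, cellsize %g, origin (%g, %g)\n",
              nrow(x$grid), ncol(x$grid), x$cellsize, x$xll, x$yll))
  cat(sprintf("  valid cells: %d/%d", length(v), length(x$grid)))
  if (length(v))
    cat(sprintf("; range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
dim.raster_surface <- function(x) dim(x$grid)

is_raster <- function(x) inherits(x, "raster_surface")

#' Check that two rasters share shape and georeference
#'
#' @param a,b `raster_surface` objects.
#' @param what label used in the error message.
#' @return invisibly `TRUE`; errors on mismatch.
#' @keywords internal
check_aligned <- function(a, b, what = "rasters") {
  if (!identical(dim(a$grid), dim(b$grid)))
    stop(sprintf("%s have mismatched shapes: %dx%d vs %dx%d", what,
                 nrow(a$grid), ncol(a$grid), nrow(b$grid), ncol(b$grid)))
  if (!isTRUE(all.equal(c(a$xll, a$yll, a$cellsize),
                        c(b$xll, b$yll, b$cellsize))))
    stop(sprintf("%s have mismatched georeferencing", what))
  invisible(TRUE)
}

#' Apply a function cellwise, keeping georeferencing
#'
#' `NA` cells propagate through `f` unless `f` handles them itself.
#'
#' @param x `raster_surface`.
#' @param f function taking and returning a numeric matrix/vector.
#' @return a new `raster_surface`.
#' @export
raster_apply <- function(x, f) {
  out <- f(x$grid)
  if (!identical(dim(out), dim(x$grid)))
    stop("cellwise function changed the grid shape")
  r <- x
  r$grid <- out
  r
}

#' Map plot coordinates to raster cells
#'
#' Cells are half-open on the right and bottom edges, so a point on the shared
#' boundary of two cells belongs to the cell to its left/above.
#'
#' @param surface `raster_surface`.
#' @param x,y map coordinates (vectors of equal length).
#' @return integer matrix with columns `row`, `col`; `NA` for points off the
#'   grid.
#' @export
cell_from_xy <- function(surface, x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  nr <- nrow(surface$grid); nc <- ncol(surface$grid)
  col <- floor((x - surface$xll) / surface$cellsize) + 1L
  ytop <- surface$yll + nr * surface$cellsize
  row <- floor((ytop - y) / surface$cellsize) + 1L
  # top and left boundary points are on the grid
  row[y == ytop] <- 1L
  col[x == surface$xll] <- 1L
  bad <- row < 1L | row > nr | col < 1L | col > nc
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line header (`ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize`, optional `nodata_value`) followed by
#' row-major cell values, north row first. Nodata cells become `NA`.
#'
#' @param path file path (`.asc`).
#' @return a `raster_surface`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[a-zA-Z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("%s: not an ESRI ASCII grid (header incomplete)", path))
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2 else 0
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop(sprintf("%s: expected %d cell values, found %d", path, nc * nr,
                 length(vals)))
  grid <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  grid[grid == nodata] <- NA_real_
  raster_surface(grid, xll = xll, yll = yll, cellsize = hdr$cellsize,
                 nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param surface `raster_surface`; `NA` cells are written as the surface's
#'   nodata sentinel.
#' @param path output path.
#' @param digits significant digits for cell values.
#' @return invisibly `path`.
#' @export
write_raster <- function(surface, path, digits = 10) {
  if (!is_raster(surface)) stop("`surface` must be a raster_surface")
  g <- surface$grid
  g[!is.finite(g)] <- surface$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", surface$xll),
    sprintf("yllcorner %.10g", surface$yll),
    sprintf("cellsize %.10g", surface$cellsize),
    sprintf("nodata_value %.10g", surface$nodata))
  body <- apply(g, 1, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Assemble co-registered rasters into a named stack
#'
#' @param surfaces named list of `raster_surface` objects.
#' @param variant flag carried on the stack (e.g. `"original"`, `"revised"`).
#' @return object of class `psd_stack`: the list plus the variant attribute.
#' @export
raster_stack <- function(surfaces, variant = "original") {
  if (!length(surfaces) || is.null(names(surfaces)) ||
      any(!nzchar(names(surfaces))))
    stop("`surfaces` must be a non-empty named list")
  if (!all(vapply(surfaces, is_raster, logical(1))))
    stop("all stack members must be raster_surface objects")
  nm <- names(surfaces)
  for (k in seq_along(surfaces)[-1])
    check_aligned(surfaces[[1]], surfaces[[k]],
                  sprintf("stack members '%s' and '%s'", nm[1], nm[k]))
  structure(surfaces, class = "psd_stack", variant = variant)
}

#' @export
print.psd_stack <- function(x, ...) {
  cat(sprintf("psd_stack (%s): %d layers [%s], %d x %d cells\n",
              attr(x, "variant"), length(x),
              paste(names(x), collapse = ", "),
              nrow(x[[1]]$grid), ncol(x[[1]]$grid)))
  invisible(x)
}
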