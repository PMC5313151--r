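#' Original (abiotic-only) potential species distribution
#'
#' Multiplicative combination of the three abiotic response surfaces: the
#' cellwise product of the light, soil-water and degree-day responses. A
#' cell that is nodata in any factor is nodata in the product.
#'
#' @param r_par,r_swc,r_gdd co-registered `raster_surface` objects with
#'   values in `[0, 1]`.
#' @return `raster_surface` of PSD values in `[0, 1]`.
#' @export
psd_original <- function(r_par, r_swc, r_gdd) {
  check_aligned(r_par, r_swc, "response surfaces (PAR vs SWC)")
  check_aligned(r_par, r_gdd, "response surfaces (PAR vs GDD)")
  for (s in list(r_par, r_swc, r_gdd)) {
    v <- s$grid[is.finite(s$grid)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("response surfaces must have values in [0, 1]")
  }
  out <- r_par
  out$grid <- r_par$grid * r_swc$grid * r_gdd$grid
  out
}

#' Competition-revised potential species distribution
#'
#' Weights each species' original PSD by its relative competitive rating
#' (P100) in the forestland type of each cell: `PSD_revised = P100[type,
#' species] * PSD_original`. Since P100 is in `[0, 1]`, the revised PSD can
#' never exceed the original. Cells without an assigned forestland type
#' become nodata.
#'
#' @param psd_orig `psd_stack` of per-species original PSD surfaces.
#' @param ratings `rating_matrix` (see [p100_matrix()]) whose columns cover
#'   every species in `psd_orig` and whose rows cover every type id present
#'   in `forestland`.
#' @param forestland `raster_surface` of integer forestland-type ids
#'   (row indices into `ratings`).
#' @return `psd_stack` with variant `"revised"`.
#' @export
psd_revised <- function(psd_orig, ratings, forestland) {
  stopifnot(inherits(psd_orig, "psd_stack"), inherits(ratings, "rating_matrix"))
  check_aligned(psd_orig[[1]], forestland, "PSD stack and forestland map")
  type_ids <- sort(unique(as.vector(forestland$grid)))
  type_ids <- type_ids[is.finite(type_ids)]
  if (any(type_ids < 1 | type_ids > nrow(ratings) | type_ids != round(type_ids)))
    stop(sprintf("forestland type id(s) missing from ratings: %s",
                 paste(type_ids[type_ids < 1 | type_ids > nrow(ratings) |
                                  type_ids != round(type_ids)],
                       collapse = ", ")))
  miss <- setdiff(names(psd_orig), colnames(ratings))
  if (length(miss))
    stop(sprintf("species missing from ratings: %s",
                 paste(miss, collapse = ", ")))
  tmat <- forestland$grid
  out <- lapply(names(psd_orig), function(k) {
    w <- matrix(NA_real_, nrow(tmat), ncol(tmat))
    ok <- is.finite(tmat)
    w[ok] <- ratings[tmat[ok], k]
    r <- psd_orig[[k]]
    r$grid <- w * r$grid
    r
  })
  names(out) <- names(psd_orig)
  raster_stack(out, variant = "revised")
}

#' Classify a suitability surface into quality classes
#'
#' Three-way split of a PSD surface: `low` below `low_cut`, `moderate` in
#' `[low_cut, high_cut)`, `high` at or above `high_cut`. Defaults align the
#' low/moderate boundary with the 0.25 presence threshold.
#'
#' @param psd `raster_surface` with values in `[0, 1]`.
#' @param low_cut,high_cut class boundaries, `0 <= low_cut < high_cut <= 1`.
#' @return `raster_surface` of codes 1 (low), 2 (moderate), 3 (high), with a
#'   `levels` attribute `c("low", "moderate", "high")`.
#' @export
classify_site_quality <- function(psd, low_cut = 0.25, high_cut = 0.5) {
  if (!(low_cut >= 0 && low_cut < high_cut && high_cut <= 1))
    stop("need 0 <= low_cut < high_cut <= 1")
  out <- raster_apply(psd, function(g) {
    cls <- ifelse(g < low_cut, 1, ifelse(g < high_cut, 2, 3))
    dim(cls) <- dim(g)
    cls
  })
  attr(out, "levels") <- c("low", "moderate", "high")
  out
}

#' Area fractions of a categorical raster
#'
#' @param categorical `raster_surface` of integer class codes, optionally
#'   with a `levels` attribute naming the codes.
#' @return named numeric vector of fractions over valid cells (sums to 1).
#' @export
area_fraction_summary <- function(categorical) {
  v <- as.vector(categorical$grid)
  v <- v[is.finite(v)]
  if (!length(v)) stop("raster has no valid cells")
  tab <- table(v)
  fr <- as.numeric(tab) / length(v)
  codes <- as.integer(names(tab))
  lv <- attr(categorical, "levels")
  names(fr) <- if (!is.null(lv) && all(codes >= 1 & codes <= length(lv)))
    lv[codes] else as.character(codes)
  fr
}
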