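#' Species response-kernel parameters
#'
#' Bundles the parameters of the three abiotic response functions for one
#' species: the light response (scaling factor `c1`, slope `c2`, compensation
#' point `cp` on the normalized PAR scale), the unimodal soil-water response
#' (`swc_min`, `swc_max` tolerance limits and optimum `psi`, all on the 0-1
#' wilting-point-to-field-capacity scale), and the parabolic growing
#' degree-day response (`gdd_min`, `gdd_max` in degree-days, the northern and
#' southern tolerance limits). `shade_tolerance_class` is an ordinal 1
#' (least shade tolerant) to 5 (most tolerant).
#'
#' @param species_code short species label, e.g. `"bF"`.
#' @param c1 dimensionless scaling factor of the light response (> 0).
#' @param c2 slope of the light response, per unit nPAR (> 0).
#' @param cp light compensation point, nPAR units in `[0, 1)`.
#' @param swc_min,swc_max lower/upper soil-water tolerance limits (0-1).
#' @param psi optimal soil water content, strictly between the limits.
#' @param gdd_min,gdd_max degree-day tolerance limits, `0 <= gdd_min < gdd_max`.
#' @param shade_tolerance_class integer 1-5.
#' @return object of class `species_params`.
#' @export
species_params <- function(species_code, c1, c2, cp, swc_min, swc_max, psi,
                           gdd_min, gdd_max, shade_tolerance_class = 3L) {
  stopifnot(is.character(species_code), length(species_code) == 1L)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("%s: `%s` must be a single finite number", species_code, nm))
    as.numeric(x)
  }
  c1 <- num1(c1, "c1"); c2 <- num1(c2, "c2"); cp <- num1(cp, "cp")
  swc_min <- num1(swc_min, "swc_min"); swc_max <- num1(swc_max, "swc_max")
  psi <- num1(psi, "psi")
  gdd_min <- num1(gdd_min, "gdd_min"); gdd_max <- num1(gdd_max, "gdd_max")
  if (c1 <= 0) stop(sprintf("%s: c1 must be > 0", species_code))
  if (c2 <= 0) stop(sprintf("%s: c2 must be > 0", species_code))
  if (cp < 0 || cp >= 1) stop(sprintf("%s: cp must be in [0, 1)", species_code))
  if (!(0 <= swc_min && swc_min < psi && psi < swc_max && swc_max <= 1))
    stop(sprintf("%s: need 0 <= swc_min < psi < swc_max <= 1", species_code))
  if (!(gdd_min >= 0 && gdd_min < gdd_max))
    stop(sprintf("%s: need 0 <= gdd_min < gdd_max", species_code))
  stc <- as.integer(shade_tolerance_class)
  if (is.na(stc) || !(stc %in% 1:5))
    stop(sprintf("%s: shade_tolerance_class must be in 1..5", species_code))
  structure(
    list(species_code = species_code, c1 = c1, c2 = c2, cp = cp,
         swc_min = swc_min, swc_max = swc_max, psi = psi,
         gdd_min = gdd_min, gdd_max = gdd_max, shade_tolerance_class = stc),
    class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat(sprintf(
    "species_params %s: light (c1=%g, c2=%g, cp=%g), SWC [%g, %g] opt %g,\n",
    x$species_code, x$c1, x$c2, x$cp, x$swc_min, x$swc_max, x$psi))
  cat(sprintf("  GDD [%g, %g], shade tolerance class %d\n",
              x$gdd_min, x$gdd_max, x$shade_tolerance_class))
  invisible(x)
}

#' Derived shape constants of the soil-water response
#'
#' The unimodal soil-water kernel is `kappa * xi^alpha * (1-xi)^(1/alpha)`
#' on the normalized position `xi`. `chi` is the normalized position of the
#' optimum; `alpha = chi/(1-chi)` makes the mode fall at `chi`, and `kappa`
#' normalizes the mode to exactly 1.
#'
#' @param params `species_params`.
#' @return list with `chi`, `alpha`, `kappa_norm`.
#' @export
swc_shape <- function(params) {
  chi <- (params$psi - params$swc_min) / (params$swc_max - params$swc_min)
  alpha <- chi / (1 - chi)
  kappa_norm <- 1 / (chi^alpha * (1 - chi)^(1 / alpha))
  list(chi = chi, alpha = alpha, kappa_norm = kappa_norm)
}

# keeps dim attributes: first argument of pmax/pmin carries them
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Growing degree days from a daily temperature series
#'
#' Seasonal accumulation of the daily mean-temperature excess over a base
#' threshold: `sum(max(0, T_avg - t_base))`.
#'
#' @param temps numeric vector of mean daily temperatures (deg C) over the
#'   growing season.
#' @param t_base base temperature threshold (deg C), default 5.
#' @return accumulated degree-days (deg C day), >= 0.
#' @export
growing_degree_days <- function(temps, t_base = 5) {
  if (length(temps) == 0L) stop("temperature series is empty")
  if (!is.numeric(temps) || any(!is.finite(temps)))
    stop("temperature series contains non-finite values")
  if (!is.finite(t_base)) stop("t_base must be finite")
  sum(pmax(0, temps - t_base))
}

#' Light response kernel
#'
#' Saturating exponential response to normalized PAR:
#' `c1 * (1 - exp(-c2 * (npar - cp)))`, clamped to `[0, 1]` so the index
#' never leaves the suitability scale (the raw curve is negative below the
#' compensation point and exceeds 1 for `c1 > 1`).
#'
#' @param npar normalized PAR in `[0, 1]`: numeric vector/matrix or
#'   `raster_surface`. `NA` cells propagate.
#' @param params `species_params` (or any list with `c1`, `c2`, `cp`).
#' @return same shape as `npar`, values in `[0, 1]`.
#' @export
response_par <- function(npar, params) {
  if (params$c2 <= 0) stop("c2 must be > 0")
  f <- function(x) clamp01(params$c1 * (1 - exp(-params$c2 * (x - params$cp))))
  if (is_raster(npar)) raster_apply(npar, f) else f(npar)
}

#' Soil-water response kernel
#'
#' Unimodal beta-shaped response on the normalized soil-water position
#' `xi = (swc - swc_min)/(swc_max - swc_min)`; zero at and beyond both
#' tolerance limits, exactly 1 at the optimum `psi`.
#'
#' @param swc soil water content in `[0, 1]`: vector/matrix or
#'   `raster_surface`. `NA` cells propagate.
#' @param params `species_params`.
#' @return same shape as `swc`, values in `[0, 1]`.
#' @export
response_swc <- function(swc, params) {
  sh <- swc_shape(params)
  f <- function(x) {
    xi <- (x - params$swc_min) / (params$swc_max - params$swc_min)
    r <- ifelse(is.na(xi) | xi <= 0 | xi >= 1, ifelse(is.na(xi), NA_real_, 0),
                sh$kappa_norm * xi^sh$alpha * (1 - xi)^(1 / sh$alpha))
    out <- clamp01(r)
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  if (is_raster(swc)) raster_apply(swc, f) else f(swc)
}

#' Growing degree-day response kernel
#'
#' Symmetric parabola between the two degree-day tolerance limits:
#' `4 (gdd - gdd_min)(gdd_max - gdd) / (gdd_max - gdd_min)^2`, clamped to
#' `[0, 1]`; 1 at the midpoint, 0 at and beyond the limits.
#'
#' @param gdd degree-days: vector/matrix or `raster_surface`. `NA`
#'   cells propagate.
#' @param params `species_params`.
#' @return same shape as `gdd`, values in `[0, 1]`.
#' @export
response_gdd <- function(gdd, params) {
  if (params$gdd_min >= params$gdd_max) stop("need gdd_min < gdd_max")
  rng2 <- (params$gdd_max - params$gdd_min)^2
  f <- function(x)
    clamp01(4 * (x - params$gdd_min) * (params$gdd_max - x) / rng2)
  if (is_raster(gdd)) raster_apply(gdd, f) else f(gdd)
}

#' Light-curve archetypes by shade-tolerance class
#'
#' Classic gap-model light curves: the most shade-tolerant class saturates
#' quickly from a low compensation point (`c1 = 1, c2 = 4.64, cp = 0.05`),
#' the least tolerant class rises slowly from a higher compensation point
#' (`c1 = 2.24, c2 = 1.136, cp = 0.08`); intermediate classes interpolate
#' linearly. Output of the resulting response is clamped to `[0, 1]`.
#'
#' @param tolerance_class integer 1 (least tolerant) to 5 (most tolerant).
#' @return list with `c1`, `c2`, `cp`.
#' @export
light_archetype <- function(tolerance_class) {
  tc <- as.integer(tolerance_class)
  if (is.na(tc) || !(tc %in% 1:5))
    stop("tolerance_class must be an integer in 1..5")
  w <- (tc - 1) / 4                      # 0 = least tolerant, 1 = most
  list(c1 = 2.24 + w * (1 - 2.24),
       c2 = 1.136 + w * (4.64 - 1.136),
       cp = 0.08 + w * (0.05 - 0.08))
}

#' Read and validate a species kernel-parameter table
#'
#' CSV with one row per species and columns exactly matching the
#' [species_params()] fields. Every row is validated; errors cite the
#' offending line.
#'
#' @param path CSV file path.
#' @return named list of `species_params`, keyed by species code.
#' @export
read_species_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_code", "c1", "c2", "cp", "swc_min", "swc_max", "psi",
            "gdd_min", "gdd_max", "shade_tolerance_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      species_params(df$species_code[i], df$c1[i], df$c2[i], df$cp[i],
                     df$swc_min[i], df$swc_max[i], df$psi[i],
                     df$gdd_min[i], df$gdd_max[i],
                     df$shade_tolerance_class[i]),
      error = function(e)
        stop(sprintf("%s line %d: %s", path, i + 1L, conditionMessage(e)),
             call. = FALSE))
  }
  names(out) <- df$species_code
  if (anyDuplicated(names(out)))
    stop(sprintf("%s: duplicated species codes", path))
  out
}

#' Write a species kernel-parameter table
#'
#' @param params_list named list of `species_params`.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_species_params <- function(params_list, path) {
  df <- do.call(rbind, lapply(params_list, function(p)
    data.frame(species_code = p$species_code, c1 = p$c1, c2 = p$c2, cp = p$cp,
               swc_min = p$swc_min, swc_max = p$swc_max, psi = p$psi,
               gdd_min = p$gdd_min, gdd_max = p$gdd_max,
               shade_tolerance_class = p$shade_tolerance_class)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
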