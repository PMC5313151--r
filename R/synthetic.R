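#' Synthetic-landscape scenario
#'
#' Describes the study conditions of a fully synthetic test landscape:
#' grid size, cell size, the value range of each abiotic surface, the
#' spatial autocorrelation length of the generated fields, the number of
#' species and observation plots, the plot observation-noise rate and the
#' master seed. All generators are pure functions of the scenario and its
#' seed.
#'
#' @param nrow,ncol grid dimensions in cells (default 200 x 200).
#' @param cellsize cell edge length in map units (default 70).
#' @param gdd_range range of the degree-day surface (default 900-2500).
#' @param autocorr_length Gaussian smoothing length in cells (default 10).
#' @param n_species number of synthetic species (default 16).
#' @param n_plots number of observation plots (default 1240).
#' @param noise_rate probability that an observed presence/absence flag is
#'   flipped relative to truth (`[0, 0.5)`, default 0).
#' @param seed master RNG seed.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(nrow = 200, ncol = 200, cellsize = 70,
                               gdd_range = c(900, 2500),
                               autocorr_length = 10, n_species = 16,
                               n_plots = 1240, noise_rate = 0, seed = 1) {
  if (nrow < 2 || ncol < 2) stop("grid must be at least 2 x 2")
  if (autocorr_length >= min(nrow, ncol))
    stop("autocorrelation length must be smaller than the grid")
  if (autocorr_length < 0) stop("autocorrelation length must be >= 0")
  if (!(noise_rate >= 0 && noise_rate < 0.5))
    stop("noise_rate must be in [0, 0.5)")
  if (gdd_range[1] >= gdd_range[2] || gdd_range[1] < 0)
    stop("invalid gdd_range")
  if (n_species < 1) stop("n_species must be >= 1")
  if (n_plots < 0) stop("n_plots must be >= 0")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 cellsize = cellsize, gdd_range = gdd_range,
                 autocorr_length = autocorr_length,
                 n_species = as.integer(n_species),
                 n_plots = as.integer(n_plots),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# separable Gaussian smoothing with reflected edges
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-half:half, sd = sigma)
  g <- g / sum(g)
  reflect_idx <- function(i, n) {
    j <- (i - 1L) %% (2L * n - 2L)
    ifelse(j < n, j + 1L, 2L * n - 1L - j)
  }
  smooth_vec <- function(v) {
    n <- length(v)
    pad <- v[reflect_idx((1L - half):(n + half), n)]
    stats::convolve(pad, g, type = "filter")
  }
  m2 <- apply(m, 2, smooth_vec)
  t(apply(t(m2), 2, smooth_vec))
}

rescale_range <- function(m, lo, hi) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Generate spatially autocorrelated abiotic surfaces
#'
#' Seeded white noise smoothed with a separable Gaussian kernel of standard
#' deviation `autocorr_length` cells, rescaled affinely to each variable's
#' range: nPAR and SWC to `[0, 1]`, GDD to the scenario's degree-day range.
#' The three fields use distinct, seed-derived noise streams.
#'
#' @param scenario `synthetic_scenario`.
#' @return named list of `raster_surface`: `npar`, `swc`, `gdd`.
#' @export
generate_surfaces <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  make_field <- function(sub_seed, lo, hi) {
    set.seed(scenario$seed + sub_seed)
    noise <- matrix(stats::rnorm(scenario$nrow * scenario$ncol),
                    scenario$nrow, scenario$ncol)
    sm <- gaussian_smooth(noise, scenario$autocorr_length)
    raster_surface(rescale_range(sm, lo, hi), cellsize = scenario$cellsize)
  }
  list(npar = make_field(101L, 0, 1),
       swc = make_field(202L, 0, 1),
       gdd = make_field(303L, scenario$gdd_range[1], scenario$gdd_range[2]))
}

#' Generate a synthetic species-parameter set
#'
#' Draws `n_species` kernel and growth parameter sets honouring every type
#' invariant. Shade-tolerance classes are balanced by cycling 1..5; light
#' curves follow the class archetype with small jitter; soil-water and
#' degree-day windows are drawn wide enough that most species' windows
#' overlap the scenario's degree-day range. More shade-tolerant species
#' receive slower intrinsic growth and longer life spans, the classic
#' successional trade-off.
#'
#' @param n_species number of species.
#' @param seed RNG seed.
#' @param gdd_range degree-day range the windows should straddle
#'   (default `c(900, 2500)`).
#' @return list with `kernel` (named list of [species_params()]) and
#'   `growth` (named list of [growth_params()]).
#' @export
generate_species_params <- function(n_species, seed = 1,
                                    gdd_range = c(900, 2500)) {
  if (n_species < 1) stop("n_species must be >= 1")
  set.seed(seed + 7L)
  codes <- sprintf("sp%02d", seq_len(n_species))
  classes <- rep(1:5, length.out = n_species)
  kernel <- list(); growth <- list()
  for (i in seq_len(n_species)) {
    arch <- light_archetype(classes[i])
    c1 <- max(arch$c1 * stats::runif(1, 0.9, 1.1), 0.9)
    c2 <- arch$c2 * stats::runif(1, 0.9, 1.1)
    cp <- min(max(arch$cp + stats::runif(1, -0.02, 0.02), 0), 0.2)
    swc_min <- stats::runif(1, 0, 0.25)
    swc_max <- stats::runif(1, 0.75, 1)
    psi <- stats::runif(1, swc_min + 0.15, swc_max - 0.15)
    span <- diff(gdd_range)
    g_lo <- stats::runif(1, gdd_range[1] - 0.4 * span, gdd_range[1] + 0.4 * span)
    g_hi <- g_lo + stats::runif(1, 0.8 * span, 1.6 * span)
    g_lo <- max(0, g_lo)
    kernel[[codes[i]]] <- species_params(
      codes[i], c1, c2, cp, swc_min, swc_max, psi, g_lo, g_hi, classes[i])
    w <- (classes[i] - 1) / 4   # 1 for most tolerant
    growth[[codes[i]]] <- growth_params(
      codes[i],
      g_growth = stats::runif(1, 0.9, 1.1) * (260 - 140 * w),
      d_max = stats::runif(1, 40, 80),
      h_max = stats::runif(1, 2000, 3200),
      age_max = (80 + 260 * w) * stats::runif(1, 0.9, 1.1),
      shade_tolerance_class = classes[i],
      gdd_min = g_lo, gdd_max = g_hi,
      swc_min = swc_min, swc_max = swc_max, psi = psi,
      biomass_a = stats::runif(1, 0.05, 0.15),
      biomass_b = stats::runif(1, 2.2, 2.6),
      recruit_rate = stats::runif(1, 0.5, 2))
  }
  list(kernel = kernel, growth = growth)
}

#' Generate plot observations from a truth PSD stack
#'
#' Samples plot locations uniformly without replacement over valid cells,
#' derives true presence per species by thresholding the truth PSD, and
#' flips each observed flag independently with probability `noise_rate`.
#' The noise-free truth is retained for tests.
#'
#' @param scenario `synthetic_scenario` (supplies `n_plots`, `noise_rate`
#'   and the seed).
#' @param true_psd `psd_stack` regarded as the true suitability.
#' @param threshold presence threshold (default 0.25).
#' @return list: `plots` (data frame: `plot_id`, `x`, `y`, one 0/1 column
#'   per species) and `truth` (same layout, noise-free).
#' @export
generate_plots <- function(scenario, true_psd, threshold = 0.25) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(true_psd, "psd_stack"))
  tmpl <- true_psd[[1]]
  valid <- which(Reduce(`&`, lapply(true_psd, function(s) is.finite(s$grid))))
  if (scenario$n_plots > length(valid))
    stop("more plots requested than valid cells")
  set.seed(scenario$seed + 404L)
  cells <- sample(valid, scenario$n_plots)
  rows <- (cells - 1L) %% nrow(tmpl$grid) + 1L
  cols <- (cells - 1L) %/% nrow(tmpl$grid) + 1L
  # plot coordinates at cell centres
  x <- tmpl$xll + (cols - 0.5) * tmpl$cellsize
  y <- tmpl$yll + (nrow(tmpl$grid) - rows + 0.5) * tmpl$cellsize
  base <- data.frame(plot_id = sprintf("p%04d", seq_along(cells)),
                     x = x, y = y, stringsAsFactors = FALSE)
  truth <- base; plots <- base
  for (k in names(true_psd)) {
    tp <- as.integer(true_psd[[k]]$grid[cbind(rows, cols)] > threshold)
    flip <- stats::runif(length(tp)) < scenario$noise_rate
    truth[[k]] <- tp
    plots[[k]] <- ifelse(flip, 1L - tp, tp)
  }
  list(plots = plots, truth = truth)
}

#' Generate a random initial stand
#'
#' Uniform random species identities and diameters; deterministic given
#' the seed.
#'
#' @param species_codes character vector of candidate species.
#' @param n_trees number of individuals (>= 0).
#' @param dbh_range diameter range in cm (default `c(1, 10)`).
#' @param seed RNG seed.
#' @return a `stand` data frame.
#' @export
generate_initial_stand <- function(species_codes, n_trees,
                                   dbh_range = c(1, 10), seed = 1) {
  if (n_trees < 0) stop("n_trees must be >= 0")
  if (dbh_range[1] <= 0 || dbh_range[1] > dbh_range[2])
    stop("invalid dbh_range")
  set.seed(seed + 505L)
  if (n_trees == 0) return(make_stand())
  make_stand(sample(species_codes, n_trees, replace = TRUE),
             stats::runif(n_trees, dbh_range[1], dbh_range[2]))
}
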