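#' Species growth parameters for the gap model
#'
#' Parameters of the JABOWA-family individual-tree model: the intrinsic
#' growth rate `g_growth` of the diameter growth equation, maximum diameter
#' `d_max` (cm) and height `h_max` (cm), maximum age (years, sets the
#' intrinsic mortality rate `4/age_max`), the shade-tolerance class driving
#' the light response under canopy, the degree-day tolerance window (shared
#' with the distribution kernels), power-law biomass allometry
#' `AGB = biomass_a * dbh^biomass_b` (kg, dbh in cm), soil-water tolerance
#' used as an establishment filter and growth multiplier, and the expected
#' sapling recruitment rate per plot-year.
#'
#' @param species_code short species label.
#' @param g_growth intrinsic growth rate (cm units of the growth equation).
#' @param d_max maximum diameter at breast height (cm, > 0).
#' @param h_max maximum height (cm, > 137).
#' @param age_max maximum age (years, > 0).
#' @param shade_tolerance_class integer 1-5 (5 = most tolerant).
#' @param gdd_min,gdd_max degree-day tolerance limits.
#' @param swc_min,swc_max,psi soil-water tolerance limits and optimum (0-1).
#' @param biomass_a,biomass_b allometric coefficients (`biomass_b > 1`).
#' @param recruit_rate expected new saplings per plot-year when eligible.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(species_code, g_growth, d_max, h_max, age_max,
                          shade_tolerance_class, gdd_min, gdd_max,
                          swc_min = 0.05, swc_max = 0.95, psi = 0.5,
                          biomass_a = 0.1, biomass_b = 2.4,
                          recruit_rate = 1) {
  stopifnot(is.character(species_code), length(species_code) == 1L)
  if (d_max <= 0) stop(sprintf("%s: d_max must be > 0", species_code))
  if (h_max <= 137)
    stop(sprintf("%s: h_max must exceed breast height (137 cm)", species_code))
  if (age_max <= 0) stop(sprintf("%s: age_max must be > 0", species_code))
  if (g_growth <= 0) stop(sprintf("%s: g_growth must be > 0", species_code))
  if (biomass_b <= 1) stop(sprintf("%s: biomass_b must be > 1", species_code))
  if (!(gdd_min >= 0 && gdd_min < gdd_max))
    stop(sprintf("%s: need 0 <= gdd_min < gdd_max", species_code))
  if (!(0 <= swc_min && swc_min < psi && psi < swc_max && swc_max <= 1))
    stop(sprintf("%s: need 0 <= swc_min < psi < swc_max <= 1", species_code))
  stc <- as.integer(shade_tolerance_class)
  if (is.na(stc) || !(stc %in% 1:5))
    stop(sprintf("%s: shade_tolerance_class must be in 1..5", species_code))
  if (recruit_rate < 0) stop(sprintf("%s: recruit_rate must be >= 0",
                                     species_code))
  structure(
    list(species_code = species_code, g_growth = g_growth, d_max = d_max,
         h_max = h_max, age_max = age_max, shade_tolerance_class = stc,
         gdd_min = gdd_min, gdd_max = gdd_max,
         swc_min = swc_min, swc_max = swc_max, psi = psi,
         biomass_a = biomass_a, biomass_b = biomass_b,
         recruit_rate = recruit_rate),
    class = "growth_params")
}

#' Site conditions for a gap-model plot
#'
#' @param gdd growing degree-days at the site (deg C day).
#' @param swc soil water content (0-1).
#' @param nutrient_index soil-fertility multiplier (0-1, 1 = no limitation).
#' @param plot_area patch area in square metres (default 100, the classic
#'   gap-model plot).
#' @return object of class `site_conditions`.
#' @export
site_conditions <- function(gdd, swc, nutrient_index = 1, plot_area = 100) {
  if (!is.finite(gdd) || gdd < 0) stop("gdd must be finite and >= 0")
  if (!is.finite(swc) || swc < 0 || swc > 1) stop("swc must be in [0, 1]")
  if (!is.finite(nutrient_index) || nutrient_index < 0 || nutrient_index > 1)
    stop("nutrient_index must be in [0, 1]")
  if (plot_area <= 0) stop("plot_area must be > 0")
  structure(list(gdd = gdd, swc = swc, nutrient_index = nutrient_index,
                 plot_area = plot_area), class = "site_conditions")
}

#' Create a stand of individual trees
#'
#' A stand is a data frame with one row per tree: `species_code`, `dbh`
#' (cm), `age` (years) and `slow_years` (consecutive years of sub-threshold
#' growth, drives stress mortality).
#'
#' @param species_code character vector of species labels (may be empty).
#' @param dbh diameters at breast height (cm, > 0).
#' @param age ages in years (default 0).
#' @return a `stand` data frame.
#' @export
make_stand <- function(species_code = character(), dbh = numeric(),
                       age = rep(0, length(dbh))) {
  if (length(species_code) != length(dbh))
    stop("species_code and dbh must have equal length")
  if (any(dbh <= 0)) stop("all dbh must be > 0")
  structure(data.frame(species_code = as.character(species_code),
                       dbh = as.numeric(dbh), age = as.numeric(age),
                       slow_years = rep(0L, length(dbh)),
                       stringsAsFactors = FALSE),
            class = c("stand", "data.frame"))
}

#' Tree height from diameter
#'
#' Parabolic gap-model allometry `H = 137 + b2 * dbh - b3 * dbh^2` with
#' `b2 = 2 (h_max - 137) / d_max` and `b3 = (h_max - 137) / d_max^2`, so
#' height is exactly 137 cm (breast height) at dbh 0 and exactly `h_max`
#' at `d_max`.
#'
#' @param dbh diameter(s) at breast height (cm, > 0).
#' @param params `growth_params`.
#' @return height(s) in cm.
#' @export
height_from_dbh <- function(dbh, params) {
  if (any(dbh <= 0)) stop("dbh must be > 0")
  b2 <- 2 * (params$h_max - 137) / params$d_max
  b3 <- (params$h_max - 137) / params$d_max^2
  137 + b2 * dbh - b3 * dbh^2
}

#' Optimal annual diameter increment
#'
#' The gap-model growth equation under no resource limitation:
#' `ddbh = g * dbh * (1 - dbh * H / (d_max * h_max)) /
#' (274 + 3 b2 dbh - 4 b3 dbh^2)`, floored at zero. The increment vanishes
#' as the tree approaches its maximum size.
#'
#' @param dbh diameter(s) (cm, > 0).
#' @param params `growth_params`.
#' @return increment(s) in cm/yr, >= 0.
#' @export
optimal_increment <- function(dbh, params) {
  if (any(dbh <= 0)) stop("dbh must be > 0")
  b2 <- 2 * (params$h_max - 137) / params$d_max
  b3 <- (params$h_max - 137) / params$d_max^2
  h <- 137 + b2 * dbh - b3 * dbh^2
  num <- params$g_growth * dbh * (1 - dbh * h / (params$d_max * params$h_max))
  den <- 274 + 3 * b2 * dbh - 4 * b3 * dbh^2
  pmax(0, num / den)
}

#' Light multiplier under canopy shading
#'
#' Available light at a tree's crown follows Beer-Lambert extinction through
#' the leaf area above it, `AL = exp(-k * LAI_above)`; the growth multiplier
#' is the shade-tolerance-class light curve evaluated at `AL` (see
#' [light_archetype()]).
#'
#' @param cum_lai_above cumulative leaf-area index of strictly taller trees.
#' @param tolerance_class shade-tolerance class 1-5.
#' @param extinction_k canopy light-extinction coefficient per unit LAI
#'   (default 0.4).
#' @return multiplier in `[0, 1]`.
#' @export
light_multiplier <- function(cum_lai_above, tolerance_class,
                             extinction_k = 0.4) {
  if (extinction_k <= 0) stop("extinction_k must be > 0")
  if (any(cum_lai_above < 0)) stop("cum_lai_above must be >= 0")
  al <- exp(-extinction_k * cum_lai_above)
  arch <- light_archetype(tolerance_class)
  response_par(al, arch)
}

#' Aboveground biomass of a tree
#'
#' Power-law allometry `AGB = biomass_a * dbh^biomass_b` (kg, dbh in cm).
#'
#' @param dbh diameter(s) (cm, > 0).
#' @param params `growth_params`.
#' @return biomass in kg.
#' @export
aboveground_biomass <- function(dbh, params) {
  if (any(dbh <= 0)) stop("dbh must be > 0")
  params$biomass_a * dbh^params$biomass_b
}

# per-tree leaf area index contribution on the plot
tree_lai <- function(dbh, plot_area, leaf_area_coeff) {
  leaf_area_coeff * dbh^2 / plot_area
}

lookup_params <- function(stand, params_table) {
  unknown <- setdiff(unique(stand$species_code), names(params_table))
  if (length(unknown))
    stop(sprintf("unknown species in stand: %s",
                 paste(unknown, collapse = ", ")))
  invisible(TRUE)
}

pt_field <- function(params_table, codes, field) {
  vapply(params_table[codes], function(p) as.numeric(p[[field]]), numeric(1))
}

#' One year of diameter growth with light competition
#'
#' Each tree's realized increment is the optimal increment scaled by four
#' multipliers: the light multiplier from Beer-Lambert shading by all
#' strictly taller trees, the degree-day and soil-water responses at the
#' site, and the nutrient index. Trees growing less than `slow_threshold`
#' accumulate `slow_years`; a good year resets the counter. Ages advance by
#' one year and diameters are capped at `d_max`.
#'
#' @param stand a `stand` data frame.
#' @param site `site_conditions`.
#' @param params_table named list of `growth_params` keyed by species code.
#' @param leaf_area_coeff leaf area (m^2) per cm^2 of squared diameter
#'   (default 0.16).
#' @param extinction_k canopy light-extinction coefficient (default 0.4).
#' @param slow_threshold slow-growth threshold (cm/yr, default 0.01).
#' @return the updated `stand`.
#' @export
annual_growth_step <- function(stand, site, params_table,
                               leaf_area_coeff = 0.16, extinction_k = 0.4,
                               slow_threshold = 0.01) {
  if (nrow(stand) == 0L) return(stand)
  lookup_params(stand, params_table)
  codes <- stand$species_code
  h <- numeric(nrow(stand))
  for (k in unique(codes)) {
    i <- codes == k
    h[i] <- height_from_dbh(pmin(stand$dbh[i], params_table[[k]]$d_max),
                            params_table[[k]])
  }
  lai <- tree_lai(stand$dbh, site$plot_area, leaf_area_coeff)
  ord <- order(h, decreasing = TRUE)
  lai_above_sorted <- cumsum(c(0, lai[ord][-length(ord)]))
  # ties in height shade each other equally: use the LAI of strictly taller
  # trees only
  lai_above <- numeric(nrow(stand))
  lai_above[ord] <- lai_above_sorted
  hs <- h[ord]
  ties <- which(duplicated(hs))
  if (length(ties))
    for (j in ties) lai_above[ord[j]] <- lai_above[ord[match(hs[j], hs)]]
  realized <- numeric(nrow(stand))
  for (k in unique(codes)) {
    p <- params_table[[k]]
    i <- which(codes == k)
    f_light <- light_multiplier(lai_above[i], p$shade_tolerance_class,
                                extinction_k)
    f_gdd <- response_gdd(site$gdd, p)
    f_swc <- response_swc(site$swc, p)
    opt <- optimal_increment(pmin(stand$dbh[i], p$d_max), p)
    opt[stand$dbh[i] >= p$d_max] <- 0
    realized[i] <- opt * f_light * f_gdd * f_swc * site$nutrient_index
    realized[i] <- pmin(realized[i], p$d_max - stand$dbh[i])
  }
  stand$dbh <- stand$dbh + pmax(0, realized)
  stand$age <- stand$age + 1
  slow <- realized < slow_threshold
  stand$slow_years <- ifelse(slow, stand$slow_years + 1L, 0L)
  stand
}

#' Annual mortality
#'
#' Each tree dies independently with probability
#' `p = p_intrinsic + (1 - p_intrinsic) * p_stress * [slow_years >= 2]`,
#' where `p_intrinsic = 4 / age_max` (so about `exp(-4)` of a cohort reaches
#' its maximum age) and `p_stress = 0.368` once a tree has grown below the
#' slow-growth threshold for two consecutive years.
#'
#' @param stand a `stand` data frame.
#' @param params_table named list of `growth_params`.
#' @param p_stress stress mortality probability (default 0.368).
#' @return the surviving `stand`.
#' @export
mortality_step <- function(stand, params_table, p_stress = 0.368) {
  if (nrow(stand) == 0L) return(stand)
  lookup_params(stand, params_table)
  p_int <- 4 / pt_field(params_table, stand$species_code, "age_max")
  p <- p_int + (1 - p_int) * p_stress * (stand$slow_years >= 2L)
  stand[stats::runif(nrow(stand)) >= p, , drop = FALSE]
}

#' Annual sapling establishment
#'
#' A species can recruit when the site's degree-days and soil water fall
#' strictly within its tolerance window and the light reaching the forest
#' floor (below the whole canopy) exceeds its compensation point. Each
#' eligible species adds `Poisson(recruit_rate)` saplings with diameters
#' drawn uniformly from `[0.5, 2.5]` cm at age 0.
#'
#' @param stand a `stand` data frame.
#' @param site `site_conditions`.
#' @param params_table named list of `growth_params`.
#' @param leaf_area_coeff,extinction_k canopy parameters as in
#'   [annual_growth_step()].
#' @return the `stand` with recruits appended.
#' @export
establishment_step <- function(stand, site, params_table,
                               leaf_area_coeff = 0.16, extinction_k = 0.4) {
  if (nrow(stand)) lookup_params(stand, params_table)
  total_lai <- sum(tree_lai(stand$dbh, site$plot_area, leaf_area_coeff))
  floor_al <- exp(-extinction_k * total_lai)
  recruits <- list()
  for (k in names(params_table)) {
    p <- params_table[[k]]
    eligible <- site$gdd > p$gdd_min && site$gdd < p$gdd_max &&
      site$swc > p$swc_min && site$swc < p$swc_max &&
      floor_al > light_archetype(p$shade_tolerance_class)$cp
    if (!eligible || p$recruit_rate == 0) next
    n_new <- stats::rpois(1, p$recruit_rate)
    if (n_new > 0)
      recruits[[k]] <- data.frame(
        species_code = rep(k, n_new),
        dbh = stats::runif(n_new, 0.5, 2.5),
        age = 0, slow_years = 0L, stringsAsFactors = FALSE)
  }
  if (length(recruits))
    stand <- rbind(stand, do.call(rbind, recruits))
  rownames(stand) <- NULL
  stand
}

summarize_stand <- function(stand, params_table, species) {
  out <- data.frame(species_code = species, stems = 0L, basal_area = 0,
                    biomass = 0, stringsAsFactors = FALSE)
  if (nrow(stand)) {
    for (j in seq_along(species)) {
      k <- species[j]
      i <- stand$species_code == k
      if (any(i)) {
        out$stems[j] <- sum(i)
        out$basal_area[j] <- sum(pi * (stand$dbh[i] / 200)^2)  # m^2
        out$biomass[j] <- sum(aboveground_biomass(stand$dbh[i],
                                                  params_table[[k]]))
      }
    }
  }
  out
}

#' Simulate stand dynamics over a number of years
#'
#' Applies growth, mortality and establishment (in that fixed order) once
#' per year and records per-species stem count, basal area (m^2) and
#' aboveground biomass (kg) after each year.
#'
#' @param stand initial `stand` (may be empty).
#' @param site `site_conditions`.
#' @param params_table named list of `growth_params`.
#' @param years number of simulated years (>= 1).
#' @param control optional list overriding `leaf_area_coeff`,
#'   `extinction_k`, `slow_threshold`, `p_stress`, `mortality` (logical),
#'   `establishment` (logical).
#' @return object of class `stand_trajectory`: data frame with columns
#'   `year`, `species_code`, `stems`, `basal_area`, `biomass`, plus the
#'   final `stand` as attribute `final_stand`.
#' @export
simulate_stand <- function(stand, site, params_table, years = 100,
                           control = list()) {
  if (years < 1) stop("years must be >= 1")
  ctl <- utils::modifyList(
    list(leaf_area_coeff = 0.16, extinction_k = 0.4, slow_threshold = 0.01,
         p_stress = 0.368, mortality = TRUE, establishment = TRUE), control)
  species <- names(params_table)
  rows <- vector("list", years)
  for (yr in seq_len(years)) {
    stand <- annual_growth_step(stand, site, params_table,
                                ctl$leaf_area_coeff, ctl$extinction_k,
                                ctl$slow_threshold)
    if (ctl$mortality)
      stand <- mortality_step(stand, params_table, ctl$p_stress)
    if (ctl$establishment)
      stand <- establishment_step(stand, site, params_table,
                                  ctl$leaf_area_coeff, ctl$extinction_k)
    s <- summarize_stand(stand, params_table, species)
    s$year <- yr
    rows[[yr]] <- s
  }
  out <- do.call(rbind, rows)[, c("year", "species_code", "stems",
                                  "basal_area", "biomass")]
  rownames(out) <- NULL
  structure(out, class = c("stand_trajectory", "data.frame"),
            final_stand = stand)
}

#' Replicate-averaged final biomass by species
#'
#' Runs `n_reps` independent replicates of [simulate_stand()] from the same
#' initial stand and averages the final-year aboveground biomass per
#' species. Replicate `r` uses RNG seed `seed + r`, so results are
#' reproducible bit-for-bit given `seed`.
#'
#' @param stand initial `stand`.
#' @param site `site_conditions`.
#' @param params_table named list of `growth_params`.
#' @param years simulation horizon (default 100).
#' @param n_reps number of replicates (default 50).
#' @param seed base RNG seed.
#' @param control passed to [simulate_stand()].
#' @return named numeric vector of mean final biomass (kg) per species.
#' @export
replicate_mean_biomass <- function(stand, site, params_table, years = 100,
                                   n_reps = 50, seed = 1, control = list()) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  species <- names(params_table)
  acc <- matrix(0, n_reps, length(species),
                dimnames = list(NULL, species))
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    traj <- simulate_stand(stand, site, params_table, years, control)
    fin <- traj[traj$year == years, ]
    acc[r, fin$species_code] <- fin$biomass
  }
  colMeans(acc)
}
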