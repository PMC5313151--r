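#' Read and validate a species growth-parameter table
#'
#' CSV with one row per species and columns matching the [growth_params()]
#' arguments. Errors cite the offending line.
#'
#' @param path CSV path.
#' @return named list of `growth_params` keyed by species code.
#' @export
read_growth_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("growth table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_code", "g_growth", "d_max", "h_max", "age_max",
            "shade_tolerance_class", "gdd_min", "gdd_max", "swc_min",
            "swc_max", "psi", "biomass_a", "biomass_b", "recruit_rate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    out[[i]] <- tryCatch(
      growth_params(df$species_code[i], df$g_growth[i], df$d_max[i],
                    df$h_max[i], df$age_max[i], df$shade_tolerance_class[i],
                    df$gdd_min[i], df$gdd_max[i], df$swc_min[i],
                    df$swc_max[i], df$psi[i], df$biomass_a[i],
                    df$biomass_b[i], df$recruit_rate[i]),
      error = function(e)
        stop(sprintf("%s line %d: %s", path, i + 1L, conditionMessage(e)),
             call. = FALSE))
  }
  names(out) <- df$species_code
  if (anyDuplicated(names(out)))
    stop(sprintf("%s: duplicated species codes", path))
  out
}

#' Write a species growth-parameter table
#'
#' @param params_table named list of `growth_params`.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_growth_params <- function(params_table, path) {
  df <- do.call(rbind, lapply(params_table, function(p)
    data.frame(species_code = p$species_code, g_growth = p$g_growth,
               d_max = p$d_max, h_max = p$h_max, age_max = p$age_max,
               shade_tolerance_class = p$shade_tolerance_class,
               gdd_min = p$gdd_min, gdd_max = p$gdd_max,
               swc_min = p$swc_min, swc_max = p$swc_max, psi = p$psi,
               biomass_a = p$biomass_a, biomass_b = p$biomass_b,
               recruit_rate = p$recruit_rate)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an initial-stand table
#'
#' CSV with columns `species_code`, `dbh_cm` and optional `count`; rows with
#' `count > 1` are expanded into that many identical individuals.
#'
#' @param path CSV path.
#' @return a `stand` data frame.
#' @export
read_stand <- function(path) {
  if (!file.exists(path)) stop(sprintf("stand file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species_code", "dbh_cm") %in% names(df)))
    stop(sprintf("%s: need columns species_code, dbh_cm", path))
  count <- if ("count" %in% names(df)) df$count else rep(1L, nrow(df))
  if (any(count < 0 | count != round(count)))
    stop(sprintf("%s: counts must be non-negative integers", path))
  idx <- rep(seq_len(nrow(df)), count)
  make_stand(df$species_code[idx], df$dbh_cm[idx])
}

#' Write a stand as one row per individual
#'
#' @param stand a `stand` data frame.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_stand <- function(stand, path) {
  utils::write.csv(
    data.frame(species_code = stand$species_code, dbh_cm = stand$dbh,
               count = 1L),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a plot-observation table
#'
#' CSV with columns `plot_id`, `x`, `y` and one 0/1 column per species code.
#'
#' @param path CSV path.
#' @return data frame of plot observations.
#' @export
read_plots <- function(path) {
  if (!file.exists(path)) stop(sprintf("plots file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("plot_id", "x", "y") %in% names(df)))
    stop(sprintf("%s: need columns plot_id, x, y", path))
  flag_cols <- setdiff(names(df), c("plot_id", "x", "y"))
  for (k in flag_cols)
    if (!all(df[[k]] %in% c(0, 1, NA)))
      stop(sprintf("%s: column %s is not 0/1", path, k))
  df
}
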