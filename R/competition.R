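#' Relative competitive ratings from simulated biomass
#'
#' Converts a forestland-type x species matrix of replicate-averaged final
#' aboveground biomass into relative competitive ratings (P100). Within each
#' forestland type, each species' biomass share of the type total is rescaled
#' by the largest share, so the best performer in every type scores exactly 1
#' and species eliminated from the community score 0. The transform is
#' invariant to rescaling a type's biomass row by any positive constant, and
#' idempotent. Ties at the row maximum all receive 1.
#'
#' @param biomass numeric matrix, rows = forestland types, columns = species,
#'   entries >= 0; every row must have at least one positive entry. Dimnames
#'   are carried through.
#' @return a `rating_matrix`: numeric matrix of P100 in `[0, 1]`, row
#'   maxima exactly 1.
#' @export
p100_matrix <- function(biomass) {
  if (!is.matrix(biomass) || !is.numeric(biomass))
    stop("`biomass` must be a numeric matrix")
  if (any(!is.finite(biomass)) || any(biomass < 0))
    stop("biomass entries must be finite and >= 0")
  rs <- rowSums(biomass)
  if (any(rs == 0)) {
    bad <- rownames(biomass)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop(sprintf("forestland type(s) with all-zero biomass: %s",
                 paste(bad, collapse = ", ")))
  }
  share <- biomass / rs
  p <- share / apply(share, 1, max)
  structure(p, class = c("rating_matrix", "matrix", "array"))
}

#' Construct a rating matrix from already-rescaled values
#'
#' Validates an externally supplied P100 matrix: entries in `[0, 1]` and
#' every row maximum exactly 1.
#'
#' @param x numeric matrix of P100 values.
#' @param tol tolerance on the row-max-equals-1 check.
#' @return a `rating_matrix`.
#' @export
rating_matrix <- function(x, tol = 1e-9) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix")
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("P100 values must be finite and in [0, 1]")
  rm <- apply(x, 1, max)
  if (any(abs(rm - 1) > tol)) {
    bad <- which(abs(rm - 1) > tol)
    lab <- if (!is.null(rownames(x))) rownames(x)[bad] else bad
    stop(sprintf("row maximum != 1 for forestland type(s): %s",
                 paste(lab, collapse = ", ")))
  }
  structure(x, class = c("rating_matrix", "matrix", "array"))
}

#' Read a competitive-rating table
#'
#' CSV layout: first column `forestland_type`, remaining columns one per
#' species code, cells = P100. Validation enforces the `[0, 1]` range and
#' row-max-1 on read, with line-numbered errors.
#'
#' @param path CSV path.
#' @return a `rating_matrix` with type row names and species column names.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop(sprintf("ratings file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "forestland_type")
    stop(sprintf("%s: malformed header (first column must be forestland_type)",
                 path))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric rating cells", path))
  rownames(m) <- df$forestland_type
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    if (any(!is.finite(row)) || any(row < 0) || any(row > 1))
      stop(sprintf("%s line %d: P100 outside [0, 1]", path, i + 1L))
    if (abs(max(row) - 1) > 1e-9)
      stop(sprintf("%s line %d: row maximum is %g, expected 1", path, i + 1L,
                   max(row)))
  }
  structure(m, class = c("rating_matrix", "matrix", "array"))
}

#' Write a competitive-rating table
#'
#' Inverse of [read_ratings()]; the round trip is lossless for labels and
#' values.
#'
#' @param ratings `rating_matrix`.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_ratings <- function(ratings, path) {
  stopifnot(inherits(ratings, "rating_matrix"))
  df <- data.frame(forestland_type = rownames(ratings),
                   unclass(ratings), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published competitive ratings for the Acadian study system
#'
#' Loads the package's built-in table of relative competitive ratings for 16
#' tree species of the western Nova Scotia landscape across 12 forestland
#' types, derived from 100-year replicate gap-model simulations of
#' interspecific competition.
#'
#' @return a `rating_matrix`, 12 types x 16 species.
#' @export
acadian_ratings <- function() {
  read_ratings(system.file("extdata", "acadian_p100_ratings.csv",
                           package = "compsd", mustWork = TRUE))
}

#' Competitive rating relative to monoculture optimum
#'
#' Alternative rating definition: each species' mixed-stand biomass as a
#' proportion of its own maximum aboveground biomass under optimum growing
#' conditions on a plot (e.g. a monoculture run at the species' optimal
#' site). Unlike [p100_matrix()], which rescales within-type biomass shares
#' so every forestland type has a best performer at 1, this variant
#' measures each species against its own potential; rows need not reach 1
#' and the result is returned as a plain matrix, not a `rating_matrix`.
#'
#' @param biomass matrix of mean final AGB (kg), rows = forestland types,
#'   columns = species.
#' @param optimum named numeric vector of per-species optimum-condition
#'   biomass (kg), all > 0, covering every column of `biomass`.
#' @return matrix of ratings, capped at 1.
#' @export
monoculture_rating <- function(biomass, optimum) {
  if (!is.matrix(biomass) || !is.numeric(biomass))
    stop("`biomass` must be a numeric matrix")
  if (is.null(colnames(biomass)) || is.null(names(optimum)))
    stop("`biomass` columns and `optimum` must be named by species code")
  miss <- setdiff(colnames(biomass), names(optimum))
  if (length(miss))
    stop(sprintf("optimum biomass missing for species: %s",
                 paste(miss, collapse = ", ")))
  opt <- optimum[colnames(biomass)]
  if (any(!is.finite(opt)) || any(opt <= 0))
    stop("optimum biomass must be finite and > 0")
  pmin(sweep(biomass, 2, opt, "/"), 1)
}
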