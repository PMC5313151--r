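#' Classify the landscape into forestland types
#'
#' Partitions valid cells into `n_types` forestland types — distinct
#' combinations of species a site can carry — by k-means clustering of the
#' per-cell vector of species PSD values. The clustering is seeded and uses
#' a fixed number of random restarts, so the same stack and seed always
#' yield the same map.
#'
#' @param psd_stack `psd_stack` of per-species suitability surfaces.
#' @param n_types number of forestland types (default 12).
#' @param seed RNG seed for the k-means initialization.
#' @param nstart random restarts passed to [stats::kmeans()] (default 5).
#' @return object of class `forestland_map`: list with `map` (a
#'   `raster_surface` of type ids 1..n_types), `centroids` (n_types x
#'   species matrix of mean PSD), and `labels` (type labels, initially
#'   `"type<i>"`).
#' @export
classify_forestland <- function(psd_stack, n_types = 12, seed = 1,
                                nstart = 5) {
  stopifnot(inherits(psd_stack, "psd_stack"))
  if (n_types < 1) stop("n_types must be >= 1")
  mat <- sapply(psd_stack, function(s) as.vector(s$grid))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(psd_stack))
  colnames(mat) <- names(psd_stack)
  valid <- rowSums(!is.finite(mat)) == 0
  if (sum(valid) < n_types)
    stop(sprintf("only %d valid cells for %d types", sum(valid), n_types))
  tmpl <- psd_stack[[1]]
  assign <- rep(NA_real_, nrow(mat))
  if (n_types == 1L) {
    assign[valid] <- 1
    centroids <- matrix(colMeans(mat[valid, , drop = FALSE]), nrow = 1,
                        dimnames = list(NULL, colnames(mat)))
  } else {
    set.seed(seed)
    km <- stats::kmeans(mat[valid, , drop = FALSE], centers = n_types,
                        nstart = nstart, iter.max = 100)
    assign[valid] <- km$cluster
    centroids <- km$centers
  }
  map <- tmpl
  map$grid <- matrix(assign, nrow(tmpl$grid), ncol(tmpl$grid))
  structure(list(map = map, centroids = centroids,
                 labels = paste0("type", seq_len(n_types))),
            class = "forestland_map")
}

#' @export
print.forestland_map <- function(x, ...) {
  cat(sprintf("forestland_map: %d types over %d valid cells\n",
              nrow(x$centroids), sum(is.finite(x$map$grid))))
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Name forestland types from their dominant species
#'
#' Labels each type by the hyphen-joined codes of up to `top_n` species
#' whose centroid PSD is at least `min_centroid`, in descending order of
#' centroid value; a type with no qualifying species keeps the fallback
#' label `type<i>`.
#'
#' @param fmap `forestland_map`.
#' @param top_n maximum species codes per label (default 3).
#' @param min_centroid minimum centroid PSD for a species to appear in the
#'   label (default 0.2).
#' @return the `forestland_map` with updated `labels`.
#' @export
label_types <- function(fmap, top_n = 3, min_centroid = 0.2) {
  stopifnot(inherits(fmap, "forestland_map"))
  cen <- fmap$centroids
  labs <- character(nrow(cen))
  for (i in seq_len(nrow(cen))) {
    v <- sort(cen[i, cen[i, ] >= min_centroid], decreasing = TRUE)
    labs[i] <- if (length(v)) paste(utils::head(names(v), top_n),
                                    collapse = "-")
    else paste0("type", i)
  }
  # duplicated labels fall back to indexed names to keep them unique
  dup <- duplicated(labs) | duplicated(labs, fromLast = TRUE)
  labs[dup] <- paste0(labs[dup], " (type", which(dup), ")")
  fmap$labels <- labs
  fmap
}
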