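#' Predicted presence from a suitability value
#'
#' A cell is predicted to carry the species when its PSD value is strictly
#' greater than the presence threshold (default 0.25).
#'
#' @param psd numeric vector of PSD values in `[0, 1]` (`NA` allowed;
#'   propagates).
#' @param threshold presence threshold.
#' @return logical vector.
#' @export
presence_from_psd <- function(psd, threshold = 0.25) {
  if (any(is.finite(psd) & (psd < 0 | psd > 1)))
    stop("PSD values must be in [0, 1]")
  psd > threshold
}

#' 2x2 presence/absence contingency table
#'
#' Cross-tabulates paired predicted and observed presence flags into the four
#' outcomes: predicted & observed presence (`n_pp`), predicted presence &
#' observed absence (`n_pa`), predicted absence & observed presence
#' (`n_ap`), predicted & observed absence (`n_aa`).
#'
#' @param predicted,observed logical vectors of equal positive length.
#' @return object of class `contingency_table`.
#' @export
contingency <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(predicted) == 0L) stop("no paired observations")
  if (anyNA(predicted) || anyNA(observed))
    stop("flags must not contain NA; exclude such plots first")
  contingency_table(sum(predicted & observed),
                    sum(predicted & !observed),
                    sum(!predicted & observed),
                    sum(!predicted & !observed))
}

#' Construct a contingency table from the four cell counts
#'
#' @param n_pp predicted presence, observed presence.
#' @param n_pa predicted presence, observed absence.
#' @param n_ap predicted absence, observed presence.
#' @param n_aa predicted absence, observed absence.
#' @return object of class `contingency_table` with an `n` total.
#' @export
contingency_table <- function(n_pp, n_pa, n_ap, n_aa) {
  cells <- c(n_pp = n_pp, n_pa = n_pa, n_ap = n_ap, n_aa = n_aa)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  structure(as.list(c(cells, n = sum(cells))), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table (n = %d)\n", x$n))
  cat(sprintf("  predicted presence: %4d observed present, %4d absent\n",
              x$n_pp, x$n_pa))
  cat(sprintf("  predicted absence:  %4d observed present, %4d absent\n",
              x$n_ap, x$n_aa))
  invisible(x)
}

#' Overall accuracy of a presence/absence prediction
#'
#' Percentage of plots on which prediction and observation agree:
#' `100 * (n_pp + n_aa) / n`.
#'
#' @param t `contingency_table`.
#' @return percent in `[0, 100]`.
#' @export
overall_accuracy <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$n == 0L) stop("empty contingency table")
  100 * (t$n_pp + t$n_aa) / t$n
}

#' Cohen's kappa for a 2x2 presence/absence table
#'
#' Chance-corrected agreement `(P_o - P_e) / (1 - P_e)`, where `P_o` is the
#' observed agreement rate and `P_e` the agreement expected under
#' independence of the row and column marginals. When the marginals force
#' `P_e = 1` (all mass in one cell), kappa is defined as 1 if agreement is
#' perfect and 0 (with a warning) otherwise.
#'
#' @param t `contingency_table`.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  n <- t$n
  if (n == 0L) stop("empty contingency table")
  po <- (t$n_pp + t$n_aa) / n
  pred_p <- t$n_pp + t$n_pa; pred_a <- t$n_ap + t$n_aa
  obs_p <- t$n_pp + t$n_ap;  obs_a <- t$n_pa + t$n_aa
  pe <- (pred_p * obs_p + pred_a * obs_a) / n^2
  if (pe >= 1) {
    if (po >= 1) return(1)
    warning("degenerate marginals (expected agreement 1); kappa set to 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Verbal agreement class on the Monserud-Leemans scale
#'
#' Half-open kappa bins: `< 0.20` poor, `[0.20, 0.40)` fair, `[0.40, 0.50)`
#' moderate, `[0.50, 0.70)` good, `[0.70, 0.80)` very good, `>= 0.80`
#' excellent.
#'
#' @param kappa numeric vector of kappa values.
#' @return character vector of class labels.
#' @export
monserud_class <- function(kappa) {
  if (any(!is.finite(kappa))) stop("kappa must be finite")
  as.character(cut(kappa, breaks = c(-Inf, 0.20, 0.40, 0.50, 0.70, 0.80, Inf),
                   labels = c("poor", "fair", "moderate", "good", "very good",
                              "excellent"),
                   right = FALSE))
}

#' Per-species accuracy report with across-species means
#'
#' Assembles per-species contingency counts into the standard validation
#' layout: counts, overall agreement (%), kappa, and its verbal class, plus
#' unweighted arithmetic means of agreement and kappa across species (the
#' mean kappa is also classed).
#'
#' @param tables named list of `contingency_table` objects, one per species.
#' @return list with `per_species` (data frame) and `mean_agreement`,
#'   `mean_kappa`, `mean_class`.
#' @export
accuracy_report <- function(tables) {
  if (!length(tables)) stop("need at least one species")
  if (is.null(names(tables))) names(tables) <- paste0("sp", seq_along(tables))
  rows <- lapply(names(tables), function(k) {
    t <- tables[[k]]
    kap <- cohen_kappa(t)
    data.frame(species = k, n = t$n, n_pp = t$n_pp, n_pa = t$n_pa,
               n_ap = t$n_ap, n_aa = t$n_aa,
               overall_agreement = overall_accuracy(t), kappa = kap,
               assessment = monserud_class(kap), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(per_species = per,
       mean_agreement = mean(per$overall_agreement),
       mean_kappa = mean(per$kappa),
       mean_class = monserud_class(mean(per$kappa)))
}

#' Assess a PSD stack against plot observations
#'
#' Locates each plot in the raster grid, thresholds the per-species PSD at
#' the plot cell into predicted presence, and cross-tabulates against the
#' observed flags. Plots falling off the grid or on nodata cells are
#' excluded (and counted).
#'
#' @param psd `psd_stack` of per-species suitability surfaces.
#' @param plots data frame with columns `plot_id`, `x`, `y` and one 0/1 (or
#'   logical) column per species code in the stack.
#' @param threshold presence threshold (strictly-greater rule).
#' @return list: `report` (see [accuracy_report()]), `n_plots_used`,
#'   `n_plots_excluded`.
#' @export
assess_psd <- function(psd, plots, threshold = 0.25) {
  stopifnot(inherits(psd, "psd_stack"), is.data.frame(plots))
  need <- c("plot_id", "x", "y")
  if (!all(need %in% names(plots)))
    stop("plots table must have columns plot_id, x, y")
  species <- names(psd)
  miss <- setdiff(species, names(plots))
  if (length(miss))
    stop(sprintf("plots table lacks observation columns: %s",
                 paste(miss, collapse = ", ")))
  rc <- cell_from_xy(psd[[1]], plots$x, plots$y)
  on_grid <- !is.na(rc[, "row"])
  idx <- cbind(rc[on_grid, "row"], rc[on_grid, "col"])
  tables <- list()
  excluded <- sum(!on_grid)
  used <- NULL
  for (k in species) {
    vals <- psd[[k]]$grid[idx]
    ok <- is.finite(vals)
    tables[[k]] <- contingency(presence_from_psd(vals[ok], threshold),
                               as.logical(plots[[k]][on_grid][ok]))
    used <- c(used, sum(ok))
  }
  # nodata exclusions can differ per species only if stacks disagree on
  # nodata; report the maximum exclusion count
  excluded <- excluded + (sum(on_grid) - min(used))
  list(report = accuracy_report(tables),
       n_plots_used = min(used), n_plots_excluded = excluded)
}

#' Built-in validation counts for the Acadian study system
#'
#' Per-species 2x2 contingency counts from the published accuracy
#' assessment of the original (abiotic-only) and competition-revised PSD
#' maps against provincial forest-inventory plots, together with the
#' reported per-species agreement, kappa and verbal class.
#'
#' @param variant `"original"` or `"revised"`.
#' @return data frame with columns `species`, `plots_reported`, `n_pp`,
#'   `n_pa`, `n_ap`, `n_aa`, `agreement_reported`, `kappa_reported`,
#'   `class_reported`.
#' @export
acadian_validation_counts <- function(variant = c("original", "revised")) {
  variant <- match.arg(variant)
  path <- system.file("extdata",
                      sprintf("validation_counts_%s.csv", variant),
                      package = "compsd", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
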