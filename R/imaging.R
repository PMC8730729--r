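## ROI-based organelle accumulation and motile-tubule summaries.

#' Area-normalized centrosome accumulation ratio
#'
#' The fraction of a cell's fluorescence found inside the centrosome ROI
#' divided by the fraction of the cell's area that ROI occupies:
#' \deqn{(I_c / I_w) / (A_c / A_w).}
#' Uniform fluorescence gives exactly 1; values above 1 mean accumulation.
#' Invariant to global intensity rescaling and to uniform changes of the
#' area unit. An optional constant background offset can be subtracted
#' from intensities per unit area before the ratio is formed.
#'
#' @param roi data.frame with columns \code{centrosome_intensity},
#'   \code{whole_cell_intensity}, \code{centrosome_area},
#'   \code{whole_cell_area} (one row per cell; extra columns such as
#'   \code{cell_id} and \code{group} are carried through untouched).
#' @param background constant background intensity per unit area
#'   subtracted from both ROIs (default 0, i.e. none).
#' @return numeric vector of ratios, one per row of \code{roi}.
#' @export
centrosomeEnrichment <- function(roi, background = 0) {
  ci <- roi$centrosome_intensity - background * roi$centrosome_area
  wi <- roi$whole_cell_intensity - background * roi$whole_cell_area
  ca <- roi$centrosome_area
  wa <- roi$whole_cell_area
  if (any(wi <= 0) || any(wa <= 0))
    stop("whole-cell intensity and area must be positive")
  if (any(ca <= 0) || any(ca > wa))
    stop("centrosome area must be positive and no larger than the cell")
  if (any(ci < 0) || any(ci > wi))
    stop("centrosome intensity must lie in [0, whole-cell intensity]")
  (ci / wi) / (ca / wa)
}

#' Count motile tubules per cell
#'
#' A tubule qualifies when it moved from its initial location AND reached
#' a maximum length strictly greater than \code{minLength} at some point
#' during its motility; stationary tubules and puncta at or below the
#' length cutoff are not counted.
#'
#' @param tracks data.frame with columns \code{cell_id}, \code{max_length}
#'   (um) and \code{moved_from_origin} (logical).
#' @param minLength um length cutoff (default 1).
#' @return data.frame with \code{cell_id} and \code{n_motile}; cells
#'   present in \code{tracks} but with no qualifying tubule appear with 0.
#' @export
countMotileTubules <- function(tracks, minLength = 1) {
  if (any(tracks$max_length < 0)) stop("max_length must be >= 0")
  ok <- as.logical(tracks$moved_from_origin) & tracks$max_length > minLength
  cells <- unique(as.character(tracks$cell_id))
  n <- vapply(cells, function(cl)
    sum(ok[as.character(tracks$cell_id) == cl]), integer(1))
  data.frame(cell_id = cells, n_motile = unname(n),
             stringsAsFactors = FALSE)
}

#' Percentage of cells above a per-cell count threshold
#'
#' @param counts numeric vector of per-cell counts (e.g. motile tubules).
#' @param threshold cells with count strictly greater than this qualify
#'   (default 5).
#' @param replicate optional factor of biological-replicate labels; when
#'   given, per-replicate percentages are returned alongside for
#'   mean +/- SEM style reporting.
#' @return list with \code{percent} (overall, 0-100) and
#'   \code{per_replicate} (named numeric vector, or NULL).
#' @export
percentCellsAbove <- function(counts, threshold = 5, replicate = NULL) {
  if (length(counts) == 0) stop("no cells supplied")
  pct <- 100 * mean(counts > threshold)
  per_rep <- NULL
  if (!is.null(replicate)) {
    per_rep <- vapply(split(counts, replicate),
                      function(x) 100 * mean(x > threshold), numeric(1))
  }
  list(percent = pct, per_replicate = per_rep)
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Rank-based multi-group comparison: the Kruskal-Wallis omnibus test
#' followed by Dunn's pairwise z tests on the pooled ranks, with the
#' tie-corrected variance
#' \deqn{\sigma^2_{ij} = \left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}
#' and two-sided p values adjusted for the number of tested pairs
#' (Bonferroni by default).
#'
#' @param values numeric vector of observations.
#' @param groups factor (or coercible) of group labels, same length.
#' @param adjust multiplicity adjustment passed to [stats::p.adjust()]
#'   (default \code{"bonferroni"}).
#' @return list with \code{kw_statistic}, \code{kw_p} (omnibus), and
#'   \code{pairs}: a data.frame of \code{group1}, \code{group2}, \code{z},
#'   \code{p_unadjusted}, \code{p_adjusted}.
#' @export
kruskalDunn <- function(values, groups, adjust = "bonferroni") {
  groups <- factor(groups)
  if (nlevels(groups) < 3)
    stop("the omnibus test needs at least 3 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  kw <- stats::kruskal.test(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  cmb <- utils::combn(lev, 2)
  z <- apply(cmb, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  list(kw_statistic = unname(kw$statistic),
       kw_p = kw$p.value,
       pairs = data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                          z = z,
                          p_unadjusted = p,
                          p_adjusted = stats::p.adjust(p, method = adjust),
                          stringsAsFactors = FALSE))
}
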