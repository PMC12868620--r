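#' Form factor (circularity) of a cell outline
#'
#' \deqn{FF = 4\pi \frac{A}{P^2}} for area \eqn{A} and perimeter \eqn{P}.
#' Equals 1 for a perfect circle and decreases toward 0 for elongated or
#' irregular shapes (the isoperimetric inequality bounds it by 1 for any
#' simple closed curve). Scale invariant.
#'
#' @param area Cell area in um^2 (> 0). Vectorised.
#' @param perimeter Cell perimeter in um (> 0). Vectorised.
#' @return Dimensionless circularity in (0, 1].
#' @examples
#' form_factor(pi * 5^2, 2 * pi * 5)  # circle -> 1
#' form_factor(4, 8)                  # unit square -> pi/4
#' @export
form_factor <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("'area' must be positive and finite")
  if (any(!is.finite(perimeter)) || any(perimeter <= 0))
    stop("'perimeter' must be positive and finite")
  4 * pi * area / perimeter^2
}

.morph_cols <- c("area_um2", "perimeter_um", "major_um", "minor_um")

.check_morph <- function(records, group_col) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data frame of per-cell measurements")
  missing <- setdiff(c(group_col, "area_um2"), names(records))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  invisible(records)
}

#' Per-ROI means of cell morphometry
#'
#' Averages each shape feature over the cells of each region of interest, so
#' the ROI mean — not the individual cell — is the independent unit for
#' downstream statistics (cells within an ROI share imaging conditions and
#' local confluency).
#'
#' @param records Data frame of per-cell measurements with columns `roi_id`,
#'   `area_um2` and optionally `perimeter_um`, `major_um`, `minor_um`,
#'   `form_factor`, plus grouping columns such as `cell_line`.
#' @return Data frame with one row per ROI: the per-feature means, the cell
#'   count `n_cells`, and any constant-within-ROI grouping columns carried
#'   through.
#' @export
summarize_rois <- function(records) {
  .check_morph(records, "roi_id")
  feat <- intersect(c(.morph_cols, "form_factor"), names(records))
  carry <- intersect(c("cell_line", "group"), names(records))
  rois <- split(records, records$roi_id)
  out <- lapply(rois, function(d) {
    row <- as.data.frame(lapply(d[feat], mean))
    row$n_cells <- nrow(d)
    row$roi_id <- d$roi_id[1]
    for (cc in carry) {
      u <- unique(d[[cc]])
      row[[cc]] <- if (length(u) == 1L) u else NA
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("roi_id", intersect(c("cell_line", "group"), names(out)), feat, "n_cells")]
}

#' Weighted per-tissue-class means for tissue-microarray records
#'
#' Computes the mean area and form factor per (TMA, tissue class), then the
#' across-TMA weighted mean per tissue class, with each TMA weighted by its
#' number of cores — the weighting used when each array contributes one data
#' point but arrays differ in how much tissue they carry. With equal weights
#' this reduces to the ordinary mean of TMA means.
#'
#' @param records Data frame of per-cell measurements with columns `tma_id`,
#'   `tissue_class`, `area_um2` and optionally `form_factor`.
#' @param weights Data frame with columns `tma_id`, `n_cores` (one row per
#'   TMA). Every TMA present in `records` must have a weight.
#' @return List with `class_means` (data frame: `tissue_class`,
#'   `mean_area_um2`, `mean_form_factor`, `total_weight`) and `tma_means`
#'   (the per-TMA, per-class means the weighting acts on).
#' @export
tissue_group_means <- function(records, weights) {
  .check_morph(records, "tissue_class")
  if (!all(c("tma_id") %in% names(records)))
    stop("missing required column(s): tma_id")
  if (!is.data.frame(weights) || !all(c("tma_id", "n_cores") %in% names(weights)))
    stop("'weights' must be a data frame with columns tma_id, n_cores")
  if (any(weights$n_cores <= 0)) stop("weights must be positive")
  w <- weights$n_cores[match(records$tma_id, weights$tma_id)]
  if (anyNA(w))
    stop("missing weight for TMA id(s): ",
         paste(unique(records$tma_id[is.na(w)]), collapse = ", "))

  has_ff <- "form_factor" %in% names(records)
  key <- interaction(records$tma_id, records$tissue_class, drop = TRUE)
  tma_means <- do.call(rbind, lapply(split(records, key), function(d) {
    data.frame(tma_id = d$tma_id[1], tissue_class = d$tissue_class[1],
               mean_area_um2 = mean(d$area_um2),
               mean_form_factor = if (has_ff) mean(d$form_factor) else NA_real_,
               weight = weights$n_cores[match(d$tma_id[1], weights$tma_id)])
  }))
  rownames(tma_means) <- NULL
  class_means <- do.call(rbind, lapply(split(tma_means, tma_means$tissue_class),
    function(d) data.frame(
      tissue_class = d$tissue_class[1],
      mean_area_um2 = stats::weighted.mean(d$mean_area_um2, d$weight),
      mean_form_factor = stats::weighted.mean(d$mean_form_factor, d$weight),
      total_weight = sum(d$weight))))
  rownames(class_means) <- NULL
  list(class_means = class_means, tma_means = tma_means)
}

#' Immunohistochemistry H-score
#'
#' Weighted sum of staining-intensity fractions:
#' \deqn{H = 0\cdot\%_{neg} + 1\cdot\%_{weak} + 2\cdot\%_{mod} + 3\cdot\%_{strong},}
#' ranging from 0 (no staining) to 300 (uniform strong staining).
#'
#' @param pct_negative,pct_weak,pct_moderate,pct_strong Percentages of cells
#'   in each staining category; must each lie in \[0, 100\] and sum to 100.
#' @return H-score in \[0, 300\].
#' @examples
#' h_score(0, 0, 0, 100)    # 300
#' h_score(10, 20, 30, 40)  # 200
#' @export
h_score <- function(pct_negative, pct_weak, pct_moderate, pct_strong) {
  p <- c(pct_negative, pct_weak, pct_moderate, pct_strong)
  if (length(p) != 4L || any(!is.finite(p)) || any(p < 0) || any(p > 100))
    stop("each staining fraction must be a percentage in [0, 100]")
  if (abs(sum(p) - 100) > 1e-9)
    stop("staining fractions must sum to 100")
  sum(p * 0:3)
}

#' Equivalent mean radius of a projected shape
#'
#' `sqrt(area / pi)`: the radius of the circle with the same projected area.
#' Used to summarise spheroid size when only the 2D projection is measured.
#'
#' @param area_um2 Projected area in um^2.
#' @return Radius in um.
#' @export
mean_radius <- function(area_um2) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0))
    stop("'area_um2' must be positive and finite")
  sqrt(area_um2 / pi)
}
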