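#' Maximum-intensity z-projection
#'
#' Per-pixel maximum across the slices of a stack. Idempotent and invariant
#' to slice order; adding a slice that is everywhere darker than the current
#' maximum leaves the projection unchanged.
#'
#' @param stack an `image_stack` (list of equally sized matrices).
#' @return projection matrix.
#' @export
max_projection <- function(stack) {
  stopifnot(length(stack) >= 1L)
  dims <- dim(stack[[1]])
  if (!all(vapply(stack, function(s) all(dim(s) == dims), logical(1))))
    stop("slice dimensions differ")
  Reduce(pmax, stack)
}

#' Threshold ROI on a projection
#'
#' Builds the measurement region the way a threshold-image workflow does:
#' binarize the projection (Otsu by default, or a fixed value or intensity
#' percentile), optionally keep only the largest connected component.
#'
#' @param projection matrix from [max_projection()].
#' @param method `"otsu"`, `"fixed"`, or `"percentile"`.
#' @param value threshold value (for `"fixed"`) or percentile in (0, 100)
#'   (for `"percentile"`).
#' @param largest_component keep only the largest 8-connected blob
#'   (default TRUE).
#' @return logical mask of class `roi_mask` with attributes `method` and
#'   `threshold` recording provenance.
#' @export
threshold_roi <- function(projection, method = c("otsu", "fixed",
                                                 "percentile"),
                          value = NULL, largest_component = TRUE) {
  method <- match.arg(method)
  if (diff(range(projection)) == 0)
    stop("cannot threshold a constant projection")
  thr <- switch(method,
    otsu = otsu_threshold(projection),
    fixed = {
      if (is.null(value)) stop("fixed threshold needs a value")
      value
    },
    percentile = {
      if (is.null(value)) stop("percentile threshold needs a value")
      stats::quantile(projection, value / 100, names = FALSE)
    })
  mask <- projection >= thr
  if (!any(mask)) stop("no signal above threshold")
  if (largest_component) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    mask <- lab == which.max(sizes)
  }
  structure(mask, class = c("roi_mask", class(mask)),
            method = method, threshold = thr)
}

#' Mean intensity over an ROI
#'
#' @param projection matrix.
#' @param mask logical mask of identical dimensions.
#' @return arithmetic mean of the projection over mask pixels.
#' @export
roi_mean <- function(projection, mask) {
  if (!all(dim(projection) == dim(mask)))
    stop("projection and mask dimensions differ")
  if (!any(mask)) stop("empty ROI mask")
  mean(projection[mask])
}

#' Quantify one stack end to end
#'
#' @param stack an `image_stack`.
#' @param method,value,largest_component passed to [threshold_roi()].
#' @return list `(roi_mean_intensity, roi_area_px, threshold)`.
#' @export
quantify_stack <- function(stack, method = "otsu", value = NULL,
                           largest_component = TRUE) {
  proj <- max_projection(stack)
  mask <- threshold_roi(proj, method, value, largest_component)
  list(roi_mean_intensity = roi_mean(proj, mask),
       roi_area_px = sum(mask),
       threshold = attr(mask, "threshold"))
}

#' Batch quantification with group statistics
#'
#' One record per brain; ROI mean intensity dispatched to the two-way ANOVA
#' (timepoint x group) with Tukey post hoc, the design used for day/night
#' fluorescence comparisons (e.g. ZT02 vs ZT14 across sex/mating groups).
#'
#' @param stacks named list of `image_stack` objects.
#' @param metadata data.frame with columns `brain_id`, `group`, `timepoint`;
#'   `brain_id` must match `names(stacks)`.
#' @param method ROI threshold method.
#' @return list with `records` (QuantRecord data.frame), `anova`
#'   ([two_way_anova()] result), `tukey` (pairwise table over
#'   timepoint:group cells).
#' @export
quantify_batch <- function(stacks, metadata, method = "otsu") {
  need <- c("brain_id", "group", "timepoint")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns brain_id, group, timepoint")
  missing_meta <- setdiff(names(stacks), metadata$brain_id)
  if (length(missing_meta))
    stop(sprintf("missing metadata row for: %s",
                 paste(missing_meta, collapse = ", ")))
  rows <- lapply(names(stacks), function(id) {
    q <- quantify_stack(stacks[[id]], method = method)
    md <- metadata[metadata$brain_id == id, , drop = FALSE][1, ]
    data.frame(brain_id = id, group = md$group, timepoint = md$timepoint,
               roi_mean_intensity = q$roi_mean_intensity,
               roi_area_px = q$roi_area_px, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (length(unique(records$group)) >= 2 &&
      length(unique(records$timepoint)) >= 2) {
    aov2 <- two_way_anova(records$roi_mean_intensity,
                          factor(records$timepoint), factor(records$group))
    cell <- interaction(records$timepoint, records$group, sep = ":")
    tk <- tukey_hsd(records$roi_mean_intensity, cell)
  } else {
    aov2 <- NULL; tk <- NULL
  }
  list(records = records, anova = aov2, tukey = tk)
}
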