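#' Segmentation configuration
#'
#' Tunable constants of the three MTV methods. All thresholds are inclusive
#' (`>=`). `heterogeneity_tolerance` is the relative difference in regional
#' maxima above which [heterogeneity_check()] advises subdividing a region
#' before applying the 41% method.
#'
#' @param fixed_threshold absolute SUV threshold (default 2.5).
#' @param max_fraction fraction of the regional maximum SUV (default 0.41).
#' @param heterogeneity_tolerance relative-difference tolerance (default 0.10).
#' @param connectivity 6, 18 or 26 (default 26, vertex-adjacent), matching
#'   typical clinical tools.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(fixed_threshold = 2.5, max_fraction = 0.41,
                                heterogeneity_tolerance = 0.10,
                                connectivity = 26L) {
  if (!is.finite(fixed_threshold) || fixed_threshold <= 0)
    stop("`fixed_threshold` must be > 0", call. = FALSE)
  if (!is.finite(max_fraction) || max_fraction <= 0 || max_fraction >= 1)
    stop("`max_fraction` must be in (0, 1)", call. = FALSE)
  if (!is.finite(heterogeneity_tolerance) || heterogeneity_tolerance <= 0 ||
      heterogeneity_tolerance >= 1)
    stop("`heterogeneity_tolerance` must be in (0, 1)", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  structure(list(fixed_threshold = fixed_threshold,
                 max_fraction = max_fraction,
                 heterogeneity_tolerance = heterogeneity_tolerance,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_config")
}

#' Fixed-threshold segmentation (SUV >= 2.5 method)
#'
#' Returns the connected component of `{SUV >= fixed_threshold}` that
#' contains the operator's seed voxel. The seed must itself lie in avid
#' disease (SUV at the seed >= threshold), otherwise the click is an
#' operator error.
#'
#' @param image an [suv_image()].
#' @param seed a [seed_point()] or integer index triple (1-based).
#' @param cfg a [segmentation_config()].
#' @return A [region_mask()] with attribute `threshold`.
#' @export
segment_fixed <- function(image, seed, cfg = segmentation_config()) {
  stop_if_not_image(image)
  idx <- as_seed_index(seed, image)
  thr <- cfg$fixed_threshold
  if (image$values[idx[1], idx[2], idx[3]] < thr)
    stop(sprintf("seed SUV %.3g is below the threshold %.3g (seed outside avid disease)",
                 image$values[idx[1], idx[2], idx[3]], thr), call. = FALSE)
  supra <- image$values >= thr
  comp <- flood_fill(supra, idx, conn_offsets(cfg$connectivity))
  structure(region_mask(comp), threshold = thr)
}

#' Percentage-of-maximum segmentation (41% method)
#'
#' Two-stage reading of the adaptive-threshold workflow: the operator
#' outlines the tumour with a constraining box; the maximum SUV `M` inside
#' the box sets the threshold `max_fraction * M`; the mask is the connected
#' component of `{voxels in the box with SUV >= max_fraction * M}` that
#' contains the argmax voxel. Disconnected supra-threshold islands inside
#' the box are taken to be separate lesions needing their own box.
#'
#' @param image an [suv_image()].
#' @param box a [box_voi()] constraining volume.
#' @param cfg a [segmentation_config()].
#' @return A [region_mask()] with attributes `threshold` and `max_suv`.
#' @export
segment_pct_max <- function(image, box, cfg = segmentation_config()) {
  stop_if_not_image(image)
  bm <- box_mask(image, box)
  if (!any(bm) || max(image$values[bm]) <= 0)
    stop("constraining box contains no positive-SUV voxel (degenerate region)",
         call. = FALSE)
  M <- max(image$values[bm])
  thr <- cfg$max_fraction * M
  eligible <- bm & image$values >= thr
  argmax <- arrayInd(which(bm & image$values == M)[1L], dim(image$values))
  comp <- flood_fill(eligible, argmax, conn_offsets(cfg$connectivity))
  structure(region_mask(comp), threshold = thr, max_suv = M)
}

#' Regional-maximum heterogeneity check
#'
#' Compares the maximum SUV of every pair of constraining boxes; where the
#' maxima differ by more than the tolerance (relative to the larger), the
#' 41% threshold derived from a merged region would be too high and the
#' region should be subdivided to avoid underestimating tumour volume. The
#' check only advises the operator; it never re-segments.
#'
#' @param image an [suv_image()].
#' @param boxes list of >= 2 [box_voi()] objects.
#' @param cfg a [segmentation_config()].
#' @return Data frame with one row per box pair: `box_a`, `box_b`, `max_a`,
#'   `max_b`, `rel_diff`, `subdivide`.
#' @export
heterogeneity_check <- function(image, boxes, cfg = segmentation_config()) {
  stop_if_not_image(image)
  if (!is.list(boxes) || length(boxes) < 2L)
    stop("need at least two boxes to compare", call. = FALSE)
  maxima <- vapply(boxes, function(b) max(voi_values(image, b)), numeric(1))
  pairs <- utils::combn(length(boxes), 2L)
  rel <- abs(maxima[pairs[1, ]] - maxima[pairs[2, ]]) /
    pmax(maxima[pairs[1, ]], maxima[pairs[2, ]])
  data.frame(box_a = pairs[1, ], box_b = pairs[2, ],
             max_a = maxima[pairs[1, ]], max_b = maxima[pairs[2, ]],
             rel_diff = rel,
             subdivide = rel > cfg$heterogeneity_tolerance)
}

#' PERCIST "tumour finder": label every supra-threshold region
#'
#' Labels all connected components of `{SUV >= threshold}` across the whole
#' image, `1..K` in decreasing volume order (ties by scan order of the first
#' voxel). No minimum component size is applied: removing physiological
#' uptake (brain, bladder, myocardium, bowel) is the operator's edit step,
#' see [edit_labels()]. `K = 0` (threshold above the global maximum) is a
#' valid result.
#'
#' @param image an [suv_image()].
#' @param threshold SUV threshold, typically from [percist_threshold()].
#' @param cfg a [segmentation_config()] (only `connectivity` is used).
#' @return An integer label array of class `label_map` (0 = background).
#' @export
percist_tumor_finder <- function(image, threshold,
                                 cfg = segmentation_config()) {
  stop_if_not_image(image)
  if (!is.finite(threshold) || threshold <= 0)
    stop("`threshold` must be > 0", call. = FALSE)
  labels <- label_components(image$values >= threshold, cfg$connectivity)
  structure(labels, threshold = threshold,
            class = c("label_map", "array"))
}

#' @export
print.label_map <- function(x, ...) {
  k <- max(x)
  cat(sprintf("<label_map> %s, %d region%s\n", paste(dim(x), collapse = " x "),
              k, if (k == 1) "" else "s"))
  if (k > 0) {
    sizes <- tabulate(x[x > 0], nbins = k)
    cat("  voxels per label:", paste(sizes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Operator editing of a label map
#'
#' Removes whole labels that contain only physiological FDG uptake (e.g.
#' brain or bladder) and/or carves physiological uptake adjacent to tumour
#' out of the remaining labels via a carve mask. Surviving labels are
#' relabelled contiguously, preserving their order.
#'
#' @param labels a `label_map` from [percist_tumor_finder()].
#' @param excluded integer vector of labels to remove entirely (may be empty).
#' @param carve_mask optional logical array; voxels set `TRUE` are cleared
#'   from every remaining label.
#' @return The edited `label_map`.
#' @export
edit_labels <- function(labels, excluded = integer(0), carve_mask = NULL) {
  if (!inherits(labels, "label_map"))
    stop("expected a `label_map`", call. = FALSE)
  k <- max(labels)
  excluded <- as.integer(excluded)
  if (length(excluded) && (anyNA(excluded) || any(excluded < 1L | excluded > k)))
    stop("`excluded` contains labels not present in the map", call. = FALSE)
  out <- unclass(labels)
  if (length(excluded)) out[out %in% excluded] <- 0L
  if (!is.null(carve_mask)) {
    if (!identical(dim(carve_mask), dim(out)))
      stop("`carve_mask` is not congruent with the label map", call. = FALSE)
    out[as.logical(carve_mask)] <- 0L
  }
  survivors <- sort(unique(out[out > 0L]))
  relab <- integer(k)
  relab[survivors] <- seq_along(survivors)
  pos <- out > 0L
  out[pos] <- relab[out[pos]]
  structure(out, threshold = attr(labels, "threshold"),
            class = c("label_map", "array"))
}

#' Extract each label of a label map as a region mask
#'
#' @param labels a `label_map`.
#' @return List of [region_mask()] objects, one per label, in label order.
#' @export
label_masks <- function(labels) {
  k <- max(labels)
  lapply(seq_len(k), function(i) region_mask(unclass(labels) == i, label = i))
}

#' Total metabolic tumour volume and total lesion glycolysis
#'
#' Sums individual lesion volumes into the total MTV and accumulates TLG as
#' the sum over lesions of `volume x mean SUV inside the lesion` (for a
#' single lesion this is exactly MTV times the mean SUV in the volume).
#'
#' @param lesions list of pairwise-disjoint [region_mask()] objects (may be
#'   empty).
#' @param image the parent [suv_image()].
#' @param patient_id,method,observer_id provenance fields carried into the
#'   record.
#' @return An object of class `mtv_record` with fields `patient_id`,
#'   `method`, `observer_id`, `lesion_volumes` (cm^3), `total_mtv` (cm^3)
#'   and `tlg` (cm^3 x SUV).
#' @export
total_mtv <- function(lesions, image, patient_id = NA_character_,
                      method = NA_character_, observer_id = NA_character_) {
  stop_if_not_image(image)
  if (!is.list(lesions)) stop("`lesions` must be a list of masks", call. = FALSE)
  if (length(lesions)) {
    for (m in lesions) check_congruent(m, image)
    overlap <- Reduce(`+`, lapply(lesions, function(m) array(as.integer(m), dim(image$values))))
    if (any(overlap > 1L))
      stop("lesion masks overlap; individual tumour volumes must be disjoint",
           call. = FALSE)
  }
  vv <- voxel_volume_cm3(image)
  vols <- vapply(lesions, function(m) sum(m) * vv, numeric(1))
  tlg <- sum(vapply(lesions, function(m) {
    n <- sum(m)
    if (n == 0) 0 else n * vv * mean(image$values[as.logical(m)])
  }, numeric(1)))
  structure(list(patient_id = patient_id, method = method,
                 observer_id = observer_id,
                 lesion_volumes = as.numeric(vols),
                 total_mtv = sum(vols), tlg = tlg),
            class = "mtv_record")
}

#' @export
print.mtv_record <- function(x, ...) {
  cat(sprintf("<mtv_record> patient %s, method %s: total MTV %.4g cm^3 (%d lesion%s), TLG %.4g\n",
              x$patient_id, x$method, x$total_mtv, length(x$lesion_volumes),
              if (length(x$lesion_volumes) == 1) "" else "s", x$tlg))
  invisible(x)
}

#' @export
as.data.frame.mtv_record <- function(x, ...) {
  data.frame(patient_id = x$patient_id, method = x$method,
             observer_id = x$observer_id,
             n_lesions = length(x$lesion_volumes),
             total_mtv_cm3 = x$total_mtv, tlg = x$tlg,
             stringsAsFactors = FALSE)
}
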