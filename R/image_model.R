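#' SUV image: a 3-D grid of standardised uptake values
#'
#' The substrate of every segmentation step: a dense 3-D array of SUV
#' (dimensionless, g/mL-standardised) voxel values together with the voxel
#' edge lengths in mm and the physical position of the first voxel centre.
#' Voxel indices are 1-based; the physical centre of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing`. Anisotropic spacing is fully
#' supported and nothing in the package ever interpolates: all statistics
#' are taken over the original voxels.
#'
#' @param values 3-D numeric array of SUV; all finite and >= 0.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, physical coordinate (mm) of the centre of
#'   voxel `(1, 1, 1)`.
#' @return An object of class `suv_image` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' img <- suv_image(array(1, c(4, 4, 4)), spacing = c(4, 4, 2))
#' voxel_volume_cm3(img)
#' @export
suv_image <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || any(dim(values) < 1L))
    stop("`values` must be a 3-D array with each axis of length >= 1", call. = FALSE)
  storage.mode(values) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel edge lengths (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite physical coordinate (mm)", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("SUV values must be finite and non-negative", call. = FALSE)
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "suv_image")
}

#' @export
print.suv_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<suv_image> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  SUV range [%.3g, %.3g], origin (%s) mm\n",
              min(x$values), max(x$values),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.suv_image <- function(x) dim(x$values)

stop_if_not_image <- function(image) {
  if (!inherits(image, "suv_image"))
    stop("expected an `suv_image`", call. = FALSE)
  invisible(image)
}

#' Volume of a single voxel in cm^3
#'
#' @param image an [suv_image()].
#' @return Scalar volume `prod(spacing) / 1000` (mm^3 to cm^3).
#' @export
voxel_volume_cm3 <- function(image) {
  stop_if_not_image(image)
  prod(image$spacing) / 1000
}

#' Binary region mask congruent with an SUV image
#'
#' A logical 3-D array marking segmented voxels, optionally carrying an
#' integer label identity (e.g. the component it came from).
#'
#' @param mask logical 3-D array.
#' @param label optional integer identity.
#' @return An object of class `region_mask` (a logical array with attributes).
#' @export
region_mask <- function(mask, label = NULL) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop("`mask` must be a 3-D array", call. = FALSE)
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("`mask` must not contain NA", call. = FALSE)
  structure(mask, label = if (!is.null(label)) as.integer(label),
            class = c("region_mask", "array"))
}

#' @export
print.region_mask <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<region_mask> %s, %d voxels%s\n",
              paste(dim(x), collapse = " x "), sum(x),
              if (is.null(lab)) "" else sprintf(", label %d", lab)))
  invisible(x)
}

check_congruent <- function(mask, image) {
  stop_if_not_image(image)
  if (!identical(dim(mask), dim(image$values)))
    stop("mask and image grids are not congruent (shape mismatch)", call. = FALSE)
  invisible(TRUE)
}

#' Volume of a region mask in cm^3
#'
#' Exactly `voxel count x voxel volume`; additive over disjoint masks.
#'
#' @param mask logical array or [region_mask()] congruent with `image`.
#' @param image the parent [suv_image()].
#' @return Scalar volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask, image) {
  check_congruent(mask, image)
  sum(mask) * voxel_volume_cm3(image)
}

#' Axis-aligned cuboid volume of interest
#'
#' A voxel belongs to the box iff its *centre* lies inside the closed box
#' (boundary ties count as inside), a deterministic, resolution-independent
#' membership rule.
#'
#' @param center physical coordinate (mm) of the box centre.
#' @param size per-axis edge lengths (mm), all > 0.
#' @return An object of class `box_voi`.
#' @export
box_voi <- function(center, size) {
  center <- as.numeric(center); size <- as.numeric(size)
  if (length(size) == 1L) size <- rep(size, 3L)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be a finite length-3 coordinate (mm)", call. = FALSE)
  if (length(size) != 3L || any(!is.finite(size)) || any(size <= 0))
    stop("`size` must be three positive edge lengths (mm)", call. = FALSE)
  structure(list(center = center, size = size), class = "box_voi")
}

#' @export
print.box_voi <- function(x, ...) {
  cat(sprintf("<box_voi> centre (%s) mm, size %s mm\n",
              paste(format(x$center), collapse = ", "),
              paste(format(x$size), collapse = " x ")))
  invisible(x)
}

#' Voxel-centre coordinates along one axis
#' @noRd
axis_centers <- function(image, axis) {
  image$origin[axis] + (seq_len(dim(image$values)[axis]) - 1) * image$spacing[axis]
}

#' Logical membership grid of a box VOI
#'
#' @param image an [suv_image()].
#' @param box a [box_voi()].
#' @return Logical array, `TRUE` where the voxel centre lies in the closed box.
#' @export
box_mask <- function(image, box) {
  stop_if_not_image(image)
  if (!inherits(box, "box_voi")) stop("expected a `box_voi`", call. = FALSE)
  lo <- box$center - box$size / 2
  hi <- box$center + box$size / 2
  tol <- 1e-7 * image$spacing  # boundary ties count as inside
  inside <- lapply(1:3, function(ax) {
    cc <- axis_centers(image, ax)
    cc >= lo[ax] - tol[ax] & cc <= hi[ax] + tol[ax]
  })
  m <- outer(outer(inside[[1]], inside[[2]], "&"), inside[[3]], "&")
  dim(m) <- dim(image$values)
  m
}

#' SUV values of the voxels whose centres lie inside a box VOI
#'
#' @inheritParams box_mask
#' @return Numeric vector of SUV values (order unspecified); errors if the
#'   box captures no voxel centre.
#' @export
voi_values <- function(image, box) {
  m <- box_mask(image, box)
  if (!any(m))
    stop("box VOI contains no voxel centre (empty VOI)", call. = FALSE)
  image$values[m]
}

#' Seed point: an operator's single-click voxel
#'
#' @param index integer voxel index `(i, j, k)`, 1-based.
#' @return An object of class `seed_point`.
#' @export
seed_point <- function(index) {
  index <- as.integer(index)
  if (length(index) != 3L || anyNA(index) || any(index < 1L))
    stop("`index` must be three positive 1-based voxel indices", call. = FALSE)
  structure(list(index = index), class = "seed_point")
}

as_seed_index <- function(seed, image) {
  idx <- if (inherits(seed, "seed_point")) seed$index else as.integer(seed)
  if (length(idx) != 3L || anyNA(idx))
    stop("seed must be a 1-based voxel index triple", call. = FALSE)
  if (any(idx < 1L) || any(idx > dim(image$values)))
    stop("seed index lies outside the image bounds", call. = FALSE)
  idx
}
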