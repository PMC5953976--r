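#' Ellipsoidal lesion specification
#'
#' Lesions are axis-aligned ellipsoids so the ground-truth volume
#' `(4/3) pi a b c` is analytic, giving exact oracles for volume-recovery
#' checks. A two-compartment lesion has a hot core (the inner ellipsoid
#' with semi-axes scaled by `rim_fraction`) and a warm rim, emulating
#' heterogeneous uptake.
#'
#' @param center physical centre (mm).
#' @param semi_axes ellipsoid semi-axes (mm).
#' @param core_suv SUV of the core (or of the whole lesion when uniform).
#' @param rim_suv optional rim SUV (`core_suv >= rim_suv >= 0`); `NULL`
#'   for a uniform lesion.
#' @param rim_fraction fraction of the semi-axes occupied by the core
#'   (default 0.6).
#' @return An object of class `lesion_spec` with an `analytic_volume_cm3`
#'   field.
#' @export
lesion_spec <- function(center, semi_axes, core_suv, rim_suv = NULL,
                        rim_fraction = 0.6) {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3L)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L,
            all(semi_axes > 0), core_suv >= 0)
  if (!is.null(rim_suv)) {
    if (rim_suv < 0 || core_suv < rim_suv)
      stop("need core_suv >= rim_suv >= 0", call. = FALSE)
    if (rim_fraction <= 0 || rim_fraction >= 1)
      stop("`rim_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(list(center = center, semi_axes = semi_axes,
                 core_suv = core_suv, rim_suv = rim_suv,
                 rim_fraction = rim_fraction,
                 analytic_volume_cm3 = 4 / 3 * pi * prod(semi_axes) / 1000),
            class = "lesion_spec")
}

#' Phantom specification
#'
#' Describes a reproducible synthetic SUV volume: a noisy low-uptake
#' background, a liver-like region with its own mean/SD, an optional
#' aorta-like region, ellipsoidal lesions of known analytic volume, and
#' physiological hot spots (brain/bladder analogues) that threshold-based
#' tumour finders will pick up and an operator must edit out. Lesions and
#' hot spots are composed onto the background by voxelwise maximum so
#' their SUV values stay exactly as specified.
#'
#' @param shape grid dimensions (voxels).
#' @param spacing voxel edge lengths (mm).
#' @param background_suv,background_sd background mean SUV and Gaussian
#'   noise SD (values are clamped at 0).
#' @param lesions list of [lesion_spec()] objects.
#' @param liver list with `center` (mm), `size` (mm), `mean`, `sd`: a box
#'   region painted with its own Gaussian uptake.
#' @param aorta like `liver`, or `NULL`.
#' @param physiologic list of hot spots, each a list with `name`, `center`,
#'   `semi_axes`, `suv`.
#' @param box_margin_mm margin added to each lesion's bounding box when
#'   writing the constraining-box annotation (default 2 mm).
#' @param seed RNG seed; identical spec + seed gives an identical phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(50, 50, 50), spacing = c(2, 2, 2),
                         background_suv = 0.4, background_sd = 0.1,
                         lesions = list(),
                         liver = list(center = c(20, 20, 24),
                                      size = c(24, 24, 24),
                                      mean = 2.0, sd = 0.2),
                         aorta = list(center = c(20, 70, 30),
                                      size = c(12, 12, 24),
                                      mean = 1.5, sd = 0.15),
                         physiologic = list(),
                         box_margin_mm = 2, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), length(spacing) == 3L,
            all(spacing > 0), background_suv >= 0, background_sd >= 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 background_suv = background_suv, background_sd = background_sd,
                 lesions = lesions, liver = liver, aorta = aorta,
                 physiologic = physiologic, box_margin_mm = box_margin_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' A ready-made two-lesion phantom specification
#'
#' Convenience builder for the phantom used throughout the examples and
#' tests: one uniform lesion (SUV 8) and one heterogeneous two-compartment
#' lesion (core SUV 10, rim SUV 4.5 by default), a liver region of mean
#' SUV 2.0, an aorta region of mean 1.5, and brain/bladder analogues at
#' SUV 12/15 on a 100 mm cube at 2 mm spacing.
#'
#' @param seed RNG seed.
#' @param lesion_scale multiplies the default lesion semi-axes, varying
#'   lesion size across phantoms.
#' @param rim_suv rim SUV of the heterogeneous lesion.
#' @param liver_mean,liver_sd liver region uptake.
#' @param box_margin_mm margin of the constraining-box annotations around
#'   each lesion's bounding box (default 2 mm; use 0 for boxes that hug
#'   the lesion, which makes the 41% method sensitive to box placement).
#' @return A [phantom_spec()].
#' @export
example_phantom_spec <- function(seed = 1L, lesion_scale = 1,
                                 rim_suv = 4.5, liver_mean = 2.0,
                                 liver_sd = 0.2, box_margin_mm = 2) {
  phantom_spec(
    box_margin_mm = box_margin_mm,
    lesions = list(
      lesion_spec(center = c(65, 30, 60),
                  semi_axes = c(14, 12, 10) * lesion_scale, core_suv = 8),
      lesion_spec(center = c(60, 70, 60),
                  semi_axes = c(12, 12, 12) * lesion_scale,
                  core_suv = 10, rim_suv = rim_suv, rim_fraction = 0.6)),
    liver = list(center = c(20, 20, 24), size = c(24, 24, 24),
                 mean = liver_mean, sd = liver_sd),
    physiologic = list(
      list(name = "brain", center = c(30, 75, 85),
           semi_axes = c(10, 10, 8), suv = 12),
      list(name = "bladder", center = c(75, 75, 12),
           semi_axes = c(8, 8, 8), suv = 15)),
    seed = seed)
}

ellipsoid_mask <- function(image, center, semi_axes) {
  sq <- lapply(1:3, function(ax)
    ((axis_centers(image, ax) - center[ax]) / semi_axes[ax])^2)
  m <- outer(outer(sq[[1]], sq[[2]], "+"), sq[[3]], "+") <= 1
  dim(m) <- dim(image$values)
  m
}

paint_box <- function(values, image, region) {
  m <- box_mask(image, box_voi(region$center, region$size))
  values[m] <- pmax(0, stats::rnorm(sum(m), region$mean, region$sd))
  values
}

#' Generate a synthetic SUV phantom with analytic ground truth
#'
#' @param spec a [phantom_spec()].
#' @return List with components:
#'   * `image`: the [suv_image()];
#'   * `truth`: list with `labels` (ground-truth lesion label array) and
#'     `volumes` (data frame of analytic and voxelised volume per lesion);
#'   * `annotations`: operator annotations -- one seed (1-based voxel
#'     index) and one constraining box per lesion, liver/aorta VOI
#'     centres, `liver_involved = FALSE` and the physiological hot-spot
#'     centres to exclude.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a `phantom_spec`", call. = FALSE)
  set.seed(spec$seed)
  dims <- spec$shape
  img0 <- suv_image(array(0, dims), spec$spacing)
  ext_hi <- img0$origin + (dims - 1) * spec$spacing
  values <- array(pmax(0, stats::rnorm(prod(dims), spec$background_suv,
                                       spec$background_sd)), dims)
  if (!is.null(spec$liver)) values <- paint_box(values, img0, spec$liver)
  if (!is.null(spec$aorta)) values <- paint_box(values, img0, spec$aorta)

  labels <- array(0L, dims)
  vols <- data.frame(lesion = integer(0), analytic_volume_cm3 = numeric(0),
                     voxel_volume_cm3 = numeric(0))
  seeds <- list(); boxes <- list()
  vv <- prod(spec$spacing) / 1000
  for (k in seq_along(spec$lesions)) {
    les <- spec$lesions[[k]]
    if (any(les$center - les$semi_axes < img0$origin - spec$spacing / 2) ||
        any(les$center + les$semi_axes > ext_hi + spec$spacing / 2))
      stop(sprintf("lesion %d extends outside the grid", k), call. = FALSE)
    m <- ellipsoid_mask(img0, les$center, les$semi_axes)
    if (any(labels[m] > 0L))
      stop(sprintf("lesion %d overlaps another lesion", k), call. = FALSE)
    lesion_vals <- array(0, dims)
    if (is.null(les$rim_suv)) {
      lesion_vals[m] <- les$core_suv
    } else {
      core <- ellipsoid_mask(img0, les$center, les$semi_axes * les$rim_fraction)
      lesion_vals[m] <- les$rim_suv
      lesion_vals[core] <- les$core_suv
    }
    values <- pmax(values, lesion_vals)
    labels[m] <- k
    vols <- rbind(vols, data.frame(lesion = k,
                                   analytic_volume_cm3 = les$analytic_volume_cm3,
                                   voxel_volume_cm3 = sum(m) * vv))
    seeds[[k]] <- as.integer(round((les$center - img0$origin) / spec$spacing) + 1L)
    boxes[[k]] <- list(center = les$center,
                       size = 2 * les$semi_axes + 2 * spec$box_margin_mm)
  }
  excluded_centers <- list()
  for (ps in spec$physiologic) {
    m <- ellipsoid_mask(img0, ps$center, ps$semi_axes)
    hot <- array(0, dims); hot[m] <- ps$suv
    values <- pmax(values, hot)
    excluded_centers[[length(excluded_centers) + 1L]] <-
      list(name = ps$name, center = ps$center)
  }
  image <- suv_image(values, spec$spacing, img0$origin)
  annotations <- list(
    patient_id = sprintf("phantom_%03d", spec$seed),
    seeds = seeds, boxes = boxes,
    liver_center = if (!is.null(spec$liver)) spec$liver$center,
    aorta_center = if (!is.null(spec$aorta)) spec$aorta$center,
    liver_involved = FALSE,
    excluded_centers = excluded_centers)
  list(image = image,
       truth = list(labels = labels, volumes = vols),
       annotations = annotations)
}

#' Perturb operator annotations (second-observer emulation)
#'
#' Displaces every seed, constraining-box centre and reference-VOI centre
#' by an independent uniform jitter in `[-jitter_mm, jitter_mm]` per axis,
#' emulating a second observer's clicks. Seed displacements are rounded to
#' whole voxels and redrawn (up to `max_retries`) if they land on a voxel
#' below `min_seed_suv`, i.e. outside avid disease -- a real observer would
#' re-click. Deterministic for a given seed; `jitter_mm = 0` is the
#' identity.
#'
#' @param annotations annotation list from [generate_phantom()].
#' @param image the phantom [suv_image()].
#' @param jitter_mm maximum per-axis displacement (mm).
#' @param seed RNG seed.
#' @param min_seed_suv jittered seeds must land on SUV >= this (default 2.5).
#' @param max_retries bounded redraws per seed before erroring.
#' @return The perturbed annotation list.
#' @export
perturb_annotations <- function(annotations, image, jitter_mm = 2, seed = 1L,
                                min_seed_suv = 2.5, max_retries = 20L) {
  if (jitter_mm < 0) stop("`jitter_mm` must be >= 0", call. = FALSE)
  if (jitter_mm == 0) return(annotations)
  stop_if_not_image(image)
  set.seed(seed)
  out <- annotations
  dims <- dim(image$values)
  for (k in seq_along(out$seeds)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      delta <- stats::runif(3, -jitter_mm, jitter_mm)
      idx <- out$seeds[[k]] + as.integer(round(delta / image$spacing))
      if (all(idx >= 1L) && all(idx <= dims) &&
          image$values[idx[1], idx[2], idx[3]] >= min_seed_suv) {
        out$seeds[[k]] <- idx; ok <- TRUE; break
      }
    }
    if (!ok)
      stop(sprintf("jitter ejected seed %d from its lesion after %d retries",
                   k, max_retries), call. = FALSE)
  }
  for (k in seq_along(out$boxes))
    out$boxes[[k]]$center <- out$boxes[[k]]$center +
      stats::runif(3, -jitter_mm, jitter_mm)
  if (!is.null(out$liver_center))
    out$liver_center <- out$liver_center + stats::runif(3, -jitter_mm, jitter_mm)
  if (!is.null(out$aorta_center))
    out$aorta_center <- out$aorta_center + stats::runif(3, -jitter_mm, jitter_mm)
  out
}

hazard_from_5y_survival <- function(s5) -log(s5) / FIVE_YEARS_DAYS

#' Cohort specification
#'
#' Parameters of the simulated patient cohort. The defaults are the study
#' conditions the package is calibrated to: 147 patients; fixed-threshold
#' MTV drawn as a cubed truncated normal (normal on the cube-root scale,
#' so the raw distribution is strongly right-skewed and fails a normality
#' check while its cube root passes), with cube-root mean `592^(1/3)` and
#' SD chosen to match observed quartiles of roughly 147 and 1387 cm^3; a
#' generating cut-off of 400 cm^3 separating 5-year PFS of 85% (low) from
#' 43% (high) under exponential hazards; uniform administrative censoring
#' over a 1.3-7.9 year follow-up window; a 41%-method column equal to a
#' patient-specific Beta-distributed fraction of the fixed-threshold MTV
#' (mean ~0.27); and a PERCIST column equal to the fixed-threshold MTV
#' inflated in a low-liver-uptake subset (~12% of patients).
#'
#' @param n cohort size.
#' @param mu_cbrt,sd_cbrt mean and SD of MTV^(1/3) (cm).
#' @param cutoff_true generating cut-off (cm^3) on the fixed-threshold MTV.
#' @param s5_pfs_low,s5_pfs_high 5-year PFS of the low/high groups.
#' @param s5_os_low,s5_os_high 5-year OS of the low/high groups.
#' @param followup_years administrative censoring window (years).
#' @param pct41_shape Beta shape parameters of the per-patient 41%/fixed
#'   volume fraction.
#' @param alt_software_sd log-scale SD of the second fixed-threshold
#'   software implementation around the first.
#' @param percist_noise_sd log-scale SD of the PERCIST column around the
#'   fixed-threshold column.
#' @param low_liver_frac fraction of patients whose low liver uptake
#'   inflates the PERCIST MTV.
#' @param percist_inflate uniform range of that inflation factor.
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 147L,
                        mu_cbrt = 592^(1 / 3),
                        sd_cbrt = (1387^(1 / 3) - 147^(1 / 3)) / (2 * stats::qnorm(0.75)),
                        cutoff_true = 400,
                        s5_pfs_low = 0.85, s5_pfs_high = 0.43,
                        s5_os_low = 0.89, s5_os_high = 0.55,
                        followup_years = c(1.3, 7.9),
                        pct41_shape = c(8.1, 21.9),
                        alt_software_sd = 0.015,
                        percist_noise_sd = 0.03,
                        low_liver_frac = 0.12,
                        percist_inflate = c(1.2, 2.2),
                        seed = 1L) {
  stopifnot(n >= 2L, sd_cbrt > 0, cutoff_true > 0,
            s5_pfs_low > s5_pfs_high, s5_pfs_high > 0,
            s5_os_low > s5_os_high, s5_os_high > 0,
            length(followup_years) == 2L, followup_years[1] > 0,
            followup_years[2] > followup_years[1])
  structure(list(n = as.integer(n), mu_cbrt = mu_cbrt, sd_cbrt = sd_cbrt,
                 cutoff_true = cutoff_true,
                 s5_pfs_low = s5_pfs_low, s5_pfs_high = s5_pfs_high,
                 s5_os_low = s5_os_low, s5_os_high = s5_os_high,
                 followup_years = followup_years, pct41_shape = pct41_shape,
                 alt_software_sd = alt_software_sd,
                 percist_noise_sd = percist_noise_sd,
                 low_liver_frac = low_liver_frac,
                 percist_inflate = percist_inflate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient MTV for the four measurement columns, assigns each
#' patient to the low/high group by the generating cut-off on the
#' fixed-threshold MTV, and simulates right-censored PFS and OS times from
#' group-specific exponential hazards (`lambda = -log(S5) / (5 x 365.25)`)
#' with uniform administrative censoring. PFS and OS event times are drawn
#' per endpoint; the cohort emulates the marginal structure of each
#' endpoint, not a joint multistate process.
#'
#' @param spec a [cohort_spec()].
#' @return A `data.frame` (the cohort table) with columns `id`,
#'   `mtv_fixed25`, `mtv_fixed25_alt`, `mtv_pct41`, `mtv_percist`,
#'   `time_pfs`, `event_pfs`, `time_os`, `event_os`, `true_group`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("expected a `cohort_spec`", call. = FALSE)
  set.seed(spec$seed)
  n <- spec$n
  cbrt <- stats::rnorm(n, spec$mu_cbrt, spec$sd_cbrt)
  while (any(cbrt <= 0.1))
    cbrt[cbrt <= 0.1] <- stats::rnorm(sum(cbrt <= 0.1), spec$mu_cbrt, spec$sd_cbrt)
  fixed25 <- cbrt^3
  fixed25_alt <- fixed25 * exp(stats::rnorm(n, 0, spec$alt_software_sd))
  pct41 <- fixed25 * stats::rbeta(n, spec$pct41_shape[1], spec$pct41_shape[2])
  percist <- fixed25 * exp(stats::rnorm(n, 0, spec$percist_noise_sd))
  low_liver <- stats::runif(n) < spec$low_liver_frac
  percist[low_liver] <- percist[low_liver] *
    stats::runif(sum(low_liver), spec$percist_inflate[1], spec$percist_inflate[2])
  group <- ifelse(fixed25 >= spec$cutoff_true, "high", "low")

  censor <- stats::runif(n, spec$followup_years[1], spec$followup_years[2]) *
    DAYS_PER_YEAR
  lam_pfs <- ifelse(group == "high",
                    hazard_from_5y_survival(spec$s5_pfs_high),
                    hazard_from_5y_survival(spec$s5_pfs_low))
  lam_os <- ifelse(group == "high",
                   hazard_from_5y_survival(spec$s5_os_high),
                   hazard_from_5y_survival(spec$s5_os_low))
  t_pfs <- stats::rexp(n, lam_pfs)
  t_os <- stats::rexp(n, lam_os)
  data.frame(id = sprintf("pt%03d", seq_len(n)),
             mtv_fixed25 = fixed25, mtv_fixed25_alt = fixed25_alt,
             mtv_pct41 = pct41, mtv_percist = percist,
             time_pfs = pmin(t_pfs, censor),
             event_pfs = as.integer(t_pfs <= censor),
             time_os = pmin(t_os, censor),
             event_os = as.integer(t_os <= censor),
             true_group = group,
             stringsAsFactors = FALSE)
}
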