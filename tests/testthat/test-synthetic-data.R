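test_that("phantom generation is deterministic and respects the spec", {
  spec <- example_phantom_spec(seed = 5)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$image$values, p2$image$values)
  expect_identical(p1$truth$labels, p2$truth$labels)
  # noiseless spec is piecewise constant
  spec0 <- phantom_spec(background_suv = 0.5, background_sd = 0,
                        liver = list(center = c(20, 20, 24), size = c(24, 24, 24),
                                     mean = 2, sd = 0),
                        aorta = NULL,
                        lesions = list(lesion_spec(c(60, 60, 60), c(12, 10, 8), 6)),
                        seed = 1)
  p0 <- generate_phantom(spec0)
  expect_setequal(unique(as.vector(p0$image$values)), c(0.5, 2, 6))
  # lesions must lie inside the grid
  expect_error(generate_phantom(phantom_spec(
    lesions = list(lesion_spec(c(95, 50, 50), c(20, 10, 10), 5)))),
    "outside the grid")
})

test_that("voxelised ellipsoid volume approximates the analytic volume", {
  # uniform ellipsoid, semi-axes 20 mm -> 33.51 cm^3, 2 mm spacing
  spec <- phantom_spec(shape = c(50, 50, 50), spacing = c(2, 2, 2),
                       background_suv = 0, background_sd = 0,
                       liver = NULL, aorta = NULL,
                       lesions = list(lesion_spec(c(49.3, 48.7, 49.1),
                                                  c(20, 20, 20), 5)),
                       seed = 1)
  ph <- generate_phantom(spec)
  v <- ph$truth$volumes
  expect_equal(v$analytic_volume_cm3, 4 / 3 * pi * 20^3 / 1000)
  expect_lt(abs(v$voxel_volume_cm3 - v$analytic_volume_cm3) /
              v$analytic_volume_cm3, 0.05)
})

test_that("two-compartment lesions separate the fixed and 41% methods", {
  spec <- example_phantom_spec(seed = 2, rim_suv = 3)
  ph <- generate_phantom(spec)
  mf <- segment_fixed(ph$image, ph$annotations$seeds[[2]])
  b <- ph$annotations$boxes[[2]]
  mp <- segment_pct_max(ph$image, box_voi(b$center, b$size))
  expect_true(all(which(as.logical(mp)) %in% which(as.logical(mf))))
  expect_lt(sum(mp), sum(mf))
})

test_that("annotation jitter is bounded, deterministic and volume-preserving for flood fill", {
  ph <- generate_phantom(example_phantom_spec(seed = 6))
  ann0 <- perturb_annotations(ph$annotations, ph$image, jitter_mm = 0, seed = 1)
  expect_identical(ann0, ph$annotations)
  a1 <- perturb_annotations(ph$annotations, ph$image, jitter_mm = 2, seed = 42)
  a2 <- perturb_annotations(ph$annotations, ph$image, jitter_mm = 2, seed = 42)
  expect_identical(a1, a2)
  # displacements bounded by the jitter
  for (k in seq_along(a1$seeds))
    expect_true(all(abs(a1$seeds[[k]] - ph$annotations$seeds[[k]]) <= 1))
  expect_true(all(abs(a1$liver_center - ph$annotations$liver_center) <= 2))
  # a 2 mm jitter cannot leave the lesion's connected component
  m0 <- segment_fixed(ph$image, ph$annotations$seeds[[1]])
  m1 <- segment_fixed(ph$image, a1$seeds[[1]])
  expect_identical(which(as.logical(m0)), which(as.logical(m1)))
  # jittered liver VOI moves the PERCIST threshold only within sampling error
  thr0 <- percist_threshold(liver_stats(ph$image, ph$annotations$liver_center))
  thr1 <- percist_threshold(liver_stats(ph$image, a1$liver_center))
  expect_lt(abs(thr1 - thr0), 0.5)
})

test_that("cohort generation matches its calibrated structure", {
  co <- generate_cohort(cohort_spec(seed = 11))
  expect_equal(nrow(co), 147)
  expect_true(all(co$time_pfs > 0) && all(co$time_os > 0))
  expect_true(all(co$event_pfs %in% 0:1) && all(co$event_os %in% 0:1))
  expect_identical(co, generate_cohort(cohort_spec(seed = 11)))
  # skewed raw MTV; the 41% column is ~27% of the fixed column
  expect_gt(mean(co$mtv_fixed25) / median(co$mtv_fixed25), 1.3)
  expect_lt(abs(mean(co$mtv_pct41 / co$mtv_fixed25) - 0.27), 0.05)
  # PERCIST is inflated for a subset, never hugely deflated
  expect_gt(mean(co$mtv_percist > co$mtv_fixed25 * 1.15), 0.05)
  expect_gt(mean(co$mtv_percist), mean(co$mtv_fixed25))
  # high group has worse outcomes
  expect_gt(mean(co$event_pfs[co$true_group == "high"]),
            mean(co$event_pfs[co$true_group == "low"]))
})

test_that("five-year group survival is recovered within binomial error", {
  # exponential S(t) = exp(-lambda t) fixes lambda from the target S(5y)
  co <- do.call(rbind, lapply(1:4, function(s)
    generate_cohort(cohort_spec(seed = 300 + s))))
  for (g in c("low", "high")) {
    idx <- co$true_group == g
    km <- km_estimate(co$time_pfs[idx], co$event_pfs[idx], g)
    target <- if (g == "low") 0.85 else 0.43
    expect_lt(abs(km$surv_5y - target), 3 * sqrt(target * (1 - target) / sum(idx)))
  }
})

test_that("equal hazards give null log-rank behaviour", {
  ps <- vapply(1:30, function(s) {
    co <- generate_cohort(cohort_spec(s5_pfs_low = 0.65, s5_pfs_high = 0.649,
                                      s5_os_low = 0.75, s5_os_high = 0.749,
                                      seed = 500 + s))
    g <- co$true_group == "high"
    logrank_test(co$time_pfs[!g], co$event_pfs[!g],
                 co$time_pfs[g], co$event_pfs[g])$p
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.2)   # ~5% expected under the null
  expect_gt(mean(ps), 0.25)          # p roughly uniform, not piled at 0
})
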