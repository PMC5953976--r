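# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: components via igraph on a pairwise adjacency
# graph, quantiles via the explicit order-statistic formula, ICC via raw
# sums of squares, Kendall's tau via exhaustive pair enumeration.

toy_image <- function(values, spacing = c(10, 10, 10), origin = c(0, 0, 0)) {
  suv_image(values, spacing = spacing, origin = origin)
}

# Brute-force connected-component labelling: build the voxel adjacency graph
# explicitly and take igraph components. O(n^2); small grids only.
bf_label_components <- function(mask, connectivity = 26L) {
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  out <- array(0L, dims)
  if (n == 0L) return(out)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- abs(idx[i, ] - idx[j, ])
    ok <- switch(as.character(connectivity),
                 "6" = sum(d) == 1,
                 "18" = max(d) <= 1 && sum(d) <= 2,
                 "26" = max(d) <= 1 && sum(d) >= 1)
    if (ok) adj[i, j] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  # relabel by decreasing size, ties by first (column-major) voxel
  lin <- (idx[, 3] - 1) * dims[1] * dims[2] + (idx[, 2] - 1) * dims[1] + idx[, 1]
  sizes <- tabulate(memb)
  firsts <- vapply(seq_along(sizes), function(k) min(lin[memb == k]), numeric(1))
  relab <- integer(length(sizes))
  relab[order(-sizes, firsts)] <- seq_along(sizes)
  out[cbind(idx)] <- relab[memb]
  out
}

# Type-7 quantile by the textbook formula: h = (n-1)p + 1, linear
# interpolation between floor(h) and floor(h)+1 order statistics.
type7_quantile_oracle <- function(x, p) {
  xs <- sort(x); n <- length(xs)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    if (lo >= n) return(xs[n])
    xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
  }, numeric(1))
}

# ICC(3,1) consistency from raw sums of squares (k = 2 raters).
icc_oracle <- function(a, b) {
  n <- length(a); k <- 2
  y <- cbind(a, b)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  rater_means <- colMeans(y)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_rater <- n * sum((rater_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_rater
  msr <- ss_subj / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

# Tie-corrected Kendall tau-b by exhaustive concordant/discordant counting.
tau_b_oracle <- function(a, b) {
  n <- length(a)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(x) sum(sapply(table(x), function(t) t * (t - 1) / 2))
  (conc - disc) / sqrt((n0 - tie_term(a)) * (n0 - tie_term(b)))
}

# Standard two-lesion phantom batch for observer studies.
observer_study <- function(n_phantoms, jitter_mm = 2, base_seed = 100) {
  rows <- list()
  for (i in seq_len(n_phantoms)) {
    ph <- generate_phantom(example_phantom_spec(
      seed = base_seed + i, lesion_scale = 0.7 + 0.6 * ((i - 1) / max(1, n_phantoms - 1)),
      box_margin_mm = 0))
    recs_a <- measure_patient(ph$image, ph$annotations, observer_id = "obsA")
    ann_b <- perturb_annotations(ph$annotations, ph$image,
                                 jitter_mm = jitter_mm, seed = base_seed + 500 + i)
    recs_b <- measure_patient(ph$image, ann_b, observer_id = "obsB")
    rows[[i]] <- do.call(rbind, c(lapply(recs_a, as.data.frame),
                                  lapply(recs_b, as.data.frame)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
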