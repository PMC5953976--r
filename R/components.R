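#' Neighbour offsets for a 3-D connectivity scheme
#'
#' @param connectivity 6 (face), 18 (face+edge) or 26 (face+edge+vertex).
#' @return Integer matrix with one `(di, dj, dk)` offset per row.
#' @keywords internal
conn_offsets <- function(connectivity = 26L) {
  d <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  ord <- rowSums(abs(d))
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1,
                 "18" = ord <= 2,
                 "26" = rep(TRUE, nrow(d)),
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  storage.mode(d) <- "integer"
  unname(d[keep, , drop = FALSE])
}

lin_index <- function(idx, dims) {
  (idx[, 3L] - 1L) * (dims[1L] * dims[2L]) + (idx[, 2L] - 1L) * dims[1L] + idx[, 1L]
}

# Breadth-first flood fill from one seed over a logical array, expanding the
# whole frontier at once (vectorised over candidate neighbours).
flood_fill <- function(mask, seed, offsets) {
  dims <- dim(mask)
  visited <- array(FALSE, dims)
  frontier <- matrix(as.integer(seed), ncol = 3L)
  if (!mask[frontier]) stop("seed voxel is not in the mask", call. = FALSE)
  visited[frontier] <- TRUE
  m <- nrow(offsets)
  while (nrow(frontier) > 0L) {
    n <- nrow(frontier)
    cand <- frontier[rep(seq_len(n), each = m), , drop = FALSE] +
      offsets[rep.int(seq_len(m), n), , drop = FALSE]
    ok <- cand[, 1L] >= 1L & cand[, 1L] <= dims[1L] &
          cand[, 2L] >= 1L & cand[, 2L] <= dims[2L] &
          cand[, 3L] >= 1L & cand[, 3L] <= dims[3L]
    cand <- cand[ok, , drop = FALSE]
    li <- lin_index(cand, dims)
    first <- !duplicated(li)
    cand <- cand[first, , drop = FALSE]; li <- li[first]
    keep <- mask[li] & !visited[li]
    cand <- cand[keep, , drop = FALSE]; li <- li[keep]
    visited[li] <- TRUE
    frontier <- cand
  }
  visited
}

#' Label the connected components of a binary 3-D mask
#'
#' Components are labelled `1..K` in decreasing order of voxel count, with
#' ties broken by the column-major (scan-order) position of each component's
#' first voxel, so the output is fully deterministic.
#'
#' @param mask logical 3-D array.
#' @param connectivity 6, 18 or 26 (default 26, vertex-adjacent).
#' @return Integer array of the same shape; 0 is background.
#' @export
label_components <- function(mask, connectivity = 26L) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3-D array", call. = FALSE)
  offsets <- conn_offsets(connectivity)
  dims <- dim(mask)
  labels <- array(0L, dims)
  remaining <- which(mask)
  comp_first <- integer(0)
  k <- 0L
  while (length(remaining) > 0L) {
    k <- k + 1L
    start <- remaining[1L]
    seed <- arrayInd(start, dims)
    comp <- flood_fill(mask, seed, offsets)
    labels[comp] <- k
    comp_first[k] <- start
    remaining <- remaining[!comp[remaining]]
  }
  if (k > 1L) {
    sizes <- tabulate(labels[labels > 0L], nbins = k)
    ord <- order(-sizes, comp_first)
    relab <- integer(k)
    relab[ord] <- seq_len(k)
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
  }
  labels
}
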