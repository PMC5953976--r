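#' Write operator annotations to a JSON sidecar
#'
#' The sidecar carries everything an operator supplies per patient: one
#' seed voxel (1-based index) and one constraining box per lesion, the
#' liver and aorta reference-VOI centres (mm), the liver-involvement flag
#' and the centres of physiological regions to exclude.
#'
#' @param annotations annotation list (see [generate_phantom()]).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read operator annotations from a JSON sidecar
#'
#' @param path path to a `.json` file written by [write_annotations()].
#' @return The annotation list, with seeds as integer index triples and
#'   centres as numeric length-3 vectors.
#' @export
read_annotations <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = TRUE)
  ann$seeds <- lapply(seq_len(nrow_or_len(ann$seeds)), function(i)
    as.integer(row_or_elt(ann$seeds, i)))
  if (!is.null(ann$boxes)) {
    if (is.data.frame(ann$boxes)) {
      ann$boxes <- lapply(seq_len(nrow(ann$boxes)), function(i)
        list(center = as.numeric(ann$boxes$center[[i]]),
             size = as.numeric(ann$boxes$size[[i]])))
    } else {
      ann$boxes <- lapply(ann$boxes, function(b)
        list(center = as.numeric(b$center), size = as.numeric(b$size)))
    }
  }
  if (!is.null(ann$liver_center)) ann$liver_center <- as.numeric(ann$liver_center)
  if (!is.null(ann$aorta_center)) ann$aorta_center <- as.numeric(ann$aorta_center)
  if (!is.null(ann$excluded_centers)) {
    if (is.data.frame(ann$excluded_centers)) {
      ann$excluded_centers <- lapply(seq_len(nrow(ann$excluded_centers)),
        function(i) list(name = ann$excluded_centers$name[[i]],
                         center = as.numeric(ann$excluded_centers$center[[i]])))
    } else {
      ann$excluded_centers <- lapply(ann$excluded_centers, function(e)
        list(name = e$name, center = as.numeric(e$center)))
    }
  }
  ann
}

nrow_or_len <- function(x) if (is.matrix(x) || is.data.frame(x)) nrow(x) else length(x)
row_or_elt <- function(x, i) if (is.matrix(x) || is.data.frame(x)) x[i, ] else x[[i]]
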