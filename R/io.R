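#' Read and write trajectory tables
#'
#' Trajectories are exchanged as plain CSV with the header
#' `track_id, frame, t_min, x_um, y_um`.
#'
#' @param tracks trajectory data.frame.
#' @param path CSV file path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` the
#'   trajectory data.frame.
#' @export
write_tracks <- function(tracks, path) {
  need <- c("track_id", "frame", "t_min", "x_um", "y_um")
  .assert(all(need %in% names(tracks)), "tracks must carry the standard columns")
  utils::write.csv(tracks[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_min", "x_um", "y_um")
  .assert(all(need %in% names(tr)), "file lacks the trajectory columns")
  tr
}

#' Write an image stack as multi-page TIFF
#'
#' @param stack rows x cols (x frames) numeric array; values are rescaled
#'   to the unit interval for storage.
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  .assert(is.array(stack) || is.matrix(stack), "stack must be an array")
  lo <- min(stack); hi <- max(stack)
  sc <- if (hi > lo) (stack - lo) / (hi - lo) else stack * 0
  sc <- if (is.matrix(sc)) t(sc) else aperm(sc, c(2, 1, 3))  # to EBImage x-y order
  EBImage::writeImage(EBImage::Image(sc), path, type = "tiff")
  invisible(path)
}

#' Read a (multi-page) TIFF into an array
#'
#' @param path TIFF file path.
#' @return matrix (single page) or rows x cols x frames array. Note that
#'   EBImage stores images x-by-y; the result is transposed to the
#'   row/column (y, x) convention used throughout this package.
#' @export
read_stack_tiff <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
}
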