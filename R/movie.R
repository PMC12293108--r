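#' Movie stacks
#'
#' A `movie_stack` is a 3D intensity array with dimensions (frame, y, x) and
#' spatial/temporal calibration attached as attributes.
#'
#' @param frames Numeric 3D array `(t, y, x)`.
#' @param pixel_size Pixel size, um.
#' @param frame_interval Frame interval, s.
#' @param scan Optional list of raster-scan metadata (`pixel_dwell`,
#'   `line_time`) for RICS stacks.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size, frame_interval, scan = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    abort("`frames` must be a 3D array (t, y, x)")
  stop_if_not_positive(pixel_size, "pixel_size")
  stop_if_not_positive(frame_interval, "frame_interval")
  structure(frames, class = "movie_stack", pixel_size = pixel_size,
            frame_interval = frame_interval, scan = scan)
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<movie_stack: %d frames of %dx%d px, px=%gum, dt=%gs>\n",
              d[1], d[2], d[3], attr(x, "pixel_size"),
              attr(x, "frame_interval")))
  invisible(x)
}

#' Extract one frame as a matrix
#' @param movie A [movie_stack()].
#' @param i Frame number (1-based).
#' @return A numeric matrix (y, x).
#' @export
get_frame <- function(movie, i) {
  matrix(movie[i, , ], nrow = dim(movie)[2], ncol = dim(movie)[3])
}

#' Read and write multi-page TIFF movies
#'
#' Intensities are stored as 32-bit float TIFF; calibration is supplied by
#' the caller on read (TIFF tags are not relied upon).
#'
#' @param movie A [movie_stack()].
#' @param path File path.
#' @param pixel_size,frame_interval Calibration to attach on read.
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` returns a [movie_stack()].
#' @export
write_movie_tiff <- function(movie, path) {
  pages <- lapply(seq_len(dim(movie)[1]), function(i) {
    m <- get_frame(movie, i)
    m / max(1, max(m))  # tiff::writeTIFF requires [0,1]; scale recorded below
  })
  scale <- vapply(seq_len(dim(movie)[1]),
                  function(i) max(1, max(get_frame(movie, i))), numeric(1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  # sidecar with per-page scale so intensities round-trip
  write.csv(data.frame(page = seq_along(scale), scale = scale),
            paste0(path, ".scale.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, pixel_size, frame_interval) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale_path <- paste0(path, ".scale.csv")
  scale <- if (file.exists(scale_path)) read.csv(scale_path)$scale else
    rep(1, length(pages))
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * scale[i]
  movie_stack(arr, pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Read a binary region mask
#'
#' Masks (e.g. nuclear-condensate regions) are 8-bit PNG or TIFF images;
#' nonzero pixels are "inside".
#'
#' @param path PNG or TIFF file path.
#' @return A logical matrix (y, x).
#' @export
read_mask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}
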