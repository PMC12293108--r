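#' Render a trajectory set into a camera movie
#'
#' Each localization is rendered as an integrated 2D Gaussian point-spread
#' function with a fixed photon budget; Poisson background and shot noise
#' are added optionally. Pixel `i` (0-based) covers
#' `[i * pixel_size, (i+1) * pixel_size)` um.
#'
#' @param ts A [trajectory_set()].
#' @param psf_sigma PSF standard deviation, um.
#' @param photons_per_frame Photons emitted per molecule per frame.
#' @param background_mean Mean background level, photons/pixel.
#' @param noise `"poisson"` (shot noise on signal + background) or `"none"`.
#' @param dims Image size in pixels, `c(ny, nx)`; default covers all
#'   positions plus a 5-sigma margin.
#' @param seed Optional integer seed.
#' @return A [movie_stack()] with one frame per movie frame
#'   (`0 ... max(frame)`).
#' @export
render_movie <- function(ts, psf_sigma = 0.15, photons_per_frame = 500,
                         background_mean = 0, noise = c("poisson", "none"),
                         dims = NULL, seed = NULL) {
  noise <- match.arg(noise)
  stop_if_not_positive(psf_sigma, "psf_sigma")
  px <- attr(ts, "pixel_size")
  set_seed_if_given(seed)
  if (is.null(dims)) {
    margin <- 5 * psf_sigma
    dims <- c(ceiling((max(ts$y_um) + margin) / px),
              ceiling((max(ts$x_um) + margin) / px))
  }
  ny <- dims[1]; nx <- dims[2]
  nf <- max(ts$frame) + 1L
  arr <- array(background_mean, dim = c(nf, ny, nx))
  xe <- (0:nx) * px  # pixel edges, um
  ye <- (0:ny) * px
  by_frame <- split(as_tibble(ts)[c("x_um", "y_um")], ts$frame)
  for (fr in names(by_frame)) {
    f <- as.integer(fr) + 1L
    img <- matrix(arr[f, , ], ny, nx)
    pts <- by_frame[[fr]]
    for (i in seq_len(nrow(pts))) {
      fx <- diff(stats::pnorm(xe, mean = pts$x_um[i], sd = psf_sigma))
      fy <- diff(stats::pnorm(ye, mean = pts$y_um[i], sd = psf_sigma))
      img <- img + photons_per_frame * outer(fy, fx)
    }
    arr[f, , ] <- img
  }
  if (noise == "poisson") {
    arr[] <- rpois(length(arr), lambda = pmax(arr, 0))
  }
  movie_stack(arr, pixel_size = px, frame_interval = attr(ts, "frame_interval"))
}

#' Simulate a confocal raster scan of diffusing particles
#'
#' Particles diffuse continuously (Brownian, periodic boundaries in a box
#' padded by 3 beam waists around the field of view); every pixel samples
#' the Gaussian illumination profile `exp(-2 r^2 / w0^2)` at that pixel's
#' acquisition time, `frame_start + row * line_time + col * pixel_dwell`
#' (row-major raster). This reproduces the time structure RICS exploits.
#'
#' @param cfg A [raster_config()].
#' @param noise `"poisson"` (shot noise) or `"none"`.
#' @param background Mean background, photons/pixel.
#' @param seed Optional integer seed.
#' @return A [movie_stack()] whose `scan` attribute records `pixel_dwell`
#'   and `line_time`; `frame_interval` is the frame period
#'   `frame_size * line_time`.
#' @export
simulate_raster_scan <- function(cfg, noise = c("poisson", "none"),
                                 background = 0, seed = NULL) {
  if (!inherits(cfg, "raster_config")) abort("`cfg` must be a raster_config")
  noise <- match.arg(noise)
  set_seed_if_given(seed)
  fs <- cfg$frame_size; nf <- cfg$n_frames
  px <- cfg$pixel_size
  fov <- fs * px
  pad <- 3 * cfg$w0
  box <- fov + 2 * pad
  n_part <- rpois(1, cfg$particle_density * box^2)

  frame_time <- fs * cfg$line_time
  n_pix <- nf * fs * fs
  # acquisition-order metadata (col fastest, then row, then frame)
  col <- rep_len(seq_len(fs), n_pix)
  row <- rep(rep(seq_len(fs), each = fs), times = nf)
  frame <- rep(seq_len(nf), each = fs * fs)
  t_pix <- (frame - 1) * frame_time + (row - 1) * cfg$line_time +
    (col - 1) * cfg$pixel_dwell
  xc <- pad + (col - 0.5) * px
  yc <- pad + (row - 0.5) * px
  sd_step <- sqrt(2 * cfg$d * diff(t_pix))

  intensity <- rep(0, n_pix)
  for (p in seq_len(n_part)) {
    xp <- runif(1, 0, box) + cumsum(c(0, rnorm(n_pix - 1, 0, sd_step)))
    yp <- runif(1, 0, box) + cumsum(c(0, rnorm(n_pix - 1, 0, sd_step)))
    dx <- xp - xc; dx <- dx - box * round(dx / box)
    dy <- yp - yc; dy <- dy - box * round(dy / box)
    intensity <- intensity + cfg$brightness * exp(-2 * (dx^2 + dy^2) / cfg$w0^2)
  }
  intensity <- intensity + background
  if (noise == "poisson") intensity <- rpois(n_pix, intensity)
  arr <- aperm(array(intensity, dim = c(fs, fs, nf)), c(3, 2, 1))
  movie_stack(arr, pixel_size = px, frame_interval = frame_time,
              scan = list(pixel_dwell = cfg$pixel_dwell,
                          line_time = cfg$line_time))
}
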