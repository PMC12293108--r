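# separable Gaussian blur with replicated edges (band-matrix formulation)
gauss_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smear <- function(n) {
    m <- matrix(0, n, n)
    for (o in -r:r) {
      j <- pmin(pmax(seq_len(n) + o, 1L), n)
      m[cbind(seq_len(n), j)] <- m[cbind(seq_len(n), j)] + k[o + r + 1]
    }
    m
  }
  smear(nrow(img)) %*% img %*% t(smear(ncol(img)))
}

# least-squares 2D Gaussian fit on a small window; local pixel-center coords
fit_gaussian_2d <- function(win, x0, y0, sigma0) {
  ny <- nrow(win); nx <- ncol(win)
  gx <- seq_len(nx) - 1; gy <- seq_len(ny) - 1
  X <- matrix(gx, ny, nx, byrow = TRUE)
  Y <- matrix(gy, ny, nx)
  obj <- function(p) {
    a <- exp(p[1]); bg <- p[2]; cx <- p[3]; cy <- p[4]; s <- exp(p[5])
    mod <- bg + a * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * s^2))
    sum((mod - win)^2)
  }
  p0 <- c(log(max(max(win) - min(win), 1e-6)), min(win), x0, y0, log(sigma0))
  fit <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 1500, reltol = 1e-9))
  list(amplitude = exp(fit$par[1]), bg = fit$par[2],
       x = fit$par[3], y = fit$par[4], sigma = exp(fit$par[5]),
       converged = fit$convergence == 0)
}

#' Detect diffraction-limited particles in one frame
#'
#' Candidate maxima are found on a band-passed (difference-of-Gaussians)
#' image as local maxima within a detection box; each candidate is refined
#' to subpixel precision by a least-squares 2D Gaussian fit. Refinements
#' that move the position by more than `max_refine_px` pixels fall back to
#' the intensity-weighted centroid of the background-subtracted window.
#'
#' @param frame Numeric matrix (y, x).
#' @param pixel_size Pixel size, um.
#' @param psf_sigma_px Expected PSF standard deviation, pixels.
#' @param box_size Detection box (local-maximum neighborhood and fit
#'   window), pixels; odd.
#' @param threshold Detection threshold in robust standard deviations of the
#'   band-passed image above its median.
#' @param max_refine_px Maximum allowed subpixel refinement shift, pixels.
#' @return A tibble with one row per localization: `x_um`, `y_um`, `x_px`,
#'   `y_px` (0-based fractional pixels), `intensity` (integrated above
#'   background), `sigma_px`, `refined`. A flat frame yields zero rows.
#' @export
detect_particles <- function(frame, pixel_size, psf_sigma_px = 1.3,
                             box_size = 7, threshold = 5,
                             max_refine_px = 1.5) {
  if (!all(is.finite(frame))) abort("`frame` must be finite")
  stop_if_not_positive(pixel_size, "pixel_size")
  empty <- tibble(x_um = numeric(), y_um = numeric(), x_px = numeric(),
                  y_px = numeric(), intensity = numeric(),
                  sigma_px = numeric(), refined = logical())
  bp <- gauss_blur(frame, psf_sigma_px) - gauss_blur(frame, 2.5 * psf_sigma_px)
  s <- mad(bp)
  if (s == 0) s <- sd(bp)
  if (!is.finite(s) || s == 0) return(empty)
  thr <- median(bp) + threshold * s
  cand <- which(bp > thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  hw <- box_size %/% 2
  ny <- nrow(frame); nx <- ncol(frame)
  out <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1, r - hw):min(ny, r + hw)
    cc <- max(1, c - hw):min(nx, c + hw)
    if (bp[r, c] < max(bp[rr, cc])) next   # not the local maximum in the box
    # ties within the box: keep only the first (top-left) occurrence
    mx <- which(bp[rr, cc] == bp[r, c], arr.ind = TRUE)
    if (rr[mx[1, 1]] != r || cc[mx[1, 2]] != c) next
    win <- frame[rr, cc]
    x0 <- c - cc[1]; y0 <- r - rr[1]   # candidate position in window coords
    g <- fit_gaussian_2d(win, x0, y0, psf_sigma_px)
    shift <- sqrt((g$x - x0)^2 + (g$y - y0)^2)
    refined <- g$converged && shift <= max_refine_px
    if (!refined) {
      w <- pmax(win - min(win), 0)
      gx <- matrix(seq_len(ncol(win)) - 1, nrow(win), ncol(win), byrow = TRUE)
      gy <- matrix(seq_len(nrow(win)) - 1, nrow(win), ncol(win))
      g$x <- sum(w * gx) / sum(w)
      g$y <- sum(w * gy) / sum(w)
      g$amplitude <- max(win) - min(win)
      g$sigma <- psf_sigma_px
    }
    x_px <- cc[1] - 1 + g$x
    y_px <- rr[1] - 1 + g$y
    out[[i]] <- tibble(x_um = px_to_um(x_px, pixel_size),
                       y_um = px_to_um(y_px, pixel_size),
                       x_px = x_px, y_px = y_px,
                       intensity = 2 * pi * g$sigma^2 * g$amplitude,
                       sigma_px = g$sigma, refined = refined)
  }
  found <- dplyr::bind_rows(out)
  if (nrow(found) == 0) empty else found
}

#' Detect particles in every frame of a movie
#'
#' @param movie A [movie_stack()].
#' @inheritParams detect_particles
#' @return A tibble of localizations with a 0-based `frame` column.
#' @export
detect_stack <- function(movie, psf_sigma_px = 1.3, box_size = 7,
                         threshold = 5, max_refine_px = 1.5) {
  px <- attr(movie, "pixel_size")
  res <- lapply(seq_len(dim(movie)[1]), function(i) {
    d <- detect_particles(get_frame(movie, i), pixel_size = px,
                          psf_sigma_px = psf_sigma_px, box_size = box_size,
                          threshold = threshold, max_refine_px = max_refine_px)
    if (nrow(d)) d$frame <- i - 1L
    d
  })
  dplyr::bind_rows(res)
}
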