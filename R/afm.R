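# AFM channel: synthesize height images of nanodot arrays and read them back.
# Protrusions (bit 1) are modeled as Gaussian bumps on a tilted, noisy
# background; read-out flattens the image, detects the dot lattice from
# row/column projections, and thresholds per-site maxima.

#' Nanodot physical model
#'
#' @param fwhm_nm Full width at half maximum of a dot (default 50 nm, the
#'   demonstrated dot size).
#' @param height_nm Dot height (default 10 nm).
#' @param pitch_nm Dot spacing; should be at least twice the FWHM so
#'   neighbouring dots stay resolvable.
#' @param noise_sd_nm Standard deviation of iid Gaussian height noise.
#' @param tilt Background plane slope, nm per pixel, `c(x, y)`.
#' @param pixel_size_nm Lateral sampling (default 5 nm/px, so a 50-nm dot
#'   spans about 10 px).
#' @return Object of class `dot_model`; `sigma_nm = fwhm / (2 sqrt(2 ln 2))`.
#' @export
dot_model <- function(fwhm_nm = 50, height_nm = 10, pitch_nm = 100,
                      noise_sd_nm = 1, tilt = c(0.01, -0.005),
                      pixel_size_nm = 5) {
  stopifnot(fwhm_nm < pitch_nm, height_nm > 0, noise_sd_nm >= 0,
            pixel_size_nm > 0, length(tilt) == 2L)
  structure(list(fwhm_nm = fwhm_nm, height_nm = height_nm, pitch_nm = pitch_nm,
                 noise_sd_nm = noise_sd_nm, tilt = as.numeric(tilt),
                 pixel_size_nm = pixel_size_nm,
                 sigma_nm = fwhm_nm / (2 * sqrt(2 * log(2)))),
            class = "dot_model")
}

#' Height image container
#' @param heights Numeric matrix of heights in nm (rows = y, columns = x).
#' @param pixel_size_nm Lateral size of one pixel.
#' @return Object of class `height_image`.
#' @export
height_image <- function(heights, pixel_size_nm) {
  heights <- as.matrix(heights)
  stopifnot(is.numeric(heights), all(is.finite(heights)), pixel_size_nm > 0)
  structure(list(heights = heights, pixel_size_nm = pixel_size_nm),
            class = "height_image")
}

#' @export
print.height_image <- function(x, ...) {
  cat(sprintf("<height_image> %d x %d px, %.3g nm/px, range [%.2f, %.2f] nm\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size_nm,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Synthesize an AFM height image of a nanodot array
#'
#' Every 1-cell of the bit matrix becomes a Gaussian bump of amplitude
#' `height_nm` and width `sigma_nm` at its lattice site; a tilted background
#' plane and iid Gaussian noise are added. Deterministic under `seed`.
#'
#' @param m A [bit_matrix()] (or plain 0/1 matrix).
#' @param dot A [dot_model()].
#' @param margin_px Blank margin around the array, in pixels.
#' @param seed Integer seed for the noise; `NULL` uses the current RNG state.
#' @param max_px Guard against runaway image sizes.
#' @return A [height_image()].
#' @export
synthesize_image <- function(m, dot = dot_model(), margin_px = 12L,
                             seed = NULL, max_px = 8192L) {
  bits <- if (inherits(m, "bit_matrix")) m$bits else as.matrix(m)
  pitch_px <- dot$pitch_nm / dot$pixel_size_nm
  nr <- as.integer(ceiling((nrow(bits) - 1L) * pitch_px)) + 2L * margin_px + 1L
  nc <- as.integer(ceiling((ncol(bits) - 1L) * pitch_px)) + 2L * margin_px + 1L
  if (nr > max_px || nc > max_px)
    stop(sprintf("matrix too large for image bounds (%d x %d px > %d)",
                 nr, nc, max_px), call. = FALSE)
  render <- function() {
    img <- outer(seq_len(nr) - 1L, seq_len(nc) - 1L,
                 function(y, x) dot$tilt[2] * y + dot$tilt[1] * x)
    sigma_px <- dot$sigma_nm / dot$pixel_size_nm
    w <- ceiling(4 * sigma_px)
    prof <- function(centre, n) {
      lo <- max(1L, floor(centre - w)); hi <- min(n, ceiling(centre + w))
      list(idx = lo:hi, g = exp(-((lo:hi - centre)^2) / (2 * sigma_px^2)))
    }
    for (r in seq_len(nrow(bits))) {
      py <- prof(margin_px + 1L + (r - 1L) * pitch_px, nr)
      for (c in seq_len(ncol(bits))) {
        if (bits[r, c] == 0L) next
        px <- prof(margin_px + 1L + (c - 1L) * pitch_px, nc)
        img[py$idx, px$idx] <- img[py$idx, px$idx] +
          dot$height_nm * (py$g %o% px$g)
      }
    }
    if (dot$noise_sd_nm > 0)
      img <- img + matrix(stats::rnorm(nr * nc, sd = dot$noise_sd_nm), nr, nc)
    img
  }
  img <- if (is.null(seed)) render() else withr::with_seed(seed, render())
  height_image(img, dot$pixel_size_nm)
}

#' Remove the least-squares background plane
#'
#' Fits `z ~ 1 + x + y` over all pixels and subtracts the fit, emulating the
#' flattening step applied to raw AFM scans. Idempotent (a projection).
#'
#' @param img A [height_image()].
#' @return The flattened [height_image()].
#' @export
plane_flatten <- function(img) {
  z <- img$heights
  nr <- nrow(z); nc <- ncol(z)
  x <- rep(seq_len(nc), each = nr)
  y <- rep(seq_len(nr), times = nc)
  fit <- stats::lm.fit(cbind(1, x, y), as.vector(z))
  height_image(matrix(fit$residuals, nr, nc), img$pixel_size_nm)
}

# Peaks of a 1-D projection profile: local maxima above a relative threshold,
# with plateau merging.
projection_peaks <- function(p, rel = 0.3) {
  p <- stats::filter(p, rep(1 / 3, 3), sides = 2)
  p[is.na(p)] <- 0
  # threshold on prominence above the baseline, robust to offset backgrounds
  base <- stats::median(p)
  thr <- base + rel * (max(p) - base)
  n <- length(p)
  cand <- which(p >= thr & p >= c(-Inf, p[-n]) & p >= c(p[-1], -Inf))
  if (length(cand) == 0L) return(numeric(0))
  # merge runs of adjacent candidates (plateaus) to their centre
  runs <- split(cand, cumsum(c(1L, diff(cand) > 2L)))
  vapply(runs, function(r) mean(r), numeric(1))
}

# Fit a 1-D lattice (origin, pitch, count) to peak positions; tolerates
# missing peaks by snapping to integer lattice indices.
fit_lattice_1d <- function(peaks) {
  if (length(peaks) < 2L)
    return(list(origin = peaks, pitch = NA_real_, count = length(peaks)))
  # base the pitch on the cluster of smallest gaps: interior lines with no
  # dots leave double/triple gaps that would bias a plain median
  d <- diff(peaks)
  base <- stats::quantile(d, 0.25, names = FALSE)
  small <- d[d <= 1.25 * base]
  pitch0 <- stats::median(small)
  k <- round((peaks - peaks[1]) / pitch0)
  fit <- stats::lm(peaks ~ k)
  pitch <- coef(fit)[[2]]
  origin <- coef(fit)[[1]]
  resid_sd <- sqrt(mean(fit$residuals^2))
  count <- max(k) + 1L
  list(origin = origin, pitch = pitch, count = as.integer(count),
       resid_sd = resid_sd)
}

# Maximum height in a window of radius w around pixel (cy, cx).
window_max <- function(z, cy, cx, w) {
  if (cy < 1 - w || cy > nrow(z) + w || cx < 1 - w || cx > ncol(z) + w)
    return(-Inf)
  ry <- max(1L, cy - w):min(nrow(z), cy + w)
  rx <- max(1L, cx - w):min(ncol(z), cx + w)
  max(z[ry, rx])
}

# Grow a fitted lattice outward while candidate boundary lines still contain
# dot-like sites: rescues edge rows/columns whose few dots fall below the
# projection peak-picking threshold. `thr` is an absolute height threshold.
extend_lattice_2d <- function(lat_r, lat_c, z, thr, w) {
  p_r <- if (is.na(lat_r$pitch)) 0 else lat_r$pitch
  p_c <- if (is.na(lat_c$pitch)) 0 else lat_c$pitch
  site_rows <- function(k_r) {
    cy <- round(lat_r$origin + k_r * p_r)
    cx <- round(lat_c$origin + (seq_len(lat_c$count) - 1L) * p_c)
    max(vapply(cx, function(x) window_max(z, cy, x, w), numeric(1)))
  }
  site_cols <- function(k_c) {
    cx <- round(lat_c$origin + k_c * p_c)
    cy <- round(lat_r$origin + (seq_len(lat_r$count) - 1L) * p_r)
    max(vapply(cy, function(y) window_max(z, y, cx, w), numeric(1)))
  }
  repeat {
    grew <- FALSE
    if (!is.na(lat_r$pitch) && site_rows(-1) > thr) {
      lat_r$origin <- lat_r$origin - lat_r$pitch
      lat_r$count <- lat_r$count + 1L; grew <- TRUE
    }
    if (!is.na(lat_r$pitch) && site_rows(lat_r$count) > thr) {
      lat_r$count <- lat_r$count + 1L; grew <- TRUE
    }
    if (!is.na(lat_c$pitch) && site_cols(-1) > thr) {
      lat_c$origin <- lat_c$origin - lat_c$pitch
      lat_c$count <- lat_c$count + 1L; grew <- TRUE
    }
    if (!is.na(lat_c$pitch) && site_cols(lat_c$count) > thr) {
      lat_c$count <- lat_c$count + 1L; grew <- TRUE
    }
    if (!grew) break
  }
  list(lat_r = lat_r, lat_c = lat_c)
}

#' Detect the dot lattice in a flattened image
#'
#' Projects the positive part of the image onto rows and columns, locates
#' projection peaks, and fits a regular 1-D lattice per axis. Accurate to
#' about half a pixel on clean synthetic arrays.
#'
#' @param img A flattened [height_image()] containing at least 4 dots.
#' @return List with `origin_px` (row, col of the first site), `pitch_px`,
#'   `rows`, `cols`.
#' @export
detect_grid <- function(img) {
  z <- pmax(img$heights, 0)
  lat_r <- fit_lattice_1d(projection_peaks(rowSums(z)))
  lat_c <- fit_lattice_1d(projection_peaks(colSums(z)))
  if (lat_r$count == 0L || lat_c$count == 0L)
    stop("no periodic structure found in image", call. = FALSE)
  pitch <- mean(c(lat_r$pitch, lat_c$pitch), na.rm = TRUE)
  if (!is.finite(pitch) || pitch <= 2)
    stop("no periodic structure found in image", call. = FALSE)
  for (lat in list(lat_r, lat_c)) {
    if (!is.na(lat$pitch) && !is.null(lat$resid_sd) && lat$resid_sd > 0.15 * pitch)
      stop("projection peaks are not regularly spaced", call. = FALSE)
  }
  # robust amplitude from the detected sites, then 2-D boundary refinement
  w_ext <- max(1L, round(pitch / 3))
  p_r <- if (is.na(lat_r$pitch)) 0 else lat_r$pitch
  p_c <- if (is.na(lat_c$pitch)) 0 else lat_c$pitch
  site_max <- numeric(0)
  for (r in seq_len(lat_r$count)) {
    cy <- round(lat_r$origin + (r - 1L) * p_r)
    for (c in seq_len(lat_c$count)) {
      cx <- round(lat_c$origin + (c - 1L) * p_c)
      site_max <- c(site_max, window_max(z, cy, cx, w_ext))
    }
  }
  split <- otsu_split(site_max)
  above <- site_max[site_max > split]
  amplitude <- if (length(above)) stats::median(above) else max(site_max)
  ext <- extend_lattice_2d(lat_r, lat_c, z, 0.4 * amplitude, w_ext)
  lat_r <- ext$lat_r; lat_c <- ext$lat_c
  list(origin_px = c(row = lat_r$origin[[1]], col = lat_c$origin[[1]]),
       pitch_px = pitch, rows = lat_r$count, cols = lat_c$count)
}

# Otsu's histogram split on a numeric vector.
otsu_split <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(x, edges, all.inside = TRUE), n_bins),
                     nbins = n_bins)
  w <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Read an encoded square bit matrix from a flattened image
#'
#' Encoded matrices are square, but an edge row or column that is entirely
#' zero (typical for the length header and the zero padding) leaves no
#' physical dots for [detect_grid()] to see. This reader restores squareness
#' by trying every placement of the detected sub-grid within the square and
#' keeping the first whose bits decode (`validate` returns without error);
#' if none decodes it falls back to the raw detected grid.
#'
#' @param img A flattened [height_image()].
#' @param validate Function applied to a candidate [bit_matrix()]; must error
#'   on undecodable content (default [matrix_to_text()]).
#' @param threshold_frac Passed to [read_matrix()].
#' @return A [bit_matrix()].
#' @export
read_matrix_auto <- function(img, validate = matrix_to_text,
                             threshold_frac = 0.5) {
  grid <- detect_grid(img)
  side <- max(grid$rows, grid$cols)
  for (t in 0:(side - grid$rows)) {
    for (l in 0:(side - grid$cols)) {
      g2 <- list(origin_px = c(row = grid$origin_px[["row"]] - t * grid$pitch_px,
                               col = grid$origin_px[["col"]] - l * grid$pitch_px),
                 pitch_px = grid$pitch_px, rows = side, cols = side)
      cand <- read_matrix(img, g2, threshold_frac)
      ok <- tryCatch({ validate(cand); TRUE }, error = function(e) FALSE)
      if (ok) return(cand)
    }
  }
  read_matrix(img, grid, threshold_frac)
}

#' Read a bit matrix back from a flattened height image
#'
#' For every lattice site the maximum height within a window of radius
#' `pitch/2` is taken; the robust dot amplitude is the median of site maxima
#' above the global Otsu split, and a site is a 1 iff its maximum exceeds
#' `threshold_frac` times that amplitude. An image whose candidate amplitude
#' does not clear the noise floor decodes to all zeros.
#'
#' @param img A flattened [height_image()].
#' @param grid Lattice description from [detect_grid()] (or built manually).
#' @param threshold_frac Fraction of the robust amplitude (default 0.5).
#' @return A [bit_matrix()].
#' @export
read_matrix <- function(img, grid, threshold_frac = 0.5) {
  z <- img$heights
  half <- max(1L, floor(grid$pitch_px / 2))
  site_max <- matrix(0, grid$rows, grid$cols)
  for (r in seq_len(grid$rows)) {
    cy <- round(grid$origin_px[["row"]] + (r - 1) * grid$pitch_px)
    if (cy + half < 1 || cy - half > nrow(z)) next  # site outside the scan
    ry <- max(1L, cy - half):min(nrow(z), cy + half)
    for (c in seq_len(grid$cols)) {
      cx <- round(grid$origin_px[["col"]] + (c - 1) * grid$pitch_px)
      if (cx + half < 1 || cx - half > ncol(z)) next
      rx <- max(1L, cx - half):min(ncol(z), cx + half)
      site_max[r, c] <- max(z[ry, rx])
    }
  }
  # noise floor from adjacent-pixel differences: dots are smooth at this
  # sampling, so first differences are noise-dominated even in dense arrays
  noise <- stats::mad(as.vector(z[, -1] - z[, -ncol(z)])) / sqrt(2)
  split <- otsu_split(as.vector(site_max))
  above <- site_max[site_max > split]
  amplitude <- if (length(above)) stats::median(above) else 0
  bits <- if (amplitude > 5 * noise && amplitude > 0)
    (site_max > threshold_frac * amplitude) * 1L
  else
    matrix(0L, grid$rows, grid$cols)
  bit_matrix(matrix(as.integer(bits), grid$rows, grid$cols),
             pitch_nm = grid$pitch_px * img$pixel_size_nm)
}
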