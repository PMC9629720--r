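# Synthetic microscopy/AFM-like images with ground truth, prominence-based
# maxima detection, difference-of-Gaussians bandpass filtering, cell
# normalisation and photobleaching copy-number estimation.
#
# Images are numeric matrices indexed [row (y), col (x)]; peak and emitter
# coordinates are (x = column, y = row) in pixels.

.gauss_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, 0, sigma)
  k / sum(k)
}

#' Gaussian blur of an image (separable, edge-replicated)
#'
#' @param img Numeric matrix.
#' @param sigma Gaussian sd in pixels.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- .gauss_kernel(sigma)
  h <- (length(k) - 1) / 2
  conv_cols <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (j in -h:h) {
      idx <- pmin(pmax(seq_len(ncol(m)) + j, 1), ncol(m))
      out <- out + k[j + h + 1] * m[, idx, drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(img))))
}

#' Difference-of-Gaussians bandpass filter
#'
#' Approximates an FFT bandpass that passes structures between `small_px`
#' and `large_px` pixels: blur at sigma `small_px / 2` minus blur at sigma
#' `large_px / 2`. The response to a constant image is identically zero.
#'
#' @param img Numeric matrix.
#' @param small_px Small structure bound in px (> 0).
#' @param large_px Large structure bound in px (> `small_px`).
#' @return Filtered matrix (zero-mean response to constants).
#' @export
bandpass_filter <- function(img, small_px = 1, large_px = 20) {
  if (!(small_px > 0 && large_px > small_px))
    stop("configuration error: need 0 < small_px < large_px")
  gaussian_blur(img, small_px / 2) - gaussian_blur(img, large_px / 2)
}

#' Find local maxima by topographic prominence
#'
#' Reimplements prominence-thresholded maxima detection ("find maxima" with
#' a prevalence setting): pixels are processed from high to low and merged
#' into growing components (8-connectivity); when a component is absorbed by
#' one with a higher peak, its prominence is its peak height above the
#' current (saddle) level, and it is reported as a maximum if the prominence
#' reaches the threshold. Plateau ties are broken by scan order. Maxima
#' outside the optional mask are removed.
#'
#' @param img Numeric matrix.
#' @param prominence Minimum prominence (intensity units), default 20.
#' @param mask Optional logical matrix; maxima where `mask` is `FALSE` are
#'   dropped.
#' @return data.frame `x`, `y` (px), `value`, `prominence`, ordered by
#'   decreasing value.
#' @export
find_maxima <- function(img, prominence = 20, mask = NULL) {
  if (prominence <= 0) stop("domain error: prominence must be > 0")
  nr <- nrow(img); nc <- ncol(img); n <- nr * nc
  v <- as.numeric(img)
  ord <- order(-v, seq_len(n))
  parent <- integer(n)             # 0 = unprocessed
  peak_px <- integer(n)            # root -> peak pixel
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  peaks <- list()
  noff <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (p in ord) {
    r <- ((p - 1L) %% nr) + 1L
    co <- ((p - 1L) %/% nr) + 1L
    roots <- integer(0)
    for (k in 1:8) {
      q <- p + noff[k]
      if (q < 1L || q > n) next
      qr <- ((q - 1L) %% nr) + 1L
      if (abs(qr - r) > 1L) next        # row wrap across column boundary
      if (parent[q] != 0L) roots <- c(roots, find(q))
    }
    roots <- unique(roots)
    if (!length(roots)) {
      parent[p] <- p
      peak_px[p] <- p
    } else {
      main <- roots[which.max(v[peak_px[roots]])]
      parent[p] <- main
      for (rt in roots) {
        if (rt == main) next
        prom <- v[peak_px[rt]] - v[p]
        if (prom >= prominence)
          peaks[[length(peaks) + 1L]] <- c(peak_px[rt], prom)
        parent[rt] <- main
      }
    }
  }
  # surviving components: prominence relative to the image minimum
  roots <- which(parent == seq_len(n))
  for (rt in roots) {
    prom <- v[peak_px[rt]] - min(v)
    if (prom >= prominence && prom > 0)
      peaks[[length(peaks) + 1L]] <- c(peak_px[rt], prom)
  }
  if (!length(peaks))
    return(data.frame(x = integer(0), y = integer(0),
                      value = numeric(0), prominence = numeric(0)))
  pm <- do.call(rbind, peaks)
  out <- data.frame(x = ((pm[, 1] - 1L) %/% nr) + 1L,
                    y = ((pm[, 1] - 1L) %% nr) + 1L,
                    value = v[pm[, 1]], prominence = pm[, 2])
  if (!is.null(mask)) out <- out[mask[cbind(out$y, out$x)], , drop = FALSE]
  out <- out[order(-out$value, out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a synthetic labelled-cell or pore-lattice image
#'
#' Sums Gaussian point-spread functions at the ground-truth emitter
#' positions over a background (scalar or matrix, e.g. a cell-curvature
#' dome), then applies seeded Poisson shot noise and Gaussian read noise.
#' Emitter `intensity` is the integrated (summed) count of one emitter, so
#' an island of N emitters adds N times that to its ROI sum.
#'
#' @param truth list with `dim` (c(rows, cols)), `emitters` (data.frame
#'   `x`, `y`, `intensity`, optional `island`), optional `cells` (data.frame
#'   `x`, `y`, `length`, `width`, `angle` in px/radians), optional
#'   `pixel_size` (nm/px).
#' @param psf_sigma PSF sd in px. Default 1.5.
#' @param background Scalar background level or matrix of `truth$dim`.
#' @param poisson Apply Poisson shot noise? Default `FALSE`.
#' @param gaussian_sd Read-noise sd, default 0 (noiseless).
#' @param seed Integer seed for the noise.
#' @return object of class `synthetic_image`: `raster`, `pixel_size`,
#'   `ground_truth`, `psf_sigma`, `noise`.
#' @export
render_cells <- function(truth, psf_sigma = 1.5, background = 0,
                         poisson = FALSE, gaussian_sd = 0, seed = 1L) {
  dm <- truth$dim
  em <- truth$emitters
  if (any(em$x < 1 | em$x > dm[2] | em$y < 1 | em$y > dm[1]))
    stop("generation error: emitters outside frame")
  img <- matrix(0, dm[1], dm[2])
  if (nrow(em)) {
    amp <- em$intensity / (2 * pi * psf_sigma^2)
    xs <- seq_len(dm[2]); ys <- seq_len(dm[1])
    for (i in seq_len(nrow(em))) {
      gx <- exp(-(xs - em$x[i])^2 / (2 * psf_sigma^2))
      gy <- exp(-(ys - em$y[i])^2 / (2 * psf_sigma^2))
      img <- img + amp[i] * outer(gy, gx)
    }
  }
  img <- img + background
  if (poisson || gaussian_sd > 0) {
    img <- .with_seed(derive_seed(seed, "image-noise"), {
      out <- img
      if (poisson) out <- matrix(stats::rpois(length(out), pmax(out, 0)),
                                 nrow(out), ncol(out))
      if (gaussian_sd > 0)
        out <- out + matrix(stats::rnorm(length(out), 0, gaussian_sd),
                            nrow(out), ncol(out))
      out
    })
  }
  structure(list(raster = img,
                 pixel_size = if (is.null(truth$pixel_size)) 1
                              else truth$pixel_size,
                 ground_truth = truth, psf_sigma = psf_sigma,
                 noise = list(poisson = poisson, gaussian_sd = gaussian_sd,
                              background = background)),
            class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat("Synthetic image:", nrow(x$raster), "x", ncol(x$raster), "px,",
      nrow(x$ground_truth$emitters), "ground-truth emitters,",
      x$pixel_size, "nm/px\n")
  invisible(x)
}

#' Ground truth for a field of labelled cells with OMP islands
#'
#' Capsule-shaped cells on a jittered grid, each carrying clusters
#' ("islands") of emitters with seeded copy numbers in `copies` (default
#' 20--30, the observed island copy-number range).
#'
#' @param n_cells Number of cells. Default 4.
#' @param islands_per_cell Emitter clusters per cell. Default 3.
#' @param copies Integer vector of candidate island copy numbers.
#' @param emitter_intensity Integrated counts per emitter. Default 90.
#' @param dim Image size c(rows, cols) in px. Default c(192, 192).
#' @param pixel_size nm per px. Default 100.
#' @param seed Integer seed.
#' @return truth list consumable by [render_cells()].
#' @export
synth_cell_field <- function(n_cells = 4, islands_per_cell = 3,
                             copies = 20:30, emitter_intensity = 90,
                             dim = c(192, 192), pixel_size = 100, seed = 1L) {
  .with_seed(derive_seed(seed, "cell-field"), {
    ncol_grid <- ceiling(sqrt(n_cells))
    nrow_grid <- ceiling(n_cells / ncol_grid)
    cw <- dim[2] / ncol_grid; ch <- dim[1] / nrow_grid
    cells <- data.frame(
      x = (((seq_len(n_cells) - 1) %% ncol_grid) + 0.5) * cw +
        stats::runif(n_cells, -2, 2),
      y = (((seq_len(n_cells) - 1) %/% ncol_grid) + 0.5) * ch +
        stats::runif(n_cells, -2, 2),
      length = pmin(0.7 * min(cw, ch), 30),
      width = pmin(0.3 * min(cw, ch), 12),
      angle = stats::runif(n_cells, 0, pi)
    )
    em <- list(); isl <- list()
    island_id <- 0L
    for (ci in seq_len(n_cells)) {
      for (ii in seq_len(islands_per_cell)) {
        island_id <- island_id + 1L
        u <- stats::runif(1, -0.35, 0.35) * cells$length[ci]
        w <- stats::runif(1, -0.35, 0.35) * cells$width[ci]
        cx <- cells$x[ci] + u * cos(cells$angle[ci]) - w * sin(cells$angle[ci])
        cy <- cells$y[ci] + u * sin(cells$angle[ci]) + w * cos(cells$angle[ci])
        nc <- sample(copies, 1)
        em[[island_id]] <- data.frame(
          x = cx + stats::rnorm(nc, 0, 0.8),
          y = cy + stats::rnorm(nc, 0, 0.8),
          intensity = emitter_intensity, island = island_id, cell = ci)
        isl[[island_id]] <- data.frame(island = island_id, cell = ci,
                                       x = cx, y = cy, n_emitters = nc)
      }
    }
    list(dim = dim, pixel_size = pixel_size, cells = cells,
         emitters = do.call(rbind, em), islands = do.call(rbind, isl))
  })
}

#' Ground truth for an AFM-like porin lattice image
#'
#' Pores on a triangular lattice at the given spacing, for benchmarking the
#' bandpass + maxima detection pipeline against a known lattice. A broad
#' intensity dome (sd `dome_sigma` px) models cell-surface curvature.
#'
#' @param dim Image size c(rows, cols) px. Default c(200, 200).
#' @param pixel_size nm per px. Default 1.
#' @param spacing Pore spacing in nm. Default 8.5.
#' @param pore_intensity Integrated counts per pore. Default 500.
#' @param dome_amplitude Peak height of the background dome. Default 200.
#' @param dome_sigma Dome sd in px. Default 100.
#' @return truth list for [render_cells()] with a `background` matrix
#'   attached as `truth$background` and pore positions as emitters.
#' @export
synth_pore_lattice <- function(dim = c(200, 200), pixel_size = 1,
                               spacing = 8.5, pore_intensity = 500,
                               dome_amplitude = 200, dome_sigma = 100) {
  s_px <- spacing / pixel_size
  margin <- 2 * s_px
  pts <- .hex_grid(margin, min(dim) - margin, s_px)
  emitters <- data.frame(x = pts[, 1], y = pts[, 2],
                         intensity = pore_intensity,
                         island = seq_len(nrow(pts)))
  xs <- seq_len(dim[2]); ys <- seq_len(dim[1])
  dome <- dome_amplitude *
    outer(exp(-(ys - dim[1] / 2)^2 / (2 * dome_sigma^2)),
          exp(-(xs - dim[2] / 2)^2 / (2 * dome_sigma^2)))
  list(dim = dim, pixel_size = pixel_size, emitters = emitters,
       background = dome)
}

#' Normalise a cell image to unit axes and unit mean intensity
#'
#' Resamples the oriented cell bounding box onto a fixed grid (long axis
#' horizontal) by bilinear interpolation and divides by the mean intensity
#' inside the inscribed elliptical cell mask, making fluorescence
#' distributions directly comparable across cells of different sizes and
#' brightness.
#'
#' @param image Numeric matrix or `synthetic_image`.
#' @param outline list with `x`, `y` (centre, px), `length`, `width` (px)
#'   and `angle` (radians) of the cell.
#' @param out_dim Output grid c(rows, cols). Default c(33, 65).
#' @return list with `raster` (normalised, NA outside the mask) and `mask`.
#' @export
normalize_cell <- function(image, outline, out_dim = c(33, 65)) {
  img <- if (inherits(image, "synthetic_image")) image$raster else image
  if (!all(c("x", "y", "length", "width") %in% names(outline)))
    stop("geometry error: outline needs x, y, length, width")
  if (outline$length <= 0 || outline$width <= 0 ||
      pi / 4 * outline$length * outline$width < 100)
    stop("geometry error: degenerate outline (needs to enclose >= 100 px)")
  ang <- if (is.null(outline$angle)) 0 else outline$angle
  u <- seq(-0.5, 0.5, length.out = out_dim[2]) * outline$length
  w <- seq(-0.5, 0.5, length.out = out_dim[1]) * outline$width
  gx <- outline$x + outer(w, u, function(wi, ui) ui * cos(ang) - wi * sin(ang))
  gy <- outline$y + outer(w, u, function(wi, ui) ui * sin(ang) + wi * cos(ang))
  raster <- .bilinear(img, gx, gy)
  un <- matrix(rep(seq(-0.5, 0.5, length.out = out_dim[2]), each = out_dim[1]),
               out_dim[1])
  wn <- matrix(rep(seq(-0.5, 0.5, length.out = out_dim[1]), out_dim[2]),
               out_dim[1])
  mask <- (un^2 + wn^2) <= 0.25
  mu <- mean(raster[mask])
  if (!is.finite(mu) || mu == 0)
    stop("geometry error: cell mask has no usable intensity")
  raster <- raster / mu
  raster[!mask] <- NA
  list(raster = raster, mask = mask)
}

.bilinear <- function(img, gx, gy) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- pmin(pmax(gx, 1), nc); gy <- pmin(pmax(gy, 1), nr)
  x0 <- pmin(floor(gx), nc - 1); y0 <- pmin(floor(gy), nr - 1)
  fx <- gx - x0; fy <- gy - y0
  i00 <- cbind(as.vector(y0), as.vector(x0))
  v <- (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[cbind(as.vector(y0), as.vector(x0) + 1)] +
    (1 - fx) * fy * img[cbind(as.vector(y0) + 1, as.vector(x0))] +
    fx * fy * img[cbind(as.vector(y0) + 1, as.vector(x0) + 1)]
  matrix(v, nrow(gx), ncol(gx))
}

#' Estimate protein copies per island from intensities
#'
#' Copies = (I_i - B_i) / F_i, where I_i is the unbleached island intensity,
#' B_i the off-state (background) intensity and F_i the intensity of a
#' single fluorophore, all in the same units.
#'
#' @param I_i Island intensity (vectorised).
#' @param B_i Background / off-state intensity.
#' @param F_i Single-fluorophore intensity (> 0).
#' @return data.frame with `copies` (raw) and `copies_rounded`.
#' @export
estimate_copies <- function(I_i, B_i, F_i) {
  if (any(F_i <= 0)) stop("domain error: F_i must be > 0")
  raw <- (I_i - B_i) / F_i
  data.frame(copies = raw, copies_rounded = round(raw))
}

#' Otsu threshold of a numeric sample
#' @param x Numeric vector.
#' @param n_bins Histogram bins. Default 256.
#' @return Threshold value maximising between-class variance.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Calibrate single-fluorophore intensity from a blinking trace tail
#'
#' Segments the tail of a photobleaching trace into on/off levels by Otsu
#' thresholding; the single-fluorophore intensity is the mean on-level minus
#' the mean off-level, and the background is the mean off-level.
#'
#' @param trace Numeric intensity-per-frame vector, or a `bleach_trace`.
#' @param tail_fraction Fraction of frames, at the trace end, used for
#'   calibration. Default 0.3.
#' @return list with `F_i`, `B_i`, `threshold`.
#' @export
blink_calibration <- function(trace, tail_fraction = 0.3) {
  x <- if (inherits(trace, "bleach_trace")) trace$intensity else trace
  if (length(x) < 100)
    stop("domain error: trace must have at least 100 frames")
  if (!(tail_fraction > 0 && tail_fraction <= 1))
    stop("domain error: tail_fraction must lie in (0, 1]")
  tail_x <- x[seq.int(length(x) - ceiling(tail_fraction * length(x)) + 1,
                      length(x))]
  thr <- otsu_threshold(tail_x)
  on <- tail_x[tail_x > thr]; off <- tail_x[tail_x <= thr]
  if (length(on) < 3 || length(off) < 3)
    stop("calibration error: no on/off bimodality in trace tail")
  sep <- mean(on) - mean(off)
  spread <- sqrt((stats::var(on) + stats::var(off)) / 2)
  if (!is.finite(sep) || sep <= 0 ||
      (is.finite(spread) && spread > 0 && sep < 2 * spread))
    stop("calibration error: on/off levels not separable")
  list(F_i = mean(on) - mean(off), B_i = mean(off), threshold = thr)
}

#' Simulate a photobleaching intensity trace with tail blinking
#'
#' Emitters bleach independently at `bleach_rate` per frame (the first frame
#' is always unbleached). Once emitters have bleached, single molecules
#' occasionally blink back on for short bursts; blink events are modelled as
#' non-overlapping single-molecule events, as observed toward the end of
#' long acquisitions, providing the on/off levels used for calibration.
#'
#' @param n_copies Emitters in the island.
#' @param F Integrated counts of one emitter. Default 90.
#' @param B Background (off-state) intensity. Default 200.
#' @param bleach_rate Per-frame bleaching probability. Default 0.01.
#' @param blink_rate Per-frame probability that a blink event starts when
#'   none is active and at least one emitter has bleached. Default 0.05.
#' @param blink_duration Frames a blink stays on. Default 3.
#' @param n_frames Trace length. Default 1000.
#' @param noise_frac Relative noise: Gaussian sd as a fraction of the
#'   instantaneous frame intensity (shot-noise-like). Default 0.
#' @param seed Integer seed.
#' @return object of class `bleach_trace`: `intensity`, `n_copies`,
#'   `F_true`, `B_true`.
#' @export
simulate_bleach_trace <- function(n_copies, F = 90, B = 200,
                                  bleach_rate = 0.01, blink_rate = 0.05,
                                  blink_duration = 3, n_frames = 1000,
                                  noise_frac = 0, seed = 1L) {
  .with_seed(derive_seed(seed, "bleach-trace"), {
    bleach_t <- stats::rgeom(n_copies, bleach_rate) + 2L  # frame 1 unbleached
    active <- vapply(seq_len(n_frames), function(t) sum(bleach_t > t),
                     numeric(1))
    blink_on <- numeric(n_frames)
    n_bleached <- n_copies - active
    t <- 1L
    while (t <= n_frames) {
      if (n_bleached[t] > 0 && stats::runif(1) < blink_rate) {
        idx <- t:min(t + blink_duration - 1L, n_frames)
        blink_on[idx] <- 1
        t <- t + blink_duration
      }
      t <- t + 1L
    }
    intensity <- B + F * (active + blink_on)
    if (noise_frac > 0)
      intensity <- intensity + stats::rnorm(n_frames) * noise_frac * intensity
    structure(list(intensity = intensity, n_copies = n_copies,
                   F_true = F, B_true = B),
              class = "bleach_trace")
  })
}

#' @export
print.bleach_trace <- function(x, ...) {
  cat("Bleach trace:", length(x$intensity), "frames,", x$n_copies,
      "emitters (F =", x$F_true, ", B =", x$B_true, ")\n")
  invisible(x)
}

#' Estimate island copy number from a bleaching trace
#'
#' Calibrates F_i and B_i from the blinking tail and applies
#' [estimate_copies()] to the unbleached island intensity (the mean of the
#' first frames).
#'
#' @param trace A `bleach_trace` or numeric vector.
#' @param tail_fraction Calibration window, see [blink_calibration()].
#' @param head_frames Frames averaged for the unbleached intensity. Default 3.
#' @return data.frame from [estimate_copies()].
#' @export
copies_from_trace <- function(trace, tail_fraction = 0.3, head_frames = 3) {
  x <- if (inherits(trace, "bleach_trace")) trace$intensity else trace
  cal <- blink_calibration(x, tail_fraction)
  I_i <- mean(x[seq_len(head_frames)])
  estimate_copies(I_i, cal$B_i, cal$F_i)
}

#' Sum intensity in a circular ROI
#'
#' @param img Numeric matrix or `synthetic_image`.
#' @param x,y ROI centre (px).
#' @param radius ROI radius (px).
#' @return Summed intensity.
#' @export
roi_sum <- function(img, x, y, radius) {
  m <- if (inherits(img, "synthetic_image")) img$raster else img
  ys <- pmax(1, floor(y - radius)):pmin(nrow(m), ceiling(y + radius))
  xs <- pmax(1, floor(x - radius)):pmin(ncol(m), ceiling(x + radius))
  sub <- m[ys, xs, drop = FALSE]
  d2 <- outer((ys - y)^2, (xs - x)^2, "+")
  sum(sub[d2 <= radius^2])
}

#' Write a synthetic image as 16-bit grayscale TIFF (with JSON sidecar)
#'
#' Requires the `tiff` package. Intensities are scaled to the 16-bit range;
#' the scale factor and the ground truth are written to a `.json` sidecar.
#'
#' @param img A `synthetic_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  m <- img$raster
  scale <- max(m, 1e-12)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 16)
  side <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  gt <- img$ground_truth
  gt$background <- NULL
  jsonlite::write_json(list(scale = scale, pixel_size = img$pixel_size,
                            psf_sigma = img$psf_sigma, ground_truth = gt),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grayscale TIFF as a numeric matrix
#'
#' @param path TIFF path. If a `.json` sidecar from [write_image_tiff()]
#'   exists, intensities are rescaled with its `scale` factor.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF import")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  side <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    m <- m * as.numeric(meta$scale)
  }
  m
}
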