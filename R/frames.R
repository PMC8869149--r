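#' Simulate a raw camera frame stack (slow path)
#'
#' Frame-level emulation of a STORM acquisition. The blink schedule (which
#' fluorophore blinks in which frame, with which photon budget) is drawn
#' exactly as in [simulate_localizations()] under the same seed, so the two
#' paths share their ground truth. Each blink's photons are placed by
#' sampling photon positions from the Gaussian PSF and binning them onto
#' the pixel grid (the integrated-Gaussian spot in expectation, with exact
#' photon conservation), and Poisson background is added per pixel.
#'
#' @param spec An [emitter_spec()].
#' @param cfg A [sim_config()] with the frame-level fields set.
#' @param margin Canvas margin around the structure in nm (default
#'   `4 * psf_sigma + 2 * pixel_size`).
#' @return A `frame_stack`: list with `frames` (array ny x nx x n_frames,
#'   photon counts), `origin` (nm, lower-left canvas corner), `pixel_size`,
#'   `psf_sigma`, `background`, and the blink `schedule` used.
#' @export
simulate_frames <- function(spec, cfg, margin = NULL) {
  stopifnot(inherits(spec, "emitter_spec"), inherits(cfg, "sim_config"))
  if (cfg$pixel_size >= 4 * cfg$psf_sigma) {
    stop("undersampling: pixel_size must be < 4 * psf_sigma", call. = FALSE)
  }
  if (is.null(margin)) margin <- 4 * cfg$psf_sigma + 2 * cfg$pixel_size
  set.seed(cfg$seed)
  bl <- .sample_blinks(spec, cfg)
  R <- spec$diameter / 2
  half_extent <- R + (if (!is.null(spec$length)) spec$length / 2 else 0)
  ps <- cfg$pixel_size
  ox <- floor((spec$center[1] - half_extent - margin) / ps) * ps
  oy <- floor((spec$center[2] - half_extent - margin) / ps) * ps
  nx <- ceiling((spec$center[1] + half_extent + margin - ox) / ps)
  ny <- ceiling((spec$center[2] + half_extent + margin - oy) / ps)
  frames <- array(0, dim = c(ny, nx, cfg$n_frames))
  for (i in seq_len(nrow(bl))) {
    nph <- bl$photons[i]
    if (nph == 0L) next
    px <- stats::rnorm(nph, bl$x[i], cfg$psf_sigma)
    py <- stats::rnorm(nph, bl$y[i], cfg$psf_sigma)
    ix <- pmin(pmax(floor((px - ox) / ps) + 1L, 1L), nx)
    iy <- pmin(pmax(floor((py - oy) / ps) + 1L, 1L), ny)
    f <- bl$frame[i]
    tab <- table(factor(iy + (ix - 1L) * ny, levels = seq_len(nx * ny)))
    frames[, , f] <- frames[, , f] + array(as.integer(tab), dim = c(ny, nx))
  }
  if (cfg$background > 0) {
    frames <- frames + array(
      stats::rpois(length(frames), cfg$background), dim = dim(frames))
  }
  structure(list(frames = frames, origin = c(ox, oy), pixel_size = ps,
                 psf_sigma = cfg$psf_sigma, background = cfg$background,
                 schedule = bl),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d x %d px, %d frames, pixel %g nm\n",
              d[2], d[1], d[3], x$pixel_size))
  invisible(x)
}

#' Write/read a frame stack as delimited text
#'
#' Plain-text exchange format (long CSV: frame, row, col, photons for
#' nonzero pixels, with a comment header carrying the geometry); a stand-in
#' for binary TIFF stacks so everything the toolkit writes stays
#' text-reviewable.
#'
#' @param stack A `frame_stack`.
#' @param path Output file.
#' @return `path` invisibly (`write_frames`), or a `frame_stack`
#'   (`read_frames`).
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  nz <- which(stack$frames != 0, arr.ind = TRUE)
  hdr <- c(sprintf("# dims: %d %d %d", d[1], d[2], d[3]),
           sprintf("# origin_nm: %s %s", .fmt_num(stack$origin[1]),
                   .fmt_num(stack$origin[2])),
           sprintf("# pixel_size_nm: %s", .fmt_num(stack$pixel_size)),
           sprintf("# psf_sigma_nm: %s", .fmt_num(stack$psf_sigma)),
           "frame,row,col,photons")
  body <- paste(nz[, 3], nz[, 1], nz[, 2],
                .fmt_num(stack$frames[nz]), sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  all_lines <- readLines(path)
  meta <- grep("^#", all_lines, value = TRUE)
  getm <- function(key) as.numeric(strsplit(trimws(sub(
    paste0("^#\\s*", key, ":"), "",
    grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)[1L])), "\\s+")[[1L]])
  d <- getm("dims")
  dat <- utils::read.csv(textConnection(
    grep("^#", all_lines, invert = TRUE, value = TRUE)))
  frames <- array(0, dim = d)
  frames[cbind(dat$row, dat$col, dat$frame)] <- dat$photons
  structure(list(frames = frames, origin = getm("origin_nm"),
                 pixel_size = getm("pixel_size_nm"),
                 psf_sigma = getm("psf_sigma_nm"), background = NA,
                 schedule = NULL),
            class = "frame_stack")
}

# integrated-Gaussian model of one spot over a pixel window; p = (x0, y0,
# sigma, N, b), edges in nm
.spot_pred <- function(p, xe, ye) {
  gx <- pnorm((xe[-1L] - p[1]) / p[3]) - pnorm((xe[-length(xe)] - p[1]) / p[3])
  gy <- pnorm((ye[-1L] - p[2]) / p[3]) - pnorm((ye[-length(ye)] - p[2]) / p[3])
  p[4] * outer(gy, gx) + p[5]
}

# 3x3 box smoothing used only for candidate detection
.smooth3 <- function(m) {
  ny <- nrow(m)
  nx <- ncol(m)
  p <- matrix(0, ny + 2L, nx + 2L)
  p[2:(ny + 1L), 2:(nx + 1L)] <- m
  acc <- matrix(0, ny, nx)
  for (dy in 0:2) for (dx in 0:2) {
    acc <- acc + p[dy + seq_len(ny), dx + seq_len(nx)]
  }
  acc / 9
}

#' Localize spots in a frame stack by 2D Gaussian fitting
#'
#' Per frame: candidate spots are local maxima of the 3x3-smoothed image
#' above a detection threshold; each candidate is refined by bounded
#' least-squares fitting of an integrated 2D Gaussian (center, width,
#' photon count, constant background) over a square window. Candidates
#' whose fit diverges or whose center leaves the window are discarded and
#' counted in the `failures` attribute. The precision column holds the
#' Thompson-style estimate
#' sqrt((s^2 + a^2/12)/N + 8 pi s^4 b^2 / (a^2 N^2)).
#'
#' In addition, spots whose fitted width exceeds `max_width_factor` times
#' the expected PSF width are rejected: overlapping same-frame emitters
#' merge into a single anomalously wide spot, and width-based rejection is
#' the standard localization-microscopy quality filter against them
#' (multi-emitter fitting proper is out of scope).
#'
#' @param stack A `frame_stack` from [simulate_frames()] or [read_frames()].
#' @param det_threshold Detection threshold in photons on the smoothed
#'   image; default `median + 4 * sqrt(median + 1)` over the whole stack.
#' @param fit_window Half-width of the fit window in pixels (default 4).
#' @param max_width_factor Reject spots with fitted sigma above this factor
#'   times the expected PSF sigma (default 1.3; `Inf` disables).
#' @return A [localization_table()] with fitted positions in nm and a
#'   `fitted_psf_sigma` column in the `extra_columns` attribute.
#' @export
localize_spots <- function(stack, det_threshold = NULL, fit_window = 4L,
                           max_width_factor = 1.3) {
  stopifnot(inherits(stack, "frame_stack"))
  fr <- stack$frames
  d <- dim(fr)
  ny <- d[1]; nx <- d[2]; nf <- d[3]
  ps <- stack$pixel_size
  if (is.null(det_threshold)) {
    med <- stats::median(fr)
    det_threshold <- med + 4 * sqrt(med + 1)
  }
  psf0 <- if (is.finite(stack$psf_sigma)) stack$psf_sigma else 1.3 * ps
  w <- as.integer(fit_window)
  res <- list()
  n_fail <- 0L
  for (f in seq_len(nf)) {
    img <- fr[, , f]
    if (max(img) < det_threshold) next
    sm <- .smooth3(img)
    # strict local maxima over the 8-neighborhood
    cand <- which(sm > det_threshold, arr.ind = TRUE)
    cand <- cand[cand[, 1] > 1 & cand[, 1] < ny &
                 cand[, 2] > 1 & cand[, 2] < nx, , drop = FALSE]
    if (nrow(cand) == 0L) next
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      nbhd <- sm[(r - 1):(r + 1), (c - 1):(c + 1)]
      keep[i] <- sm[r, c] == max(nbhd) &&
        sum(nbhd == max(nbhd)) == 1L
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0L) next
    # greedy dedup: drop maxima within the fit window of a brighter one
    if (nrow(cand) > 1L) {
      o <- order(-sm[cand])
      cand <- cand[o, , drop = FALSE]
      taken <- rep(TRUE, nrow(cand))
      for (i in 2:nrow(cand)) {
        prev <- cand[seq_len(i - 1L), , drop = FALSE][
          taken[seq_len(i - 1L)], , drop = FALSE]
        if (any(abs(prev[, 1] - cand[i, 1]) <= w &
                abs(prev[, 2] - cand[i, 2]) <= w)) taken[i] <- FALSE
      }
      cand <- cand[taken, , drop = FALSE]
    }
    for (i in seq_len(nrow(cand))) {
      r0 <- cand[i, 1]; c0 <- cand[i, 2]
      rows <- max(1L, r0 - w):min(ny, r0 + w)
      cols <- max(1L, c0 - w):min(nx, c0 + w)
      W <- img[rows, cols]
      xe <- stack$origin[1] + (c(cols, cols[length(cols)] + 1L) - 1L) * ps
      ye <- stack$origin[2] + (c(rows, rows[length(rows)] + 1L) - 1L) * ps
      b0 <- stats::median(W)
      N0 <- max(sum(W - b0), 10)
      Wp <- pmax(W - b0, 0)
      x0 <- sum(Wp %*% ((xe[-1] + xe[-length(xe)]) / 2)) / max(sum(Wp), 1)
      y0 <- sum(t(Wp) %*% ((ye[-1] + ye[-length(ye)]) / 2)) / max(sum(Wp), 1)
      p0 <- c(x0, y0, psf0, N0, max(b0, 0.01))
      lo <- c(min(xe), min(ye), 0.3 * ps, 1, 0)
      hi <- c(max(xe), max(ye), 4 * psf0, Inf, Inf)
      # Poisson-weighted least squares: pixel variance scales with the
      # photon count, and the weighting is needed to approach the
      # psf/sqrt(N) precision law at high photon counts
      wts <- 1 / pmax(W, 1)
      fit <- tryCatch(stats::nlminb(
        p0, function(p) sum(wts * (W - .spot_pred(p, xe, ye))^2),
        lower = lo, upper = hi,
        control = list(iter.max = 200L, rel.tol = 1e-10)),
        error = function(e) NULL)
      bad <- is.null(fit) || !is.finite(fit$objective) ||
        fit$par[1] <= lo[1] + 1e-9 || fit$par[1] >= hi[1] - 1e-9 ||
        fit$par[2] <= lo[2] + 1e-9 || fit$par[2] >= hi[2] - 1e-9 ||
        fit$par[3] > max_width_factor * psf0
      if (bad) {
        n_fail <- n_fail + 1L
        next
      }
      p <- fit$par
      prec <- sqrt((p[3]^2 + ps^2 / 12) / p[4] +
                     8 * pi * p[3]^4 * p[5]^2 / (ps^2 * p[4]^2))
      res[[length(res) + 1L]] <- c(f, p[1], p[2], p[4], prec, p[3])
    }
  }
  if (length(res) == 0L) {
    tab <- localization_table()
  } else {
    m <- do.call(rbind, res)
    tab <- localization_table(frame = m[, 1], x = m[, 2], y = m[, 3],
                              photons = m[, 4], precision = m[, 5])
    attr(tab, "extra_columns") <- data.frame(fitted_psf_sigma = m[, 6])
  }
  attr(tab, "failures") <- n_fail
  tab
}
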