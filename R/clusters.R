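#' Principal axis of a 2D point set
#'
#' The leading eigenvector of the 2x2 coordinate covariance — the "long
#' axis" along which cluster line profiles are taken. Sign convention:
#' nonnegative first component; if the first component is zero, nonnegative
#' second. For (near-)isotropic point sets the eigenvalues tie and the
#' direction falls back to (1, 0) with `tie = TRUE`.
#'
#' @param points Two-column matrix or data frame of (x, y) in nm.
#' @return List with `centroid`, `direction` (unit 2-vector), `tie` flag and
#'   `eigenvalues`.
#' @export
principal_axis <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) < 2L) stop("`points` must have two columns", call. = FALSE)
  pts <- pts[, 1:2, drop = FALSE]
  if (nrow(pts) < 3L || anyNA(pts)) {
    stop("degenerate input: need at least 3 finite points", call. = FALSE)
  }
  centroid <- colMeans(pts)
  cv <- stats::cov(pts)
  e <- eigen(cv, symmetric = TRUE)
  lam <- e$values
  tie <- (lam[1] - lam[2]) <= 1e-9 * max(lam[1] + lam[2], .Machine$double.eps)
  if (tie) {
    v <- c(1, 0)
  } else {
    v <- e$vectors[, 1]
    if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  }
  list(centroid = as.numeric(centroid), direction = as.numeric(v),
       tie = tie, eigenvalues = lam)
}

# grid-indexed eps-neighbor lookup; avoids the n^2 distance matrix
.neighbor_index <- function(x, y, eps) {
  cx <- floor(x / eps)
  cy <- floor(y / eps)
  key <- paste(cx, cy)
  cells <- split(seq_along(x), key)
  list(cx = cx, cy = cy, cells = cells,
       query = function(i) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      ids <- cells[[k]]
      if (!is.null(ids)) cand <- c(cand, ids)
    }
    d2 <- (x[cand] - x[i])^2 + (y[cand] - y[i])^2
    sort(cand[d2 <= eps^2])
  })
}

#' Density-based cluster detection on a localization table
#'
#' DBSCAN over the (x, y) coordinates: a point with at least `min_pts`
#' neighbors within `eps` (itself included) is a core point; clusters are
#' the connected components of core points plus their border points. Noise
#' points are excluded and clusters smaller than `min_cluster_size` are
#' dropped. Deterministic given the input order.
#'
#' @param table A [localization_table()].
#' @param eps Neighborhood radius in nm (default 100).
#' @param min_pts Core-point threshold (default 10).
#' @param min_cluster_size Minimum cluster size to keep (default 20).
#' @return List of `storm_cluster` objects (possibly empty), each with
#'   member `indices`, `centroid`, `principal_axis`, `axis_extent`,
#'   `n_localizations` and the isotropy `tie` flag.
#' @export
find_clusters <- function(table, eps = 100, min_pts = 10L,
                          min_cluster_size = 20L) {
  stopifnot(inherits(table, "localization_table"))
  if (!is.numeric(eps) || eps <= 0) {
    stop("invalid parameter: `eps` must be > 0", call. = FALSE)
  }
  n <- nrow(table)
  if (n == 0L) return(list())
  x <- table$x
  y <- table$y
  nb <- .neighbor_index(x, y, eps)
  labels <- integer(n)            # 0 = unassigned, -1 = noise
  cluster_id <- 0L
  queue <- integer(n)             # each point is enqueued at most once
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    neigh <- nb$query(i)
    if (length(neigh) < min_pts) {
      labels[i] <- -1L
      next
    }
    cluster_id <- cluster_id + 1L
    labels[i] <- cluster_id
    # previously-noise neighbors become border points (no expansion);
    # unvisited neighbors are claimed now and expanded from the queue
    grow <- neigh[labels[neigh] == 0L]
    labels[neigh[labels[neigh] == -1L]] <- cluster_id
    labels[grow] <- cluster_id
    qlen <- length(grow)
    queue[seq_len(qlen)] <- grow
    head <- 1L
    while (head <= qlen) {
      j <- queue[head]
      head <- head + 1L
      nj <- nb$query(j)
      if (length(nj) < min_pts) next              # border point
      labels[nj[labels[nj] == -1L]] <- cluster_id
      grow <- nj[labels[nj] == 0L]
      labels[grow] <- cluster_id
      if (length(grow) > 0L) {
        queue[qlen + seq_along(grow)] <- grow
        qlen <- qlen + length(grow)
      }
    }
  }
  out <- list()
  for (cid in seq_len(cluster_id)) {
    idx <- which(labels == cid)
    if (length(idx) < min_cluster_size) next
    pa <- principal_axis(cbind(x[idx], y[idx]))
    proj <- (x[idx] - pa$centroid[1]) * pa$direction[1] +
            (y[idx] - pa$centroid[2]) * pa$direction[2]
    out[[length(out) + 1L]] <- structure(list(
      indices = idx,
      centroid = pa$centroid,
      principal_axis = pa$direction,
      tie = pa$tie,
      axis_extent = diff(range(proj)),
      n_localizations = length(idx)), class = "storm_cluster")
  }
  out
}

#' @export
print.storm_cluster <- function(x, ...) {
  cat(sprintf(
    "<storm_cluster> n=%d centroid=(%.1f, %.1f) axis=(%.3f, %.3f) extent=%.1f nm\n",
    x$n_localizations, x$centroid[1], x$centroid[2],
    x$principal_axis[1], x$principal_axis[2], x$axis_extent))
  invisible(x)
}

#' Extract a line profile from a cluster
#'
#' Projects the cluster's member localizations onto its principal axis
#' (signed distance from the centroid) and bins them into a histogram over
#' `[-extent/2 - pad, +extent/2 + pad)` with uniform, half-open
#' `[left, right)` bins. `axis = "minor"` projects onto the perpendicular
#' axis instead — the cross-sectional profile of elongated structures such
#' as cylinders.
#'
#' @param cluster A `storm_cluster` from [find_clusters()].
#' @param table The [localization_table()] the cluster indexes into.
#' @param bin_width Bin width in nm (default 10).
#' @param pad Extra window on each side in nm (default `4 * bin_width`).
#' @param axis `"major"` (principal axis, default) or `"minor"`
#'   (perpendicular).
#' @return A [line_profile()] with origin and direction recorded.
#' @export
extract_profile <- function(cluster, table, bin_width = 10,
                            pad = 4 * bin_width,
                            axis = c("major", "minor")) {
  stopifnot(inherits(cluster, "storm_cluster"),
            inherits(table, "localization_table"))
  axis <- match.arg(axis)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("invalid parameter: `bin_width` must be > 0", call. = FALSE)
  }
  v <- cluster$principal_axis
  if (axis == "minor") {
    v <- c(-v[2], v[1])
    if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  }
  idx <- cluster$indices
  t_proj <- (table$x[idx] - cluster$centroid[1]) * v[1] +
            (table$y[idx] - cluster$centroid[2]) * v[2]
  span <- diff(range(t_proj))
  if (bin_width > span) {
    stop("bin_width larger than the projected span: single-bin profile",
         call. = FALSE)
  }
  half <- span / 2 + pad
  nbins <- ceiling(2 * half / bin_width)
  lo <- -half
  mid <- mean(range(t_proj))
  k <- floor((t_proj - mid - lo) / bin_width)
  keep <- k >= 0L & k < nbins
  counts <- tabulate(k[keep] + 1L, nbins)
  centers <- lo + (seq_len(nbins) - 0.5) * bin_width + mid
  line_profile(centers, counts, bin_width = bin_width,
               origin = cluster$centroid, direction = v)
}

#' Render a localization table as a raster image
#'
#' 2D histogram of localization counts at the requested pixel size, with an
#' optional Gaussian display blur. The canvas is grown by the kernel
#' half-width when blurring so total intensity is conserved. Pixel centers
#' sit at `(i + 0.5) * pixel_size` from the recorded origin (the minimum
#' coordinate snapped to the pixel grid).
#'
#' @param table A [localization_table()].
#' @param pixel_size Pixel size in nm.
#' @param blur_sigma Display blur standard deviation in nm (0 = none).
#' @return A `storm_image`: list with `image` matrix (rows = y), `pixel_size`,
#'   `origin` (nm), `blur_sigma`.
#' @export
render_storm_image <- function(table, pixel_size, blur_sigma = 0) {
  stopifnot(inherits(table, "localization_table"))
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("invalid parameter: `pixel_size` must be > 0", call. = FALSE)
  }
  if (nrow(table) == 0L) stop("empty localization table", call. = FALSE)
  ox <- floor(min(table$x) / pixel_size) * pixel_size
  oy <- floor(min(table$y) / pixel_size) * pixel_size
  ix <- floor((table$x - ox) / pixel_size) + 1L
  iy <- floor((table$y - oy) / pixel_size) + 1L
  nx <- max(ix)
  ny <- max(iy)
  img <- matrix(0, ny, nx)
  for (i in seq_along(ix)) img[iy[i], ix[i]] <- img[iy[i], ix[i]] + 1
  if (blur_sigma > 0) {
    m <- ceiling(6 * blur_sigma / pixel_size)
    kern <- dnorm(seq(-m, m) * pixel_size, sd = blur_sigma)
    kern <- kern / sum(kern)
    # full ("open") separable convolution: the canvas grows by m pixels per
    # side, so the normalized kernel conserves total intensity exactly
    conv1 <- function(v) stats::convolve(v, rev(kern), type = "open")
    img <- t(apply(img, 1, conv1))               # ny x (nx + 2m)
    img <- apply(img, 2, conv1)                  # (ny + 2m) x (nx + 2m)
    ox <- ox - m * pixel_size
    oy <- oy - m * pixel_size
  }
  structure(list(image = img, pixel_size = pixel_size,
                 origin = c(ox, oy), blur_sigma = blur_sigma),
            class = "storm_image")
}
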