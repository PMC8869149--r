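#' Gaussian localization kernel
#'
#' The blur acting on every fluorophore position along the profile axis. In
#' localization microscopy this is the effective localization precision: the
#' standard deviation of the error between a fluorophore's true position and
#' its fitted position. The kernel density is the standard normal density
#' scaled to width `sigma`, and integrates to 1 over the real line.
#'
#' @param sigma Kernel standard deviation in nm; strictly positive.
#' @return An object of class `gaussian_kernel`.
#' @examples
#' k <- gaussian_kernel(20)
#' @export
gaussian_kernel <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("invalid parameter: `sigma` must be a single finite value > 0",
         call. = FALSE)
  }
  structure(list(sigma = as.numeric(sigma)), class = "gaussian_kernel")
}

.sba_shapes <- c("sphere_surface", "sphere_volume", "disc_solid", "disc_ring")

#' Structural function of a labeled geometry
#'
#' Describes the normalized 1D projection density S(x) of fluorophore
#' positions for a labeled shape of radius R. Supported shapes:
#' \describe{
#'   \item{sphere_surface}{uniform labeling on a spherical shell (or the
#'     uniform band cross-section of a labeled cylinder); the projection onto
#'     any axis is uniform on \[-R, R\] (Archimedes hat-box property).}
#'   \item{sphere_volume}{uniform labeling throughout the ball; projection
#'     proportional to (R^2 - x^2).}
#'   \item{disc_solid}{uniform labeling on a filled in-plane disc; projection
#'     proportional to sqrt(R^2 - x^2).}
#'   \item{disc_ring}{uniform labeling on a circle's circumference; projection
#'     proportional to 1/sqrt(R^2 - x^2), divergent (but integrable) at the
#'     rim.}
#' }
#'
#' @param shape One of `"sphere_surface"`, `"sphere_volume"`, `"disc_solid"`,
#'   `"disc_ring"`.
#' @param radius Structure radius in nm; strictly positive.
#' @return An object of class `structural_model`.
#' @examples
#' m <- structural_model("sphere_surface", radius = 50)
#' eval_structure(m, c(-25, 0, 25))
#' @export
structural_model <- function(shape = .sba_shapes, radius) {
  shape <- match.arg(shape)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("invalid parameter: `radius` must be a single finite value > 0",
         call. = FALSE)
  }
  structure(list(shape = shape, radius = as.numeric(radius)),
            class = "structural_model")
}

#' @export
print.structural_model <- function(x, ...) {
  cat(sprintf("<structural_model> shape=%s radius=%g nm\n", x$shape, x$radius))
  invisible(x)
}

#' Evaluate a structural function
#'
#' Returns the normalized projection density S(x) in 1/nm; exactly 0 outside
#' \[-R, R\]. For `disc_ring` the density diverges at |x| = R; the limit
#' convention `+Inf` is returned there (callers fitting data must use the
#' convolved form, which is finite everywhere).
#'
#' @param model A [structural_model()].
#' @param x Numeric vector of positions in nm.
#' @return Density values, same length as `x`.
#' @export
eval_structure <- function(model, x) {
  stopifnot(inherits(model, "structural_model"))
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("invalid parameter: `x` must be finite numeric", call. = FALSE)
  }
  R <- model$radius
  inside <- abs(x) <= R
  out <- numeric(length(x))
  xi <- x[inside]
  out[inside] <- switch(model$shape,
    sphere_surface = rep.int(1 / (2 * R), length(xi)),
    sphere_volume  = 3 * (R^2 - xi^2) / (4 * R^3),
    disc_solid     = 2 * sqrt(R^2 - xi^2) / (pi * R^2),
    disc_ring      = 1 / (pi * sqrt(pmax(R^2 - xi^2, 0)))
  )
  out
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem;
# cached per order. Used for the smooth theta-substituted disc convolutions.
.gl_cache <- new.env(parent = emptyenv())

.gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  res <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  .gl_cache[[key]] <- res
  res
}

# order chosen so the Gaussian factor (width ~ sigma/R in theta) is resolved
.disc_gl_order <- function(R, sigma) {
  n <- max(201, ceiling(24 * R / sigma))
  min(n, 4001)
}

#' Convolved model profile D(x) = (S * G)(x)
#'
#' The expected localization density of a labeled structure: its structural
#' function convolved with the Gaussian localization kernel. `sphere_surface`
#' and `sphere_volume` use closed forms in the normal CDF/PDF; the disc
#' shapes are evaluated by high-order Gauss-Legendre quadrature after the
#' substitution u = R sin(theta), which removes the ring's rim singularity
#' and leaves a smooth integrand.
#'
#' @param model A [structural_model()].
#' @param kernel A [gaussian_kernel()].
#' @param x Numeric vector of positions in nm.
#' @return Density values in 1/nm, same length as `x`.
#' @examples
#' m <- structural_model("sphere_surface", 50)
#' eval_convolved(m, gaussian_kernel(20), 0)  # 0.01 * (2*pnorm(2.5) - 1)
#' @export
eval_convolved <- function(model, kernel, x) {
  stopifnot(inherits(model, "structural_model"))
  if (!inherits(kernel, "gaussian_kernel")) {
    stop("invalid parameter: `kernel` must be a gaussian_kernel", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("invalid parameter: `x` must be finite numeric", call. = FALSE)
  }
  R <- model$radius
  s <- kernel$sigma
  out <- switch(model$shape,
    sphere_surface = (pnorm((x + R) / s) - pnorm((x - R) / s)) / (2 * R),
    sphere_volume = {
      a <- (-R - x) / s
      b <- (R - x) / s
      dPhi <- pnorm(b) - pnorm(a)
      dphi <- dnorm(a) - dnorm(b)
      # int (R^2-u^2) phi_s(x-u) du expanded in normal moments
      (3 / (4 * R^3)) * ((R^2 - x^2 - s^2) * dPhi - 2 * x * s * dphi -
                           s^2 * (a * dnorm(a) - b * dnorm(b)))
    },
    disc_solid = {
      gl <- .gauss_legendre(.disc_gl_order(R, s))
      th <- gl$nodes * (pi / 2)
      w <- gl$weights * (pi / 2)
      # S du = (2/pi) cos^2(theta) dtheta under u = R sin(theta)
      fx <- outer(x, R * sin(th), function(xx, u) dnorm(xx - u, sd = s))
      as.numeric(fx %*% (w * (2 / pi) * cos(th)^2))
    },
    disc_ring = {
      gl <- .gauss_legendre(.disc_gl_order(R, s))
      th <- gl$nodes * (pi / 2)
      w <- gl$weights * (pi / 2)
      # S du = (1/pi) dtheta under u = R sin(theta)
      fx <- outer(x, R * sin(th), function(xx, u) dnorm(xx - u, sd = s))
      as.numeric(fx %*% (w / pi))
    }
  )
  # the closed forms can go epsilon-negative far in the tails by
  # cancellation; a density is nonnegative
  pmax(out, 0)
}

#' Brute-force quadrature reference for the convolution
#'
#' Adaptive quadrature of the defining integral per grid point, independent
#' of the closed forms and of the fixed-order rule used by
#' [eval_convolved()]. Slow; reference/testing only. For `disc_ring` the
#' substitution u = R sin(theta) removes the endpoint singularity.
#'
#' @param model A [structural_model()].
#' @param kernel A [gaussian_kernel()].
#' @param x_grid Numeric vector of positions in nm.
#' @return Density values in 1/nm.
#' @export
quadrature_oracle <- function(model, kernel, x_grid) {
  stopifnot(inherits(model, "structural_model"))
  if (!inherits(kernel, "gaussian_kernel")) {
    stop("invalid parameter: `kernel` must be a gaussian_kernel", call. = FALSE)
  }
  if (!is.numeric(x_grid) || anyNA(x_grid) || any(!is.finite(x_grid))) {
    stop("invalid parameter: `x_grid` must be finite numeric", call. = FALSE)
  }
  R <- model$radius
  s <- kernel$sigma
  one <- function(xx) {
    if (model$shape == "disc_ring") {
      f <- function(th) dnorm(xx - R * sin(th), sd = s) / pi
      stats::integrate(f, -pi / 2, pi / 2, rel.tol = 1e-12, abs.tol = 1e-13,
                       subdivisions = 1000L)$value
    } else {
      f <- function(u) eval_structure(model, u) * dnorm(xx - u, sd = s)
      # split at 0 to help the subdivision near sqrt endpoints
      stats::integrate(f, -R, 0, rel.tol = 1e-12, abs.tol = 1e-13,
                       subdivisions = 1000L)$value +
        stats::integrate(f, 0, R, rel.tol = 1e-12, abs.tol = 1e-13,
                         subdivisions = 1000L)$value
    }
  }
  vapply(x_grid, one, numeric(1))
}

#' Full fitted curve specification
#'
#' Bundles a structural model, kernel and the fit parameters into the curve
#' `counts(x) = bin_width * amplitude * D(x - center) + background`, where
#' `amplitude` is the total expected number of localizations and
#' `background` a constant count per bin.
#'
#' @param model A [structural_model()].
#' @param kernel A [gaussian_kernel()].
#' @param amplitude Total expected localizations (> 0).
#' @param background Constant counts per bin (>= 0).
#' @param center Profile-axis position of the structure center, nm.
#' @return An object of class `model_profile`.
#' @export
model_profile <- function(model, kernel, amplitude, background = 0,
                          center = 0) {
  stopifnot(inherits(model, "structural_model"),
            inherits(kernel, "gaussian_kernel"))
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude) || amplitude <= 0) {
    stop("invalid parameter: `amplitude` must be > 0", call. = FALSE)
  }
  if (!is.numeric(background) || length(background) != 1L ||
      !is.finite(background) || background < 0) {
    stop("invalid parameter: `background` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center)) {
    stop("invalid parameter: `center` must be finite", call. = FALSE)
  }
  structure(list(model = model, kernel = kernel,
                 amplitude = as.numeric(amplitude),
                 background = as.numeric(background),
                 center = as.numeric(center)),
            class = "model_profile")
}

#' Predicted bin counts of a model profile
#'
#' @param object A [model_profile()].
#' @param bin_centers Bin center positions in nm.
#' @param bin_width Bin width in nm.
#' @param ... Unused.
#' @return Expected counts per bin.
#' @export
predict.model_profile <- function(object, bin_centers, bin_width, ...) {
  stopifnot(is.numeric(bin_centers), is.numeric(bin_width), bin_width > 0)
  bin_width * object$amplitude *
    eval_convolved(object$model, object$kernel, bin_centers - object$center) +
    object$background
}
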