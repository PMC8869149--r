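#' Line profile of localization counts
#'
#' A histogram of localizations along an axis through a cluster: uniformly
#' spaced bin centers (nm), nonnegative counts, and the geometry of the
#' profile line (origin point and unit direction in the image plane). The
#' bin coordinate is the signed distance from `origin` along `direction`.
#'
#' @param bin_centers Strictly increasing, uniformly spaced positions (nm).
#' @param counts Nonnegative counts (or nonnegative reals for
#'   intensity-derived profiles), same length as `bin_centers`.
#' @param bin_width Bin width in nm; inferred from the spacing when `NULL`.
#' @param origin Length-2 numeric, profile origin (x, y) in nm.
#' @param direction Length-2 numeric unit vector.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(bin_centers, counts, bin_width = NULL,
                         origin = c(0, 0), direction = c(1, 0)) {
  if (!is.numeric(bin_centers) || length(bin_centers) < 2L ||
      anyNA(bin_centers)) {
    stop("`bin_centers` must be numeric with at least 2 bins", call. = FALSE)
  }
  d <- diff(bin_centers)
  if (any(d <= 0)) {
    stop("`bin_centers` must be strictly increasing", call. = FALSE)
  }
  bw <- if (is.null(bin_width)) stats::median(d) else as.numeric(bin_width)
  if (any(abs(d - bw) > 1e-9 * bw)) {
    stop("non-uniform bin spacing (relative jitter > 1e-9)", call. = FALSE)
  }
  if (!is.numeric(counts) || length(counts) != length(bin_centers) ||
      anyNA(counts) || any(counts < 0)) {
    stop("`counts` must be nonnegative and match `bin_centers`",
         call. = FALSE)
  }
  if (length(origin) != 2L || anyNA(origin)) {
    stop("`origin` must be length-2 numeric", call. = FALSE)
  }
  nrm <- sqrt(sum(direction^2))
  if (length(direction) != 2L || !is.finite(nrm) || nrm == 0) {
    stop("`direction` must be a nonzero length-2 vector", call. = FALSE)
  }
  structure(list(bin_centers = as.numeric(bin_centers),
                 counts = as.numeric(counts),
                 bin_width = bw,
                 origin = as.numeric(origin),
                 direction = as.numeric(direction) / nrm),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf(
    "<line_profile> %d bins x %g nm, %g counts, span [%g, %g] nm\n",
    length(x$bin_centers), x$bin_width, sum(x$counts),
    min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}

#' @export
as.data.frame.line_profile <- function(x, ...) {
  data.frame(bin_center_nm = x$bin_centers, count = x$counts)
}

# noiseless profile synthesized from a model_profile; used by tests and
# self-consistency checks
profile_from_model <- function(mp, from, to, bin_width) {
  centers <- seq(from + bin_width / 2, to - bin_width / 2 + 1e-12,
                 by = bin_width)
  line_profile(centers, predict(mp, centers, bin_width),
               bin_width = bin_width)
}
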