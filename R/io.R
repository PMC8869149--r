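#' Localization table
#'
#' The universal exchange object: one row per localization with frame index,
#' coordinates in nm, and optional photon count and per-localization
#' precision (nm). Coordinates are always nm internally; pixel-unit inputs
#' must be converted at the boundary with an explicit pixel size.
#'
#' @param frame Positive integer frame indices.
#' @param x,y Coordinates in nm, finite.
#' @param photons Optional photon counts.
#' @param precision Optional per-localization precision in nm.
#' @param pixel_size Optional pixel size metadata (nm).
#' @return A data frame of class `localization_table`.
#' @export
localization_table <- function(frame = integer(), x = numeric(),
                               y = numeric(), photons = NULL,
                               precision = NULL, pixel_size = NULL) {
  n <- length(x)
  if (length(y) != n || length(frame) != n) {
    stop("frame, x and y must have equal length", call. = FALSE)
  }
  if (n > 0) {
    if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
      stop("coordinates must be finite", call. = FALSE)
    }
    if (anyNA(frame) || any(frame < 1) || any(frame != round(frame))) {
      stop("frame indices must be positive integers", call. = FALSE)
    }
  }
  df <- data.frame(frame = as.integer(frame), x = as.numeric(x),
                   y = as.numeric(y))
  df$photons <- if (is.null(photons)) rep(NA_real_, n) else as.numeric(photons)
  df$precision <- if (is.null(precision)) rep(NA_real_, n)
                  else as.numeric(precision)
  attr(df, "pixel_size") <- pixel_size
  class(df) <- c("localization_table", "data.frame")
  df
}

.generic_cols <- c(frame = "frame", x = "x_nm", y = "y_nm",
                   photons = "photons", precision = "precision_nm")
.thunderstorm_cols <- c(frame = "frame", x = "x [nm]", y = "y [nm]",
                        photons = "intensity [photon]",
                        precision = "uncertainty [nm]")

# 6 significant digits, plain decimal where possible; deterministic
.fmt_num <- function(v) {
  out <- formatC(v, digits = 6, format = "g", flag = "")
  out[is.na(v)] <- ""
  trimws(out)
}

#' Read a localization table
#'
#' Two dialects of comma-delimited text are supported. `generic`: header
#' columns `frame, x_nm, y_nm` with optional `photons, precision_nm`.
#' `thunderstorm`: the column naming used by the ThunderSTORM ImageJ plugin
#' (`"frame"`, `"x [nm]"`, `"y [nm]"`, `"intensity [photon]"`,
#' `"uncertainty [nm]"`). Unknown extra columns are preserved as metadata.
#' Output coordinates are always nm.
#'
#' @param path File to read.
#' @param dialect `"generic"` or `"thunderstorm"`.
#' @return A [localization_table()].
#' @export
read_localizations <- function(path, dialect = c("generic", "thunderstorm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", comment.char = "#")
  map <- if (dialect == "generic") .generic_cols else .thunderstorm_cols
  for (field in c("frame", "x", "y")) {
    if (!(map[[field]] %in% names(raw))) {
      stop(sprintf("format error: missing mandatory column \"%s\" (%s)",
                   map[[field]], field), call. = FALSE)
    }
  }
  getnum <- function(field) {
    col <- map[[field]]
    if (!(col %in% names(raw))) return(NULL)
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("", "NA")))
    if (length(bad) > 0L) {
      stop(sprintf(
        "format error: non-numeric value \"%s\" in column \"%s\" at line %d",
        raw[[col]][bad[1L]], col, bad[1L] + 1L), call. = FALSE)
    }
    v
  }
  tab <- localization_table(frame = getnum("frame"), x = getnum("x"),
                            y = getnum("y"), photons = getnum("photons"),
                            precision = getnum("precision"))
  extra <- setdiff(names(raw), unname(map))
  if (length(extra) > 0L) attr(tab, "extra_columns") <- raw[extra]
  attr(tab, "dialect") <- dialect
  tab
}

#' Write a localization table
#'
#' Deterministic column order and fixed 6-significant-digit decimal
#' formatting; identical tables produce byte-identical files. Optional
#' columns are written when any value is present.
#'
#' @param table A [localization_table()].
#' @param path Output file.
#' @param dialect `"generic"` or `"thunderstorm"`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path,
                                dialect = c("generic", "thunderstorm")) {
  stopifnot(inherits(table, "localization_table"))
  dialect <- match.arg(dialect)
  map <- if (dialect == "generic") .generic_cols else .thunderstorm_cols
  fields <- c("frame", "x", "y")
  if (any(!is.na(table$photons))) fields <- c(fields, "photons")
  if (any(!is.na(table$precision))) fields <- c(fields, "precision")
  header <- paste(vapply(fields, function(f) {
    nm <- map[[f]]
    if (grepl("[ ,]", nm)) sprintf("\"%s\"", nm) else nm
  }, character(1)), collapse = ",")
  cols <- lapply(fields, function(f) {
    if (f == "frame") as.character(table$frame) else .fmt_num(table[[f]])
  })
  lines <- if (nrow(table) == 0L) character(0) else do.call(paste,
    c(cols, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Write a line profile
#'
#' Two-column delimited text (`bin_center_nm,count`) preceded by a comment
#' header carrying the profile geometry (origin, direction, bin width).
#'
#' @param profile A [line_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "line_profile"))
  hdr <- c(
    sprintf("# origin_nm: %s %s", .fmt_num(profile$origin[1]),
            .fmt_num(profile$origin[2])),
    sprintf("# direction: %s %s",
            formatC(profile$direction[1], digits = 12, format = "g"),
            formatC(profile$direction[2], digits = 12, format = "g")),
    sprintf("# bin_width_nm: %s", .fmt_num(profile$bin_width)),
    "bin_center_nm,count")
  body <- paste(.fmt_num(profile$bin_centers), .fmt_num(profile$counts),
                sep = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Read a line profile
#'
#' Counterpart of [write_profile()]. Missing metadata lines fall back to
#' origin (0, 0), direction (1, 0) and the observed bin spacing, with a
#' warning and a `defaulted_metadata` attribute set. Non-uniform bin
#' spacing (relative jitter above 1e-6 of the bin width) is a format error.
#'
#' @param path File to read.
#' @return A [line_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  all_lines <- readLines(path)
  meta_lines <- grep("^#", all_lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta_lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    as.numeric(strsplit(trimws(sub(paste0("^#\\s*", key, ":"), "",
                                   hit[1L])), "\\s+")[[1L]])
  }
  origin <- get_meta("origin_nm")
  direction <- get_meta("direction")
  bw <- get_meta("bin_width_nm")
  defaulted <- is.null(origin) || is.null(direction)
  if (is.null(origin)) origin <- c(0, 0)
  if (is.null(direction)) direction <- c(1, 0)
  dat <- utils::read.csv(textConnection(
    grep("^#", all_lines, value = TRUE, invert = TRUE)))
  if (!all(c("bin_center_nm", "count") %in% names(dat))) {
    stop("format error: expected columns bin_center_nm,count", call. = FALSE)
  }
  centers <- dat$bin_center_nm
  d <- diff(centers)
  if (is.null(bw)) bw <- stats::median(d)
  if (any(abs(d - bw) > 1e-6 * bw)) {
    stop("format error: non-uniform bin spacing", call. = FALSE)
  }
  if (defaulted) {
    warning("profile metadata header missing; using origin (0,0), ",
            "direction (1,0)", call. = FALSE)
  }
  # regularize sub-tolerance formatting jitter to an exactly uniform grid
  centers <- centers[1L] + (seq_along(centers) - 1L) * bw
  prof <- line_profile(centers, dat$count, bin_width = bw, origin = origin,
                       direction = direction)
  attr(prof, "defaulted_metadata") <- defaulted
  prof
}
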