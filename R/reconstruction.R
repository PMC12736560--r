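#' Read a localization table from CSV
#'
#' Supports the ThunderSTORM column dialect (`frame`, `"x [nm]"`,
#' `"y [nm]"`, `"intensity [photon]"`, `"uncertainty [nm]"`) and a minimal
#' `x,y` dialect (coordinates assumed to be nm). Unknown extra columns are
#' ignored with a warning; missing x/y columns are a format error.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (default), `"thunderstorm"` or `"xy"`.
#' @return A `loc_table` data frame with columns frame, x, y, intensity,
#'   uncertainty (all coordinates in nm).
#' @export
read_localizations <- function(path, dialect = c("auto", "thunderstorm", "xy")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("localization file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- names(df)
  ts_map <- c(frame = "frame", x = "x [nm]", y = "y [nm]",
              intensity = "intensity [photon]", uncertainty = "uncertainty [nm]")
  has_ts <- all(c("x [nm]", "y [nm]") %in% nm)
  has_xy <- all(c("x", "y") %in% nm)
  use <- switch(dialect,
                auto = if (has_ts) "thunderstorm" else if (has_xy) "xy" else NA,
                thunderstorm = if (has_ts) "thunderstorm" else NA,
                xy = if (has_xy) "xy" else NA)
  if (is.na(use))
    stop("unrecognized localization CSV header; mandatory x/y columns not ",
         "found among: ", paste(nm, collapse = ", "), call. = FALSE)
  if (use == "thunderstorm") {
    known <- unname(ts_map)
    extra <- setdiff(nm, known)
    if (length(extra))
      warning("ignoring unknown columns: ", paste(extra, collapse = ", "),
              call. = FALSE)
    get_col <- function(col, default) if (col %in% nm) df[[col]] else default
    n <- nrow(df)
    out <- new_loc_table(
      frame = get_col("frame", rep(1L, n)),
      x = as.numeric(df[["x [nm]"]]),
      y = as.numeric(df[["y [nm]"]]),
      intensity = as.numeric(get_col("intensity [photon]", rep(NA_real_, n))),
      uncertainty = as.numeric(get_col("uncertainty [nm]", rep(NA_real_, n))))
  } else {
    extra <- setdiff(nm, c("x", "y"))
    if (length(extra))
      warning("ignoring unknown columns: ", paste(extra, collapse = ", "),
              call. = FALSE)
    n <- nrow(df)
    out <- new_loc_table(rep(1L, n), as.numeric(df$x), as.numeric(df$y),
                         rep(NA_real_, n), rep(NA_real_, n))
  }
  if (any(!is.finite(out$x)) || any(!is.finite(out$y)))
    stop("non-finite coordinates in localization table", call. = FALSE)
  out
}

#' Write a localization table as ThunderSTORM-style CSV
#'
#' Header is exactly `frame,"x [nm]","y [nm]","intensity [photon]",
#' "uncertainty [nm]"`.
#'
#' @param locs a `loc_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('frame,"x [nm]","y [nm]","intensity [photon]","uncertainty [nm]"',
             con)
  df <- data.frame(locs$frame, locs$x, locs$y, locs$intensity, locs$uncertainty)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a 2D histogram reconstruction of a localization table
#'
#' Bins localizations into half-open square pixels
#' `[k*px, (k+1)*px) x [m*px, (m+1)*px)` relative to `origin`; pixel (i, j)
#' of the count grid covers row i (y) and column j (x). The sum of counts
#' equals the number of in-extent localizations.
#'
#' @param locs a `loc_table` (or any data frame with x, y in nm).
#' @param pixel_size pixel edge in nm (the dSTORM reconstructions this
#'   models use 20 nm).
#' @param extent numeric length-4 `c(xmin, xmax, ymin, ymax)` in nm, or
#'   `NULL` to cover the data (expanded to whole pixels).
#' @param origin numeric length-2 (x, y) nm offset of the corner of pixel
#'   (1, 1); defaults to the extent minimum.
#' @return A `recon_image`: list with `counts` (integer matrix, rows = y),
#'   `pixel_size`, `origin`.
#' @export
render_histogram <- function(locs, pixel_size, extent = NULL, origin = NULL) {
  check_scalar(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop_field("pixel_size", "must be > 0")
  x <- locs$x; y <- locs$y
  if (is.null(extent)) {
    if (length(x) == 0) extent <- c(0, pixel_size, 0, pixel_size)
    else extent <- c(floor(min(x) / pixel_size) * pixel_size,
                     (floor(max(x) / pixel_size) + 1) * pixel_size,
                     floor(min(y) / pixel_size) * pixel_size,
                     (floor(max(y) / pixel_size) + 1) * pixel_size)
  }
  if (is.null(origin)) origin <- c(extent[1L], extent[3L])
  nx <- max(1L, as.integer(ceiling((extent[2L] - origin[1L]) / pixel_size - 1e-9)))
  ny <- max(1L, as.integer(ceiling((extent[4L] - origin[2L]) / pixel_size - 1e-9)))
  counts <- matrix(0L, nrow = ny, ncol = nx)
  if (length(x) > 0) {
    ix <- floor((x - origin[1L]) / pixel_size) + 1
    iy <- floor((y - origin[2L]) / pixel_size) + 1
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    if (any(ok)) {
      lin <- (ix[ok] - 1) * ny + iy[ok]
      tab <- tabulate(lin, nbins = nx * ny)
      counts <- matrix(as.integer(tab), nrow = ny, ncol = nx)
    }
  }
  structure(list(counts = counts, pixel_size = pixel_size, origin = origin),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("recon_image: %d x %d px at %.3g nm/px, origin (%.4g, %.4g) nm, %d localizations\n",
              nrow(x$counts), ncol(x$counts), x$pixel_size,
              x$origin[1L], x$origin[2L], sum(x$counts)))
  invisible(x)
}

#' Rigidly rotate a localization table
#'
#' Rotates every (x, y) about `center` by `angle` (radians, positive from
#' +x towards +y, i.e. clockwise on screen with y pointing down). All
#' non-coordinate fields are preserved. Rotation acts on the continuous
#' localization list, never on a rendered image, so re-rendering after
#' rotation incurs no interpolation loss.
#'
#' @param locs a `loc_table`.
#' @param angle rotation angle in radians.
#' @param center numeric length-2 (x, y) rotation center in nm.
#' @return The rotated `loc_table`.
#' @export
rotate_localizations <- function(locs, angle, center = c(0, 0)) {
  check_scalar(angle, "angle")
  ca <- cos(angle); sa <- sin(angle)
  dx <- locs$x - center[1L]; dy <- locs$y - center[2L]
  out <- locs
  out$x <- center[1L] + ca * dx - sa * dy
  out$y <- center[2L] + sa * dx + ca * dy
  out
}

#' Write a reconstructed image as 16-bit TIFF
#'
#' Counts are clipped at 65535; pixel size and origin (nm) go to a JSON
#' sidecar at `<path>.json`.
#'
#' @param img a `recon_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_recon_tiff <- function(img, path) {
  m <- pmin(img$counts, 65535L) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_nm = img$pixel_size,
                            origin_nm = img$origin),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
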