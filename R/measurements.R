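# Sensor measurement math: PAM-fluorometry quantum yield, hyperspectral
# reflectance calibration and region sampling, red-edge derivative, thermal
# region sampling, and record export.

#' Effective PSII quantum yield (YII)
#'
#' YII = (F'M - F) / F'M, the effective photochemical yield of photosystem
#' II under illumination: F is the momentary fluorescence just before the
#' saturation pulse and F'M the pulse-induced maximum. Vectorized; with
#' 0 <= F <= F'M the result lies in [0, 1]. F > F'M (a physically
#' inconsistent pair) raises a warning and returns the negative value so
#' bad readings remain visible downstream.
#'
#' @param F momentary fluorescence, arbitrary units, >= 0
#' @param F_M_prime saturation-pulse maximal fluorescence, same units, > 0
#' @return numeric YII
#' @export
compute_yii <- function(F, F_M_prime) {
  if (any(F_M_prime <= 0)) stop("'F_M_prime' must be positive")
  if (any(F < 0)) stop("'F' must be non-negative")
  if (any(F > F_M_prime))
    warning("F exceeds F_M_prime for some readings; YII is negative there")
  (F_M_prime - F) / F_M_prime
}

#' White/dark reflectance calibration
#'
#' Converts raw digital numbers to reflectance against per-band white and
#' dark references: R = (raw - dark) / (white - dark). Calibrating an
#' already-calibrated cube against white = 1, dark = 0 is the identity.
#'
#' @param raw H x W x B array (or `spectral_cube`) of raw values
#' @param bands band wavelengths (nm) if `raw` is a bare array
#' @param white,dark length-B reference vectors (scalars recycled);
#'   `white > dark` must hold in every band
#' @return a `spectral_cube` of reflectances
#' @export
calibrate_reflectance <- function(raw, white, dark, bands = NULL) {
  if (inherits(raw, "spectral_cube")) {
    bands <- raw$bands
    raw <- raw$data
  }
  if (is.null(bands)) stop("'bands' required when 'raw' is a bare array")
  B <- dim(raw)[3]
  white <- rep_len(as.numeric(white), B)
  dark <- rep_len(as.numeric(dark), B)
  bad <- which(white <= dark)
  if (length(bad))
    stop(sprintf("white reference does not exceed dark in band %d (%.1f nm)",
                 bad[1], bands[bad[1]]))
  out <- raw
  for (b in seq_len(B)) out[, , b] <- (raw[, , b] - dark[b]) / (white[b] - dark[b])
  spectral_cube(bands, out)
}

#' Sampling shapes on synthetic images
#'
#' Regions are drawn on the synthetic image in pixel coordinates (x = column,
#' y = row, both starting at 1). Membership is pixel-center-in-shape:
#' deterministic, no partial pixels.
#'
#' @param cx,cy circle center, px
#' @param radius circle radius, px
#' @return object of class `region_shape`
#' @export
region_circle <- function(cx, cy, radius) {
  if (radius <= 0) stop("'radius' must be positive")
  structure(list(kind = "circle", cx = cx, cy = cy, radius = radius),
            class = "region_shape")
}

#' @param p1,p2 line endpoints c(x, y), px; must be distinct
#' @param thickness full line thickness, px
#' @rdname region_circle
#' @export
region_line <- function(p1, p2, thickness = 1) {
  if (all(p1 == p2)) stop("line endpoints must be distinct")
  if (thickness <= 0) stop("'thickness' must be positive")
  structure(list(kind = "line", p1 = as.numeric(p1), p2 = as.numeric(p2),
                 thickness = thickness),
            class = "region_shape")
}

# Logical H x W mask of pixel centers inside the shape.
region_mask <- function(shape, H, W) {
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)
  if (shape$kind == "circle") {
    (xs - shape$cx)^2 + (ys - shape$cy)^2 <= shape$radius^2
  } else {
    v <- shape$p2 - shape$p1
    len2 <- sum(v^2)
    t_par <- ((xs - shape$p1[1]) * v[1] + (ys - shape$p1[2]) * v[2]) / len2
    t_cl <- pmin(pmax(t_par, 0), 1)
    dx <- xs - (shape$p1[1] + t_cl * v[1])
    dy <- ys - (shape$p1[2] + t_cl * v[2])
    dx^2 + dy^2 <= (shape$thickness / 2)^2
  }
}

#' Mean spectrum over a drawn region
#'
#' Unweighted per-band mean of the cube over the pixels whose centers fall
#' inside the shape.
#'
#' @param cube `spectral_cube`
#' @param shape `region_shape`
#' @return list with `spectrum` (length B), `bands`, `n_pixels`
#' @export
sample_region_spectrum <- function(cube, shape) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(shape, "region_shape"))
  d <- dim(cube$data)
  m <- region_mask(shape, d[1], d[2])
  n <- sum(m)
  if (n == 0) stop("region does not intersect the image")
  spec <- vapply(seq_len(d[3]), function(b) mean(cube$data[, , b][m]), numeric(1))
  list(spectrum = spec, bands = cube$bands, n_pixels = n)
}

#' Mean temperature over a drawn region
#'
#' @param img `thermal_image` (or plain matrix of degC)
#' @param shape `region_shape`
#' @return list with `mean_temp` (degC) and `n_pixels`
#' @export
sample_region_temperature <- function(img, shape) {
  stopifnot(inherits(shape, "region_shape"))
  img <- unclass(img)
  m <- region_mask(shape, nrow(img), ncol(img))
  n <- sum(m)
  if (n == 0) stop("region does not intersect the image")
  list(mean_temp = mean(img[m]), n_pixels = n)
}

#' Red-edge first derivative of a reflectance spectrum
#'
#' Finite-difference first derivative on the band grid (central differences
#' at interior bands, one-sided at the grid edges), with the maximum sought
#' inside the red-edge window (default 690-730 nm, bracketing the 700-720 nm
#' chlorophyll-sensitive rise). Ties — e.g. a perfectly flat spectrum —
#' resolve to the lowest wavelength in the window.
#'
#' @param spectrum per-band reflectance
#' @param bands band wavelengths, nm, strictly increasing
#' @param window length-2 red-edge search window, nm; must lie within the
#'   band range and contain at least 3 bands
#' @return list with `wavelength` (nm of maximum derivative),
#'   `max_derivative` (reflectance per nm), `derivative` (full-grid values)
#' @export
red_edge_derivative <- function(spectrum, bands, window = c(690, 730)) {
  bands <- as.numeric(bands)
  spectrum <- as.numeric(spectrum)
  if (length(spectrum) != length(bands)) stop("spectrum/bands length mismatch")
  if (is.unsorted(bands, strictly = TRUE)) stop("'bands' must be strictly increasing")
  if (window[1] < min(bands) || window[2] > max(bands))
    stop("red-edge window lies outside the band range")
  B <- length(bands)
  deriv <- numeric(B)
  deriv[1] <- (spectrum[2] - spectrum[1]) / (bands[2] - bands[1])
  deriv[B] <- (spectrum[B] - spectrum[B - 1]) / (bands[B] - bands[B - 1])
  if (B > 2) {
    i <- 2:(B - 1)
    deriv[i] <- (spectrum[i + 1] - spectrum[i - 1]) / (bands[i + 1] - bands[i - 1])
  }
  in_win <- which(bands >= window[1] & bands <= window[2])
  if (length(in_win) < 3) stop("red-edge window must contain at least 3 bands")
  best <- in_win[which.max(deriv[in_win])]  # which.max takes the first tie
  list(wavelength = bands[best], max_derivative = deriv[best], derivative = deriv)
}

#' Export measurement records
#'
#' Writes fluorometer/spectral/thermal records to CSV or JSON (lossless
#' round-trip at >= 6 significant digits) or renders a PNG overlay of a
#' synthetic image with numbered site markers and drawn shapes.
#'
#' @param records data.frame of records; for YII readings the frozen column
#'   order is `site_index, x, y, z, YII`
#' @param path output file path
#' @param format `"csv"`, `"json"` or `"png"`
#' @param image for `"png"`: a `thermal_image` or H x W matrix to render
#' @param shapes for `"png"`: list of `region_shape` overlays
#' @return `path`, invisibly
#' @export
export_records <- function(records, path, format = c("csv", "json", "png"),
                           image = NULL, shapes = list()) {
  format <- match.arg(format)
  if (is.data.frame(records) && nrow(records) == 0)
    stop("no records to export")
  if (!is.data.frame(records) && !length(records))
    stop("no records to export")
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(records, path, digits = NA, dataframe = "rows")
  } else {
    if (is.null(image)) stop("'image' is required for PNG export")
    img <- unclass(image)
    grDevices::png(path, width = 640, height = 640)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(2, 2, 2, 2))
    graphics::image(t(img), useRaster = TRUE, col = grDevices::hcl.colors(64),
                    axes = FALSE, main = "synthetic image")
    W <- ncol(img); H <- nrow(img)
    if (all(c("x", "y") %in% names(records)) || all(c("px", "py") %in% names(records))) {
      xs <- if ("px" %in% names(records)) records$px else records$x
      ys <- if ("py" %in% names(records)) records$py else records$y
      graphics::points((xs - 0.5) / W, (ys - 0.5) / H, pch = 21, bg = "white", cex = 2)
      graphics::text((xs - 0.5) / W, (ys - 0.5) / H, labels = seq_along(xs), cex = 0.7)
    }
    for (sh in shapes) {
      if (sh$kind == "circle") {
        th <- seq(0, 2 * pi, length.out = 73)
        graphics::lines((sh$cx + sh$radius * cos(th) - 0.5) / W,
                        (sh$cy + sh$radius * sin(th) - 0.5) / H, col = "white")
      } else {
        graphics::segments((sh$p1[1] - 0.5) / W, (sh$p1[2] - 0.5) / H,
                           (sh$p2[1] - 0.5) / W, (sh$p2[2] - 0.5) / H, col = "white")
      }
    }
  }
  invisible(path)
}

#' Read records back from CSV or JSON
#'
#' @param path file written by [export_records()]
#' @param format `"csv"` or `"json"`
#' @return data.frame
#' @export
import_records <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") utils::read.csv(path)
  else as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
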