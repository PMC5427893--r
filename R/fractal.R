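#' Configuration for local connected fractal dimension mapping
#'
#' The local connected fractal dimension (LFD) at a foreground pixel is the
#' least-squares slope of `ln(mu_eps)` on `ln(eps)`, where `mu_eps` counts
#' the pixels of the locally connected foreground set inside concentric boxes
#' of side `eps` centered on the pixel. Values near 1 indicate line-like
#' structure, near 2 filled regions.
#'
#' @param box_sizes_px strictly increasing odd box sides (pixels), at least
#'   `min_scales_for_fit` of them; the largest is the sampling window.
#' @param stride_px foreground subsampling step (1 = every pixel).
#' @param connectivity 4 or 8, for the locally connected set.
#' @param min_scales_for_fit minimum number of distinct box masses required
#'   for a valid slope.
#' @param clip_max upper clip for LFD values (clipped pixels are counted).
#' @return A `fractal_config` object.
#' @export
fractal_config <- function(box_sizes_px = seq(3L, 31L, by = 2L),
                           stride_px = 4L,
                           connectivity = 8L,
                           min_scales_for_fit = 3L,
                           clip_max = 2.2) {
  box_sizes_px <- as.integer(box_sizes_px)
  if (length(box_sizes_px) < min_scales_for_fit)
    stop_config("need at least min_scales_for_fit box sizes")
  if (any(box_sizes_px %% 2L != 1L) || any(box_sizes_px < 3L))
    stop_config("box sizes must be odd integers >= 3")
  if (any(diff(box_sizes_px) <= 0L))
    stop_config("box sizes must be strictly increasing")
  check_number(stride_px, "stride_px", min = 1, integer = TRUE)
  if (!connectivity %in% c(4L, 8L)) stop_config("connectivity must be 4 or 8")
  check_number(min_scales_for_fit, "min_scales_for_fit", min = 3,
               integer = TRUE)
  structure(list(box_sizes_px = box_sizes_px,
                 max_box_px = max(box_sizes_px),
                 stride_px = as.integer(stride_px),
                 connectivity = as.integer(connectivity),
                 min_scales_for_fit = as.integer(min_scales_for_fit),
                 clip_max = clip_max),
            class = "fractal_config")
}

#' Map the local connected fractal dimension over a vessel mask
#'
#' For each sampled foreground pixel inside the ROI, the connected component
#' of the foreground restricted to the max-box window centered on the pixel
#' is flood-filled, its pixel mass is counted inside each concentric box, and
#' the LFD is the slope of `ln(mass)` against `ln(box size)`. Pixels whose
#' component yields fewer than `min_scales_for_fit` distinct masses are
#' marked invalid.
#'
#' @param mask a `vessel_mask` (or logical matrix).
#' @param roi_mask optional logical ROI (default: whole image).
#' @param config a [fractal_config()].
#' @return An `lfd_map`: `lfd` (numeric matrix, `NA` outside samples),
#'   `valid_mask`, `n_clipped`, `n_invalid`, and the configuration. An ROI
#'   with no foreground yields an empty (flagged) map, not an error.
#' @export
local_fractal_dimension_map <- function(mask, roi_mask = NULL,
                                        config = fractal_config()) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_config("mask must be a logical matrix")
  if (!inherits(config, "fractal_config"))
    stop_config("config must be a fractal_config")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(mask), ncol(mask))
  if (!identical(dim(roi_mask), dim(mask)))
    stop_config("roi_mask must match mask dimensions")
  m <- unclass(mask); attributes(m) <- list(dim = dim(mask))
  r <- unclass(roi_mask); attributes(r) <- list(dim = dim(roi_mask))
  res <- .lfd_map_cpp(m, r, config$box_sizes_px, config$stride_px,
                      config$connectivity, config$min_scales_for_fit,
                      config$clip_max)
  structure(list(lfd = res$lfd, valid_mask = res$valid,
                 n_clipped = res$n_clipped, n_invalid = res$n_invalid,
                 n_valid = sum(res$valid), config = config),
            class = "lfd_map")
}

#' @export
print.lfd_map <- function(x, ...) {
  if (x$n_valid == 0L) {
    cat("<lfd_map> empty (no valid samples)\n")
  } else {
    v <- x$lfd[x$valid_mask]
    cat(sprintf("<lfd_map> %d samples, LFD mean %.3f [%.3f, %.3f], %d clipped, %d invalid\n",
                x$n_valid, mean(v), min(v), max(v), x$n_clipped, x$n_invalid))
  }
  invisible(x)
}

#' Relative-frequency histogram of an LFD map
#'
#' Fixed bins covering `[0, clip_max]` (default width 0.01); frequencies are
#' normalized to sum to 1 over the valid samples.
#'
#' @param map an `lfd_map` (or numeric vector of LFD samples).
#' @param bin_width histogram bin width in LFD units.
#' @return List with `bin_edges`, `bin_mids` and `relative_frequencies`.
#' @export
lfd_histogram <- function(map, bin_width = 0.01) {
  v <- if (inherits(map, "lfd_map")) map$lfd[map$valid_mask] else
    map[is.finite(map)]
  if (length(v) == 0L) stop("empty LFD map: no valid samples to bin")
  upper <- if (inherits(map, "lfd_map")) map$config$clip_max else
    max(2.2, max(v))
  nb <- ceiling(upper / bin_width)
  edges <- (0:nb) * bin_width
  idx <- pmin(pmax(floor(v / bin_width) + 1L, 1L), nb)
  freq <- tabulate(idx, nbins = nb) / length(v)
  list(bin_edges = edges, bin_mids = edges[-1L] - bin_width / 2,
       relative_frequencies = freq, n = length(v))
}

#' Histogram complexity features of an LFD map
#'
#' `peak_lfd` is the LFD at the center of the modal histogram bin and
#' `peak_frequency` the relative frequency of that bin. Skewness and kurtosis
#' are the third and fourth standardized moments of the underlying LFD
#' samples (population moments); kurtosis is excess kurtosis (normal = 0).
#' With fewer than two distinct occupied bins the moment fields are `NA` and
#' flagged undefined.
#'
#' @param map an `lfd_map` (or numeric vector of LFD samples).
#' @param bin_width histogram bin width for the peak fields.
#' @return A `fractal_features` list: `peak_lfd`, `peak_frequency`,
#'   `skewness`, `kurtosis`, `moments_defined`, `histogram`, `n`.
#' @export
fractal_features <- function(map, bin_width = 0.01) {
  h <- lfd_histogram(map, bin_width)
  v <- if (inherits(map, "lfd_map")) map$lfd[map$valid_mask] else
    map[is.finite(map)]
  # locate the modal bin on a lightly smoothed histogram (triangular kernel)
  # so the peak position is stable under foreground subsampling; the peak
  # frequency reported is still the raw relative frequency at that bin
  kern <- c(1, 2, 4, 2, 1) / 10
  sm <- as.numeric(stats::filter(h$relative_frequencies, kern, sides = 2))
  sm[is.na(sm)] <- h$relative_frequencies[is.na(sm)]
  modal <- which.max(sm)
  occupied <- sum(h$relative_frequencies > 0)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  defined <- occupied >= 2L && m2 > 0
  structure(list(
    peak_lfd = h$bin_mids[modal],
    peak_frequency = h$relative_frequencies[modal],
    skewness = if (defined) mean((v - mu)^3) / m2^1.5 else NA_real_,
    kurtosis = if (defined) mean((v - mu)^4) / m2^2 - 3 else NA_real_,
    moments_defined = defined,
    histogram = h,
    n = length(v)),
    class = "fractal_features")
}

#' @export
print.fractal_features <- function(x, ...) {
  cat(sprintf("<fractal_features> peak LFD %.3f (freq %.4f), skew %.3f, ex. kurtosis %.3f, n = %d\n",
              x$peak_lfd, x$peak_frequency, x$skewness, x$kurtosis, x$n))
  invisible(x)
}

#' @export
as.data.frame.fractal_features <- function(x, ...) {
  data.frame(peak_lfd = x$peak_lfd, peak_frequency = x$peak_frequency,
             skewness = x$skewness, kurtosis = x$kurtosis, n = x$n)
}

#' Write an LFD map as 32-bit float TIFF
#' @param map an `lfd_map`.
#' @param path output path. Invalid pixels are written as 0.
#' @return `path`, invisibly.
#' @export
write_lfd_tiff <- function(map, path) {
  m <- map$lfd
  m[!map$valid_mask] <- 0
  tiff::writeTIFF(m / max(map$config$clip_max, 1), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write a colorized LFD map PNG (red = low complexity, purple = high)
#' @param map an `lfd_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lfd_png <- function(map, path) {
  m <- map$lfd
  nr <- nrow(m); nc <- ncol(m)
  t01 <- pmin(pmax(m / map$config$clip_max, 0), 1)
  # rainbow-like ramp red -> yellow -> green -> blue -> purple
  cols <- grDevices::rainbow(256L, start = 0, end = 0.8)
  rgbm <- grDevices::col2rgb(cols) / 255
  idx <- pmin(floor(t01 * 255) + 1L, 256L)
  img <- array(0, c(nr, nc, 3L))
  ok <- map$valid_mask
  for (ch in 1:3) {
    plane <- matrix(0, nr, nc)
    plane[ok] <- rgbm[ch, idx[ok]]
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  invisible(path)
}
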