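#' Susceptibility-weighted phase-mask processing
#'
#' Homodyne filtering per slice: the complex image (magnitude times
#' `exp(i * phase)`) is divided by its own low-pass version, obtained by
#' windowing central k-space with a `hanning_size x hanning_size` 2D Hann
#' window. The filtered phase `phi` builds a negative-phase mask
#' `f(phi) = (phi + pi) / pi` for `phi < 0` (1 otherwise), and the SWI volume
#' is `magnitude * f^mask_power`.
#'
#' `hanning_size = 0` disables homodyne filtering (the raw phase is used),
#' which exposes the closed-form mask behavior directly.
#'
#' @param magnitude,phase numeric arrays `[row, col, slice]` (or matrices for
#'   a single slice); phase in `[-pi, pi]`.
#' @param hanning_size side of the central k-space Hann window (voxels).
#' @param mask_power number of mask multiplications.
#' @return List with `swi`, `filtered_phase` and `mask` arrays.
#' @export
swi_process <- function(magnitude, phase, hanning_size = 48L, mask_power = 4L) {
  if (!identical(dim(magnitude), dim(phase)))
    stop_config("magnitude and phase must have identical dimensions")
  if (any(phase < -pi - 1e-9) || any(phase > pi + 1e-9))
    stop_config("phase must lie in [-pi, pi]")
  dm <- dim(magnitude)
  two_d <- length(dm) == 2L
  if (two_d) {
    dim(magnitude) <- c(dm, 1L)
    dim(phase) <- c(dm, 1L)
    dm <- dim(magnitude)
  }
  fphase <- array(0, dm)
  for (k in seq_len(dm[3L])) {
    fphase[, , k] <- if (hanning_size > 0)
      homodyne_phase(magnitude[, , k], phase[, , k], hanning_size)
    else phase[, , k]
  }
  mask <- swi_phase_mask(fphase)
  swi <- magnitude * mask^mask_power
  if (two_d) {
    swi <- swi[, , 1L]; fphase <- fphase[, , 1L]; mask <- mask[, , 1L]
  }
  list(swi = swi, filtered_phase = fphase, mask = mask)
}

#' Negative-phase mask
#'
#' `f(phi) = (phi + pi) / pi` for `phi < 0`, 1 otherwise: a voxel at phase
#' `-pi` is suppressed to 0, a voxel at `-pi/2` to 0.5 (0.0625 after four
#' multiplications).
#'
#' @param phi phase values in `[-pi, pi]`.
#' @return Mask values in `[0, 1]`, same shape as `phi`.
#' @export
swi_phase_mask <- function(phi) {
  out <- phi
  neg <- phi < 0
  out[neg] <- (phi[neg] + pi) / pi
  out[!neg] <- 1
  out
}

# homodyne high-pass phase of one complex slice
homodyne_phase <- function(mag, phs, hanning_size) {
  nr <- nrow(mag); nc <- ncol(mag)
  cm <- mag * exp(1i * phs)
  L <- min(hanning_size, nr - 2, nc - 2)
  # separable raised-cosine (Hann) window of full width L, symmetric about
  # the DC sample so a real image keeps a real low-pass
  half <- L / 2
  taper <- function(n) {
    k <- seq_len(n) - 1
    d <- pmin(k, n - k)                 # distance to DC in fft layout
    ifelse(d <= half, 0.5 * (1 + cos(pi * d / half)), 0)
  }
  wk <- outer(taper(nr), taper(nc))
  lp <- fft(fft(cm) * wk, inverse = TRUE) / (nr * nc)
  h <- cm / ifelse(Mod(lp) < .Machine$double.eps, 1 + 0i, lp)
  Arg(h)
}

circshift <- function(m, by_r, by_c) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - by_r) %% nr) + 1, ((seq_len(nc) - 1 - by_c) %% nc) + 1]
}

#' Configuration for hierarchical region splitting (HRS)
#'
#' @param histogram_bins number of bins over the rescaled `[0, 255]` range.
#' @param smoothing_window odd moving-average window for histogram smoothing.
#' @param min_peak_separation minimum distance between the two modes, in
#'   rescaled intensity units.
#' @param uniformity_cv_max stop splitting when a region's coefficient of
#'   variation (sd/mean, original units) falls at or below this.
#' @param min_region_voxels do not split regions smaller than this.
#' @param max_depth maximum recursion depth.
#' @param mean_target,mean_tolerance a-priori mean intensity (original units)
#'   selecting lesion leaves in [extract_lesion()].
#' @return An `hrs_config` object.
#' @export
hrs_config <- function(histogram_bins = 256L,
                       smoothing_window = 5L,
                       min_peak_separation = 30,
                       uniformity_cv_max = 0.02,
                       min_region_voxels = 50L,
                       max_depth = 6L,
                       mean_target = NULL,
                       mean_tolerance = NULL) {
  check_number(histogram_bins, "histogram_bins", min = 8, integer = TRUE)
  check_number(smoothing_window, "smoothing_window", min = 1, integer = TRUE)
  if (smoothing_window %% 2L != 1L)
    stop_config("smoothing_window must be odd")
  check_number(min_peak_separation, "min_peak_separation",
               min = .Machine$double.eps)
  check_number(uniformity_cv_max, "uniformity_cv_max",
               min = .Machine$double.eps)
  check_number(min_region_voxels, "min_region_voxels", min = 1,
               integer = TRUE)
  check_number(max_depth, "max_depth", min = 1, integer = TRUE)
  structure(list(histogram_bins = as.integer(histogram_bins),
                 smoothing_window = as.integer(smoothing_window),
                 min_peak_separation = min_peak_separation,
                 uniformity_cv_max = uniformity_cv_max,
                 min_region_voxels = as.integer(min_region_voxels),
                 max_depth = as.integer(max_depth),
                 mean_target = mean_target, mean_tolerance = mean_tolerance),
            class = "hrs_config")
}

find_histogram_peaks <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] > s[i - 1L]) {
      j <- i
      while (j < n && s[j + 1L] == s[j]) j <- j + 1L   # walk plateaus
      if (j < n && s[j + 1L] < s[j])
        peaks <- c(peaks, as.integer(floor((i + j) / 2)))
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

#' Hierarchical region splitting of an MR volume
#'
#' Preprocessing restricts the volume to the brain mask and linearly rescales
#' intensities to `[0, 255]` (the inverse map is stored, and all reported
#' means/split values are in original units). Each region's intensity
#' histogram is smoothed; when two modes separated by at least
#' `min_peak_separation` exist, the region splits at the valley between them
#' and recursion continues. Splitting stops on uniformity
#' (CV <= `uniformity_cv_max`), small regions, unimodal histograms, or
#' `max_depth`. Final leaves are the 6-connected 3D components of each
#' terminal intensity class.
#'
#' @param volume numeric array `[row, col, slice]`.
#' @param brain_mask logical array of the same shape (non-empty).
#' @param config an [hrs_config()].
#' @return An `hrs_tree`: `root` (nested nodes with voxel indices, mean, sd,
#'   depth, split value, children) and `leaves` (list of final regions with
#'   `idx`, `mean`, `n`, `depth`).
#' @export
hrs_segment <- function(volume, brain_mask, config = hrs_config()) {
  if (!identical(dim(volume), dim(brain_mask)))
    stop_config("volume and brain_mask must have identical dimensions")
  if (!any(brain_mask)) stop_config("empty brain mask")
  if (!inherits(config, "hrs_config"))
    stop_config("config must be an hrs_config")
  v <- as.numeric(volume)
  idx0 <- which(brain_mask)
  lo <- min(v[idx0]); hi <- max(v[idx0])
  scale <- if (hi > lo) 255 / (hi - lo) else 0
  resc <- (v - lo) * scale
  bw <- 256 / config$histogram_bins

  split_region <- function(idx, depth) {
    vals <- v[idx]
    node <- list(idx = idx, mean = mean(vals), sd = sd(vals),
                 n = length(idx), depth = depth, split_value = NA_real_,
                 children = NULL)
    if (length(idx) < config$min_region_voxels) return(node)
    rv <- resc[idx]
    # uniformity on the rescaled intensities, so the criterion (like the
    # rest of the recursion) is invariant under constant intensity shifts
    cv <- sd(rv) / max(abs(mean(rv)), 1)
    if (is.finite(cv) && cv <= config$uniformity_cv_max) return(node)
    if (depth >= config$max_depth) return(node)
    counts <- tabulate(pmin(floor(rv / bw) + 1L, config$histogram_bins),
                       nbins = config$histogram_bins)
    pad <- (config$smoothing_window - 1L) %/% 2L
    padded <- c(rep(counts[1L], pad), counts, rep(counts[length(counts)], pad))
    s <- as.numeric(stats::filter(padded, rep(1 / config$smoothing_window,
                                              config$smoothing_window),
                                  sides = 2L))[pad + seq_along(counts)]
    peaks <- find_histogram_peaks(s)
    if (length(peaks) < 2L) return(node)
    ord <- peaks[order(s[peaks], decreasing = TRUE)]
    p1 <- ord[1L]
    sep_bins <- config$min_peak_separation / bw
    p2 <- ord[which(abs(ord - p1) >= sep_bins)[1L]]
    if (is.na(p2)) return(node)
    lohi <- sort(c(p1, p2))
    between <- lohi[1L]:lohi[2L]
    vmin <- min(s[between])
    ties <- between[s[between] == vmin]   # middle of a flat valley
    valley_bin <- ties[ceiling(length(ties) / 2)]
    split_resc <- (valley_bin - 0.5) * bw
    node$split_value <- split_resc / max(scale, .Machine$double.eps) + lo
    lower <- idx[rv <= split_resc]
    upper <- idx[rv > split_resc]
    if (length(lower) == 0L || length(upper) == 0L) {
      node$split_value <- NA_real_
      return(node)
    }
    node$children <- list(split_region(lower, depth + 1L),
                          split_region(upper, depth + 1L))
    node
  }

  root <- split_region(idx0, 1L)

  # collect terminal intensity classes, then split into 3D components
  leaves <- list()
  collect <- function(node) {
    if (is.null(node$children)) {
      leaves[[length(leaves) + 1L]] <<- node
    } else {
      collect(node$children[[1L]])
      collect(node$children[[2L]])
    }
  }
  collect(root)
  dm <- dim(volume)
  final <- list()
  for (lf in leaves) {
    m <- array(FALSE, dm)
    m[lf$idx] <- TRUE
    lab <- .label3d_cpp(as.logical(m), as.integer(dm))
    for (comp in seq_len(max(lab))) {
      cidx <- which(lab == comp)
      final[[length(final) + 1L]] <- list(idx = cidx, mean = mean(v[cidx]),
                                          n = length(cidx), depth = lf$depth)
    }
  }

  structure(list(root = root, leaves = final, dim = dm,
                 rescale = c(lo = lo, hi = hi), config = config),
            class = "hrs_tree")
}

#' @export
print.hrs_tree <- function(x, ...) {
  mns <- vapply(x$leaves, `[[`, numeric(1), "mean")
  cat(sprintf("<hrs_tree> %d leaves, leaf means %s\n", length(x$leaves),
              paste(sprintf("%.1f", sort(unique(round(mns, 1)))),
                    collapse = ", ")))
  invisible(x)
}

#' First split value of an HRS tree (original intensity units)
#' @param tree an `hrs_tree`.
#' @return Numeric split value, or `NA` if the root never split.
#' @export
hrs_first_split <- function(tree) tree$root$split_value

#' Extract a lesion from an HRS tree by a-priori mean intensity
#'
#' The lesion mask is the union of leaves whose mean intensity (original
#' units) lies within `mean_tolerance` of `mean_target`.
#'
#' @param tree an `hrs_tree`.
#' @param config an [hrs_config()] with `mean_target` and `mean_tolerance`
#'   set (or pass them via `...` overrides).
#' @param brain_mask logical array; the denominator of `volume_percent`.
#' @param mean_target,mean_tolerance optional overrides of the config values.
#' @return A `lesion_result`: `lesion_mask`, `brain_mask`, `volume_percent`
#'   (100 * lesion voxels / brain voxels) and the means of selected leaves.
#'   No matching leaf yields an empty lesion with `volume_percent = 0`.
#' @export
extract_lesion <- function(tree, config, brain_mask,
                           mean_target = NULL, mean_tolerance = NULL) {
  target <- mean_target %||% config$mean_target
  tol <- mean_tolerance %||% config$mean_tolerance
  if (is.null(target) || is.null(tol))
    stop_config("mean_target and mean_tolerance are required")
  mask <- array(FALSE, tree$dim)
  sel_means <- numeric(0)
  for (lf in tree$leaves) {
    if (abs(lf$mean - target) <= tol) {
      mask[lf$idx] <- TRUE
      sel_means <- c(sel_means, lf$mean)
    }
  }
  mask <- mask & brain_mask
  structure(list(lesion_mask = mask, brain_mask = brain_mask,
                 volume_percent = 100 * sum(mask) / sum(brain_mask),
                 selected_leaf_means = sel_means),
            class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf("<lesion_result> %d voxels, %.2f%% of brain (%d leaves)\n",
              sum(x$lesion_mask), x$volume_percent,
              length(x$selected_leaf_means)))
  invisible(x)
}

#' Write per-slice lesion overlay PNGs
#'
#' Each slice of the volume is written as a grayscale PNG with the lesion
#' mask overlaid in red.
#'
#' @param volume numeric array `[row, col, slice]`.
#' @param lesion_mask logical array of the same shape.
#' @param path_prefix output prefix; files are `<prefix>_z01.png`, ...
#' @return Invisible character vector of written paths.
#' @export
write_lesion_overlay_png <- function(volume, lesion_mask, path_prefix) {
  rng <- range(volume)
  norm <- if (diff(rng) > 0) (volume - rng[1]) / diff(rng) else volume * 0
  paths <- character(dim(volume)[3L])
  for (k in seq_len(dim(volume)[3L])) {
    sl <- norm[, , k]
    img <- array(rep(sl, 3L), c(dim(sl), 3L))
    les <- lesion_mask[, , k]
    r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
    r[les] <- 1; g[les] <- 0.1; b[les] <- 0.1
    img[, , 1L] <- r; img[, , 2L] <- g; img[, , 3L] <- b
    paths[k] <- sprintf("%s_z%02d.png", path_prefix, k)
    png::writePNG(img, paths[k])
  }
  invisible(paths)
}

#' Threshold-plus-largest-component brain mask estimate
#'
#' Fallback when no brain mask is supplied with real data: Otsu threshold on
#' the volume intensities, then the largest 6-connected 3D component.
#'
#' @param volume numeric array `[row, col, slice]`.
#' @return Logical array.
#' @export
estimate_brain_mask <- function(volume) {
  v <- as.numeric(volume)
  rng <- range(v)
  if (diff(rng) == 0) stop_config("constant volume")
  th <- EBImage::otsu(matrix(v, nrow = 1L), range = rng, levels = 256L)
  fg <- array(volume > th, dim(volume))
  lab <- .label3d_cpp(as.logical(fg), as.integer(dim(volume)))
  if (max(lab) == 0L) return(fg)
  counts <- tabulate(lab[lab > 0L])
  array(lab == which.max(counts), dim(volume))
}
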