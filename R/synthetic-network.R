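#' Configuration for the synthetic vessel-network generator
#'
#' The generator grows a 2D branching network emulating the dense cortical
#' surface vascular plexus seen in vessel-painted whole-brain images: trunks
#' seeded on the image border grow inward as jittered random walks and split
#' into two daughter branches (at roughly +/- 45 degrees) with a fixed
#' per-step probability. An occupancy grid keeps segments from overlapping,
#' so the recorded ground truth (segments, junctions, total length) stays
#' exact after rasterization.
#'
#' Defaults are calibrated so that an unablated ("sham-like") network at
#' 20 um/px is dense enough for its local-fractal-dimension histogram to peak
#' in the 1.3-1.6 range typical of healthy cortical plexus images.
#'
#' @param image_height_px,image_width_px canvas size in pixels.
#' @param pixel_size_um physical pixel size (um/px).
#' @param n_seed_trunks number of trunks seeded on the border.
#' @param branch_probability per-growth-step probability of a binary split.
#' @param step_length_px length of one growth step, in pixels.
#' @param max_steps maximum growth steps per branch.
#' @param direction_jitter_rad s.d. of the per-step heading perturbation.
#' @param width_range_px integer `c(min, max)` vessel widths in pixels.
#' @param max_total_segments safety cap on the number of segments.
#' @param rng_seed integer seed; identical configuration implies identical
#'   output.
#' @return A `network_config` object (named list).
#' @export
network_config <- function(image_height_px = 768L,
                           image_width_px = 768L,
                           pixel_size_um = 20,
                           n_seed_trunks = 48L,
                           branch_probability = 0.85,
                           step_length_px = 8,
                           max_steps = 120L,
                           direction_jitter_rad = 0.22,
                           width_range_px = c(2L, 3L),
                           max_total_segments = 20000L,
                           rng_seed = 1L) {
  check_number(image_height_px, "image_height_px", min = 8, integer = TRUE)
  check_number(image_width_px, "image_width_px", min = 8, integer = TRUE)
  check_number(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  check_number(n_seed_trunks, "n_seed_trunks", min = 0, integer = TRUE)
  check_number(branch_probability, "branch_probability", min = 0, max = 1)
  check_number(step_length_px, "step_length_px", min = .Machine$double.eps)
  check_number(max_steps, "max_steps", min = 1, integer = TRUE)
  check_number(direction_jitter_rad, "direction_jitter_rad", min = 0)
  if (length(width_range_px) != 2L || any(width_range_px < 1) ||
      width_range_px[1] > width_range_px[2])
    stop_config("width_range_px must be c(min, max) with min >= 1")
  check_number(rng_seed, "rng_seed", integer = TRUE)
  structure(list(image_height_px = as.integer(image_height_px),
                 image_width_px = as.integer(image_width_px),
                 pixel_size_um = pixel_size_um,
                 n_seed_trunks = as.integer(n_seed_trunks),
                 branch_probability = branch_probability,
                 step_length_px = step_length_px,
                 max_steps = as.integer(max_steps),
                 direction_jitter_rad = direction_jitter_rad,
                 width_range_px = as.integer(round(width_range_px)),
                 max_total_segments = as.integer(max_total_segments),
                 rng_seed = as.integer(rng_seed)),
            class = "network_config")
}

#' Focal + global lesion specification for network ablation
#'
#' Models a focal contusion (strong vessel loss at an epicenter, decaying
#' with distance) superimposed on a diffuse bilateral rarefication. A segment
#' whose midpoint lies at distance `d` from the epicenter is removed with
#' probability `max(global_ablation_fraction,
#' core_ablation_fraction * falloff(d))`.
#'
#' @param center_rc_px epicenter `c(row, col)` in pixels.
#' @param radius_px lesion radius in pixels (0 disables the focal term).
#' @param core_ablation_fraction removal probability at the epicenter.
#' @param falloff `"flat"` (1 inside the radius, 0 outside; the default,
#'   matching the sharply delimited disruption zone under an impactor tip) or
#'   `"linear"` (1 at the center, decaying to 0 at `radius_px`).
#' @param global_ablation_fraction distance-independent removal probability.
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(center_rc_px, radius_px,
                        core_ablation_fraction = 0.9,
                        falloff = c("flat", "linear"),
                        global_ablation_fraction = 0) {
  falloff <- match.arg(falloff)
  if (length(center_rc_px) != 2L || !is.numeric(center_rc_px))
    stop_config("center_rc_px must be c(row, col)")
  check_number(radius_px, "radius_px", min = 0)
  check_number(core_ablation_fraction, "core_ablation_fraction", 0, 1)
  check_number(global_ablation_fraction, "global_ablation_fraction", 0, 1)
  structure(list(center_rc_px = as.numeric(center_rc_px),
                 radius_px = radius_px,
                 core_ablation_fraction = core_ablation_fraction,
                 falloff = falloff,
                 global_ablation_fraction = global_ablation_fraction),
            class = "lesion_spec")
}

new_ground_truth_network <- function(segments, config) {
  len_px <- if (nrow(segments)) {
    sqrt((segments$r1 - segments$r0)^2 + (segments$c1 - segments$c0)^2)
  } else numeric(0)
  structure(list(segments = segments,
                 junction_points = infer_junctions(segments),
                 total_length_um = sum(len_px) * config$pixel_size_um,
                 pixel_size_um = config$pixel_size_um,
                 image_height_px = config$image_height_px,
                 image_width_px = config$image_width_px,
                 config = config),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth_network> %d segments, %d junctions, ",
                     "total length %.1f um (%d x %d px @ %.3g um/px)\n"),
              nrow(x$segments), nrow(x$junction_points), x$total_length_um,
              x$image_height_px, x$image_width_px, x$pixel_size_um))
  invisible(x)
}

#' Junctions are the points where three or more segments meet
#' @noRd
infer_junctions <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L)
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  keys <- c(sprintf("%.4f,%.4f", segments$r0, segments$c0),
            sprintf("%.4f,%.4f", segments$r1, segments$c1))
  tab <- table(keys)
  jk <- names(tab)[tab >= 3L]
  if (length(jk) == 0L)
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  m <- do.call(rbind, lapply(strsplit(jk, ",", fixed = TRUE), as.numeric))
  dimnames(m) <- list(NULL, c("row", "col"))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

#' Grow a synthetic vessel network with exact ground truth
#'
#' Seeded, collision-avoiding branching growth (see [network_config()]).
#' Returns the exact segment list; junction points are exactly the points
#' where at least three segments meet, and the total length is the sum of
#' segment Euclidean lengths times the pixel size.
#'
#' @param config a [network_config()].
#' @return A `ground_truth_network`: list with `segments` (data frame
#'   `r0, c0, r1, c1, width_px`), `junction_points` (matrix of row/col),
#'   `total_length_um` and the generating configuration.
#' @export
generate_vessel_network <- function(config) {
  if (!inherits(config, "network_config"))
    stop_config("config must be a network_config")
  H <- config$image_height_px
  W <- config$image_width_px
  wmax <- config$width_range_px[2L]
  clearance <- wmax / 2 + 2.5
  step <- config$step_length_px
  occ <- matrix(0L, H, W)
  offsets <- lapply(seq_len(wmax), function(w) disk_offsets(w / 2 + clearance))
  # collision samples closer than this to the segment start are skipped:
  # that zone legitimately touches the parent/previous corridor at joints
  r_free <- wmax / 2 + clearance + 1

  segs <- vector("list", 512L)
  nseg <- 0L

  with_seed(config$rng_seed, {
    tips <- vector("list", config$n_seed_trunks)
    for (i in seq_len(config$n_seed_trunks)) {
      side <- sample.int(4L, 1L)
      pos <- runif(1)
      start <- switch(side,
                      c(2, 2 + pos * (W - 4), pi / 2),        # top, growing down
                      c(2 + pos * (H - 4), W - 1, pi),        # right, growing left
                      c(H - 1, 2 + pos * (W - 4), -pi / 2),   # bottom, growing up
                      c(2 + pos * (H - 4), 2, 0))             # left, growing right
      tips[[i]] <- list(r = start[1], c = start[2],
                        ang = start[3] + runif(1, -0.5, 0.5),
                        width = sample(seq.int(config$width_range_px[1L],
                                               config$width_range_px[2L]), 1L),
                        steps = 0L, recent = integer(0), fresh = FALSE)
    }
    while (length(tips) > 0L && nseg < config$max_total_segments) {
      tip <- tips[[length(tips)]]
      tips[[length(tips)]] <- NULL
      if (tip$steps >= config$max_steps) next
      ang <- tip$ang + rnorm(1, 0, config$direction_jitter_rad)
      r2 <- tip$r + step * sin(ang)
      c2 <- tip$c + step * cos(ang)
      if (r2 < 2 || r2 > H - 1 || c2 < 2 || c2 > W - 1) next
      ts <- seq(0, 1, length.out = max(3L, ceiling(step) + 1L))
      rs <- tip$r + ts * (r2 - tip$r)
      cs <- tip$c + ts * (c2 - tip$c)
      # the corridor of the tip's own previous segments (and its parent's
      # last) is whitelisted via recent ids; only the first step after a
      # branch skips a short start zone, where the sibling branch
      # legitimately shares the junction blob
      chk <- if (isTRUE(tip$fresh)) ts * step > r_free else rep(TRUE, length(ts))
      if (any(chk)) {
        hit <- occ[cbind(round(rs[chk]), round(cs[chk]))]
        if (any(hit != 0L & !(hit %in% tip$recent))) next
      }
      nseg <- nseg + 1L
      if (nseg > length(segs)) segs <- c(segs, vector("list", length(segs)))
      segs[[nseg]] <- c(tip$r, tip$c, r2, c2, tip$width)
      off <- offsets[[tip$width]]
      for (k in seq_along(ts)) {
        pr <- round(rs[k]) + off[, 1L]
        pc <- round(cs[k]) + off[, 2L]
        ok <- pr >= 1L & pr <= H & pc >= 1L & pc <= W
        cells <- cbind(pr[ok], pc[ok])
        free <- occ[cells] == 0L          # first writer wins
        occ[cells[free, , drop = FALSE]] <- nseg
      }
      recent <- c(nseg, tip$recent)[seq_len(min(3L, length(tip$recent) + 1L))]
      if (runif(1) < config$branch_probability) {
        spread <- pi / 4 + rnorm(2, 0, 0.08)
        wchild <- max(config$width_range_px[1L], tip$width - 1L)
        tips[[length(tips) + 1L]] <- list(r = r2, c = c2, ang = ang - spread[1],
                                          width = wchild, steps = tip$steps + 1L,
                                          recent = recent, fresh = TRUE)
        tips[[length(tips) + 1L]] <- list(r = r2, c = c2, ang = ang + spread[2],
                                          width = wchild, steps = tip$steps + 1L,
                                          recent = recent, fresh = TRUE)
      } else {
        tips[[length(tips) + 1L]] <- list(r = r2, c = c2, ang = ang,
                                          width = tip$width,
                                          steps = tip$steps + 1L,
                                          recent = recent, fresh = FALSE)
      }
    }
  })

  segments <- if (nseg > 0L) {
    m <- do.call(rbind, segs[seq_len(nseg)])
    data.frame(r0 = m[, 1L], c0 = m[, 2L], r1 = m[, 3L], c1 = m[, 4L],
               width_px = as.integer(m[, 5L]))
  } else {
    data.frame(r0 = numeric(0), c0 = numeric(0), r1 = numeric(0),
               c1 = numeric(0), width_px = integer(0))
  }
  new_ground_truth_network(segments, config)
}

#' Apply a focal/global lesion to a ground-truth network
#'
#' Each segment is removed independently with probability
#' `max(global, core * falloff(distance of midpoint to epicenter))`.
#' Junctions and total length are recomputed exactly from the survivors, so
#' ablation never increases either.
#'
#' @param network a `ground_truth_network`.
#' @param lesion a [lesion_spec()].
#' @param rng_seed integer seed for the removal draws.
#' @return The ablated `ground_truth_network`.
#' @export
ablate_network <- function(network, lesion, rng_seed = 1L) {
  if (!inherits(network, "ground_truth_network"))
    stop_config("network must be a ground_truth_network")
  if (!inherits(lesion, "lesion_spec"))
    stop_config("lesion must be a lesion_spec")
  seg <- network$segments
  if (nrow(seg) == 0L) return(network)
  mid_r <- (seg$r0 + seg$r1) / 2
  mid_c <- (seg$c0 + seg$c1) / 2
  d <- sqrt((mid_r - lesion$center_rc_px[1])^2 +
            (mid_c - lesion$center_rc_px[2])^2)
  fall <- if (lesion$radius_px <= 0) {
    rep(0, length(d))
  } else if (lesion$falloff == "flat") {
    as.numeric(d <= lesion$radius_px)
  } else {
    pmax(0, 1 - d / lesion$radius_px)
  }
  p_remove <- pmax(lesion$global_ablation_fraction,
                   lesion$core_ablation_fraction * fall)
  keep <- with_seed(rng_seed, runif(nrow(seg)) >= p_remove)
  new_ground_truth_network(seg[keep, , drop = FALSE], network$config)
}

#' Rasterize a ground-truth network into a grayscale image
#'
#' Segments are drawn as capsules of their widths (a pixel is foreground when
#' its center lies within `width/2` of the segment) at `foreground` intensity
#' over `background`, with optional additive Gaussian noise.
#'
#' @param network a `ground_truth_network`.
#' @param config optional [network_config()] overriding canvas size and pixel
#'   size (defaults to the network's own).
#' @param noise_sd additive Gaussian noise s.d. (intensity units).
#' @param foreground,background intensities in `[0, 1]`.
#' @param rng_seed seed for the noise draws.
#' @return A [vessel_image()].
#' @export
rasterize_network <- function(network, config = NULL, noise_sd = 0,
                              foreground = 0.85, background = 0.08,
                              rng_seed = 1L) {
  if (!inherits(network, "ground_truth_network"))
    stop_config("network must be a ground_truth_network")
  H <- (config %||% network)$image_height_px
  W <- (config %||% network)$image_width_px
  ps <- (config %||% network)$pixel_size_um
  fg <- matrix(FALSE, H, W)
  seg <- network$segments
  for (i in seq_len(nrow(seg))) {
    r0 <- seg$r0[i]; c0 <- seg$c0[i]; r1 <- seg$r1[i]; c1 <- seg$c1[i]
    half <- seg$width_px[i] / 2
    rr <- max(1L, floor(min(r0, r1) - half)):min(H, ceiling(max(r0, r1) + half))
    cc <- max(1L, floor(min(c0, c1) - half)):min(W, ceiling(max(c0, c1) + half))
    dy <- r1 - r0; dx <- c1 - c0
    l2 <- dy * dy + dx * dx
    rg <- matrix(rr, length(rr), length(cc))
    cg <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    tt <- if (l2 > 0) pmin(1, pmax(0, ((rg - r0) * dy + (cg - c0) * dx) / l2)) else 0
    d2 <- (rg - (r0 + tt * dy))^2 + (cg - (c0 + tt * dx))^2
    hit <- d2 <= half^2
    fg[rr, cc] <- fg[rr, cc] | hit
  }
  img <- matrix(background, H, W)
  img[fg] <- foreground
  if (noise_sd > 0)
    img <- img + with_seed(rng_seed, matrix(rnorm(H * W, 0, noise_sd), H, W))
  vessel_image(pmin(pmax(img, 0), 1), ps)
}
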