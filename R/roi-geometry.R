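#' Concentric ring ROIs around an injury epicenter
#'
#' Ring 1 is the disk of radius `radii_mm[1]`; ring k > 1 is the annulus
#' `(r[k-1], r[k]]`. Rings are pairwise disjoint and their union is the disk
#' of the largest radius, all clipped to the cortex mask. The reported
#' clipping fraction per ring is the fraction of the ideal (analytic) ring
#' area lost to image bounds plus cortex clipping.
#'
#' @param epicenter_rc_px epicenter `c(row, col)` in pixels.
#' @param radii_mm strictly increasing ring radii in millimeters.
#' @param pixel_size_um physical pixel size; radii convert to pixels as
#'   `radius_mm * 1000 / pixel_size_um`, rounded half-up.
#' @param cortex_mask logical matrix of the analyzable cortex.
#' @return A `roi_set`: `ring_masks` (list of logical matrices),
#'   `ring_radii_mm`, `ring_radii_px`, `clipping_fractions`, `epicenter_rc_px`
#'   and `cortex_mask`.
#' @export
concentric_rings <- function(epicenter_rc_px, radii_mm, pixel_size_um,
                             cortex_mask) {
  if (!is.matrix(cortex_mask) || !is.logical(cortex_mask))
    stop_config("cortex_mask must be a logical matrix")
  if (any(diff(radii_mm) <= 0) || any(radii_mm <= 0))
    stop_config("radii_mm must be positive and strictly increasing")
  er <- epicenter_rc_px[1]; ec <- epicenter_rc_px[2]
  nr <- nrow(cortex_mask); nc <- ncol(cortex_mask)
  if (er < 1 || er > nr || ec < 1 || ec > nc ||
      !cortex_mask[round(er), round(ec)])
    stop_config("epicenter must lie inside the cortex mask")
  radii_px <- round_half_up(radii_mm * 1000 / pixel_size_um)
  d2 <- outer((seq_len(nr) - er)^2, (seq_len(nc) - ec)^2, `+`)
  rings <- vector("list", length(radii_px))
  clip <- numeric(length(radii_px))
  prev2 <- -Inf
  for (k in seq_along(radii_px)) {
    rk2 <- radii_px[k]^2
    ring <- d2 > prev2 & d2 <= rk2 & cortex_mask
    rings[[k]] <- ring
    ideal <- pi * (rk2 - max(prev2, 0))
    clip[k] <- max(0, 1 - sum(ring) / ideal)
    prev2 <- rk2
  }
  names(rings) <- paste0("ring", seq_along(rings))
  structure(list(ring_masks = rings, ring_radii_mm = radii_mm,
                 ring_radii_px = radii_px, clipping_fractions = clip,
                 epicenter_rc_px = c(er, ec), cortex_mask = cortex_mask,
                 pixel_size_um = pixel_size_um),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> epicenter (%.0f, %.0f), %d rings at %s mm (clip %s)\n",
              x$epicenter_rc_px[1], x$epicenter_rc_px[2],
              length(x$ring_masks),
              paste(x$ring_radii_mm, collapse = "/"),
              paste(sprintf("%.2f", x$clipping_fractions), collapse = "/")))
  invisible(x)
}

#' Split a cortex mask into hemispheres at a midline column
#'
#' The midline column itself is assigned to neither hemisphere, so the two
#' masks are disjoint and their union plus the midline column covers the
#' cortex mask.
#'
#' @param cortex_mask logical matrix.
#' @param midline_col_px midline column index.
#' @param ipsilateral which side (`"right"` = columns greater than the
#'   midline) carries the injury.
#' @return List with `ipsilateral` and `contralateral` logical masks.
#' @export
hemisphere_masks <- function(cortex_mask, midline_col_px,
                             ipsilateral = c("right", "left")) {
  ipsilateral <- match.arg(ipsilateral)
  if (midline_col_px < 1 || midline_col_px > ncol(cortex_mask))
    stop_config("midline_col_px must lie within the image")
  cols <- matrix(seq_len(ncol(cortex_mask)), nrow(cortex_mask),
                 ncol(cortex_mask), byrow = TRUE)
  left <- cortex_mask & cols < midline_col_px
  right <- cortex_mask & cols > midline_col_px
  if (ipsilateral == "right") list(ipsilateral = right, contralateral = left)
  else list(ipsilateral = left, contralateral = right)
}

#' Serialize a ROI set as a labeled TIFF plus JSON metadata
#'
#' Ring k is written with gray level k (8-bit); the metadata JSON records the
#' epicenter, radii and per-ring clipping fractions.
#'
#' @param roi_set a [concentric_rings()] result.
#' @param tiff_path,json_path output paths.
#' @return Invisible list of written paths.
#' @export
write_roi_set <- function(roi_set, tiff_path, json_path) {
  lab <- matrix(0, nrow(roi_set$cortex_mask), ncol(roi_set$cortex_mask))
  for (k in seq_along(roi_set$ring_masks)) lab[roi_set$ring_masks[[k]]] <- k
  tiff::writeTIFF(lab / 255, tiff_path, bits.per.sample = 8L)
  jsonlite::write_json(list(epicenter_rc_px = roi_set$epicenter_rc_px,
                            ring_radii_mm = roi_set$ring_radii_mm,
                            ring_radii_px = roi_set$ring_radii_px,
                            clipping_fractions = roi_set$clipping_fractions,
                            pixel_size_um = roi_set$pixel_size_um),
                       json_path, digits = NA)
  invisible(list(tiff = tiff_path, json = json_path))
}

#' Mirror a mask across a vertical midline
#'
#' Column `c` maps to `2 * midline_col_px - c`; pixels reflected out of the
#' image are dropped. Applying the mirror twice returns the original mask for
#' any region whose reflection stays in-bounds.
#'
#' @param roi_mask logical matrix.
#' @param midline_col_px midline column index.
#' @return The mirrored logical matrix.
#' @export
mirror_mask <- function(roi_mask, midline_col_px) {
  nc <- ncol(roi_mask)
  out <- matrix(FALSE, nrow(roi_mask), nc)
  src <- which(roi_mask, arr.ind = TRUE)
  if (nrow(src)) {
    dst_c <- 2 * midline_col_px - src[, 2L]
    ok <- dst_c >= 1 & dst_c <= nc
    out[cbind(src[ok, 1L], dst_c[ok])] <- TRUE
  }
  out
}
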