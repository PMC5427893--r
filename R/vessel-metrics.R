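#' Binarize a grayscale vessel image
#'
#' Foreground = vessels (bright). The default method is Otsu's threshold on
#' the full image (via \pkg{EBImage}); a fixed threshold is available for
#' strict reproducibility across images.
#'
#' @param image a [vessel_image()] or numeric matrix with intensities in
#'   `[0, 1]` (a plain matrix needs `pixel_size_um`).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold in intensity units (required for
#'   `method = "fixed"`); pixels strictly above it are foreground.
#' @param pixel_size_um pixel size when `image` is a plain matrix.
#' @return A `vessel_mask`: logical matrix with the pixel size attached.
#' @export
binarize <- function(image, method = c("otsu", "fixed"),
                     fixed_threshold = NULL, pixel_size_um = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image) || length(dim(image)) != 2L || length(image) == 0L)
    stop_config("image must be a non-empty 2D matrix")
  ps <- attr(image, "pixel_size_um") %||% pixel_size_um
  if (is.null(ps)) stop_config("image carries no pixel size; pass pixel_size_um")
  m <- unclass(image)
  if (method == "otsu") {
    rng <- range(m)
    if (diff(rng) == 0)
      stop_config("constant image: Otsu threshold is undefined")
    th <- EBImage::otsu(m, range = rng, levels = 256L)
  } else {
    if (is.null(fixed_threshold))
      stop_config("method = \"fixed\" requires fixed_threshold")
    th <- fixed_threshold
  }
  vessel_mask(m > th, ps)
}

#' Construct a binary vessel mask
#' @param mask logical matrix (TRUE = vessel foreground).
#' @param pixel_size_um physical pixel size in micrometers.
#' @return A `vessel_mask` object.
#' @export
vessel_mask <- function(mask, pixel_size_um) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_config("mask must be a logical matrix")
  check_number(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  structure(mask, pixel_size_um = pixel_size_um,
            class = c("vessel_mask", "matrix", "array"))
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, %.3g um/px, %.1f%% foreground\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), 100 * mean(x)))
  invisible(x)
}

# the 8 dihedral transforms of a matrix, with their inverses
d4_transforms <- function() {
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])   # 90 deg clockwise
  rot270 <- function(m) t(m)[nrow(t(m)):1, , drop = FALSE]
  list(
    list(fwd = identity, inv = identity),
    list(fwd = rot90, inv = rot270),
    list(fwd = function(m) m[nrow(m):1, ncol(m):1, drop = FALSE],
         inv = function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]),
    list(fwd = rot270, inv = rot90),
    list(fwd = function(m) m[nrow(m):1, , drop = FALSE],
         inv = function(m) m[nrow(m):1, , drop = FALSE]),
    list(fwd = function(m) m[, ncol(m):1, drop = FALSE],
         inv = function(m) m[, ncol(m):1, drop = FALSE]),
    list(fwd = t, inv = t),
    list(fwd = function(m) t(m)[nrow(t(m)):1, ncol(t(m)):1, drop = FALSE],
         inv = function(m) t(m)[nrow(t(m)):1, ncol(t(m)):1, drop = FALSE])
  )
}

# index of the lexicographically minimal transform of a logical matrix;
# ties resolved by transform enumeration order
canonical_d4_index <- function(m, transforms) {
  best <- NULL
  best_i <- 1L
  for (i in seq_along(transforms)) {
    cand <- transforms[[i]]$fwd(m)
    v <- c(dim(cand), as.integer(cand))
    if (is.null(best)) {
      best <- v; best_i <- i
    } else {
      k <- which(v != best)
      if (length(k) && v[k[1L]] < best[k[1L]]) {
        best <- v; best_i <- i
      }
    }
  }
  best_i
}

#' Skeletonize a binary vessel mask
#'
#' Topology-preserving thinning to a one-pixel-wide, 8-connected skeleton.
#' Thinning runs in a canonical orientation (the lexicographically minimal of
#' the eight axis-aligned rotations/reflections of the mask) and the result
#' is mapped back, so skeleton metrics are exactly invariant under 90-degree
#' rotations and flips of the input.
#'
#' @param mask a `vessel_mask` (or logical matrix).
#' @return Logical skeleton matrix (a `vessel_mask` when the input carried a
#'   pixel size).
#' @export
skeletonize_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_config("mask must be a logical matrix")
  ps <- attr(mask, "pixel_size_um")
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(m))
  if (!any(m)) {
    return(if (is.null(ps)) m else vessel_mask(m, ps))
  }
  tr <- d4_transforms()
  i <- canonical_d4_index(m, tr)
  thin <- tr[[i]]$inv(.thin_raster_cpp(tr[[i]]$fwd(m)))
  if (is.null(ps)) thin else vessel_mask(thin, ps)
}

#' Extract the junction/endpoint graph of a skeleton
#'
#' Junctions are maximal 8-connected clusters of skeleton pixels having three
#' or more skeleton neighbors, counted once per cluster; endpoints have
#' exactly one neighbor. Edge length follows the inter-pixel step convention:
#' each orthogonal step counts 1 pixel and each diagonal step `sqrt(2)`
#' pixels, times the pixel size (an N-pixel straight path has length N - 1).
#'
#' @param skeleton logical matrix from [skeletonize_mask()].
#' @param pixel_size_um pixel size; taken from the skeleton when attached.
#' @return A `skeleton_graph`: `nodes` (data frame: row, col, degree, kind),
#'   `edges` (node ids, step counts, length), `steps` (matrix of the pixel
#'   pairs that carry length, with weights in pixel units), `junction_count`
#'   and `total_length_um`.
#' @export
extract_network_graph <- function(skeleton, pixel_size_um = NULL) {
  ps <- attr(skeleton, "pixel_size_um") %||% pixel_size_um
  if (is.null(ps)) stop_config("pixel_size_um is required")
  S <- unclass(skeleton)
  attributes(S) <- list(dim = dim(S))
  nr <- nrow(S); nc <- ncol(S)

  empty <- function() {
    structure(list(
      nodes = data.frame(node_id = integer(0), row = integer(0),
                         col = integer(0), degree = integer(0),
                         kind = character(0)),
      edges = data.frame(node_a = integer(0), node_b = integer(0),
                         n_orth = integer(0), n_diag = integer(0),
                         length_um = numeric(0)),
      steps = matrix(numeric(0), 0L, 3L,
                     dimnames = list(NULL, c("a", "b", "w"))),
      junction_count = 0L, total_length_um = 0,
      pixel_size_um = ps, skeleton = S, dim = c(nr, nc)),
      class = "skeleton_graph")
  }
  pix <- which(S)
  if (length(pix) == 0L) return(empty())

  # adjacency among skeleton pixels via matrix shifts
  pr <- ((pix - 1L) %% nr) + 1L
  pcix <- ((pix - 1L) %/% nr) + 1L
  id_of <- integer(nr * nc)
  id_of[pix] <- seq_along(pix)
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  pairs_a <- integer(0); pairs_b <- integer(0); pairs_w <- numeric(0)
  for (k in seq_len(8L)) {
    qr <- pr + offs[k, 1L]; qc <- pcix + offs[k, 2L]
    ok <- qr >= 1L & qr <= nr & qc >= 1L & qc <= nc
    qi <- (qc[ok] - 1L) * nr + qr[ok]
    hit <- id_of[qi] > 0L
    pa <- which(ok)[hit]
    pairs_a <- c(pairs_a, pa)
    pairs_b <- c(pairs_b, id_of[qi[hit]])
    pairs_w <- c(pairs_w, rep(if (all(offs[k, ] != 0L)) sqrt(2) else 1,
                              sum(hit)))
  }
  deg <- tabulate(pairs_a, nbins = length(pix))
  ord <- order(pairs_a, pairs_b)
  adj <- split(pairs_b[ord], factor(pairs_a[ord], levels = seq_along(pix)))
  wadj <- split(pairs_w[ord], factor(pairs_a[ord], levels = seq_along(pix)))

  # node assignment: junction clusters then endpoints
  jmask <- matrix(FALSE, nr, nc)
  jmask[pix[deg >= 3L]] <- TRUE
  jlab <- .label2d_cpp(jmask, 8L)
  n_junction <- max(jlab)
  node_of <- integer(length(pix))         # 0 = path pixel
  node_of[deg >= 3L] <- jlab[pix[deg >= 3L]]
  ep <- which(deg == 1L)
  node_of[ep] <- n_junction + seq_along(ep)
  n_nodes <- n_junction + length(ep)

  step_w <- function(i, j) if (abs(pr[i] - pr[j]) == 1L && abs(pcix[i] - pcix[j]) == 1L)
    sqrt(2) else 1

  edges <- list(); steps <- list(); se <- 0L
  visited <- logical(length(pix))
  direct_seen <- character(0)
  node_pix <- which(node_of > 0L)
  for (p in node_pix) {
    for (q in adj[[p]]) {
      if (node_of[q] > 0L) {
        if (node_of[q] == node_of[p]) next      # intra-cluster adjacency
        key <- paste(min(p, q), max(p, q))
        if (key %in% direct_seen) next
        direct_seen <- c(direct_seen, key)
        w <- step_w(p, q)
        se <- se + 1L
        edges[[se]] <- c(node_of[p], node_of[q],
                         as.integer(w == 1), as.integer(w != 1), w)
        steps[[se]] <- matrix(c(pix[p], pix[q], w), 1L, 3L)
      } else if (!visited[q]) {
        w <- step_w(p, q)
        n_orth <- as.integer(w == 1); n_diag <- as.integer(w != 1)
        st <- list(c(pix[p], pix[q], w))
        visited[q] <- TRUE
        prev <- p; cur <- q
        end_node <- NA_integer_
        repeat {
          nb <- adj[[cur]]
          nxt <- nb[nb != prev]
          if (length(nxt) == 0L) break            # dangling pixel chain
          nxt <- nxt[1L]
          w <- step_w(cur, nxt)
          n_orth <- n_orth + as.integer(w == 1)
          n_diag <- n_diag + as.integer(w != 1)
          st[[length(st) + 1L]] <- c(pix[cur], pix[nxt], w)
          if (node_of[nxt] > 0L) { end_node <- node_of[nxt]; break }
          if (visited[nxt]) break                 # safety (should not occur)
          visited[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        se <- se + 1L
        edges[[se]] <- c(node_of[p], end_node, n_orth, n_diag,
                         n_orth + sqrt(2) * n_diag)
        steps[[se]] <- do.call(rbind, st)
      }
    }
  }
  # pure cycles: chains of degree-2 pixels with no incident node
  leftover <- which(!visited & node_of == 0L & deg == 2L)
  for (p0 in leftover) {
    if (visited[p0]) next
    visited[p0] <- TRUE
    nb <- adj[[p0]]
    prev <- p0; cur <- nb[1L]
    w <- step_w(p0, cur)
    n_orth <- as.integer(w == 1); n_diag <- as.integer(w != 1)
    st <- list(c(pix[p0], pix[cur], w))
    while (cur != p0) {
      visited[cur] <- TRUE
      nb <- adj[[cur]]
      nxt <- nb[nb != prev][1L]
      if (is.na(nxt)) break
      w <- step_w(cur, nxt)
      n_orth <- n_orth + as.integer(w == 1)
      n_diag <- n_diag + as.integer(w != 1)
      st[[length(st) + 1L]] <- c(pix[cur], pix[nxt], w)
      prev <- cur; cur <- nxt
    }
    se <- se + 1L
    edges[[se]] <- c(NA_integer_, NA_integer_, n_orth, n_diag,
                     n_orth + sqrt(2) * n_diag)
    steps[[se]] <- do.call(rbind, st)
  }

  edge_df <- if (se > 0L) {
    m <- do.call(rbind, edges)
    data.frame(node_a = m[, 1L], node_b = m[, 2L],
               n_orth = as.integer(m[, 3L]), n_diag = as.integer(m[, 4L]),
               length_um = m[, 5L] * ps)
  } else {
    data.frame(node_a = integer(0), node_b = integer(0), n_orth = integer(0),
               n_diag = integer(0), length_um = numeric(0))
  }
  step_mat <- if (se > 0L) do.call(rbind, steps) else
    matrix(numeric(0), 0L, 3L)
  colnames(step_mat) <- c("a", "b", "w")

  # node table: junction clusters use the cluster pixel closest to the centroid
  nodes <- data.frame(node_id = seq_len(n_nodes),
                      row = rep(NA_integer_, n_nodes),
                      col = rep(NA_integer_, n_nodes),
                      degree = rep(NA_integer_, n_nodes),
                      kind = rep(NA_character_, n_nodes))
  if (n_junction > 0L) {
    for (j in seq_len(n_junction)) {
      members <- which(node_of == j & deg >= 3L)
      mr <- pr[members]; mc <- pcix[members]
      ctr <- c(mean(mr), mean(mc))
      rep_i <- members[which.min((mr - ctr[1])^2 + (mc - ctr[2])^2)]
      nodes$row[j] <- pr[rep_i]; nodes$col[j] <- pcix[rep_i]
      nodes$degree[j] <- max(deg[members])
      nodes$kind[j] <- "junction"
    }
  }
  if (length(ep) > 0L) {
    nodes$row[n_junction + seq_along(ep)] <- pr[ep]
    nodes$col[n_junction + seq_along(ep)] <- pcix[ep]
    nodes$degree[n_junction + seq_along(ep)] <- 1L
    nodes$kind[n_junction + seq_along(ep)] <- "endpoint"
  }

  structure(list(nodes = nodes, edges = edge_df, steps = step_mat,
                 junction_count = n_junction,
                 total_length_um = sum(step_mat[, "w"]) * ps,
                 pixel_size_um = ps, skeleton = S, dim = c(nr, nc)),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d junctions, %d endpoints, total length %.2f um\n",
              x$junction_count, sum(x$nodes$kind == "endpoint"),
              x$total_length_um))
  invisible(x)
}

#' Classical vessel metrics inside a region of interest
#'
#' @param mask a `vessel_mask`.
#' @param graph the matching [extract_network_graph()] result.
#' @param roi_mask logical matrix of the analysis region (default: whole
#'   image). Junctions are counted when the junction's representative pixel
#'   falls inside the ROI; length sums the skeleton steps whose two pixels
#'   both fall inside.
#' @return A `vessel_metrics` list: `junction_count`, `total_length_um`,
#'   `vessel_area_um2`, `roi_area_um2`, `vessel_density`.
#' @export
compute_metrics <- function(mask, graph, roi_mask = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_config("mask must be a logical matrix")
  ps <- attr(mask, "pixel_size_um")
  if (is.null(ps)) stop_config("mask carries no pixel_size_um")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(mask), ncol(mask))
  if (!identical(dim(roi_mask), dim(mask)))
    stop_config("roi_mask must match the mask dimensions")
  if (!any(roi_mask)) stop_config("empty ROI")
  if (!inherits(graph, "skeleton_graph"))
    stop_config("graph must be a skeleton_graph")

  jn <- graph$nodes[graph$nodes$kind == "junction", , drop = FALSE]
  j_in <- if (nrow(jn)) sum(roi_mask[cbind(jn$row, jn$col)]) else 0L
  st <- graph$steps
  len <- if (nrow(st)) {
    inside <- roi_mask[st[, "a"]] & roi_mask[st[, "b"]]
    sum(st[inside, "w"]) * ps
  } else 0
  vessel_area <- sum(mask & roi_mask) * ps^2
  roi_area <- sum(roi_mask) * ps^2
  structure(list(junction_count = as.integer(j_in),
                 total_length_um = len,
                 vessel_area_um2 = vessel_area,
                 roi_area_um2 = roi_area,
                 vessel_density = vessel_area / roi_area),
            class = "vessel_metrics")
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat(sprintf(paste0("<vessel_metrics> junctions %d | length %.1f um | ",
                     "density %.4f (vessel %.0f um2 / roi %.0f um2)\n"),
              x$junction_count, x$total_length_um, x$vessel_density,
              x$vessel_area_um2, x$roi_area_um2))
  invisible(x)
}

#' @export
as.data.frame.vessel_metrics <- function(x, ...) {
  data.frame(junction_count = x$junction_count,
             total_length_um = x$total_length_um,
             vessel_area_um2 = x$vessel_area_um2,
             roi_area_um2 = x$roi_area_um2,
             vessel_density = x$vessel_density)
}

#' Write per-ROI vessel metrics as CSV
#'
#' @param metrics_list named list of `vessel_metrics` (names become `roi_id`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics_list, path) {
  rows <- do.call(rbind, lapply(metrics_list, as.data.frame))
  rows <- cbind(roi_id = names(metrics_list), rows)
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a skeleton + junction overlay PNG
#'
#' Vessels (mask) in dark red, skeleton in red, junction representatives as
#' blue dots, on black.
#'
#' @param mask a `vessel_mask`.
#' @param graph a `skeleton_graph`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(mask, graph, path) {
  nr <- nrow(mask); nc <- ncol(mask)
  img <- array(0, c(nr, nc, 3L))
  img[, , 1L][unclass(mask)] <- 0.45
  img[, , 1L][graph$skeleton] <- 1
  jn <- graph$nodes[graph$nodes$kind == "junction", , drop = FALSE]
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[cbind(jn$row, jn$col)] <- if (ch == 3L) 1 else 0
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  invisible(path)
}
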