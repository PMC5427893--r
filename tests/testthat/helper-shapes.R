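# Shared fixtures, built in code.

# plus sign: two crossing 11-px orthogonal lines
make_plus <- function(n = 21L) {
  m <- matrix(FALSE, n, n)
  mid <- (n + 1L) %/% 2L
  m[mid, (mid - 5L):(mid + 5L)] <- TRUE
  m[(mid - 5L):(mid + 5L), mid] <- TRUE
  m
}

make_hline <- function(len = 10L, pad = 3L) {
  m <- matrix(FALSE, 2L * pad + 1L, len + 2L * pad)
  m[pad + 1L, (pad + 1L):(pad + len)] <- TRUE
  m
}

make_diag <- function(len = 10L, pad = 3L) {
  n <- len + 2L * pad
  m <- matrix(FALSE, n, n)
  for (i in seq_len(len)) m[pad + i, pad + i] <- TRUE
  m
}

# Sierpinski right triangle of side 2^level via the bitwise-AND construction
sierpinski_mask <- function(level = 7L) {
  n <- 2L^level
  outer(0:(n - 1L), 0:(n - 1L), function(r, c) bitwAnd(r, c) == 0L)
}

# independent global box-counting dimension oracle: partition the raster into
# s x s blocks at dyadic s, count occupied blocks, regress log N on log(1/s)
box_count_dimension <- function(mask, sizes = 2^(1:6)) {
  n <- numeric(length(sizes))
  for (k in seq_along(sizes)) {
    s <- sizes[k]
    occ <- 0L
    for (i in seq(1L, nrow(mask), by = s)) {
      for (j in seq(1L, ncol(mask), by = s)) {
        blk <- mask[i:min(nrow(mask), i + s - 1L),
                    j:min(ncol(mask), j + s - 1L)]
        if (any(blk)) occ <- occ + 1L
      }
    }
    n[k] <- occ
  }
  unname(coef(lm(log(n) ~ log(1 / sizes)))[2L])
}

# brute-force junction-count oracle: pixels with >= 3 skeleton neighbours,
# clustered by 8-connected flood fill (plain R, independent of the package)
oracle_junction_count <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  nb_count <- function(r, c) {
    s <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && skel[rr, cc])
        s <- s + 1L
    }
    s
  }
  jmask <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (skel[r, c] && nb_count(r, c) >= 3L) jmask[r, c] <- TRUE
  seen <- matrix(FALSE, nr, nc)
  clusters <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!jmask[r, c] || seen[r, c]) next
    clusters <- clusters + 1L
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1L] + dr; cc <- p[2L] + dc
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            jmask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  clusters
}

# the eight axis-aligned rotations/reflections of a matrix
d4_variants <- function(m) {
  rot <- function(x) t(x[nrow(x):1, , drop = FALSE])
  list(m, rot(m), rot(rot(m)), rot(rot(rot(m))),
       m[nrow(m):1, , drop = FALSE], m[, ncol(m):1, drop = FALSE],
       t(m), rot(rot(t(m))))
}

# small, fast network configuration for property tests
small_network_config <- function(rng_seed, size = 256L, trunks = 16L,
                                 max_steps = 60L, ...) {
  network_config(image_height_px = size, image_width_px = size,
                 n_seed_trunks = trunks, max_steps = max_steps,
                 rng_seed = rng_seed, ...)
}

# scaled-down two-group cohort phantom for HRS tests
two_gaussian_volume <- function(seed = 9L, dm = c(48L, 48L, 12L),
                                lesion_mean = 180, brain_mean = 60, sd = 5) {
  set.seed(seed)
  vol <- array(rnorm(prod(dm), brain_mean, sd), dm)
  lesion <- array(FALSE, dm)
  lesion[20:35, 20:35, 4:9] <- TRUE
  vol[lesion] <- rnorm(sum(lesion), lesion_mean, sd)
  list(volume = vol, lesion = lesion, brain = array(TRUE, dm))
}
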