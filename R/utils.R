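#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("vesselfract_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a single finite number")
  if (x < min || x > max)
    stop_config(name, " must be in [", min, ", ", max, "]")
  if (integer && x != round(x))
    stop_config(name, " must be an integer")
  invisible(x)
}

#' Round half away from zero (mm to pixel conversions)
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return `2|a & b| / (|a| + |b|)`; 1 when both masks are empty.
#' @examples
#' dice_coefficient(matrix(c(TRUE, TRUE, FALSE, FALSE), 2),
#'                  matrix(c(TRUE, FALSE, FALSE, FALSE), 2))
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have identical dimensions")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Derive per-subject seeds from a master seed
#' @noRd
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(2147483646L, n))
}
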