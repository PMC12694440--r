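#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can dispatch on failure mode.
abort_teaprof <- function(message, class, ...) {
  stop(structure(
    class = c(class, "teaprof_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_parameter <- function(message, ...) {
  abort_teaprof(message, "teaprof_parameter_error", ...)
}

#' Round half away from zero
#'
#' Rounding convention used wherever values are formatted at a fixed printed
#' precision (percentages, table reports). Unlike [base::round()], which rounds
#' half to even, 0.5 always moves away from zero: `round_half_up(74.5) == 75`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (may be negative).
#' @return numeric vector rounded at `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(74.5, -0.125), c(0, 2))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code under a temporary RNG state; the caller's .Random.seed is untouched.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# --- raster validation helpers -------------------------------------------

check_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    abort_parameter(sprintf("`%s` must be a height x width x 3 array", arg))
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    abort_parameter(sprintf("`%s` must contain at least one pixel", arg))
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    abort_parameter(sprintf("`%s` must hold 8-bit intensities in [0, 255]", arg))
  invisible(image)
}

check_gray_image <- function(gray, arg = "gray") {
  if (!is.matrix(gray) || length(gray) == 0L)
    abort_parameter(sprintf("`%s` must be a non-empty matrix", arg))
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 255)
    abort_parameter(sprintf("`%s` must hold 8-bit intensities in [0, 255]", arg))
  invisible(gray)
}

check_mask <- function(mask, arg = "mask") {
  m <- if (inherits(mask, "shoot_mask")) mask$mask else mask
  if (!is.matrix(m))
    abort_parameter(sprintf("`%s` must be a logical matrix", arg))
  if (is.numeric(m)) {
    if (anyNA(m) || !all(m %in% c(0, 1)))
      abort_parameter(sprintf("`%s` must be strictly binary", arg))
    m <- m > 0
  }
  if (!is.logical(m) || anyNA(m))
    abort_parameter(sprintf("`%s` must be strictly binary", arg))
  m
}

check_scalar <- function(x, field, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    abort_parameter(sprintf("`%s` must be a single finite number", field))
  if (x < lo || x > hi)
    abort_parameter(sprintf("`%s` must lie in [%s, %s], got %s", field, lo, hi, x))
  if (integer && x != round(x))
    abort_parameter(sprintf("`%s` must be an integer, got %s", field, x))
  invisible(x)
}

# Luminance with the standard Rec.601 weights; returns an H x W matrix on the
# same 0-255 scale as the input channels.
luminance <- function(image) {
  matrix(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3],
         dim(image)[1], dim(image)[2])
}

# Positive numeric vector check for measured depth values (l_near / l_far).
check_depth_value <- function(x, field) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(!is.finite(x)))
    abort_parameter(sprintf("`%s` must be finite", field))
  if (any(x <= 0))
    abort_parameter(sprintf("`%s` must be positive (cm)", field))
  invisible(x)
}
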