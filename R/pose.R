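#' Rig geometry configuration
#'
#' All fixed geometry of the cutter/camera assembly, in centimetres:
#' `a_near` and `a_far` are the vertical distances from the camera to the
#' cutter's centre and left end; `L` is the expected bud-layer (plucking)
#' length; `r` the distance from the bracket's rotation point to the
#' cutter's left end; `b` the bracket length; `m` the distance from the
#' rotation point to the cutter's middle; `c_zero` the actuator-to-cutter
#' distance at the zero point. `b`, `r`, `c_zero` form the actuator
#' triangle, so `|b - r| < c_zero < b + r` must hold.
#'
#' The default `r = 114` is a documented package default (the deployed
#' value is rig-specific and should be measured); every field is
#' overridable.
#'
#' @param a_near,a_far,L,r,b,m,c_zero geometry in cm, all positive.
#' @return object of class `rig_config`.
#' @export
rig_config <- function(a_near = 55, a_far = 61, L = 10,
                       r = 114, b = 40, m = 57, c_zero = 80) {
  for (f in c("a_near", "a_far", "L", "r", "b", "m", "c_zero"))
    check_scalar(get(f), f, lo = 1e-9)
  if (!(abs(b - r) < c_zero && c_zero < b + r))
    abort_parameter(sprintf(
      "linkage triangle violated: need |b - r| < c_zero < b + r (|%g - %g| = %g, c_zero = %g)",
      b, r, abs(b - r), c_zero))
  structure(list(a_near = a_near, a_far = a_far, L = L,
                 r = r, b = b, m = m, c_zero = c_zero),
            class = "rig_config")
}

#' Height adjustment d of the cutter
#'
#' `d = a_near - l_near - L`: the signed vertical shift putting the
#' cutter's centre exactly `L` below the shoot surface measured in the
#' central region. Positive `d` means the cutter must rise.
#'
#' @param rig a [rig_config()].
#' @param l_near mean central shoot depth in cm, positive.
#' @return signed height adjustment in cm.
#' @export
compute_d <- function(rig, l_near) {
  check_depth_value(l_near, "l_near")
  rig$a_near - l_near - rig$L
}

#' Rotation adjustment alpha of the cutter
#'
#' `alpha = (L - (a_far - l_far)) * 180 / (r * pi)` degrees: the small-angle
#' rotation bringing the cutter's left end `L` below the shoot surface
#' measured in the left region. Positive alpha rotates the left end down
#' toward the canopy; alpha is strictly increasing in `l_far`.
#'
#' @param rig a [rig_config()].
#' @param l_far mean left-region shoot depth in cm, positive.
#' @return signed rotation in degrees.
#' @export
compute_alpha <- function(rig, l_far) {
  check_depth_value(l_far, "l_far")
  (rig$L - (rig$a_far - l_far)) * 180 / (rig$r * pi)
}

# Opening angle (radians) of the actuator triangle at chord length c.
linkage_theta <- function(rig, c_len) {
  arg <- (rig$b^2 + rig$r^2 - c_len^2) / (2 * rig$b * rig$r)
  if (is.na(arg) || arg < -1 || arg > 1)
    abort_teaprof(
      sprintf("linkage chord %g cm is outside the mechanism's reach", c_len),
      "teaprof_mechanism_limit")
  acos(arg)
}

#' Rotation produced by an actuator displacement (forward linkage)
#'
#' Law-of-cosines forward map of the cutter linkage: the rotation in degrees
#' caused by extending the actuator from `c_current` to `c_current + delta_x`.
#'
#' @param rig a [rig_config()].
#' @param delta_x actuator displacement in cm.
#' @param c_current current actuator chord length in cm (default the rig
#'   zero point).
#' @return rotation alpha in degrees.
#' @export
alpha_from_delta_x <- function(rig, delta_x, c_current = rig$c_zero) {
  th0 <- linkage_theta(rig, c_current)
  th1 <- linkage_theta(rig, c_current + delta_x)
  (th1 - th0) * 180 / pi
}

#' Actuator displacement for a requested rotation (inverse linkage)
#'
#' Closed-form inversion of the linkage: with the current opening angle
#' `theta0 = acos((b^2 + r^2 - c^2) / (2 b r))`, the target angle is
#' `theta1 = theta0 + alpha * pi/180` and
#' `delta_x = sqrt(b^2 + r^2 - 2 b r cos(theta1)) - c`. Requests pushing
#' `theta1` outside (0, pi) exceed the mechanism's travel and raise a
#' mechanism-limit error. The forward map recovers `alpha` exactly.
#'
#' @param rig a [rig_config()].
#' @param alpha requested rotation in degrees.
#' @param c_current current actuator chord length in cm.
#' @return signed actuator displacement in cm.
#' @export
compute_delta_x <- function(rig, alpha, c_current = rig$c_zero) {
  check_scalar(alpha, "alpha")
  th0 <- linkage_theta(rig, c_current)
  th1 <- th0 + alpha * pi / 180
  if (th1 <= 0 || th1 >= pi)
    abort_teaprof(
      sprintf("rotation %g deg exceeds the mechanism travel (theta would be %.3f rad)",
              alpha, th1),
      "teaprof_mechanism_limit")
  sqrt(rig$b^2 + rig$r^2 - 2 * rig$b * rig$r * cos(th1)) - c_current
}

# --- motion decision table -----------------------------------------------

band_tibble <- function(label, lo, hi) {
  tibble::tibble(label = label, lo = lo, hi = hi)
}

#' Default motion decision table
#'
#' The cutter's discrete motion logic over the (l_near, l_far) plane. Each
#' axis is split into closed-open bands (cm): `low` / `ideal` / `high`,
#' where the ideal bands (l_near in \[43, 47), l_far in \[51, 55)) mean the
#' cutter already sits `L` below the canopy with no offset. The 3 x 3 band
#' grid plus per-axis out-of-range gives the machine's ten motion types.
#' Vertical action follows the near band (canopy closer than ideal =>
#' rise); rotation follows the far deviation *after* the height correction,
#' which reproduces the coupled case "cutter low and offset => rise and
#' rotate down". Fully configurable; see [as_decision_table()].
#'
#' @return object of class `decision_table` with fields `near_bands`,
#'   `far_bands` (tibbles label/lo/hi) and `rules` (tibble near/far/
#'   vertical/rotation including the `out` rows).
#' @export
default_decision_table <- function() {
  near <- band_tibble(c("low", "ideal", "high"), c(35, 43, 47), c(43, 47, 55))
  far <- band_tibble(c("low", "ideal", "high"), c(47, 51, 55), c(51, 55, 59))
  vert <- c(low = "rise", ideal = "hold", high = "fall", out = "out_of_range")
  centre <- function(b) (b$lo + b$hi) / 2
  near_err <- stats::setNames(centre(near) - 45, near$label)
  far_err <- stats::setNames(centre(far) - 53, far$label)
  grid <- expand.grid(near = c(near$label, "out"), far = c(far$label, "out"),
                      stringsAsFactors = FALSE)
  rot <- function(nl, fl) {
    if (fl == "out") return("out_of_range")
    rel <- if (nl == "out") far_err[[fl]] else far_err[[fl]] - near_err[[nl]]
    if (rel > 0) "rotate_down" else if (rel < 0) "rotate_up" else "hold"
  }
  rules <- tibble::tibble(
    near = grid$near, far = grid$far,
    vertical = unname(vert[grid$near]),
    rotation = mapply(rot, grid$near, grid$far, USE.NAMES = FALSE)
  )
  validate_decision_table(structure(
    list(near_bands = near, far_bands = far, rules = rules),
    class = "decision_table"))
}

#' Build and validate a decision table from plain lists
#'
#' @param x a list with `near_bands`, `far_bands` (each a data frame with
#'   columns label/lo/hi) and `rules` (data frame near/far/vertical/
#'   rotation), e.g. parsed from a JSON configuration file.
#' @return a validated `decision_table`.
#' @export
as_decision_table <- function(x) {
  validate_decision_table(structure(
    list(near_bands = tibble::as_tibble(x$near_bands),
         far_bands = tibble::as_tibble(x$far_bands),
         rules = tibble::as_tibble(x$rules)),
    class = "decision_table"))
}

#' Validate a decision table
#'
#' Enforces at load time (never at query time): bands on each axis are
#' finite, non-empty (`lo < hi`), mutually non-overlapping and contiguous
#' (the operating range has no gaps), and the rule grid holds exactly one
#' entry for every band-label pair including the `out` rows.
#'
#' @param table a `decision_table`.
#' @return the table, invisibly validated (errors are classed
#'   `teaprof_config_error`).
#' @export
validate_decision_table <- function(table) {
  bad <- function(msg) abort_teaprof(msg, "teaprof_config_error")
  for (axis in c("near_bands", "far_bands")) {
    b <- table[[axis]]
    if (!all(c("label", "lo", "hi") %in% names(b))) bad(
      sprintf("%s must have columns label, lo, hi", axis))
    if (nrow(b) < 1L || anyNA(b$lo) || anyNA(b$hi) ||
        !all(is.finite(b$lo)) || !all(is.finite(b$hi)))
      bad(sprintf("%s bands must be finite", axis))
    if (any(b$hi <= b$lo)) bad(sprintf("%s has an empty band (hi <= lo)", axis))
    o <- order(b$lo)
    if (any(b$lo[o][-1] < b$hi[o][-nrow(b)]))
      bad(sprintf("%s bands overlap", axis))
    if (any(b$lo[o][-1] > b$hi[o][-nrow(b)]))
      bad(sprintf("%s bands leave a gap in the operating range", axis))
    if (anyDuplicated(b$label)) bad(sprintf("%s labels must be unique", axis))
  }
  want <- expand.grid(near = c(table$near_bands$label, "out"),
                      far = c(table$far_bands$label, "out"),
                      stringsAsFactors = FALSE)
  key <- function(df) paste(df$near, df$far)
  if (!setequal(key(want), key(table$rules)) ||
      anyDuplicated(key(table$rules)))
    bad("rules must contain exactly one entry per band pair (including `out`)")
  ok_v <- c("rise", "fall", "hold", "out_of_range")
  ok_r <- c("rotate_up", "rotate_down", "hold", "out_of_range")
  if (!all(table$rules$vertical %in% ok_v) || !all(table$rules$rotation %in% ok_r))
    bad("rules contain an unknown vertical/rotation action")
  table
}

band_label <- function(bands, value) {
  i <- which(value >= bands$lo & value < bands$hi)
  if (length(i) == 1L) bands$label[i] else "out"
}

#' Select the cutter motion for a measured (l_near, l_far) pair
#'
#' Looks the pair up in the decision table's band grid. A value outside all
#' bands on an axis yields `out_of_range` on that axis (a value, not an
#' error); the other axis is still decided.
#'
#' @param table a validated `decision_table`.
#' @param l_near,l_far measured mean shoot depths in cm.
#' @return object of class `motion_decision` with fields `vertical`
#'   (`rise`/`fall`/`hold`/`out_of_range`) and `rotation`
#'   (`rotate_up`/`rotate_down`/`hold`/`out_of_range`).
#' @export
decide_motion <- function(table, l_near, l_far) {
  check_scalar(l_near, "l_near")
  check_scalar(l_far, "l_far")
  nl <- band_label(table$near_bands, l_near)
  fl <- band_label(table$far_bands, l_far)
  row <- table$rules[table$rules$near == nl & table$rules$far == fl, ]
  structure(list(vertical = row$vertical, rotation = row$rotation,
                 near_band = nl, far_band = fl),
            class = "motion_decision")
}

#' @export
print.motion_decision <- function(x, ...) {
  cat(sprintf("<motion_decision> vertical: %s, rotation: %s\n",
              x$vertical, x$rotation))
  invisible(x)
}

#' Full cutting-pose computation for one depth pair
#'
#' Computes the height adjustment `d`, rotation `alpha`, actuator
#' displacement `delta_x` and the discrete motion decision in one call.
#' When the decision is (hold, hold) the pose is still reported but flagged
#' `no_op`. If the requested rotation exceeds the mechanism travel,
#' `delta_x` is `NA` and the mechanism-limit condition message is recorded.
#'
#' @param rig a [rig_config()].
#' @param table a `decision_table` (default [default_decision_table()]).
#' @param l_near,l_far measured mean shoot depths in cm.
#' @param c_current current actuator chord length in cm.
#' @return object of class `cutting_pose`: `d`, `alpha`, `delta_x` (cm/deg/
#'   cm), `decision` (a `motion_decision`), `no_op`, and `mechanism_note`
#'   (NA unless delta_x was unreachable).
#' @export
pose_pipeline <- function(rig, table = default_decision_table(),
                          l_near, l_far, c_current = rig$c_zero) {
  d <- compute_d(rig, l_near)
  alpha <- compute_alpha(rig, l_far)
  note <- NA_character_
  dx <- tryCatch(compute_delta_x(rig, alpha, c_current),
                 teaprof_mechanism_limit = function(e) {
                   note <<- conditionMessage(e)
                   NA_real_
                 })
  decision <- decide_motion(table, l_near, l_far)
  structure(
    list(d = d, alpha = alpha, delta_x = dx, decision = decision,
         no_op = decision$vertical == "hold" && decision$rotation == "hold",
         mechanism_note = note),
    class = "cutting_pose"
  )
}

#' @export
print.cutting_pose <- function(x, ...) {
  cat(sprintf("<cutting_pose> d = %.4f cm, alpha = %.4f deg, delta_x = %s cm%s\n",
              x$d, x$alpha,
              if (is.na(x$delta_x)) "NA (mechanism limit)" else sprintf("%.4f", x$delta_x),
              if (x$no_op) " [no-op]" else ""))
  print(x$decision)
  invisible(x)
}
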