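#' Pixel-level confusion counts between two shoot masks
#'
#' Counts per-pixel agreement of a predicted mask against a reference mask:
#' `tp` foreground in both, `fp` predicted-only, `fn` reference-only.
#'
#' @param predicted,truth [segment_shoots()] results or logical matrices,
#'   pixel-aligned.
#' @return one-row tibble with columns `tp`, `fp`, `fn`.
#' @export
score_mask <- function(predicted, truth) {
  p <- check_mask(predicted, "predicted")
  t <- check_mask(truth, "truth")
  if (!all(dim(p) == dim(t)))
    abort_parameter("predicted and truth masks must have the same shape")
  tibble::tibble(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = tp / (tp + fp)`, `R = tp / (tp + fn)`, `F1 = 2 P R / (P + R)`
#' (the harmonic mean, so F1 always lies between P and R). Values are
#' returned as fractions; use [round_half_up()] at the desired printed
#' precision for reporting.
#'
#' @param counts result of [score_mask()], or any list with `tp`, `fp`, `fn`.
#' @return one-row tibble with columns `precision`, `recall`, `f1`.
#' @export
detection_score <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  for (v in c("tp", "fp", "fn")) check_scalar(counts[[v]], v, lo = 0)
  if (tp + fp == 0)
    abort_teaprof("precision undefined: no predicted positives (tp + fp = 0)",
                  "teaprof_undefined_metric")
  if (tp + fn == 0)
    abort_teaprof("recall undefined: no actual positives (tp + fn = 0)",
                  "teaprof_undefined_metric")
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  if (p + r == 0)
    abort_teaprof("F1 undefined: precision + recall = 0",
                  "teaprof_undefined_metric")
  tibble::tibble(precision = p, recall = r, f1 = 2 * p * r / (p + r))
}

#' Harvest-quality metrics of field trials
#'
#' Mass-fraction quality measures of a harvest trial, each in percent:
#' integrity rate `100 W1 / W` (complete buds among the sampled mass), loss
#' rate `100 W3 / (W2 + W3)` (dropped but cut), leakage rate
#' `100 W4 / (W2 + W3 + W4)` (left uncut), qualified rate `100 W5 / W`
#' (length within the agronomic band), and hourly productivity per unit
#' cutting width `E = A / (T B)` in m^2/(m h). All rates are invariant to
#' the mass unit. Vectorized: pass a tibble with one row per trial.
#'
#' @param trials data frame (or list) with columns `w_total`, `w1_intact`,
#'   `w2_sample`, `w3_dropped`, `w4_uncut`, `w5_qualified` (masses, any
#'   single unit), `area` (m^2), `time` (h), `cut_width` (m).
#' @return tibble with columns `integrity_rate`, `loss_rate`,
#'   `leakage_rate`, `qualified_rate` (percent) and `productivity`
#'   (m^2/(m h)), one row per trial.
#' @export
field_metrics <- function(trials) {
  t <- tibble::as_tibble(trials)
  need <- c("w_total", "w1_intact", "w2_sample", "w3_dropped", "w4_uncut",
            "w5_qualified", "area", "time", "cut_width")
  missing <- setdiff(need, names(t))
  if (length(missing))
    abort_parameter(paste("missing trial columns:", paste(missing, collapse = ", ")))
  if (any(as.matrix(t[need]) < 0, na.rm = TRUE))
    abort_parameter("trial masses, areas and times must be non-negative")
  if (any(t$w1_intact > t$w_total) || any(t$w5_qualified > t$w_total))
    abort_parameter("component masses w1/w5 cannot exceed w_total")
  deno <- function(x, metric) {
    if (any(x <= 0))
      abort_teaprof(sprintf("%s undefined: zero denominator", metric),
                    "teaprof_undefined_metric")
    x
  }
  tibble::tibble(
    integrity_rate = 100 * t$w1_intact / deno(t$w_total, "integrity_rate"),
    loss_rate = 100 * t$w3_dropped / deno(t$w2_sample + t$w3_dropped, "loss_rate"),
    leakage_rate = 100 * t$w4_uncut /
      deno(t$w2_sample + t$w3_dropped + t$w4_uncut, "leakage_rate"),
    qualified_rate = 100 * t$w5_qualified / deno(t$w_total, "qualified_rate"),
    productivity = t$area / deno(t$time * t$cut_width, "productivity")
  )
}

#' Overall hourly productivity across several trials
#'
#' The multi-trial form sums areas and times before dividing:
#' `E = sum(A) / (sum(T) * B)`.
#'
#' @param area areas in m^2, one per trial.
#' @param time operating times in h, one per trial.
#' @param cut_width cutting width in m (single machine constant).
#' @return overall productivity in m^2/(m h).
#' @export
overall_productivity <- function(area, time, cut_width) {
  if (sum(time) * cut_width <= 0)
    abort_teaprof("productivity undefined: zero denominator",
                  "teaprof_undefined_metric")
  sum(area) / (sum(time) * cut_width)
}

#' Mean and population standard deviation across trials
#'
#' Aggregates per-trial metric values the way harvest test reports do:
#' arithmetic mean and the *population* standard deviation (divide by n,
#' not n - 1).
#'
#' @param values numeric vector of per-trial values (n >= 2), or a data
#'   frame of such columns (one summary row per column).
#' @return tibble with columns `metric`, `n`, `mean`, `sd`.
#' @export
summarize_trials <- function(values) {
  if (is.data.frame(values)) {
    out <- lapply(names(values), function(nm) {
      s <- summarize_trials(values[[nm]])
      s$metric <- nm
      s
    })
    return(do.call(rbind, out))
  }
  if (!is.numeric(values) || length(values) < 2L || anyNA(values))
    abort_parameter("`values` must be a numeric vector with n >= 2 and no NA")
  n <- length(values)
  m <- mean(values)
  tibble::tibble(metric = NA_character_, n = n, mean = m,
                 sd = sqrt(sum((values - m)^2) / n))
}
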