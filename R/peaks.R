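#' Cardiac phase windows for peak assignment
#'
#' Fractions of the RR interval from the R wave assigning each velocity
#' peak to its physiological window: systole for the venous S peak, early
#' diastole for the transmitral E and venous D peaks, late diastole for the
#' atrial-contraction A peak. The published analysis gives no timings, so
#' these follow the canonical S -> D/E -> A ordering of the cardiac cycle
#' and are configurable.
#'
#' @param systole,early_diastole,late_diastole Two-element `[lo, hi)`
#'   fractions of RR.
#' @return Named list of windows.
#' @export
phase_windows <- function(systole = c(0, 0.40),
                          early_diastole = c(0.40, 0.75),
                          late_diastole = c(0.75, 1.0)) {
  w <- list(systole = systole, early_diastole = early_diastole,
            late_diastole = late_diastole)
  for (x in w) stopifnot(length(x) == 2, x[1] < x[2], x[1] >= 0, x[2] <= 1)
  w
}

.curve_fractions <- function(curve) {
  rr <- attr(curve, "rr_ms")
  if (is.null(rr)) rr <- max(curve$time_ms) * length(curve$time_ms) /
      (length(curve$time_ms) - 1)
  curve$time_ms / rr
}

.in_window <- function(fr, w) which(fr >= w[1] & fr < w[2])

# first (earliest) index attaining the window maximum
.window_max <- function(curve, fr, w) {
  idx <- .in_window(fr, w)
  if (!length(idx)) stop("empty phase window", call. = FALSE)
  i <- idx[which.max(curve$vmax_cm_s[idx])]
  list(value = curve$vmax_cm_s[i], phase = curve$phase_index[i])
}

# local maxima (one-sided at the endpoints) with topographic prominence:
# walk out from each peak until a strictly higher sample or the boundary,
# tracking the minimum on the way; prominence = height - max(left, right base)
.local_peaks <- function(v) {
  n <- length(v)
  idx <- which(vapply(seq_len(n), function(i) {
    left_ok <- i == 1 || v[i] >= v[i - 1]
    right_ok <- i == n || v[i] >= v[i + 1]
    strict <- (i > 1 && v[i] > v[i - 1]) || (i < n && v[i] > v[i + 1])
    left_ok && right_ok && strict
  }, logical(1)))
  prom <- vapply(idx, function(i) {
    base <- function(rng) {
      if (!length(rng)) return(v[i])
      m <- v[i]
      for (j in rng) {
        if (v[j] > v[i]) break
        m <- min(m, v[j])
      }
      m
    }
    lb <- base(rev(seq_len(i - 1)))
    rb <- base(seq.int(i + 1, length.out = n - i))
    v[i] - max(lb, rb)
  }, numeric(1))
  data.frame(index = idx, height = v[idx], prominence = prom)
}

#' Detect transmitral (outflow) peaks
#'
#' `v_E` is the maximum of the curve in the early diastolic window. `v_A`
#' is reported only when the transmitral profile is biphasic: a local
#' maximum must exist in the late diastolic window with prominence at least
#' `prominence_frac` of the overall curve maximum; otherwise the profile is
#' classified monophasic and `v_A` is `NA`. Ties are broken toward the
#' earliest sample.
#'
#' @param curve An `la_curve` at the mitral junction or mitral valve tips.
#' @param windows Phase windows, see [phase_windows()].
#' @param prominence_frac Biphasic criterion threshold (default 0.10).
#' @return An `la_peaks` list with `v_E`, `v_A`, phase indices, `location`,
#'   `curve_max` and `curve_mean`.
#' @export
detect_outflow_peaks <- function(curve, windows = phase_windows(),
                                 prominence_frac = 0.10) {
  loc <- curve$location[1]
  if (!loc %in% c("mitral_junction", "mitral_tips"))
    stop("outflow peaks are defined for transmitral curves, got '", loc, "'",
         call. = FALSE)
  fr <- .curve_fractions(curve)
  e <- .window_max(curve, fr, windows$early_diastole)

  late_idx <- .in_window(fr, windows$late_diastole)
  if (!length(late_idx)) stop("empty phase window", call. = FALSE)
  lp <- .local_peaks(curve$vmax_cm_s)
  lp <- lp[lp$index %in% late_idx &
             lp$prominence >= prominence_frac * max(curve$vmax_cm_s), ,
           drop = FALSE]
  if (nrow(lp)) {
    i <- lp$index[which.max(lp$height)]
    v_A <- curve$vmax_cm_s[i]; phase_A <- curve$phase_index[i]
  } else {
    v_A <- NA_real_; phase_A <- NA_integer_
  }
  structure(list(v_E = e$value, v_A = v_A,
                 phase_E = e$phase, phase_A = phase_A,
                 location = loc,
                 curve_max = max(curve$vmax_cm_s),
                 curve_mean = mean(curve$vmax_cm_s)),
            class = "la_peaks")
}

#' Detect pulmonary venous (inflow) peaks
#'
#' `v_S` is the curve maximum in the systolic window, `v_D` the maximum in
#' the early diastolic window; earliest sample wins a tie.
#'
#' @param curve An `la_curve` at a vein orifice or inside the vein.
#' @param windows Phase windows, see [phase_windows()].
#' @return An `la_peaks` list with `v_S`, `v_D`, phase indices, `location`,
#'   `curve_max` and `curve_mean`.
#' @export
detect_inflow_peaks <- function(curve, windows = phase_windows()) {
  loc <- curve$location[1]
  if (!loc %in% c("vein_orifice_left", "vein_orifice_right", "vein_interior"))
    stop("inflow peaks are defined for pulmonary venous curves, got '",
         loc, "'", call. = FALSE)
  fr <- .curve_fractions(curve)
  s <- .window_max(curve, fr, windows$systole)
  d <- .window_max(curve, fr, windows$early_diastole)
  structure(list(v_S = s$value, v_D = d$value,
                 phase_S = s$phase, phase_D = d$phase,
                 location = loc,
                 curve_max = max(curve$vmax_cm_s),
                 curve_mean = mean(curve$vmax_cm_s)),
            class = "la_peaks")
}

#' Select the pulmonary vein with the higher velocities
#'
#' The inflow peaks are taken from whichever inferior pulmonary vein
#' exhibits the higher velocities. "Higher" is read as the larger overall
#' curve maximum (`statistic = "max"`, the default) or the larger curve
#' mean; an exact tie goes to the right vein.
#'
#' @param left,right `la_peaks` from the left and right vein curves.
#' @param statistic `"max"` or `"mean"`.
#' @return The selected `la_peaks`.
#' @export
select_vein <- function(left, right, statistic = c("max", "mean")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(left, "la_peaks"), inherits(right, "la_peaks"))
  key <- if (statistic == "max") "curve_max" else "curve_mean"
  if (left[[key]] > right[[key]]) left else right
}
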