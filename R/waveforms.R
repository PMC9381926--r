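#' Waveform sampling configuration
#'
#' Maximal-velocity-time curves over one cardiac (RR) cycle are modelled as
#' sums of localized raised-cosine bumps, one per physiological peak, and
#' sampled at `n_phases` reconstructed cardiac phases (the 4D flow protocol
#' reconstructs 20). Peak times and half-widths are fractions of the RR
#' interval measured from the R wave and must satisfy
#' `0 < t_S < t_D = t_E < t_A < 1` up to the stated ordering; defaults put
#' the systolic inflow peak at 0.20, the early diastolic peaks at 0.55 and
#' the late diastolic (atrial contraction) peak at 0.85, all on the default
#' 20-phase sampling grid so that noise-free peak extraction is exact.
#'
#' @param n_phases Number of sampled cardiac phases (>= 10).
#' @param rr_interval_ms RR interval, ms (default 850, ~ 71 bpm).
#' @param peak_times Named fractions of RR for the S, D, E, A peak centres.
#' @param peak_widths Named half-widths (fractions of RR) of the bumps.
#' @param noise_sd SD of additive measurement noise, cm/s (curves are
#'   clipped at zero).
#' @param seed Optional integer seed for the noise stream.
#' @return A `la_waveform_config` list.
#' @export
waveform_config <- function(n_phases = 20,
                            rr_interval_ms = 850,
                            peak_times = c(S = 0.20, D = 0.55, E = 0.55, A = 0.85),
                            peak_widths = c(S = 0.14, D = 0.12, E = 0.12, A = 0.10),
                            noise_sd = 0,
                            seed = NULL) {
  stopifnot(n_phases >= 10, rr_interval_ms > 0, noise_sd >= 0,
            all(c("S", "D", "E", "A") %in% names(peak_times)),
            all(c("S", "D", "E", "A") %in% names(peak_widths)),
            all(peak_times > 0), all(peak_times < 1), all(peak_widths > 0))
  if (!(peak_times["S"] < peak_times["D"] && peak_times["E"] < peak_times["A"]))
    stop("peak times must be ordered S < D and E < A within the cycle",
         call. = FALSE)
  structure(list(n_phases = as.integer(n_phases),
                 rr_interval_ms = rr_interval_ms,
                 peak_times = peak_times, peak_widths = peak_widths,
                 noise_sd = noise_sd, seed = seed),
            class = "la_waveform_config")
}

#' Raised-cosine bump
#'
#' `height/2 * (1 + cos(pi * (t - center) / width))` for
#' `|t - center| < width`, zero outside; attains exactly `height` at the
#' centre. Used as the elementary peak shape of synthetic velocity curves.
#'
#' @param t Time points (same units as `center`/`width`).
#' @param center,width,height Bump centre, half-width and peak height.
#' @return Bump values at `t`.
#' @export
raised_cosine_bump <- function(t, center, width, height) {
  d <- abs(t - center)
  ifelse(d < width, height / 2 * (1 + cos(pi * d / width)), 0)
}

# continuous (un-sampled) curve for a named set of peaks; checks that the
# planted maxima are attained, i.e. bumps do not overlap enough to bury a peak
.curve_fun <- function(peaks, wconfig) {
  peaks <- peaks[!is.na(peaks)]
  ct <- wconfig$peak_times[names(peaks)]
  cw <- wconfig$peak_widths[names(peaks)]
  f <- function(fr) {
    v <- numeric(length(fr))
    for (k in seq_along(peaks))
      v <- v + raised_cosine_bump(fr, ct[k], cw[k], peaks[k])
    v
  }
  for (k in seq_along(peaks)) {
    if (abs(f(ct[k]) - peaks[k]) > 1e-9 * max(peaks))
      stop("overlapping peaks: planted maximum for '", names(peaks)[k],
           "' is not attained", call. = FALSE)
  }
  f
}

.sample_curve <- function(f, location, wconfig) {
  n <- wconfig$n_phases
  fr <- (seq_len(n) - 1) / n
  v <- f(fr)
  if (wconfig$noise_sd > 0)
    v <- pmax(0, v + stats::rnorm(n, 0, wconfig$noise_sd))
  out <- data.frame(location = location, phase_index = seq_len(n),
                    time_ms = fr * wconfig$rr_interval_ms,
                    vmax_cm_s = v, stringsAsFactors = FALSE)
  attr(out, "rr_ms") <- wconfig$rr_interval_ms
  class(out) <- c("la_curve", "data.frame")
  out
}

#' Generate transmitral and pulmonary venous velocity-time curves
#'
#' Builds smooth non-negative maximal-velocity curves whose planted peak
#' heights equal the record's velocities: the transmitral (outflow) curve
#' carries E and A bumps (no A bump for a monophasic record), the venous
#' (inflow) curve carries S and D bumps.
#'
#' @param record One cohort row (fields `vE`, `vA`, `vS`, `vD`).
#' @param wconfig A [waveform_config()].
#' @return List with elements `transmitral` and `venous`, each an
#'   `la_curve` data frame (`location`, `phase_index`, `time_ms`,
#'   `vmax_cm_s`).
#' @export
generate_waveforms <- function(record, wconfig = waveform_config()) {
  stopifnot(inherits(wconfig, "la_waveform_config"))
  if (!is.null(wconfig$seed)) set.seed(wconfig$seed)
  need <- c("vE", "vS", "vD")
  if (any(!need %in% names(record)) || any(is.na(record[need])))
    stop("record must provide vE, vS and vD", call. = FALSE)
  vA <- if ("vA" %in% names(record)) record$vA else NA_real_
  vein_loc <- if (!is.null(record$vein_used) &&
                  identical(record$vein_used, "left_inferior"))
    "vein_orifice_left" else "vein_orifice_right"
  tm <- .curve_fun(c(E = record$vE, A = vA), wconfig)
  ve <- .curve_fun(c(S = record$vS, D = record$vD), wconfig)
  list(transmitral = .sample_curve(tm, "mitral_junction", wconfig),
       venous = .sample_curve(ve, vein_loc, wconfig))
}

#' Write / read waveform curves as CSV
#'
#' Long format: `patient_id`, `location`, `phase_index`, `time_ms`,
#' `vmax_cm_s`.
#'
#' @param curves Named list of `la_curve` data frames (or a single curve),
#'   or for reading, a file path.
#' @param patient_id Patient identifier recorded with each row.
#' @param path File path.
#' @return `read_waveforms_csv` returns a data frame; the writer returns
#'   `path` invisibly.
#' @export
write_waveforms_csv <- function(curves, patient_id, path) {
  if (inherits(curves, "la_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, as.data.frame))
  rows <- cbind(patient_id = patient_id, rows)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_waveforms_csv
#' @export
read_waveforms_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
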