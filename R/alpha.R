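#' LA acceleration factor
#'
#' The left atrial acceleration factor is the dimensionless ratio of the
#' early diastolic LA peak outflow velocity to the average of the systolic
#' and early diastolic LA peak inflow velocities:
#' `alpha = v_E / ((v_S + v_D) / 2)`. The late diastolic outflow peak `v_A`
#' is not required, so the factor is defined for patients with a monophasic
#' transmitral profile as well. All arguments are vectorised.
#'
#' @param v_E Early diastolic LA peak outflow (transmitral) velocity, cm/s.
#' @param v_S Systolic LA peak inflow (pulmonary venous) velocity, cm/s.
#' @param v_D Early diastolic LA peak inflow velocity, cm/s.
#' @return Dimensionless acceleration factor(s).
#' @seealso [alpha_general()] for the two-parameter ratio family of which
#'   this is the `(c_out, c_in) = (1, 0)` member.
#' @export
#' @examples
#' la_alpha(54, 34, 33)  # ~ 1.61 at the cohort-mean velocities
la_alpha <- function(v_E, v_S, v_D) {
  denom <- (v_S + v_D) / 2
  if (any(!is.na(denom) & denom <= 0))
    stop("non-positive inflow denominator (v_S + v_D)/2", call. = FALSE)
  v_E / denom
}

#' General outflow/inflow velocity-ratio family
#'
#' Up to a multiplicative constant, every ratio of a linear combination of
#' the LA outflow peaks to a linear combination of the inflow peaks can be
#' written as
#' `(v_EplusA + c_out * v_EminusA) / (v_SplusD + c_in * v_SminusD)`,
#' where `v_EplusA = (v_E + v_A)/2`, `v_EminusA = (v_E - v_A)/2`,
#' `v_SplusD = (v_S + v_D)/2`, `v_SminusD = (v_S - v_D)/2`.
#' Algebraic identities: `(c_out, c_in) = (1, 0)` gives [la_alpha()];
#' `(1, 1)` gives `v_E / v_S`. `v_SminusD` may be negative (`v_D > v_S`
#' occurs in post-capillary records); only the full denominator must stay
#' positive.
#'
#' @inheritParams la_alpha
#' @param v_A Late diastolic LA peak outflow velocity, cm/s; required.
#' @param c_out,c_in Dimensionless constants of the ratio family.
#' @return Dimensionless ratio(s).
#' @export
alpha_general <- function(v_E, v_A, v_S, v_D, c_out, c_in) {
  if (any(is.na(v_A)))
    stop("alpha_general requires v_A; use la_alpha (c_out = 1, c_in = 0) ",
         "for monophasic records", call. = FALSE)
  num <- (v_E + v_A) / 2 + c_out * (v_E - v_A) / 2
  den <- (v_S + v_D) / 2 + c_in * (v_S - v_D) / 2
  if (any(!is.na(den) & den <= 0))
    stop("non-positive denominator in alpha_general", call. = FALSE)
  num / den
}

#' Acceleration factors at all measurement locations
#'
#' Adds the acceleration factor and its three alternative-location variants
#' to a cohort table: `alpha` from the junction velocities, `alpha_tip`
#' replacing the outflow peak by its mitral-valve-tip measurement,
#' `alpha_vein` replacing the inflow peaks by the intra-vein measurements,
#' and `alpha_tip_vein` replacing both. Records missing a needed component
#' get `NA` in that column and are counted in a message.
#'
#' @param cohort An `la_cohort` data frame (columns `vE`, `vS`, `vD` and,
#'   for the variants, `vE_tip`, `vS_vein`, `vD_vein`).
#' @param quiet Suppress the skipped-record message.
#' @return The cohort with columns `alpha`, `alpha_tip`, `alpha_vein`,
#'   `alpha_tip_vein` appended.
#' @export
alpha_variants <- function(cohort, quiet = FALSE) {
  stopifnot(all(c("vE", "vS", "vD") %in% names(cohort)))
  cohort$alpha <- la_alpha(cohort$vE, cohort$vS, cohort$vD)
  safe <- function(vE, vS, vD) {
    ok <- !is.na(vE) & !is.na(vS) & !is.na(vD)
    out <- rep(NA_real_, length(vE))
    out[ok] <- la_alpha(vE[ok], vS[ok], vD[ok])
    out
  }
  cohort$alpha_tip <- safe(cohort$vE_tip, cohort$vS, cohort$vD)
  cohort$alpha_vein <- safe(cohort$vE, cohort$vS_vein, cohort$vD_vein)
  cohort$alpha_tip_vein <- safe(cohort$vE_tip, cohort$vS_vein, cohort$vD_vein)
  n_skip <- sum(is.na(cohort$alpha_tip) | is.na(cohort$alpha_vein) |
                  is.na(cohort$alpha_tip_vein))
  if (n_skip > 0 && !quiet)
    message(n_skip, " record(s) lack alternative-location velocities; ",
            "variant set to NA")
  cohort
}
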