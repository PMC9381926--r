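#' Generate a toy 4D velocity field for one patient
#'
#' Builds a time-resolved three-directional velocity field on a regular
#' voxel grid containing three Gaussian-profile jets: one through the
#' atrio-ventricular (mitral) junction plane and one through each inferior
#' pulmonary vein orifice. Per cardiac phase, the maximal speed within each
#' plane's region of interest equals the corresponding sample of the
#' patient's velocity-time waveform, with the jet centred on a voxel so the
#' equality is exact. The mitral plane translates by one voxel in diastole
#' (time-varying plane); the vein planes are fixed. The vein selected in
#' the record carries the record's inflow peaks, the other vein the same
#' waveform scaled by `other_vein_scale`, so vein selection by maximal
#' velocity recovers the recorded vein.
#'
#' @param record One cohort row (`vE`, `vA`, `vS`, `vD`, `vein_used`).
#' @param wconfig A [waveform_config()].
#' @param grid Integer vector `c(nx, ny, nz)` of voxel counts; must be
#'   large enough to hold three non-overlapping jet regions.
#' @param voxel_size_mm Voxel edge lengths, mm (protocol-like default
#'   2.4 x 1.8 x 6.0).
#' @param jet_sigma_vox In-plane Gaussian radius of each jet, voxels.
#' @param other_vein_scale Velocity scale of the non-selected vein (< 1).
#' @param venc_cm_s Velocity-encoding bound, cm/s; a planted speed above it
#'   aborts, mirroring the aliasing the VENC setting avoids.
#' @return An `la_flow4d` list: `velocity` array `(x, y, z, phase, 3)` in
#'   cm/s, `voxel_size_mm`, `planes` (per-plane, per-phase z index, ROI
#'   centre and radius, normal), and a `sidecar` list (`venc_cm_s`,
#'   `phase_duration_ms`, `rr_ms`).
#' @export
generate_flow_field <- function(record, wconfig = waveform_config(),
                                grid = c(20, 20, 10),
                                voxel_size_mm = c(2.4, 1.8, 6.0),
                                jet_sigma_vox = 1.5,
                                other_vein_scale = 0.8,
                                venc_cm_s = 90) {
  stopifnot(length(grid) == 3, all(grid >= 8), venc_cm_s > 0,
            other_vein_scale > 0, other_vein_scale <= 1)
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  nph <- wconfig$n_phases
  curves <- generate_waveforms(record, wconfig)

  left_selected <- identical(record$vein_used, "left_inferior")
  venous <- curves$venous$vmax_cm_s
  vein_waves <- list(
    vein_left = if (left_selected) venous else other_vein_scale * venous,
    vein_right = if (left_selected) other_vein_scale * venous else venous)

  fr <- (seq_len(nph) - 1) / nph
  mitral_z <- ifelse(fr >= 0.40 & fr < 0.75, 4L, 3L)  # translates in diastole
  roi_r <- ceiling(2 * jet_sigma_vox) + 1
  planes <- list(
    mitral = list(z = mitral_z, center = c(round(nx * 0.3), round(ny * 0.5)),
                  radius = roi_r, normal = c(0, 0, 1)),
    vein_left = list(z = rep(nz - 1L, nph),
                     center = c(round(nx * 0.7), round(ny * 0.25)),
                     radius = roi_r, normal = c(0, 0, 1)),
    vein_right = list(z = rep(nz - 1L, nph),
                      center = c(round(nx * 0.7), round(ny * 0.75)),
                      radius = roi_r, normal = c(0, 0, 1)))

  for (p in planes) {
    if (any(p$center - p$radius < 1) ||
        p$center[1] + p$radius > nx || p$center[2] + p$radius > ny ||
        any(p$z < 1) || any(p$z > nz))
      stop("grid too small to contain the jet regions", call. = FALSE)
  }
  d_veins <- sqrt(sum((planes$vein_left$center - planes$vein_right$center)^2))
  if (d_veins <= 2 * roi_r)
    stop("grid too small: vein jet regions overlap", call. = FALSE)

  waves <- c(list(mitral = curves$transmitral$vmax_cm_s), vein_waves)
  if (max(unlist(waves)) > venc_cm_s)
    stop("planted jet speed exceeds the VENC bound of ", venc_cm_s,
         " cm/s (would alias)", call. = FALSE)

  vel <- array(0, dim = c(nx, ny, nz, nph, 3))
  xs <- seq_len(nx); ys <- seq_len(ny)
  for (nm in names(planes)) {
    pl <- planes[[nm]]
    prof <- outer((xs - pl$center[1])^2, (ys - pl$center[2])^2, "+")
    prof <- exp(-prof / (2 * jet_sigma_vox^2))
    for (ph in seq_len(nph))
      vel[, , pl$z[ph], ph, 3] <- vel[, , pl$z[ph], ph, 3] +
        waves[[nm]][ph] * prof
  }
  structure(list(velocity = vel, voxel_size_mm = voxel_size_mm,
                 planes = planes,
                 sidecar = list(venc_cm_s = venc_cm_s,
                                phase_duration_ms = wconfig$rr_interval_ms / nph,
                                rr_ms = wconfig$rr_interval_ms)),
            class = "la_flow4d")
}

#' Extract the maximal-speed curve across a measurement plane
#'
#' For every cardiac phase, takes the maximum Euclidean speed over the
#' voxels intersected by the plane within its region of interest, giving
#' the maximal-velocity-time curve used for peak detection.
#'
#' @param field An `la_flow4d` from [generate_flow_field()].
#' @param plane_id `"mitral"`, `"vein_left"` or `"vein_right"`.
#' @return An `la_curve` data frame.
#' @export
extract_max_speed_curve <- function(field,
                                    plane_id = c("mitral", "vein_left",
                                                 "vein_right")) {
  plane_id <- match.arg(plane_id)
  stopifnot(inherits(field, "la_flow4d"))
  pl <- field$planes[[plane_id]]
  dm <- dim(field$velocity)
  if (any(pl$z < 1) || any(pl$z > dm[3]))
    stop("plane lies outside the voxel grid", call. = FALSE)
  nph <- dm[4]
  xs <- seq_len(dm[1]); ys <- seq_len(dm[2])
  in_roi <- outer((xs - pl$center[1])^2, (ys - pl$center[2])^2, "+") <=
    pl$radius^2
  vmax <- vapply(seq_len(nph), function(ph) {
    sl <- field$velocity[, , pl$z[ph], ph, , drop = FALSE]
    speed <- sqrt(sl[, , 1, 1, 1]^2 + sl[, , 1, 1, 2]^2 + sl[, , 1, 1, 3]^2)
    max(speed[in_roi])
  }, numeric(1))
  loc <- c(mitral = "mitral_junction", vein_left = "vein_orifice_left",
           vein_right = "vein_orifice_right")[[plane_id]]
  out <- data.frame(location = loc, phase_index = seq_len(nph),
                    time_ms = (seq_len(nph) - 1) * field$sidecar$phase_duration_ms,
                    vmax_cm_s = vmax, stringsAsFactors = FALSE)
  attr(out, "rr_ms") <- field$sidecar$rr_ms
  class(out) <- c("la_curve", "data.frame")
  out
}

#' Write a toy 4D field to NIfTI with a JSON sidecar
#'
#' Stores the `(x, y, z, phase, component)` velocity array as a 5D NIfTI
#' volume and the acquisition metadata (VENC, phase duration, plane
#' definitions) as JSON next to it. Requires the RNifti package.
#'
#' @param field An `la_flow4d`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_flow_field <- function(field, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI requires the RNifti package", call. = FALSE)
  img <- RNifti::asNifti(field$velocity,
                         pixdim = c(field$voxel_size_mm,
                                    field$sidecar$phase_duration_ms, 1))
  RNifti::writeNifti(img, path)
  sidecar <- c(field$sidecar, list(voxel_size_mm = field$voxel_size_mm,
                                   plane_definitions = field$planes))
  jsonlite::write_json(sidecar, paste0(sub("\\.nii(\\.gz)?$", "", path),
                                       ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_flow_field
#' @export
read_flow_field <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package", call. = FALSE)
  vel <- array(as.array(RNifti::readNifti(path)),
               dim = dim(RNifti::readNifti(path)))
  sc <- jsonlite::read_json(paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                            simplifyVector = TRUE)
  planes <- lapply(sc$plane_definitions, function(p)
    list(z = as.integer(p$z), center = as.numeric(p$center),
         radius = as.numeric(p$radius), normal = as.numeric(p$normal)))
  structure(list(velocity = vel,
                 voxel_size_mm = as.numeric(sc$voxel_size_mm),
                 planes = planes,
                 sidecar = list(venc_cm_s = sc$venc_cm_s,
                                phase_duration_ms = sc$phase_duration_ms,
                                rr_ms = sc$rr_ms)),
            class = "la_flow4d")
}
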