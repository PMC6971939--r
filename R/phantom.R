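#' Digital vessel geometry
#'
#' A rigid straight tube of radius `radius_mm` running along one grid axis
#' through the center of an isotropic voxel grid, standing in for a
#' carotid-style flow phantom. The binary lumen mask is derived
#' analytically from the voxel-center distances to the tube axis so that
#' ground-truth velocity fields and oracle quantities are available in
#' closed form.
#'
#' @param shape integer grid dimensions `c(nx, ny, nz)`; the two
#'   phase-encode directions are y and z.
#' @param radius_mm tube radius in mm (default 3).
#' @param voxel_mm isotropic voxel size in mm (default 0.8).
#' @param axis grid axis the tube runs along (1, 2 or 3; default 1, the
#'   fully sampled readout direction).
#' @return object of class `vessel_geometry` with fields `shape`,
#'   `radius_mm`, `voxel_mm`, `axis`, `lumen` (logical array) and `rho_mm`
#'   (distance to the axis, per voxel).
#' @export
vessel_geometry <- function(shape = c(8L, 64L, 64L), radius_mm = 3,
                            voxel_mm = 0.8, axis = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 2), axis %in% 1:3)
  if (radius_mm < 2 * voxel_mm) {
    stop("tube radius must be at least 2 voxels", call. = FALSE)
  }
  perp <- setdiff(1:3, axis)
  co <- lapply(1:3, function(d) grid_coord(seq_len(shape[d]), shape[d],
                                           voxel_mm))
  u <- co[[perp[1]]]; v <- co[[perp[2]]]
  half_u <- max(abs(u)); half_v <- max(abs(v))
  if (radius_mm >= min(half_u, half_v)) {
    stop("lumen does not fit inside the grid", call. = FALSE)
  }
  # rho^2 broadcast over the two perpendicular axes, constant along `axis`
  rho2_plane <- outer(u^2, v^2, `+`)
  rho <- array(0, shape)
  idx <- rep(list(quote(expr = )), 3)
  for (i in seq_len(shape[axis])) {
    idx[[axis]] <- i
    if (axis == 1L) rho[i, , ] <- sqrt(rho2_plane)
    else if (axis == 2L) rho[, i, ] <- sqrt(rho2_plane)
    else rho[, , i] <- sqrt(rho2_plane)
  }
  structure(list(shape = as.integer(shape), radius_mm = radius_mm,
                 voxel_mm = voxel_mm, axis = as.integer(axis),
                 rho_mm = rho, lumen = rho <= radius_mm),
            class = "vessel_geometry")
}

#' Pulsatile inlet waveform
#'
#' A smooth periodic inlet flow-rate waveform: a raised-cosine systolic
#' pulse of width `systole_ms` centered at `t_peak_ms`, riding on a
#' constant diastolic baseline. Baseline and pulse amplitude are solved so
#' the cycle maximum equals `peak_mlps` and the cycle mean equals
#' `mean_mlps` exactly. A steady mode (`steady = Q0`) returns a constant
#' waveform, useful for Poiseuille-flow oracle tests.
#'
#' @param peak_mlps peak flow rate in ml/s (default 10).
#' @param mean_mlps cycle-mean flow rate in ml/s (default 3).
#' @param period_ms cardiac period in ms (default 1000, i.e. 60 bpm).
#' @param systole_ms full width of the systolic pulse in ms (default 300).
#' @param t_peak_ms time of the systolic peak within the cycle (default
#'   150 ms).
#' @param steady if non-NULL, a constant flow rate in ml/s overriding the
#'   pulsatile shape.
#' @return object of class `flow_waveform`.
#' @export
flow_waveform <- function(peak_mlps = 10, mean_mlps = 3, period_ms = 1000,
                          systole_ms = 300, t_peak_ms = 150,
                          steady = NULL) {
  if (!is.null(steady)) {
    stopifnot(is.finite(steady), steady >= 0)
    return(structure(list(steady = steady, period_ms = period_ms,
                          peak_mlps = steady, mean_mlps = steady),
                     class = "flow_waveform"))
  }
  if (peak_mlps < mean_mlps) {
    stop("peak flow must be >= mean flow", call. = FALSE)
  }
  stopifnot(systole_ms > 0, systole_ms < period_ms)
  frac <- systole_ms / (2 * period_ms)  # cycle-mean of the unit pulse
  baseline <- (mean_mlps - peak_mlps * frac) / (1 - frac)
  if (baseline < 0) {
    stop("infeasible waveform: shrink 'systole_ms' or raise 'mean_mlps'",
         call. = FALSE)
  }
  amplitude <- peak_mlps - baseline
  structure(list(steady = NULL, period_ms = period_ms,
                 peak_mlps = peak_mlps, mean_mlps = mean_mlps,
                 systole_ms = systole_ms, t_peak_ms = t_peak_ms,
                 baseline = baseline, amplitude = amplitude),
            class = "flow_waveform")
}

#' Evaluate the inlet waveform
#'
#' @param t time(s) in ms (any real values; the waveform is periodic).
#' @param waveform a [flow_waveform()].
#' @return flow rate(s) in ml/s.
#' @export
inlet_waveform <- function(t, waveform = flow_waveform()) {
  stopifnot(inherits(waveform, "flow_waveform"))
  if (!is.null(waveform$steady)) {
    return(rep(waveform$steady, length(t)))
  }
  tc <- t %% waveform$period_ms
  dt <- tc - waveform$t_peak_ms
  # wrap the pulse across the cycle boundary
  dt <- dt - round(dt / waveform$period_ms) * waveform$period_ms
  q <- rep(waveform$baseline, length(t))
  inb <- abs(dt) <= waveform$systole_ms / 2
  q[inb] <- waveform$baseline + waveform$amplitude *
    0.5 * (1 + cos(2 * pi * dt[inb] / waveform$systole_ms))
  q
}

#' RR-interval generator
#'
#' Independent Gaussian RR intervals with mean 60000/`mean_bpm` ms and
#' standard deviation `sd_fraction` times the mean, truncated at three
#' standard deviations; reproducible given `seed`.
#'
#' @param n number of intervals to draw.
#' @param mean_bpm mean heart rate in beats per minute (default 60).
#' @param sd_fraction RR standard deviation as a fraction of the mean
#'   (default 0.05).
#' @param seed integer seed (NULL = use the current RNG stream).
#' @return numeric vector of RR intervals in ms.
#' @export
rr_intervals <- function(n, mean_bpm = 60, sd_fraction = 0.05,
                         seed = NULL) {
  stopifnot(n >= 1, mean_bpm > 0, sd_fraction >= 0)
  mu <- 60000 / mean_bpm
  sd <- sd_fraction * mu
  with_seed(seed, {
    x <- stats::rnorm(n, mu, sd)
    bad <- abs(x - mu) > 3 * sd
    while (any(bad)) {
      x[bad] <- stats::rnorm(sum(bad), mu, sd)
      bad <- abs(x - mu) > 3 * sd
    }
    x
  })
}

#' Acquisition configuration
#'
#' Scan settings of the simulated four-point flow-encoded acquisition.
#' `noise_sd` is the per-component standard deviation of the complex
#' Gaussian k-space noise relative to the peak image magnitude (1.0 in the
#' lumen).
#'
#' @param venc velocity-encoding sensitivity in cm/s (default 150).
#' @param tr repetition time in ms (default 8.9).
#' @param n_coils number of receive coils (default 4).
#' @param noise_sd relative complex-noise SD (default 0.02).
#' @param seed integer noise seed.
#' @param time_quantization number of waveform evaluation levels per
#'   cardiac cycle (default 64; 0 = exact per-event times, slower).
#' @return object of class `acquisition_config`.
#' @export
acquisition_config <- function(venc = 150, tr = 8.9, n_coils = 4L,
                               noise_sd = 0.02, seed = 1L,
                               time_quantization = 64L) {
  stopifnot(venc > 0, tr > 0, n_coils >= 1, noise_sd >= 0,
            time_quantization >= 0)
  structure(list(venc = venc, tr = tr, n_coils = as.integer(n_coils),
                 noise_sd = noise_sd, seed = seed,
                 time_quantization = as.integer(time_quantization)),
            class = "acquisition_config")
}

#' Simulated coil sensitivity maps
#'
#' Smooth complex sensitivities: Gaussian magnitude lobes centered on the
#' perimeter of the phase-encode (y,z) plane with a gentle linear phase
#' ramp per coil. Deterministic in the geometry and coil count.
#'
#' @param geometry a [vessel_geometry()].
#' @param n_coils number of coils.
#' @return complex array of dim `c(shape, n_coils)`.
#' @export
coil_sensitivities <- function(geometry, n_coils = 4L) {
  stopifnot(inherits(geometry, "vessel_geometry"), n_coils >= 1)
  sh <- geometry$shape
  co <- lapply(1:3, function(d) grid_coord(seq_len(sh[d]), sh[d],
                                           geometry$voxel_mm))
  half_y <- max(abs(co[[2]])); half_z <- max(abs(co[[3]]))
  sigma <- 0.8 * max(half_y, half_z)
  ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils
  cy <- 1.1 * half_y * cos(ang)
  cz <- 1.1 * half_z * sin(ang)
  maps <- array(0 + 0i, c(sh, n_coils))
  yz_y <- matrix(co[[2]], sh[2], sh[3])
  yz_z <- matrix(co[[3]], sh[2], sh[3], byrow = TRUE)
  for (c_i in seq_len(n_coils)) {
    mag <- 0.25 + exp(-((yz_y - cy[c_i])^2 + (yz_z - cz[c_i])^2) /
                        (2 * sigma^2))
    phs <- 0.3 * (yz_y * cos(ang[c_i]) + yz_z * sin(ang[c_i])) /
      max(half_y, half_z) + ang[c_i] / 7
    plane <- mag * exp(1i * phs)
    for (i in seq_len(sh[1])) maps[i, , , c_i] <- plane
  }
  maps
}

#' Ground-truth velocity field
#'
#' Axial parabolic (Poiseuille) profile
#' v(rho, t) = 2 Q(t) / (pi a^2) * (1 - rho^2 / a^2) inside the lumen and
#' zero outside; transverse components are zero. Units: Q in ml/s and the
#' radius in mm give velocities in cm/s.
#'
#' @param geometry a [vessel_geometry()].
#' @param waveform a [flow_waveform()].
#' @param t time in ms (scalar).
#' @return list of arrays `vx`, `vy`, `vz` (cm/s) of the grid shape.
#' @export
velocity_field <- function(geometry, waveform, t = 0) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  q <- inlet_waveform(t, waveform)      # ml/s = cm^3/s
  a_cm <- geometry$radius_mm / 10
  v_axis <- array(0, geometry$shape)
  lum <- geometry$lumen
  v_axis[lum] <- 2 * q / (pi * a_cm^2) *
    (1 - (geometry$rho_mm[lum] / geometry$radius_mm)^2)
  zero <- array(0, geometry$shape)
  out <- list(vx = zero, vy = zero, vz = zero)
  out[[geometry$axis]] <- v_axis
  out
}

# Complex scene image for one flow segment at one time: magnitude 1.0 in
# the lumen / 0.3 background, phase pi * v_d / venc (0 for the reference
# segment 0; segments 1..3 encode vx, vy, vz).
scene_image <- function(geometry, waveform, t, segment, venc) {
  mag <- 0.3 + 0.7 * geometry$lumen
  if (segment == 0L) return(mag * exp(0i))
  v <- velocity_field(geometry, waveform, t)[[segment]]
  mag * exp(1i * pi * v / venc)
}

#' Simulate a four-point flow-encoded multi-coil acquisition
#'
#' Plays a [build_schedule()] sampling schedule against the digital
#' phantom: every event evaluates the pulsatile velocity field at its
#' acquisition time (using the waveform phase within the current simulated
#' beat, so RR variability produces genuine frame blur), forms the complex
#' scene image for its flow segment, weights it by each coil sensitivity,
#' and records the orthonormal 2D DFT sample at the event's (ky,kz)
#' coordinate for every readout position x and coil. Complex Gaussian
#' noise is added per sample. Velocities exceeding the VENC are allowed
#' (they alias in phase) and counted in `n_wrapped`.
#'
#' For speed, event times are quantized within the cardiac cycle to
#' `acq$time_quantization` levels (default 64, i.e. ~16 ms at 60 bpm, well
#' below one cardiac frame) so scene DFTs are shared between events;
#' `time_quantization = 0` evaluates every event exactly.
#'
#' @param geometry a [vessel_geometry()].
#' @param waveform a [flow_waveform()].
#' @param timeline a [cardiac_timeline()] covering the schedule.
#' @param schedule a [build_schedule()] result.
#' @param acq an [acquisition_config()].
#' @param coil_maps optional precomputed [coil_sensitivities()] array.
#' @return object of class `raw_container`: list with `kspace` (complex
#'   array `n_coils` x `nx` x `n_events`), `profiles`, `segments`,
#'   `times_ms`, `rtops_ms`, `coil_maps`, `geometry`, `acq`, `schedule`
#'   metadata and `n_wrapped`.
#' @export
encode_kspace <- function(geometry, waveform, timeline, schedule, acq,
                          coil_maps = NULL) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(timeline, "cardiac_timeline"),
            inherits(schedule, "sampling_schedule"),
            inherits(acq, "acquisition_config"))
  sh <- geometry$shape
  params <- attr(schedule, "params")
  if (params$matrix_ky != sh[2] || params$matrix_kz != sh[3]) {
    stop("schedule matrix does not match the geometry's (y,z) shape",
         call. = FALSE)
  }
  if (is.null(coil_maps)) {
    coil_maps <- coil_sensitivities(geometry, acq$n_coils)
  }
  n_coils <- dim(coil_maps)[4]
  n_ev <- nrow(schedule)
  rt <- timeline$r_top_times
  beat <- findInterval(schedule$acquisition_time, rt)
  phase_ms <- ifelse(beat >= 1L,
                     schedule$acquisition_time - rt[pmax(beat, 1L)],
                     (schedule$acquisition_time - rt[1]) %%
                       waveform$period_ms)
  phase_ms <- phase_ms %% waveform$period_ms
  if (acq$time_quantization > 0L) {
    nq <- acq$time_quantization
    lev <- floor(phase_ms / waveform$period_ms * nq)
    lev[lev >= nq] <- nq - 1L
    t_eval <- (lev + 0.5) * waveform$period_ms / nq
  } else {
    t_eval <- phase_ms
  }
  # peak lumen speed for VENC-wrap accounting
  a_cm <- geometry$radius_mm / 10
  v_peak <- 2 * inlet_waveform(t_eval, waveform) / (pi * a_cm^2)
  n_wrapped <- sum(abs(v_peak) > acq$venc)
  if (n_wrapped > 0) {
    message(sprintf("encode_kspace: %d events exceed VENC (phase wrap)",
                    n_wrapped))
  }
  kspace <- array(0 + 0i, c(n_coils, sh[1], n_ev))
  iy <- k_index(schedule$ky, sh[2])
  iz <- k_index(schedule$kz, sh[3])
  groups <- split(seq_len(n_ev),
                  list(t = t_eval, s = schedule$flow_segment), drop = TRUE)
  for (g in groups) {
    tg <- t_eval[g[1]]
    sg <- schedule$flow_segment[g[1]]
    img <- scene_image(geometry, waveform, tg, sg, acq$venc)
    lin <- iy[g] + sh[2] * (iz[g] - 1L)   # index into the (ky,kz) plane
    for (c_i in seq_len(n_coils)) {
      for (x in seq_len(sh[1])) {
        kplane <- fft2_ortho(img[x, , ] * coil_maps[x, , , c_i])
        kspace[c_i, x, g] <- kplane[lin]
      }
    }
  }
  if (acq$noise_sd > 0) {
    kspace <- kspace + with_seed(acq$seed, {
      n <- length(kspace)
      complex(real = stats::rnorm(n, 0, acq$noise_sd),
              imaginary = stats::rnorm(n, 0, acq$noise_sd))
    })
  }
  structure(list(kspace = kspace,
                 profiles = cbind(ky = schedule$ky, kz = schedule$kz),
                 segments = schedule$flow_segment,
                 times_ms = schedule$acquisition_time,
                 rtops_ms = rt,
                 coil_maps = coil_maps, geometry = geometry,
                 acq = acq, n_wrapped = n_wrapped,
                 schedule_attrs = list(
                   params = params, spec = attr(schedule, "spec"),
                   tr = attr(schedule, "tr"))),
            class = "raw_container")
}
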