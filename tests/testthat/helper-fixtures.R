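# Shared fixtures: all inputs are generated in code at test time.

# A small scene: 4 x 16 x 16 grid, 2.4 mm tube along x, 1.2 mm voxels.
tiny_geometry <- function() {
  vessel_geometry(c(4L, 16L, 16L), radius_mm = 2.4, voxel_mm = 1.2)
}

# Hand-built sampling schedule from explicit profiles (bypasses the
# spiral generator so binning/encoding can be tested in isolation).
manual_schedule <- function(profiles, n_card, tr = 8.9, n_flow = 4L,
                            matrix_ky = 16L, matrix_kz = 16L) {
  n_prof <- nrow(profiles)
  ev <- profiles[rep(seq_len(n_prof), each = n_flow), , drop = FALSE]
  rownames(ev) <- NULL
  ev <- as.data.frame(ev)
  names(ev) <- c("ky", "kz")
  ev$arm_index <- 0L
  ev$point_index <- rep(seq_len(n_prof) - 1L, each = n_flow)
  ev$flow_segment <- rep(seq_len(n_flow) - 1L, times = n_prof)
  ev$acquisition_time <- (seq_len(nrow(ev)) - 1) * tr
  params <- spiral_params(matrix_ky, matrix_kz, n_readouts = 2L)
  spec <- acceleration_spec(matrix_ky, matrix_kz, n_card, n_flow,
                            R_target = 1)
  structure(ev, class = c("sampling_schedule", "data.frame"),
            tr = tr, params = params, spec = spec,
            n_profiles = n_prof,
            realized_R = spec$N_fully / (n_prof * n_flow))
}

# Full-grid profile list (every (ky, kz) once, row-major).
full_grid_profiles <- function(matrix_ky = 16L, matrix_kz = 16L) {
  as.matrix(expand.grid(ky = seq(-matrix_ky / 2, matrix_ky / 2 - 1),
                        kz = seq(-matrix_kz / 2, matrix_kz / 2 - 1)))
}

# Wrap plain velocity arrays as a velocity_series.
as_velocity_series <- function(vx, vy, vz, n_discard = 0L,
                               frame_duration = 100, venc = 150) {
  structure(list(vx = vx, vy = vy, vz = vz,
                 magnitude = array(1, dim(vx)), venc = venc,
                 n_card = dim(vx)[4], n_discard = n_discard,
                 frame_duration = frame_duration),
            class = "velocity_series")
}

# Velocity series holding a single static 3D field.
static_series <- function(vf, n_discard = 0L, frame_duration = 100) {
  d <- c(dim(vf$vx), 1L)
  as_velocity_series(array(vf$vx, d), array(vf$vy, d), array(vf$vz, d),
                     n_discard = n_discard,
                     frame_duration = frame_duration)
}

# Small end-to-end simulated acquisition, reused across recon tests.
tiny_pipeline <- function(R_target = 2, n_card = 4L, noise_sd = 0,
                          steady = 3, seed = 11L, n_readouts = 20L,
                          n_coils = 2L) {
  geom <- tiny_geometry()
  wf <- if (is.null(steady)) flow_waveform() else flow_waveform(steady = steady)
  params <- spiral_params(16, 16, n_readouts = n_readouts)
  spec <- acceleration_spec(16, 16, n_card, 4L, R_target = R_target)
  sch <- build_schedule(params, spec, tr = 8.9)
  rr <- rr_intervals(ceiling(nrow(sch) * 8.9 / 1000) + 3, seed = seed)
  tl <- cardiac_timeline(cumsum(c(0, rr)), nominal_rr = 1000)
  bc <- binning_config(n_card, nominal_rr = 1000, n_discard = 1L)
  acq <- acquisition_config(n_coils = n_coils, noise_sd = noise_sd,
                            seed = seed + 1L, time_quantization = 16L)
  cm <- coil_sensitivities(geom, n_coils)
  raw <- encode_kspace(geom, wf, tl, sch, acq, cm)
  mask <- build_kt_mask(sch, tl, bc)
  binned <- bin_kspace(raw, mask)
  list(geom = geom, wf = wf, schedule = sch, timeline = tl,
       config = bc, acq = acq, coil_maps = cm, raw = raw, mask = mask,
       binned = binned)
}
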