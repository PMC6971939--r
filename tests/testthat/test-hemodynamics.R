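test_that("flow rate integrates through-plane velocity times area", {
  # uniform 10 cm/s over a 1 cm^2 ROI -> 10 ml/s
  lum <- array(FALSE, c(4L, 12L, 12L))
  lum[, 2:11, 2:11] <- TRUE   # 100 pixels of 1 mm^2
  d <- c(4L, 12L, 12L, 2L)
  vx <- array(0, d)
  vx[2, , , 1] <- 10
  vel <- as_velocity_series(vx, array(0, d), array(0, d))
  roi <- roi_plane(lum, slice = 2L, axis = 1L, voxel_mm = 1)
  q <- flow_rate(vel, roi)
  expect_equal(q$q_mlps, c(10, 0))
  # zero field -> zero curve
  vel0 <- as_velocity_series(array(0, d), array(0, d), array(0, d))
  expect_equal(flow_rate(vel0, roi)$q_mlps, c(0, 0))
  expect_error(roi_plane(array(FALSE, c(4, 4, 4)), 1), "empty")
})

test_that("ROI flow recovers the waveform and conserves between planes", {
  geom <- vessel_geometry(c(8L, 64L, 64L), radius_mm = 3, voxel_mm = 0.8)
  wf <- flow_waveform()
  n_card <- 10L
  gt <- ground_truth_velocity(geom, wf, n_card, 100)
  roi <- roi_plane(geom$lumen, slice = 4L, axis = 1L, voxel_mm = 0.8)
  q <- flow_rate(gt, roi)
  q_true <- inlet_waveform((seq_len(n_card) - 0.5) * 100, wf)
  expect_equal(q$q_mlps, q_true, tolerance = 0.02)
  # steady flow agrees between two parallel planes within 3%
  gts <- ground_truth_velocity(geom, flow_waveform(steady = 3), 2L, 100)
  q1 <- flow_rate(gts, roi_plane(geom$lumen, 2L, 1L, 0.8))$q_mlps[1]
  q2 <- flow_rate(gts, roi_plane(geom$lumen, 7L, 1L, 0.8))$q_mlps[1]
  expect_equal(q1, q2, tolerance = 0.03)
  expect_equal(q1, 3, tolerance = 0.03)
})

test_that("peak systole picks the highest mean speed, earliest on ties", {
  lum <- array(TRUE, c(2L, 2L, 2L))
  mk <- function(speeds) {
    d <- c(2L, 2L, 2L, length(speeds))
    vx <- array(rep(speeds, each = 8), d)
    as_velocity_series(vx, array(0, d), array(0, d))
  }
  expect_identical(peak_systole_frame(mk(c(1, 3, 2)), lum, 0L), 2L)
  expect_identical(peak_systole_frame(mk(c(3, 3, 1)), lum, 0L), 1L)
  # discarded frames are excluded from the search
  expect_identical(peak_systole_frame(mk(c(1, 2, 9)), lum, 1L), 2L)
  # noiseless phantom: peak frame contains the waveform peak time
  geom <- tiny_geometry()
  wf <- flow_waveform()
  gt <- ground_truth_velocity(geom, wf, 10L, 100)
  pk <- peak_systole_frame(gt, geom$lumen, 0L)
  t_pk <- 150
  expect_identical(pk, as.integer(ceiling(t_pk / 100)))
})

test_that("wall meshes digitize a cylinder with inward radial normals", {
  geom <- vessel_geometry(c(8L, 64L, 64L), radius_mm = 5, voxel_mm = 0.8)
  mesh <- wall_mesh(geom$lumen, 0.8)
  d_axis <- sqrt(mesh$points[, 2]^2 + mesh$points[, 3]^2)
  expect_true(all(abs(d_axis - 5) <= 0.8 + 1e-9))
  expect_equal(rowSums(mesh$normals^2), rep(1, nrow(mesh$normals)),
               tolerance = 1e-12)
  # perpendicular to the tube axis within 5 degrees
  ang <- asin(pmin(abs(mesh$normals[, 1]), 1)) * 180 / pi
  expect_lt(max(ang), 5)
  # normals point inward (toward the axis)
  inward <- rowSums(-cbind(0, mesh$points[, 2], mesh$points[, 3]) *
                      cbind(0, mesh$normals[, 2], mesh$normals[, 3]))
  expect_true(all(inward > 0))
  expect_error(wall_mesh(array(TRUE, c(4, 4, 4))), "interior")
})

test_that("WSS is exact on a linear shear and zero on a still fluid", {
  sh <- c(8L, 16L, 16L)
  lum <- array(FALSE, sh)
  lum[, , 9:16] <- TRUE
  zco <- (seq_len(16) - 8.5) * 0.8
  d <- c(sh, 1L)
  vx <- array(0, d)
  for (k in 1:16) vx[, , k, 1] <- 100 * zco[k] * 1e-3 * 100  # cm/s
  vel <- as_velocity_series(vx, array(0, d), array(0, d))
  mesh <- wall_mesh(lum, 0.8)
  w <- wss(vel, 1L, mesh, eta = 3.2e-3)
  flat <- mesh$normals[, 3] > 0.99
  expect_equal(unname(w$tau_mag[flat & w$valid]),
               rep(0.32, sum(flat & w$valid)), tolerance = 1e-9)
  # zero field
  vel0 <- as_velocity_series(array(0, d), array(0, d), array(0, d))
  w0 <- wss(vel0, 1L, mesh)
  expect_true(all(w0$tau_mag[w0$valid] == 0))
})

test_that("Poiseuille WSS approximates 4 eta Q / (pi a^3)", {
  geom <- vessel_geometry(c(8L, 64L, 64L), radius_mm = 3, voxel_mm = 0.8)
  gt <- ground_truth_velocity(geom, flow_waveform(steady = 3), 1L, 1000)
  mesh <- wall_mesh(geom$lumen, 0.8)
  w <- wss(gt, 1L, mesh, eta = 3.2e-3)
  analytic <- 4 * 3.2e-3 * 3e-6 / (pi * (3e-3)^3)
  expect_equal(mean(w$tau_mag[w$valid]), analytic, tolerance = 0.15)
  # tau is tangential: orthogonal to the normal at every point
  dots <- abs(rowSums(w$tau * w$normals)) / pmax(w$tau_mag, 1e-12)
  expect_lt(max(dots[w$valid]), 1e-6)
  # linear in viscosity and in the velocity scale
  w2 <- wss(gt, 1L, mesh, eta = 6.4e-3)
  expect_equal(w2$tau_mag[w$valid], 2 * w$tau_mag[w$valid],
               tolerance = 1e-10)
  gt2 <- gt
  gt2$vx <- 3 * gt$vx
  w3 <- wss(gt2, 1L, mesh, eta = 3.2e-3)
  expect_equal(w3$tau_mag[w$valid], 3 * w$tau_mag[w$valid],
               tolerance = 1e-10)
})

test_that("pairing against a reference survives small perturbations", {
  geom <- vessel_geometry(c(8L, 32L, 32L), radius_mm = 3, voxel_mm = 0.8)
  gt <- ground_truth_velocity(geom, flow_waveform(steady = 3), 1L, 1000)
  mesh <- wall_mesh(geom$lumen, 0.8)
  w <- wss(gt, 1L, mesh)
  p_self <- resample_to_reference(w, w)
  expect_identical(p_self$n_dropped, 0L)
  expect_equal(p_self$test, p_self$reference)
  # translated mesh by 0.1 voxel still pairs nearly everything
  w_shift <- w
  w_shift$points[, 2] <- w_shift$points[, 2] + 0.08
  p_shift <- resample_to_reference(w_shift, w)
  expect_gte(length(p_shift$test) / sum(w$valid), 0.99)
  # disjoint geometries drop everything
  w_far <- w
  w_far$points <- w_far$points + 100
  p_far <- resample_to_reference(w_far, w)
  expect_identical(length(p_far$test), 0L)
  expect_identical(p_far$n_dropped, sum(w_far$valid))
  # voxel-wise velocity pairing on identical grids is the identity
  pv <- resample_to_reference(gt, gt, lumen = geom$lumen, frame = 1L)
  expect_equal(pv$test, pv$reference)
})

test_that("stroke volume integrates non-discarded frames", {
  d <- c(2L, 4L, 4L, 10L)
  lum <- array(TRUE, d[1:3])
  vx <- array(0, d)
  vx[1, , , ] <- 3 / (16 * 0.01)   # uniform: 3 ml/s through 16 mm^2
  vel <- as_velocity_series(vx, array(0, d), array(0, d),
                            frame_duration = 100, n_discard = 0L)
  roi <- roi_plane(lum, 1L, 1L, voxel_mm = 1)
  curve <- flow_rate(vel, roi)
  expect_equal(stroke_volume(curve), 3)       # 3 ml/s over 1 s
  vel0 <- as_velocity_series(array(0, d), array(0, d), array(0, d))
  expect_equal(stroke_volume(flow_rate(vel0, roi)), 0)
  # phantom waveform: SV over the full cycle equals mean flow x period
  geom <- vessel_geometry(c(4L, 64L, 64L), radius_mm = 3, voxel_mm = 0.8)
  wf <- flow_waveform()
  gt <- ground_truth_velocity(geom, wf, 20L, 50)
  roi2 <- roi_plane(geom$lumen, 2L, 1L, voxel_mm = 0.8)
  sv <- stroke_volume(flow_rate(gt, roi2))
  expect_equal(sv, 3, tolerance = 0.03)
})
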