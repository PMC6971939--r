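# build a binned_kspace object directly from given per-frame k-planes
# (all-true mask), bypassing the simulator
binned_from_k <- function(kplanes, n_coils, nx, n_card) {
  ny <- dim(kplanes[[1]][[1]])[1]
  nz <- dim(kplanes[[1]][[1]])[2]
  y <- array(0 + 0i, c(ny, nz, n_card, n_coils, nx))
  for (f in seq_len(n_card)) {
    for (c_i in seq_len(n_coils)) {
      for (x in seq_len(nx)) {
        y[, , f, c_i, x] <- kplanes[[f]][[c_i]][, , x]
      }
    }
  }
  structure(list(y = list(y), mask = array(TRUE, c(ny, nz, n_card, 1)),
                 counts = array(1L, c(ny, nz, n_card, 1)),
                 n_card = n_card, n_discard = 0L, frame_duration = 100,
                 shape = c(nx, ny, nz), n_coils = n_coils),
            class = "binned_kspace")
}

# independently coded oracle: naive DFT matrices + weighted coil sum
oracle_sense_combine <- function(y, coil_maps) {
  ny <- dim(y)[1]; nz <- dim(y)[2]; nx <- dim(coil_maps)[1]
  n_coils <- dim(coil_maps)[4]
  wy <- exp(2i * pi * outer(0:(ny - 1), 0:(ny - 1)) / ny) / sqrt(ny)
  wz <- exp(2i * pi * outer(0:(nz - 1), 0:(nz - 1)) / nz) / sqrt(nz)
  out <- array(0 + 0i, c(nx, ny, nz))
  for (x in seq_len(nx)) {
    num <- matrix(0 + 0i, ny, nz)
    den <- matrix(0, ny, nz)
    for (c_i in seq_len(n_coils)) {
      img <- wy %*% y[, , c_i, x] %*% t(wz)
      num <- num + Conj(coil_maps[x, , , c_i]) * img
      den <- den + Mod(coil_maps[x, , , c_i])^2
    }
    out[x, , ] <- num / den
  }
  out
}

test_that("zero-filled recon matches the naive inverse-DFT oracle", {
  set.seed(21)
  nx <- 4L; ny <- 16L; nz <- 16L; n_coils <- 2L
  geom <- tiny_geometry()
  cm <- coil_sensitivities(geom, n_coils)
  rnd_k <- function() {
    array(complex(real = rnorm(ny * nz * nx), imaginary = rnorm(ny * nz * nx)),
          c(ny, nz, nx))
  }
  kp <- list(list(rnd_k(), rnd_k()))
  bn <- binned_from_k(kp, n_coils, nx, 1L)
  zf <- zero_filled(bn, cm)
  y_perm <- aperm(bn$y[[1]][, , 1, , ], c(1, 2, 3, 4))  # (ky,kz,coil,x)
  orc <- oracle_sense_combine(y_perm, cm)
  expect_equal(zf$m[[1]][, , , 1], orc, tolerance = 1e-10)
})

test_that("zero-filled recon is linear in the data", {
  pl <- tiny_pipeline(R_target = 4, noise_sd = 0)
  b1 <- pl$binned
  b2 <- b1
  b2$y <- lapply(b1$y, function(a) 2i * a)
  b3 <- b1
  b3$y <- Map(function(a, b) a + b, b1$y, b2$y)
  z1 <- zero_filled(b1, pl$coil_maps)
  z2 <- zero_filled(b2, pl$coil_maps)
  z3 <- zero_filled(b3, pl$coil_maps)
  expect_equal(z3$m[[1]], z1$m[[1]] + z2$m[[1]], tolerance = 1e-10)
})

test_that("with full sampling and lambda 0 the CS solution is zero-filled", {
  geom <- tiny_geometry()
  wf <- flow_waveform(steady = 3)
  prof <- full_grid_profiles()
  s <- manual_schedule(prof, n_card = 2L, tr = 0.05)
  tl <- cardiac_timeline(c(0, 1e5, 2e5), nominal_rr = 1e5)
  bc <- binning_config(2L, nominal_rr = 1e5, n_discard = 0L)
  acq <- acquisition_config(n_coils = 2L, noise_sd = 0,
                            time_quantization = 0L)
  cm <- coil_sensitivities(geom, 2L)
  raw <- encode_kspace(geom, wf, tl, s, acq, cm)
  mask <- build_kt_mask(s, tl, bc)
  bn <- bin_kspace(raw, mask)
  # frame 2 never sampled here; restrict to the sampled frame
  bn$y <- lapply(bn$y, function(a) a[, , 1, , , drop = FALSE])
  bn$mask <- bn$mask[, , 1, , drop = FALSE]
  bn$counts <- bn$counts[, , 1, , drop = FALSE]
  bn$n_card <- 1L
  zf <- zero_filled(bn, cm)
  cs <- cs_recon(bn, cm, recon_config(lambda = 0, iterations = 5))
  expect_equal(cs$m[[1]], zf$m[[1]], tolerance = 1e-6)
})

test_that("the CS objective never increases and data consistency holds", {
  pl <- tiny_pipeline(R_target = 6, n_card = 4L, noise_sd = 0.02,
                      steady = NULL)
  cs <- cs_recon(pl$binned, pl$coil_maps, recon_config(iterations = 6))
  for (tr in cs$objective) {
    expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
  }
  # ||F_U m - y|| of the solution is below that of the zero image (= ||y||)
  misfit_end <- 2 * (tail(cs$objective[[1]], 1))  # upper bound: includes TV
  norm_y <- sum(Mod(pl$binned$y[[1]])^2) /
    max(Mod(zero_filled(pl$binned, pl$coil_maps)$m[[1]]))^2
  expect_lt(misfit_end, norm_y)
})

test_that("velocity decoding maps phase differences linearly to VENC", {
  d <- c(1L, 1L, 1L, 1L)
  mk <- function(phase) array(exp(1i * phase), d)
  series <- structure(list(m = list(mk(0), mk(pi), mk(0), mk(-pi / 2)),
                           n_card = 1L, n_discard = 0L,
                           frame_duration = 100, objective = NULL),
                      class = "image_series")
  vel <- velocity_decode(series, venc = 150)
  expect_equal(as.numeric(vel$vx), 150)
  expect_equal(as.numeric(vel$vy), 0)
  expect_equal(as.numeric(vel$vz), -75)
  expect_error(velocity_decode(series, venc = 0), "positive")
})

test_that("velocity decode ignores a global constant phase", {
  set.seed(9)
  d <- c(2L, 4L, 4L, 3L)
  mk <- function() {
    array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  }
  base <- list(mk(), mk(), mk(), mk())
  s1 <- structure(list(m = base, n_card = 3L, n_discard = 0L,
                       frame_duration = 100), class = "image_series")
  s2 <- s1
  s2$m <- lapply(base, function(a) a * exp(1.3i))
  v1 <- velocity_decode(s1, 150)
  v2 <- velocity_decode(s2, 150)
  expect_equal(v1$vx, v2$vx, tolerance = 1e-10)
  expect_equal(v1$vz, v2$vz, tolerance = 1e-10)
})

test_that("decoded velocities stay inside the VENC range", {
  pl <- tiny_pipeline(R_target = 4, noise_sd = 0.05, steady = NULL)
  cs <- cs_recon(pl$binned, pl$coil_maps, recon_config(iterations = 3))
  vel <- velocity_decode(cs, 150)
  expect_true(all(abs(vel$vx) <= 150))
  expect_true(all(abs(vel$vy) <= 150))
  expect_true(all(abs(vel$vz) <= 150))
})

test_that("static phase-offset correction removes an additive plane", {
  geom <- tiny_geometry()
  sh <- geom$shape
  d <- c(sh, 2L)
  zero <- array(0, d)
  vel <- as_velocity_series(zero, zero, zero)
  # additive first-order offset field
  plane <- array(0, sh)
  for (i in seq_len(sh[1])) for (j in seq_len(sh[2])) {
    plane[i, j, ] <- 0.5 + 0.2 * i - 0.1 * j +
      0.05 * seq_len(sh[3])
  }
  velp <- vel
  for (f in 1:2) velp$vx[, , , f] <- velp$vx[, , , f] + plane
  static <- !geom$lumen
  corr <- static_phase_offset_correct(velp, static)
  expect_lt(max(abs(corr$vx[array(static, d)])), 1e-6 * 150)
  # zero-offset input is unchanged
  corr0 <- static_phase_offset_correct(vel, static)
  expect_equal(corr0$vx, vel$vx, tolerance = 1e-10)
  # bypass is the identity
  expect_identical(static_phase_offset_correct(velp, static,
                                               enabled = FALSE), velp)
})
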