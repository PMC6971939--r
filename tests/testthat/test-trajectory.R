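test_that("tiny golden angle sequence matches its closed form", {
  expect_equal(round(tiny_golden_angle(7), 2), 23.63)
  expect_equal(tiny_golden_angle(1), 111.2461180, tolerance = 1e-8)
  angles <- vapply(1:21, tiny_golden_angle, 0)
  expect_true(all(diff(angles) < 0))
  expect_error(tiny_golden_angle(0), "positive")
  expect_error(tiny_golden_angle(-3), "positive")
})

# brute-force arm oracle: evaluates the quadratic spiral directly, with
# the same sampling/rounding conventions, independent of spiral_arm()
oracle_arm <- function(n, l, inc_deg, m_ky, m_kz, arm) {
  phi <- seq(0, 2 * pi * l, length.out = n)
  r <- phi^2
  r <- r / max(r) * (m_ky / 2 - 1)
  th <- phi + ((arm * inc_deg) %% 360) * pi / 180
  ky <- r * cos(th)
  kz <- r * sin(th) * (m_kz / 2) / (m_ky / 2)
  rnd <- function(x) sign(x) * ceiling(abs(x) - 0.5)
  clamp <- function(x, m) {
    as.integer(pmin(pmax(rnd(x), -(m / 2 - 1)), m / 2 - 1))
  }
  cbind(clamp(ky, m_ky), clamp(kz, m_kz))
}

test_that("gridded spiral arms match the brute-force spiral oracle", {
  p <- spiral_params(160, 160)
  for (arm in c(0L, 1L, 7L, 40L)) {
    a <- spiral_arm(p, arm)
    o <- oracle_arm(100, 3, p$angle_increment, 160, 160, arm)
    expect_identical(cbind(a$ky, a$kz), unname(o))
  }
  pa <- spiral_params(160, 40)
  a <- spiral_arm(pa, 3L)
  o <- oracle_arm(100, 3, pa$angle_increment, 160, 40, 3)
  expect_identical(cbind(a$ky, a$kz), unname(o))
})

test_that("spiral arms start at k-space center and span the grid", {
  p <- spiral_params(160, 160)
  for (arm in 0:19) {
    a <- spiral_arm(p, arm)
    expect_identical(c(a$ky[1], a$kz[1]), c(0L, 0L))
  }
  a0 <- spiral_arm(p, 0L)
  expect_identical(max(pmax(abs(a0$ky), abs(a0$kz))), 79L)
})

test_that("asymmetric matrices rescale kz by the matrix aspect ratio", {
  p <- spiral_params(160, 40)
  mk <- max(vapply(0:49, function(i) max(abs(spiral_arm(p, i)$kz)), 0L))
  expect_lte(mk, 19L)
})

test_that("sampling density decreases radially (variable density)", {
  p <- spiral_params(64, 64)
  prof <- do.call(rbind, lapply(0:40, function(i) {
    a <- spiral_arm(p, i)
    cbind(a$ky, a$kz)
  }))
  prof <- unique(prof)
  r <- sqrt(prof[, 1]^2 + prof[, 2]^2)
  r_max <- 31
  inner <- sum(r <= r_max / 4) / (pi * (r_max / 4)^2)
  outer <- sum(r > r_max / 2) / (pi * (r_max^2 - (r_max / 2)^2))
  expect_gt(inner, outer)
})

test_that("acceleration factor follows the fully-sampled readout ratio", {
  n_full <- 160 * 40 * 19 * 4
  expect_equal(acceleration_factor(160, 40, 19, 4, n_full), 1)
  expect_equal(acceleration_factor(160, 40, 19, 4, n_full / 10), 10)
  r_seq <- vapply(c(1000, 2000, 4000, 8000),
                  function(nu) acceleration_factor(160, 40, 19, 4, nu), 0)
  expect_true(all(diff(r_seq) < 0))
  expect_error(acceleration_factor(160, 40, 19, 4, 0), ">= 1")
})

test_that("schedules stop at the target readout count in whole arms", {
  p <- spiral_params(16, 16, n_readouts = 20L)
  # boundary: R chosen so exactly one arm is needed
  n_fully <- 16 * 16 * 4 * 4
  r_one <- n_fully / (4 * 20)
  s1 <- build_schedule(p, acceleration_spec(16, 16, 4, 4, r_one))
  expect_identical(attr(s1, "n_profiles"), 20L)
  # realized R within one arm quantum of the target
  p32 <- spiral_params(32, 32)
  sp <- acceleration_spec(32, 32, 8, 4, R_target = 10)
  s <- build_schedule(p32, sp)
  n_readouts_emitted <- nrow(s)
  quantum <- 100 * 4
  expect_lt(abs(n_readouts_emitted - sp$N_fully / 10), quantum + 1)
  expect_equal(attr(s, "realized_R"), sp$N_fully / n_readouts_emitted)
  # four consecutive flow segments per profile, times in TR steps
  expect_identical(s$flow_segment[1:8], rep(0:3, 2L))
  expect_equal(diff(s$acquisition_time), rep(8.9, nrow(s) - 1))
  # determinism
  s2 <- build_schedule(p32, sp)
  expect_identical(as.data.frame(s), as.data.frame(s2))
  expect_error(build_schedule(p32, acceleration_spec(32, 32, 8, 4, 0.5)))
})

test_that("every arm samples the k-space center", {
  p <- spiral_params(64, 64)
  for (i in 0:30) {
    a <- spiral_arm(p, i)
    expect_true(any(a$ky == 0L & a$kz == 0L))
  }
})

test_that("profile files round-trip and report malformed lines", {
  p <- spiral_params(32, 32)
  s <- build_schedule(p, acceleration_spec(32, 32, 4, 4, 4))
  f <- withr::local_tempfile(fileext = ".txt")
  export_profiles(s, f)
  lines <- readLines(f)
  first <- s[s$flow_segment == 0L, ]
  expect_identical(lines[1:2], sprintf("%d %d", first$ky[1:2],
                                       first$kz[1:2]))
  imp <- import_profiles(f)
  expect_identical(imp$ky, first$ky)
  expect_identical(imp$kz, first$kz)
  # comments and blank lines ignored
  writeLines(c("# header", "", "0 0", "1 0"), f)
  expect_identical(import_profiles(f)$ky, c(0L, 1L))
  writeLines(c("a b"), f)
  expect_error(import_profiles(f), "line 1")
  writeLines(c("0 0", "1 2 3"), f)
  expect_error(import_profiles(f), "line 2")
})
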