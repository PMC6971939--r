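#' Tiny golden angle
#'
#' Members of the tiny golden-angle sequence generalize the golden angle
#' (111.246...°) to smaller increments: the N-th member is
#' 180 / (tau + N - 1) degrees with tau the golden ratio (1 + sqrt(5))/2.
#' Rotating successive pseudo-spiral arms by a tiny golden angle yields
#' near-uniform azimuthal coverage of the phase-encode plane while keeping
#' the arm-to-arm rotation (and hence gradient jumps) small. The order-7
#' member, 23.63°, is the package default throughout.
#'
#' @param order positive integer index into the sequence (1 gives the
#'   classic golden angle 111.246°).
#' @return angle increment in degrees.
#' @examples
#' tiny_golden_angle(7)  # 23.628...
#' @export
tiny_golden_angle <- function(order = 7) {
  if (!is.numeric(order) || length(order) != 1L || !is.finite(order) ||
      order < 1 || order != round(order)) {
    stop("'order' must be a positive integer", call. = FALSE)
  }
  tau <- (1 + sqrt(5)) / 2
  180 / (tau + order - 1)
}

#' Pseudo-spiral sampling parameters
#'
#' Parameters of one pseudo-spiral arm gridded onto the Cartesian
#' phase-encode matrix. The arm follows r(phi) = phi^2 with phi increasing
#' linearly from 0 to 2*pi*n_turns over `n_readouts` samples; the radius is
#' normalized so the last sample reaches the edge of the ky grid, and the kz
#' coordinate is rescaled by the matrix aspect ratio before rounding to
#' integer grid points.
#'
#' @param n_readouts number of Cartesian readouts per arm (default 100).
#' @param n_turns number of spiral turns per arm (default 3).
#' @param angle_increment arm-to-arm rotation in degrees
#'   (default `tiny_golden_angle(7)`, i.e. 23.63°).
#' @param matrix_ky,matrix_kz even phase-encode matrix sizes (>= 4).
#' @return object of class `spiral_params`.
#' @export
spiral_params <- function(matrix_ky, matrix_kz, n_readouts = 100L,
                          n_turns = 3L,
                          angle_increment = tiny_golden_angle(7)) {
  stopifnot(is.numeric(matrix_ky), is.numeric(matrix_kz))
  if (n_readouts < 2) stop("'n_readouts' must be >= 2", call. = FALSE)
  if (n_turns < 1) stop("'n_turns' must be >= 1", call. = FALSE)
  if (!is.finite(angle_increment) || angle_increment <= 0 ||
      angle_increment >= 360) {
    stop("'angle_increment' must be in (0, 360) degrees", call. = FALSE)
  }
  for (m in c(matrix_ky, matrix_kz)) {
    if (m < 4 || m %% 2 != 0) {
      stop("matrix sizes must be even and >= 4", call. = FALSE)
    }
  }
  structure(
    list(n_readouts = as.integer(n_readouts), n_turns = as.integer(n_turns),
         angle_increment = angle_increment,
         matrix_ky = as.integer(matrix_ky),
         matrix_kz = as.integer(matrix_kz)),
    class = "spiral_params")
}

# round to nearest integer, ties toward zero
round_to_zero <- function(x) sign(x) * ceiling(abs(x) - 0.5)

#' Grid one pseudo-spiral arm
#'
#' Evaluates the quadratic spiral r(phi) = phi^2 at `n_readouts` uniformly
#' spaced angles in [0, 2*pi*n_turns], rotates the arm by
#' `arm_index * angle_increment` (accumulated and reduced modulo 360°),
#' rescales kz by (matrix_kz/2)/(matrix_ky/2), rounds to the integer grid
#' (ties toward zero) and clamps out-of-range points to the valid index
#' range so every arm has a constant length.
#'
#' @param params a [spiral_params()] object.
#' @param arm_index zero-based arm number.
#' @return data.frame with integer columns `ky`, `kz` (zero-centered grid
#'   coordinates), `arm_index` and `point_index`.
#' @export
spiral_arm <- function(params, arm_index = 0L) {
  stopifnot(inherits(params, "spiral_params"), arm_index >= 0)
  n <- params$n_readouts
  phi <- seq(0, 2 * pi * params$n_turns, length.out = n)
  r <- phi^2
  r_max_grid <- params$matrix_ky / 2 - 1
  r <- r / r[n] * r_max_grid
  rot <- (arm_index * params$angle_increment) %% 360
  theta <- phi + rot * pi / 180
  ky <- r * cos(theta)
  kz <- r * sin(theta) * (params$matrix_kz / 2) / (params$matrix_ky / 2)
  ky <- round_to_zero(ky)
  kz <- round_to_zero(kz)
  # symmetric clamp to +/-(m/2 - 1): keeps |k| within the normalization
  # radius (the extra -m/2 row of the even grid is never targeted)
  ky <- pmin(pmax(ky, -(params$matrix_ky / 2 - 1)), params$matrix_ky / 2 - 1)
  kz <- pmin(pmax(kz, -(params$matrix_kz / 2 - 1)), params$matrix_kz / 2 - 1)
  data.frame(ky = as.integer(ky), kz = as.integer(kz),
             arm_index = as.integer(arm_index),
             point_index = seq_len(n) - 1L)
}

#' Acceleration specification
#'
#' Bookkeeping for the acceleration factor R = N_fully / N_undersampled,
#' where N_fully = N_ky * N_kz * N_card * N_flow is the readout count of a
#' fully sampled retrospectively gated 4D flow scan.
#'
#' @param N_ky,N_kz phase-encode matrix sizes.
#' @param N_card number of reconstructed cardiac frames.
#' @param N_flow number of flow-encoding segments (4 for referenced
#'   four-point encoding).
#' @param R_target desired acceleration factor (>= 1).
#' @return object of class `acceleration_spec` with an `N_fully` field.
#' @export
acceleration_spec <- function(N_ky, N_kz, N_card, N_flow = 4L,
                              R_target = 10) {
  stopifnot(N_ky >= 1, N_kz >= 1, N_card >= 1, N_flow >= 1)
  if (!is.finite(R_target) || R_target < 1) {
    stop("'R_target' must be >= 1", call. = FALSE)
  }
  structure(
    list(N_ky = as.integer(N_ky), N_kz = as.integer(N_kz),
         N_card = as.integer(N_card), N_flow = as.integer(N_flow),
         R_target = R_target,
         N_fully = as.numeric(N_ky) * N_kz * N_card * N_flow),
    class = "acceleration_spec")
}

#' Acceleration factor
#'
#' R = N_fully / N_undersampled with
#' N_fully = N_ky * N_kz * N_card * N_flow.
#'
#' @param N_ky,N_kz,N_card,N_flow fully sampled scan dimensions.
#' @param N_undersampled actually acquired readout count (>= 1).
#' @return dimensionless acceleration factor.
#' @export
acceleration_factor <- function(N_ky, N_kz, N_card, N_flow,
                                N_undersampled) {
  if (N_undersampled < 1) {
    stop("'N_undersampled' must be >= 1", call. = FALSE)
  }
  as.numeric(N_ky) * N_kz * N_card * N_flow / N_undersampled
}

#' Build an acquisition-ordered sampling schedule
#'
#' Emits whole pseudo-spiral arms in tiny-golden-angle order until the total
#' readout count (profiles times `N_flow`) first reaches
#' `N_fully / R_target`. Each (ky,kz)-profile expands into `N_flow`
#' consecutive flow-segment events (all flow encodings are acquired before
#' the profile changes), and acquisition time advances by one TR per event.
#' The construction is fully deterministic.
#'
#' @param params a [spiral_params()] object.
#' @param spec an [acceleration_spec()] object (its `N_ky`/`N_kz` must match
#'   `params`).
#' @param tr repetition time in ms (default 8.9).
#' @return object of class `sampling_schedule`: a data.frame with columns
#'   `ky`, `kz`, `arm_index`, `point_index`, `flow_segment` (0-based) and
#'   `acquisition_time` (ms), plus attributes `tr`, `params`, `spec`,
#'   `n_profiles` and `realized_R`.
#' @export
build_schedule <- function(params, spec, tr = 8.9) {
  stopifnot(inherits(params, "spiral_params"),
            inherits(spec, "acceleration_spec"))
  if (spec$N_ky != params$matrix_ky || spec$N_kz != params$matrix_kz) {
    stop("matrix sizes of 'params' and 'spec' disagree", call. = FALSE)
  }
  if (spec$R_target < 1) stop("'R_target' must be >= 1", call. = FALSE)
  target_readouts <- spec$N_fully / spec$R_target
  arms <- list()
  total_readouts <- 0
  arm <- 0L
  while (total_readouts < target_readouts) {
    arms[[arm + 1L]] <- spiral_arm(params, arm)
    total_readouts <- total_readouts + params$n_readouts * spec$N_flow
    arm <- arm + 1L
  }
  profiles <- do.call(rbind, arms)
  n_prof <- nrow(profiles)
  seg <- rep(seq_len(spec$N_flow) - 1L, times = n_prof)
  ev <- profiles[rep(seq_len(n_prof), each = spec$N_flow), , drop = FALSE]
  rownames(ev) <- NULL
  ev$flow_segment <- seg
  ev$acquisition_time <- (seq_len(nrow(ev)) - 1) * tr
  structure(ev, class = c("sampling_schedule", "data.frame"),
            tr = tr, params = params, spec = spec,
            n_profiles = n_prof,
            realized_R = spec$N_fully / (n_prof * spec$N_flow))
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat(sprintf(
    "sampling_schedule: %d events (%d profiles x %d segments), TR %.2f ms\n",
    nrow(x), attr(x, "n_profiles"), attr(x, "spec")$N_flow, attr(x, "tr")))
  cat(sprintf("  matrix %d x %d, target R %.3g, realized R %.3f\n",
              attr(x, "params")$matrix_ky, attr(x, "params")$matrix_kz,
              attr(x, "spec")$R_target, attr(x, "realized_R")))
  invisible(x)
}

#' Export (ky,kz)-profiles to a scanner text file
#'
#' Writes one line per profile in acquisition order, two whitespace-separated
#' signed integers "ky kz". This is the text-file format imported by
#' prospective-undersampling scanner patches; flow segments are implicit
#' (each profile is played out once per flow encoding).
#'
#' @param schedule a [build_schedule()] result.
#' @param path output file path (or connection).
#' @return `path`, invisibly.
#' @export
export_profiles <- function(schedule, path) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  first_seg <- schedule$flow_segment == 0L
  lines <- sprintf("%d %d", schedule$ky[first_seg], schedule$kz[first_seg])
  writeLines(lines, path)
  invisible(path)
}

#' Import a (ky,kz)-profile text file
#'
#' Parses a profile file written by [export_profiles()] (or by other
#' trajectory tools using the same "ky kz" per-line convention). Lines
#' starting with "#" and blank lines are ignored. Malformed lines raise an
#' error naming the offending line number.
#'
#' @param path input file path.
#' @return data.frame with integer columns `ky` and `kz` in acquisition
#'   order.
#' @export
import_profiles <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  idx <- which(keep)
  parsed <- lapply(idx, function(i) {
    parts <- strsplit(trimws(raw[i]), "\\s+")[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("line %d: expected two fields, found %d",
                   i, length(parts)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals) || any(vals != round(vals))) {
      stop(sprintf("line %d: fields must be integers (got '%s')",
                   i, raw[i]), call. = FALSE)
    }
    vals
  })
  m <- do.call(rbind, parsed)
  if (is.null(m)) {
    return(data.frame(ky = integer(0), kz = integer(0)))
  }
  data.frame(ky = as.integer(m[, 1]), kz = as.integer(m[, 2]))
}
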