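#' Reconstruction configuration
#'
#' Settings of the compressed-sensing solver: the temporal-TV weight
#' `lambda` (applied after normalizing the data so the zero-filled image
#' peak is ~1, which makes the default transferable across scales), the
#' number of outer ADMM iterations, and the solver's numerical
#' parameters (split penalty and inner conjugate-gradient depth, which
#' control convergence rate but not the minimizer).
#'
#' @param lambda regularization weight (default 0.01).
#' @param iterations outer solver iterations (default 10).
#' @param rho ADMM penalty parameter on the temporal-difference split
#'   (default 0.1).
#' @param cg_iters inner conjugate-gradient steps per image update
#'   (default 10).
#' @return object of class `recon_config`.
#' @export
recon_config <- function(lambda = 0.01, iterations = 10L, rho = 0.1,
                         cg_iters = 10L) {
  if (!is.finite(lambda) || lambda < 0) {
    stop("'lambda' must be >= 0", call. = FALSE)
  }
  if (iterations < 1) stop("'iterations' must be >= 1", call. = FALSE)
  stopifnot(rho > 0, cg_iters >= 1)
  structure(list(lambda = lambda, iterations = as.integer(iterations),
                 rho = rho, cg_iters = as.integer(cg_iters)),
            class = "recon_config")
}

#' Bin raw k-space data onto the k-t grid
#'
#' Accumulates every accepted event of a raw container into per-segment
#' k-t arrays, averaging duplicate acquisitions of the same
#' (ky, kz, frame) cell by their sample count.
#'
#' @param raw an [encode_kspace()] result (or a compatible container).
#' @param mask the [build_kt_mask()] of the same schedule and timeline.
#' @return object of class `binned_kspace`: list with `y` (one complex
#'   array of dim (ky, kz, frame, coil, x) per flow segment, k indices in
#'   DFT-natural order), `mask` and `counts` reordered to match, `n_card`,
#'   `n_discard`, `frame_duration`.
#' @export
bin_kspace <- function(raw, mask) {
  stopifnot(inherits(raw, "raw_container"), inherits(mask, "kt_mask"))
  sh <- raw$geometry$shape
  ny <- sh[2]; nz <- sh[3]; nx <- sh[1]
  n_coils <- dim(raw$kspace)[1]
  n_card <- mask$n_card
  n_flow <- dim(mask$counts)[4]
  # k indices in DFT-natural order, matching the encoder's FFT planes
  iy <- k_index(raw$profiles[, "ky"], ny)
  iz <- k_index(raw$profiles[, "kz"], nz)
  # centered-order -> natural-order permutations for the mask arrays
  qy <- ((seq_len(ny) - 1L + ny / 2) %% ny) + 1L
  qz <- ((seq_len(nz) - 1L + nz / 2) %% nz) + 1L
  counts_nat <- mask$counts[qy, qz, , , drop = FALSE]
  frame <- mask$frame
  y <- vector("list", n_flow)
  for (s in seq_len(n_flow) - 1L) {
    ev <- which(raw$segments == s & !is.na(frame))
    li <- iy[ev] + ny * (iz[ev] - 1L + nz * frame[ev])
    vals <- matrix(raw$kspace[, , ev], n_coils * nx, length(ev))
    agg_re <- rowsum(t(Re(vals)), li)
    agg_im <- rowsum(t(Im(vals)), li)
    rows <- as.integer(rownames(agg_re))
    full <- matrix(0 + 0i, ny * nz * n_card, n_coils * nx)
    full[rows, ] <- complex(real = agg_re, imaginary = agg_im)
    cnt <- as.numeric(counts_nat[, , , s + 1L])
    cnt[cnt == 0] <- 1
    full <- full / cnt
    arr <- array(full, c(ny, nz, n_card, n_coils, nx))
    y[[s + 1L]] <- arr
  }
  structure(list(y = y,
                 mask = counts_nat >= 1L, counts = counts_nat,
                 n_card = n_card, n_discard = mask$n_discard,
                 frame_duration = mask$frame_duration,
                 shape = sh, n_coils = n_coils),
            class = "binned_kspace")
}

# batched orthonormal 2D DFT over the first two dims of a 4D array
fft_yz4 <- function(a, inverse = FALSE) {
  d <- dim(a)
  m1 <- stats::mvfft(matrix(a, d[1], prod(d[-1])), inverse = inverse)
  a <- aperm(array(m1, d), c(2, 1, 3, 4))
  m2 <- stats::mvfft(matrix(a, d[2], prod(d[-2])), inverse = inverse)
  a <- aperm(array(m2, d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  a / sqrt(d[1] * d[2])
}

# coil maps in operator layout: list over coils of (ny, nz, nx), plus the
# voxel-wise sum of squared magnitudes
coil_operator_maps <- function(coil_maps) {
  n_coils <- dim(coil_maps)[4]
  s <- lapply(seq_len(n_coils), function(c_i) {
    aperm(coil_maps[, , , c_i, drop = FALSE][, , , 1], c(2, 3, 1))
  })
  den <- Reduce(`+`, lapply(s, function(m) Mod(m)^2))
  list(s = s, den = den)
}

#' Zero-filled reconstruction
#'
#' Adjoint of the undersampling Fourier operator (unsampled cells stay
#' zero, duplicates already count-averaged at binning) followed by
#' sensitivity-weighted coil combination. Serves as the linear baseline
#' against the compressed-sensing solver and as its initialization.
#'
#' @param binned a [bin_kspace()] result.
#' @param coil_maps the coil sensitivity array used in simulation.
#' @return object of class `image_series`: list with `m` (one complex
#'   array of dim (x, y, z, frame) per flow segment) plus binning
#'   metadata.
#' @export
zero_filled <- function(binned, coil_maps) {
  stopifnot(inherits(binned, "binned_kspace"))
  sh <- binned$shape
  if (!all(dim(coil_maps)[1:3] == sh) ||
      dim(coil_maps)[4] != binned$n_coils) {
    stop("coil map dimensions do not match the data", call. = FALSE)
  }
  cop <- coil_operator_maps(coil_maps)
  n_flow <- length(binned$y)
  out <- vector("list", n_flow)
  for (s in seq_len(n_flow)) {
    # (ky, kz, frame, coil, x) -> per coil (ky, kz, x, frame)
    dy <- dim(binned$y[[s]])
    num <- 0
    for (c_i in seq_len(binned$n_coils)) {
      yp <- aperm(array(binned$y[[s]][, , , c_i, ], dy[c(1, 2, 3, 5)]),
                  c(1, 2, 4, 3))
      num <- num + as.vector(Conj(cop$s[[c_i]])) *
        fft_yz4(yp, inverse = TRUE)
    }
    mp <- num / as.vector(pmax(cop$den, 1e-12))
    out[[s]] <- aperm(mp, c(3, 1, 2, 4))   # -> (x, y, z, frame)
  }
  structure(list(m = out, n_card = binned$n_card,
                 n_discard = binned$n_discard,
                 frame_duration = binned$frame_duration,
                 objective = NULL),
            class = "image_series")
}

# cyclic first-order temporal difference of a (nvox x T) matrix
tdiff <- function(x) x[, c(seq_len(ncol(x))[-1], 1L), drop = FALSE] - x
tdiff_adj <- function(p) {
  p[, c(ncol(p), seq_len(ncol(p) - 1L)), drop = FALSE] - p
}

tv_value <- function(m_mat) sum(Mod(tdiff(m_mat)))

# complex soft-thresholding (modulus shrinkage)
soft_threshold <- function(x, gamma) {
  mag <- Mod(x)
  shrink <- pmax(mag - gamma, 0) / pmax(mag, 1e-300)
  x * shrink
}

#' Compressed-sensing reconstruction with temporal total variation
#'
#' Approximately solves, per flow segment,
#' \deqn{\hat m = \arg\min_m \tfrac12 \|F_U m - y\|_2^2 +
#'   \lambda \, \mathrm{TV}_t(m)}
#' where F_U is the coil-weighted undersampling Fourier operator and TV_t
#' is the l1 norm of first-order temporal differences, cyclic over the
#' cardiac cycle. The solver splits the temporal differences into an
#' auxiliary variable (ADMM): the image update solves a regularized
#' least-squares system by warm-started conjugate gradients, the split
#' variable update is a complex soft-thresholding, and the scaled dual
#' ascends. It is initialized at the zero-filled image; data are
#' internally normalized so the zero-filled peak magnitude is 1, making
#' `lambda` scale-free. The per-iteration objective values are attached
#' to the result.
#'
#' @param binned a [bin_kspace()] result.
#' @param coil_maps coil sensitivity array.
#' @param config a [recon_config()].
#' @return an `image_series` like [zero_filled()], with an `objective`
#'   field (one numeric trace per flow segment, length iterations + 1).
#' @export
cs_recon <- function(binned, coil_maps, config = recon_config()) {
  stopifnot(inherits(binned, "binned_kspace"),
            inherits(config, "recon_config"))
  zf <- zero_filled(binned, coil_maps)
  sh <- binned$shape
  ny <- sh[2]; nz <- sh[3]; nx <- sh[1]
  n_card <- binned$n_card
  n_coils <- binned$n_coils
  cop <- coil_operator_maps(coil_maps)
  s_vec <- lapply(cop$s, as.vector)
  n_flow <- length(binned$y)
  out <- vector("list", n_flow)
  traces <- vector("list", n_flow)
  op_dims <- c(ny, nz, nx, n_card)
  as_mat <- function(a) matrix(a, ny * nz * nx, n_card)
  as_arr <- function(mm) array(mm, op_dims)
  cdot <- function(a, b) sum(Re(Conj(a) * b))
  for (s in seq_len(n_flow)) {
    dy <- dim(binned$y[[s]])
    if (!all(is.finite(Re(binned$y[[s]]))) ||
        !all(is.finite(Im(binned$y[[s]])))) {
      stop("non-finite k-space data", call. = FALSE)
    }
    # data and mask in operator layout (ky, kz, x, frame)
    yp <- lapply(seq_len(n_coils), function(c_i) {
      aperm(array(binned$y[[s]][, , , c_i, ], dy[c(1, 2, 3, 5)]),
            c(1, 2, 4, 3))
    })
    msk <- array(binned$mask[, , , s], c(ny, nz, n_card))
    mexp <- aperm(array(msk, c(ny, nz, n_card, nx)), c(1, 2, 4, 3))
    if (sum(msk) == 0) stop("empty sampling mask", call. = FALSE)
    scale <- max(Mod(zf$m[[s]]))
    if (scale == 0) scale <- 1
    yp <- lapply(yp, function(a) a / scale)
    m <- aperm(zf$m[[s]], c(2, 3, 1, 4)) / scale   # (y, z, x, frame)
    # normal operator A^H A and right-hand side A^H y
    AtA <- function(m) {
      acc <- 0
      for (c_i in seq_len(n_coils)) {
        k <- fft_yz4(m * s_vec[[c_i]]) * mexp
        acc <- acc + Conj(s_vec[[c_i]]) * fft_yz4(k, inverse = TRUE)
      }
      acc
    }
    misfit_of <- function(m) {
      mis <- 0
      for (c_i in seq_len(n_coils)) {
        k <- fft_yz4(m * s_vec[[c_i]]) * mexp
        mis <- mis + sum(Mod(k - yp[[c_i]])^2)
      }
      mis
    }
    Aty <- 0
    for (c_i in seq_len(n_coils)) {
      Aty <- Aty + Conj(s_vec[[c_i]]) * fft_yz4(yp[[c_i]],
                                                inverse = TRUE)
    }
    objective <- function(m) {
      0.5 * misfit_of(m) + config$lambda * tv_value(as_mat(m))
    }
    rho <- config$rho
    z <- tdiff(as_mat(m))
    u <- matrix(0 + 0i, nrow(z), ncol(z))
    obj <- objective(m)
    trace <- obj
    for (it in seq_len(config$iterations)) {
      # m-update: (A^H A + rho D^H D) m = A^H y + rho D^H (z - u), by
      # warm-started conjugate gradients
      rhs <- Aty + as_arr(tdiff_adj(z - u)) * rho
      Hx <- function(v) AtA(v) + rho * as_arr(tdiff_adj(tdiff(as_mat(v))))
      r <- rhs - Hx(m)
      p <- r
      rs <- cdot(r, r)
      for (cg in seq_len(config$cg_iters)) {
        if (rs < 1e-14) break
        hp <- Hx(p)
        alpha <- rs / cdot(p, hp)
        m <- m + alpha * p
        r <- r - alpha * hp
        rs_new <- cdot(r, r)
        p <- r + (rs_new / rs) * p
        rs <- rs_new
      }
      # z-update: complex soft-thresholding; dual ascent
      dm <- tdiff(as_mat(m))
      z <- soft_threshold(dm + u, config$lambda / rho)
      u <- u + dm - z
      obj <- objective(m)
      trace <- c(trace, obj)
    }
    out[[s]] <- aperm(m, c(3, 1, 2, 4)) * scale   # back to (x, y, z, f)
    traces[[s]] <- trace
  }
  structure(list(m = out, n_card = n_card, n_discard = binned$n_discard,
                 frame_duration = binned$frame_duration,
                 objective = traces),
            class = "image_series")
}

#' Decode velocities from four-point flow-encoded images
#'
#' Referenced four-point decoding: per direction d, voxel and frame,
#' v_d = Arg(m_d conj(m_ref)) / pi * venc, which wraps into
#' (-venc, venc]. The magnitude output is |m_ref|.
#'
#' @param series an `image_series` with the reference segment first and
#'   the x, y, z flow encodings after it.
#' @param venc velocity-encoding sensitivity in cm/s.
#' @return object of class `velocity_series`: arrays `vx`, `vy`, `vz`
#'   (cm/s) and `magnitude`, each of dim (x, y, z, frame), plus `venc` and
#'   binning metadata.
#' @export
velocity_decode <- function(series, venc = 150) {
  stopifnot(inherits(series, "image_series"), length(series$m) == 4L)
  if (venc <= 0) stop("'venc' must be positive", call. = FALSE)
  ref <- series$m[[1]]
  dec <- lapply(2:4, function(d) Arg(series$m[[d]] * Conj(ref)) / pi * venc)
  structure(list(vx = dec[[1]], vy = dec[[2]], vz = dec[[3]],
                 magnitude = Mod(ref), venc = venc,
                 n_card = series$n_card, n_discard = series$n_discard,
                 frame_duration = series$frame_duration),
            class = "velocity_series")
}

#' Static-tissue phase-offset correction
#'
#' Optional linear background-phase correction: per velocity direction,
#' fits a first-order 3D polynomial to the time-averaged velocity over
#' static voxels and subtracts the fitted field from every frame. Off by
#' default in synthetic pipelines (the simulator introduces no offsets).
#'
#' @param vel a [velocity_decode()] result.
#' @param static_mask logical array of static-tissue voxels.
#' @param enabled set FALSE to bypass (identity).
#' @return corrected `velocity_series`.
#' @export
static_phase_offset_correct <- function(vel, static_mask,
                                        enabled = TRUE) {
  stopifnot(inherits(vel, "velocity_series"))
  if (!enabled) return(vel)
  if (!any(static_mask)) stop("static mask is empty", call. = FALSE)
  sh <- dim(vel$vx)[1:3]
  idx <- which(static_mask, arr.ind = TRUE)
  grids <- expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]),
                       z = seq_len(sh[3]))
  for (comp in c("vx", "vy", "vz")) {
    v <- vel[[comp]]
    vbar <- apply(v, 1:3, mean)
    df <- data.frame(v = vbar[static_mask],
                     x = idx[, 1], y = idx[, 2], z = idx[, 3])
    X <- cbind(1, df$x, df$y, df$z)
    if (qr(X)$rank < 4L) {
      warning("degenerate static mask; constant-only offset fit")
      fitted_field <- array(mean(df$v), sh)
    } else {
      fit <- stats::lm(v ~ x + y + z, data = df)
      fitted_field <- array(
        stats::predict(fit, newdata = grids), sh)
    }
    for (f in seq_len(dim(v)[4])) {
      v[, , , f] <- v[, , , f] - fitted_field
    }
    vel[[comp]] <- v
  }
  vel
}

#' Ground-truth velocity series at frame centers
#'
#' Samples the analytic phantom velocity field at the nominal center time
#' of each cardiac frame, for oracle comparisons against reconstructed
#' series.
#'
#' @param geometry a [vessel_geometry()].
#' @param waveform a [flow_waveform()].
#' @param n_card number of frames.
#' @param frame_duration frame length in ms.
#' @param n_discard trailing discard flags to carry (default 0).
#' @return a `velocity_series`.
#' @export
ground_truth_velocity <- function(geometry, waveform, n_card,
                                  frame_duration, n_discard = 0L) {
  sh <- geometry$shape
  mk <- function() array(0, c(sh, n_card))
  out <- list(vx = mk(), vy = mk(), vz = mk())
  for (f in seq_len(n_card)) {
    t_f <- (f - 0.5) * frame_duration
    vf <- velocity_field(geometry, waveform, t_f)
    out$vx[, , , f] <- vf$vx
    out$vy[, , , f] <- vf$vy
    out$vz[, , , f] <- vf$vz
  }
  structure(c(out, list(magnitude = array(0.3 + 0.7 * geometry$lumen,
                                          c(sh, n_card)),
                        venc = NA_real_, n_card = n_card,
                        n_discard = n_discard,
                        frame_duration = frame_duration)),
            class = "velocity_series")
}

#' Normalized root-mean-square error over a region
#'
#' NRMSE = ||est - ref|| / ||ref|| over the voxels of `mask`, pooled
#' across frames; accepts complex image arrays or real velocity arrays.
#'
#' @param est,ref arrays of dim (x, y, z, frame).
#' @param mask logical array of dim (x, y, z).
#' @return scalar NRMSE.
#' @export
nrmse <- function(est, ref, mask) {
  n_f <- dim(ref)[4]
  sel <- array(rep(mask, n_f), dim(ref))
  sqrt(sum(Mod(est[sel] - ref[sel])^2) / sum(Mod(ref[sel])^2))
}
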