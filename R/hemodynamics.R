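#' ROI plane for flow quantification
#'
#' A cross-sectional region of interest: one slice of the volume along a
#' chosen axis with an in-plane lumen mask, used to integrate through-plane
#' velocity into a flow rate.
#'
#' @param lumen logical 3D lumen mask.
#' @param slice slice index along `axis`.
#' @param axis plane-normal axis (1, 2 or 3).
#' @param voxel_mm isotropic voxel size in mm.
#' @return object of class `roi_plane`.
#' @export
roi_plane <- function(lumen, slice, axis = 1L, voxel_mm = 0.8) {
  stopifnot(axis %in% 1:3, slice >= 1, slice <= dim(lumen)[axis])
  mask2d <- switch(axis,
                   lumen[slice, , ],
                   lumen[, slice, ],
                   lumen[, , slice])
  if (!any(mask2d)) stop("ROI mask is empty", call. = FALSE)
  structure(list(mask2d = mask2d, slice = as.integer(slice),
                 axis = as.integer(axis),
                 pixel_area_mm2 = voxel_mm^2),
            class = "roi_plane")
}

#' Time-resolved flow rate through an ROI plane
#'
#' Q(t) = sum over ROI pixels of the through-plane velocity component
#' times the pixel area, per cardiac frame, in ml/s. The through-plane
#' component (not the speed) is integrated so that retrograde flow carries
#' its sign.
#'
#' @param vel a `velocity_series`.
#' @param roi a [roi_plane()].
#' @return object of class `flow_curve`: list with `q_mlps` (length
#'   n_card), `discard` (logical flags for the trailing frames excluded
#'   from flow-curve analysis) and `frame_duration`.
#' @export
flow_rate <- function(vel, roi) {
  stopifnot(inherits(vel, "velocity_series"), inherits(roi, "roi_plane"))
  comp <- switch(roi$axis, vel$vx, vel$vy, vel$vz)
  n_card <- vel$n_card
  q <- numeric(n_card)
  for (f in seq_len(n_card)) {
    vol <- comp[, , , f]
    plane <- switch(roi$axis,
                    vol[roi$slice, , ],
                    vol[, roi$slice, ],
                    vol[, , roi$slice])
    # cm/s * mm^2 -> ml/s carries a factor 0.01
    q[f] <- sum(plane[roi$mask2d]) * roi$pixel_area_mm2 * 0.01
  }
  discard <- rep(FALSE, n_card)
  nd <- if (is.null(vel$n_discard)) 0L else vel$n_discard
  if (nd > 0) discard[(n_card - nd + 1L):n_card] <- TRUE
  structure(list(q_mlps = q, discard = discard,
                 frame_duration = vel$frame_duration),
            class = "flow_curve")
}

#' Peak-systolic frame
#'
#' The cardiac frame with the highest absolute velocity (speed) averaged
#' over the segmented volume, searched over non-discarded frames only;
#' ties resolve to the earliest frame.
#'
#' @param vel a `velocity_series`.
#' @param lumen logical 3D mask of the segmented volume.
#' @param n_discard trailing frames to exclude (default: the series' own
#'   discard setting, else 0).
#' @return 1-based frame index.
#' @export
peak_systole_frame <- function(vel, lumen, n_discard = NULL) {
  stopifnot(inherits(vel, "velocity_series"), any(lumen))
  if (is.null(n_discard)) {
    n_discard <- if (is.null(vel$n_discard)) 0L else vel$n_discard
  }
  n_use <- vel$n_card - n_discard
  speeds <- vapply(seq_len(n_use), function(f) {
    sp <- sqrt(vel$vx[, , , f]^2 + vel$vy[, , , f]^2 + vel$vz[, , , f]^2)
    mean(sp[lumen])
  }, 0)
  which.max(speeds)
}

#' Extract a wall mesh from a lumen mask
#'
#' Surfel extraction at the 0.5 iso-level of the binary mask: one wall
#' point per face between a lumen voxel and a background voxel, placed at
#' the face center. Inward unit normals are taken from the gradient of a
#' Gaussian-smoothed copy of the mask (the gradient of the lumen indicator
#' points into the lumen), evaluated by central differences at the face's
#' voxel pair.
#'
#' @param lumen logical 3D lumen mask (must have both interior and
#'   exterior voxels).
#' @param voxel_mm isotropic voxel size in mm.
#' @return object of class `wall_mesh`: `points` (N x 3, mm, zero-centered
#'   grid coordinates), `normals` (N x 3, unit, inward), `voxel_mm`,
#'   `shape`.
#' @export
wall_mesh <- function(lumen, voxel_mm = 0.8) {
  sh <- dim(lumen)
  if (!any(lumen) || all(lumen)) {
    stop("lumen mask must have interior and exterior", call. = FALSE)
  }
  sm <- smooth3_gauss(array(as.numeric(lumen), sh), sigma = 1.2)
  grad <- function(d) {
    g <- array(0, sh)
    n <- sh[d]
    lo <- rep(list(quote(expr = )), 3); hi <- lo; ce <- lo
    lo[[d]] <- 1:(n - 2); hi[[d]] <- 3:n; ce[[d]] <- 2:(n - 1)
    g_ce <- do.call(`[`, c(list(sm), hi)) - do.call(`[`, c(list(sm), lo))
    g <- do.call(`[<-`, c(list(g), ce, list(g_ce / 2)))
    g
  }
  gx <- grad(1); gy <- grad(2); gz <- grad(3)
  pts <- NULL; nrm <- NULL
  li <- which(lumen, arr.ind = TRUE)
  for (d in 1:3) {
    for (sgn in c(-1L, 1L)) {
      nb <- li
      nb[, d] <- nb[, d] + sgn
      inside <- nb[, d] >= 1 & nb[, d] <= sh[d]
      # neighbors outside the grid are open ends (the vessel continues),
      # not wall
      is_bg <- rep(FALSE, nrow(nb))
      is_bg[inside] <- !lumen[nb[inside, , drop = FALSE]]
      face <- li[is_bg, , drop = FALSE]
      if (nrow(face) == 0) next
      p <- face
      p[, d] <- p[, d] + sgn * 0.5
      g <- cbind(gx[face], gy[face], gz[face])
      pts <- rbind(pts, p)
      nrm <- rbind(nrm, g)
    }
  }
  len <- sqrt(rowSums(nrm^2))
  ok <- len > 1e-9
  pts <- pts[ok, , drop = FALSE]
  nrm <- nrm[ok, , drop = FALSE] / len[ok]
  coords <- sapply(1:3, function(d) grid_coord(pts[, d], sh[d], voxel_mm))
  structure(list(points = coords, points_vox = pts, normals = nrm,
                 voxel_mm = voxel_mm, shape = sh),
            class = "wall_mesh")
}

# deterministic local wall frame: z' = inward normal, x' orthogonal to it
# built from the global axis with the smallest |n| component, y' = z' x x'
local_wall_frames <- function(normals) {
  n_pts <- nrow(normals)
  a_idx <- apply(abs(normals), 1, which.min)
  e <- diag(3)
  xprime <- matrix(0, n_pts, 3)
  for (i in seq_len(n_pts)) {
    v <- e[a_idx[i], ] - sum(e[a_idx[i], ] * normals[i, ]) * normals[i, ]
    xprime[i, ] <- v / sqrt(sum(v^2))
  }
  yprime <- cbind(
    normals[, 2] * xprime[, 3] - normals[, 3] * xprime[, 2],
    normals[, 3] * xprime[, 1] - normals[, 1] * xprime[, 3],
    normals[, 1] * xprime[, 2] - normals[, 2] * xprime[, 1])
  list(xprime = xprime, yprime = yprime)
}

#' Wall shear stress at one cardiac frame
#'
#' Computes the viscous wall shear stress vector tau = 2 eta (rate-of-
#' deformation tensor) . n at every wall point, using the standard
#' simplification in a local frame whose z' axis is the inward normal and
#' assuming no through-wall flow: tau = eta (dv_x'/dz', dv_y'/dz', 0),
#' rotated back to global coordinates. Tangential velocity components are
#' sampled at `k` points spaced one voxel apart along the inward normal
#' (trilinear interpolation; the wall sample itself is clamped to zero by
#' the no-slip assumption) and differentiated at the wall by a quadratic
#' least-squares fit through the samples. Wall points whose normal ray
#' leaves the grid are excluded and counted.
#'
#' @param vel a `velocity_series` (cm/s).
#' @param frame 1-based frame to evaluate.
#' @param mesh a [wall_mesh()].
#' @param eta dynamic viscosity in Pa s (default 3.2e-3, blood).
#' @param k number of samples along the normal (default 4).
#' @return object of class `wss_field`: `tau` (N x 3, Pa, global frame),
#'   `tau_mag`, `points`, `normals`, `n_excluded`, `eta`.
#' @export
wss <- function(vel, frame, mesh, eta = 3.2e-3, k = 4L) {
  stopifnot(inherits(vel, "velocity_series"), inherits(mesh, "wall_mesh"),
            k >= 3)
  sh <- mesh$shape
  h_mm <- mesh$voxel_mm
  n_pts <- nrow(mesh$normals)
  vx <- vel$vx[, , , frame]; vy <- vel$vy[, , , frame]
  vz <- vel$vz[, , , frame]
  # sample positions in voxel coordinates, j = 0..k-1 along the normal
  samp <- array(NA_real_, c(n_pts, k, 3))   # velocity components, cm/s
  valid <- rep(TRUE, n_pts)
  for (j in seq_len(k) - 1L) {
    pv <- mesh$points_vox + j * mesh$normals   # spacing = 1 voxel
    sx <- interp3_trilinear(vx, pv)
    sy <- interp3_trilinear(vy, pv)
    sz <- interp3_trilinear(vz, pv)
    bad <- is.na(sx) | is.na(sy) | is.na(sz)
    valid <- valid & !bad
    samp[, j + 1L, 1] <- sx
    samp[, j + 1L, 2] <- sy
    samp[, j + 1L, 3] <- sz
  }
  frames <- local_wall_frames(mesh$normals)
  # tangential components, k x N, converted cm/s -> m/s
  u <- matrix(0, k, n_pts); w <- matrix(0, k, n_pts)
  for (j in seq_len(k)) {
    u[j, ] <- 0.01 * rowSums(samp[, j, ] * frames$xprime)
    w[j, ] <- 0.01 * rowSums(samp[, j, ] * frames$yprime)
  }
  u[1, ] <- 0; w[1, ] <- 0   # no-slip clamp at the wall sample
  u[is.na(u)] <- 0; w[is.na(w)] <- 0
  # quadratic LS fit v(z') = b z' + c z'^2 through the origin;
  # derivative at the wall is b. z' in meters.
  z <- (seq_len(k) - 1) * h_mm * 1e-3
  Z <- cbind(z, z^2)
  P <- solve(crossprod(Z), t(Z))   # 2 x k pseudo-inverse
  b_u <- (P %*% u)[1, ]
  b_w <- (P %*% w)[1, ]
  tau <- eta * (b_u * frames$xprime + b_w * frames$yprime)
  tau[!valid, ] <- NA_real_
  structure(list(tau = tau, tau_mag = sqrt(rowSums(tau^2)),
                 points = mesh$points, normals = mesh$normals,
                 valid = valid, n_excluded = sum(!valid), eta = eta,
                 voxel_mm = mesh$voxel_mm, frame = frame),
            class = "wss_field")
}

#' Pair values against a reference geometry
#'
#' For voxel-wise statistics across scans: WSS fields are paired by
#' nearest reference wall point (pairs farther than `max_dist_vox` voxels
#' are dropped and counted); velocity series are paired voxel-wise on the
#' reference lumen grid (identical grids in synthetic runs, where
#' registration is the identity).
#'
#' @param field a `wss_field`, or a `velocity_series` plus `frame`.
#' @param reference the reference `wss_field` (or reference
#'   `velocity_series`) to pair against.
#' @param lumen for velocity pairing: logical mask of reference voxels.
#' @param frame for velocity pairing: frame index in each series.
#' @param max_dist_vox pairing distance cutoff in voxels (default 2).
#' @return list with `reference`, `test` (aligned numeric vectors),
#'   `n_dropped`.
#' @export
resample_to_reference <- function(field, reference, lumen = NULL,
                                  frame = NULL, max_dist_vox = 2) {
  if (inherits(field, "wss_field")) {
    stopifnot(inherits(reference, "wss_field"))
    ok_t <- field$valid & is.finite(field$tau_mag)
    ok_r <- reference$valid & is.finite(reference$tau_mag)
    pt <- field$points[ok_t, , drop = FALSE]
    pr <- reference$points[ok_r, , drop = FALSE]
    if (nrow(pt) == 0 || nrow(pr) == 0) {
      stop("no valid wall points to pair", call. = FALSE)
    }
    # nearest reference point per test point (blocked brute force)
    nn_idx <- integer(nrow(pt)); nn_d <- numeric(nrow(pt))
    block <- 2000L
    for (start in seq(1L, nrow(pt), by = block)) {
      sel <- start:min(start + block - 1L, nrow(pt))
      d2 <- outer(rowSums(pt[sel, , drop = FALSE]^2),
                  rowSums(pr^2), `+`) -
        2 * pt[sel, , drop = FALSE] %*% t(pr)
      nn_idx[sel] <- max.col(-d2, ties.method = "first")
      nn_d[sel] <- sqrt(pmax(d2[cbind(seq_along(sel), nn_idx[sel])], 0))
    }
    keep <- nn_d <= max_dist_vox * field$voxel_mm
    if (!any(keep)) {
      return(list(reference = numeric(0), test = numeric(0),
                  n_dropped = length(keep)))
    }
    list(reference = reference$tau_mag[ok_r][nn_idx[keep]],
         test = field$tau_mag[ok_t][keep],
         n_dropped = sum(!keep))
  } else if (inherits(field, "velocity_series")) {
    stopifnot(inherits(reference, "velocity_series"), !is.null(lumen),
              !is.null(frame))
    sp <- function(v, f) {
      sqrt(v$vx[, , , f]^2 + v$vy[, , , f]^2 + v$vz[, , , f]^2)
    }
    f2 <- if (length(frame) == 2L) frame[2] else frame
    list(reference = sp(reference, frame[1])[lumen],
         test = sp(field, f2)[lumen], n_dropped = 0L)
  } else {
    stop("unsupported field type", call. = FALSE)
  }
}

#' Stroke volume from a flow curve
#'
#' Rectangle-rule integral SV = sum of Q(t) * frame_duration over
#' non-discarded frames, in ml.
#'
#' @param curve a [flow_rate()] result.
#' @param frame_duration frame length in ms (default: the curve's own).
#' @return stroke volume in ml.
#' @export
stroke_volume <- function(curve, frame_duration = NULL) {
  stopifnot(inherits(curve, "flow_curve"))
  if (is.null(frame_duration)) frame_duration <- curve$frame_duration
  use <- !curve$discard
  if (sum(use) < 2) stop("need at least 2 non-discarded frames",
                         call. = FALSE)
  sum(curve$q_mlps[use]) * frame_duration / 1000
}
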