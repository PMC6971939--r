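#' Cardiac timeline
#'
#' Holds the ECG R-top (R-wave peak) times of a retrospectively gated
#' acquisition, plus the nominal RR interval used to fix the reconstructed
#' frame duration.
#'
#' @param r_top_times strictly increasing R-top times in ms from scan start
#'   (at least two).
#' @param nominal_rr nominal RR interval in ms; defaults to the mean
#'   observed interval.
#' @return object of class `cardiac_timeline`.
#' @export
cardiac_timeline <- function(r_top_times,
                             nominal_rr = mean(diff(r_top_times))) {
  if (length(r_top_times) < 2L) {
    stop("need at least 2 R-top times", call. = FALSE)
  }
  if (any(diff(r_top_times) <= 0)) {
    stop("R-top times must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(nominal_rr) || nominal_rr <= 0) {
    stop("'nominal_rr' must be positive", call. = FALSE)
  }
  structure(list(r_top_times = as.numeric(r_top_times),
                 nominal_rr = nominal_rr),
            class = "cardiac_timeline")
}

#' Absolute cardiac binning configuration
#'
#' "Absolute" binning assigns each acquired readout to cardiac frame
#' floor((t - preceding R-top) / frame_duration) with a fixed frame duration
#' derived from the nominal RR interval, rather than stretching each beat.
#' Frames beyond `n_card` (events late in long beats) are rejected. The last
#' `n_discard` frames receive systematically less data under RR variability
#' and are flagged so flow-curve analysis can exclude them.
#'
#' @param n_card number of reconstructed cardiac frames (>= 2).
#' @param nominal_rr nominal RR in ms used to derive `frame_duration`.
#' @param frame_duration frame length in ms (default `nominal_rr / n_card`).
#' @param n_discard trailing frames flagged for exclusion from flow-curve
#'   analysis (default 2, phantom-style; 3 is typical in vivo).
#' @return object of class `binning_config`.
#' @export
binning_config <- function(n_card, nominal_rr = 1000,
                           frame_duration = nominal_rr / n_card,
                           n_discard = 2L) {
  if (n_card < 2) stop("'n_card' must be >= 2", call. = FALSE)
  if (n_discard < 0 || n_discard >= n_card) {
    stop("'n_discard' must be in [0, n_card)", call. = FALSE)
  }
  if (!is.finite(frame_duration) || frame_duration <= 0) {
    stop("'frame_duration' must be positive", call. = FALSE)
  }
  structure(list(n_card = as.integer(n_card),
                 frame_duration = frame_duration,
                 n_discard = as.integer(n_discard)),
            class = "binning_config")
}

#' Assign events to cardiac frames
#'
#' Vectorized absolute binning: each event time is referred to the
#' preceding R-top and mapped to frame floor(delay / frame_duration) on the
#' half-open convention [k*dur, (k+1)*dur). Events before the first R-top
#' or with frame index >= n_card are rejected (NA).
#'
#' @param t_event event times in ms.
#' @param timeline a [cardiac_timeline()].
#' @param config a [binning_config()].
#' @return integer vector of 0-based frame indices, NA where rejected.
#' @export
assign_frame <- function(t_event, timeline, config) {
  stopifnot(inherits(timeline, "cardiac_timeline"),
            inherits(config, "binning_config"))
  beat <- findInterval(t_event, timeline$r_top_times)
  frame <- rep(NA_integer_, length(t_event))
  ok <- beat >= 1L
  delay <- t_event[ok] - timeline$r_top_times[beat[ok]]
  f <- as.integer(floor(delay / config$frame_duration))
  f[f >= config$n_card] <- NA_integer_
  frame[ok] <- f
  frame
}

#' Build per-flow-segment k-t sampling masks
#'
#' Bins every event of a sampling schedule onto the
#' (ky, kz, frame, flow_segment) grid via absolute cardiac binning, keeping
#' a sample count per cell (duplicate acquisitions of the same profile in
#' the same frame and segment are merged by count and later averaged at
#' reconstruction). Each flow-encoding segment is binned independently. The
#' boolean mask (count >= 1) is the support of the undersampling Fourier
#' operator.
#'
#' @param schedule a [build_schedule()] result.
#' @param timeline a [cardiac_timeline()] covering the schedule.
#' @param config a [binning_config()].
#' @return object of class `kt_mask`: list with `counts` and logical `mask`
#'   arrays of dim (matrix_ky, matrix_kz, n_card, N_flow) indexed so that
#'   ky = -matrix_ky/2 maps to index 1, `frame` (per event, NA = rejected),
#'   `n_rejected`, and the discard flags of `config`.
#' @export
build_kt_mask <- function(schedule, timeline, config) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  params <- attr(schedule, "params")
  n_flow <- attr(schedule, "spec")$N_flow
  frame <- assign_frame(schedule$acquisition_time, timeline, config)
  keep <- !is.na(frame)
  if (!any(keep)) {
    stop("no schedule event falls inside the cardiac timeline",
         call. = FALSE)
  }
  dims <- c(params$matrix_ky, params$matrix_kz, config$n_card, n_flow)
  counts <- array(0L, dims)
  i_ky <- schedule$ky[keep] + params$matrix_ky / 2 + 1L
  i_kz <- schedule$kz[keep] + params$matrix_kz / 2 + 1L
  i_fr <- frame[keep] + 1L
  i_sg <- schedule$flow_segment[keep] + 1L
  lin <- i_ky + dims[1] * (i_kz - 1L + dims[2] *
           (i_fr - 1L + dims[3] * (i_sg - 1L)))
  tab <- tabulate(lin, nbins = prod(dims))
  counts[] <- tab
  structure(list(counts = counts, mask = counts >= 1L,
                 frame = frame, n_rejected = sum(!keep),
                 n_card = config$n_card, n_discard = config$n_discard,
                 frame_duration = config$frame_duration),
            class = "kt_mask")
}

#' Effective acceleration factor of a k-t mask
#'
#' Ratio of the fully sampled k-line count (the size of the whole
#' (ky, kz, frame, segment) index set) to the number of actually sampled
#' k-lines, computed retrospectively after binning.
#'
#' @param mask a [build_kt_mask()] result.
#' @return dimensionless effective R.
#' @export
effective_R <- function(mask) {
  stopifnot(inherits(mask, "kt_mask"))
  n_sampled <- sum(mask$mask)
  if (n_sampled == 0L) stop("mask has no sampled entries", call. = FALSE)
  length(mask$mask) / n_sampled
}
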