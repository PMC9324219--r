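# Golden-angle radial trajectory: spoke angles, k-space coordinates,
# density compensation, and binning of spokes into time frames.

#' Golden-angle increment in degrees
#'
#' The small golden angle, 180 * (sqrt(5) - 1) / 2 = 111.246 degrees (to three
#' decimals). Successive radial readout directions are rotated by this
#' increment, which yields near-uniform angular coverage for any window
#' length.
#' @export
golden_angle <- function() 180 * (sqrt(5) - 1) / 2

#' Golden-angle spoke angles
#'
#' @param n_spokes number of spokes.
#' @return numeric vector of angles in degrees, stored modulo 360;
#'   `angle[i] = (i - 1) * 111.246 mod 360`.
#' @examples
#' golden_angles(3)
#' @export
golden_angles <- function(n_spokes) {
  stopifnot(n_spokes >= 1)
  ((seq_len(n_spokes) - 1) * golden_angle()) %% 360
}

#' Sample coordinates along one radial spoke
#'
#' Coordinates are in cycles/pixel; `n_samples` points uniformly span
#' [-0.5, 0.5) along the readout direction with the centre sample exactly at
#' k = 0 (even `n_samples`; Nyquist sampling along the spoke when
#' `n_samples` equals the matrix size).
#'
#' @param angle spoke angle in degrees.
#' @param n_samples number of readout samples (>= 2).
#' @return matrix with columns `kx`, `ky`.
#' @export
spoke_coords <- function(angle, n_samples) {
  stopifnot(n_samples >= 2)
  j <- seq_len(n_samples) - 1 - n_samples %/% 2
  k <- j / n_samples
  th <- angle * pi / 180
  cbind(kx = k * cos(th), ky = k * sin(th))
}

#' Ram-Lak density-compensation weights for one spoke
#'
#' Radial sampling density falls off as 1/|k|, so gridding uses ramp weights
#' proportional to |k|. The centre sample (k = 0) is assigned the finite
#' weight 1/(4 n), the area-equivalent value for the central disc of the
#' polar sampling pattern. Weights are normalized to mean 1; the mean of the
#' raw ramp is attached as attribute `raw_mean` for use in absolute-scale
#' gridding.
#'
#' @param n_samples number of readout samples (>= 2).
#' @return numeric weights, mean 1.
#' @export
ramlak_weights <- function(n_samples) {
  stopifnot(n_samples >= 2)
  j <- seq_len(n_samples) - 1 - n_samples %/% 2
  w <- abs(j) / n_samples
  w[j == 0] <- 1 / (4 * n_samples)
  m <- mean(w)
  out <- w / m
  attr(out, "raw_mean") <- m
  out
}

#' Bin spokes into reconstruction time frames
#'
#' Consecutive, non-overlapping bins of `spokes_per_frame` spokes per
#' velocity encoding. The two encodings of a pair share a spoke angle and a
#' frame index, so the frame duration is
#' `spokes_per_frame * n_encodings * tr` (168 ms for 8 spokes, 2 encodings,
#' TR 10.5 ms). A trailing partial frame is discarded.
#'
#' @param n_spokes_per_encoding spokes available in each encoding.
#' @param spokes_per_frame spokes per frame and encoding (>= 1).
#' @param tr repetition time in ms.
#' @param n_encodings number of interleaved velocity encodings (default 2).
#' @return list with `frame` (frame index per spoke, `NA` for discarded
#'   trailing spokes), `n_frames`, `frame_duration_s`, and `timestamps_s`
#'   (window centres).
#' @export
frame_bins <- function(n_spokes_per_encoding, spokes_per_frame, tr,
                       n_encodings = 2) {
  stopifnot(spokes_per_frame >= 1, tr > 0, n_encodings >= 1)
  n_frames <- n_spokes_per_encoding %/% spokes_per_frame
  if (n_frames < 1)
    stop("fewer spokes than one frame (", n_spokes_per_encoding, " < ",
         spokes_per_frame, ")")
  frame <- rep(seq_len(n_frames), each = spokes_per_frame)
  length(frame) <- n_spokes_per_encoding  # trailing spokes -> NA
  dur <- spokes_per_frame * n_encodings * tr / 1000
  list(frame = frame,
       n_frames = n_frames,
       frame_duration_s = dur,
       timestamps_s = (seq_len(n_frames) - 0.5) * dur)
}

#' Dump a trajectory description to CSV (debugging aid)
#'
#' @param angles spoke angles (degrees).
#' @param times spoke timestamps (s).
#' @param enc_sign encoding sign per spoke.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
trajectory_to_csv <- function(angles, times, enc_sign, path) {
  df <- data.frame(spoke_index = seq_along(angles) - 1L,
                   angle_deg = angles, time_s = times, enc_sign = enc_sign)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
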