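# Geometry calibration against a powder calibrant with known d-spacings.
# The sample-to-detector distance (SDD) is the dominant scale factor for q,
# so it is refined by matching observed calibrant peak positions, re-derived
# under each candidate SDD by fine-binned reduction, to the reference
# positions q_i = 2*pi/d_i.

#' Match observed peaks to reference d-spacings
#'
#' Each reference position `q_i = 2*pi/d_i` is matched to the nearest
#' still-unassigned observed peak within `tolerance`, in a greedy
#' nearest-distance order (smallest distances assigned first; an exact tie
#' is broken toward the lower-q observed peak).  Unmatched references are
#' reported.
#'
#' @param observed_peaks Observed peak positions, q nm^-1.
#' @param reference_d Reference d-spacings, nm.
#' @param tolerance Maximum match distance, nm^-1.
#' @return List with `pairs` (data.frame `q_ref`, `q_obs`, `distance`) and
#'   `unmatched_ref` (reference q values with no match).
#' @export
match_reference_peaks <- function(observed_peaks, reference_d,
                                  tolerance = 1.0) {
  if (length(observed_peaks) == 0 || length(reference_d) == 0)
    stop("observed_peaks and reference_d must be non-empty")
  q_ref <- sort(2 * pi / reference_d)
  obs <- sort(observed_peaks)
  d <- abs(outer(q_ref, obs, `-`))
  pairs <- data.frame(q_ref = numeric(0), q_obs = numeric(0),
                      distance = numeric(0))
  used_r <- logical(length(q_ref)); used_o <- logical(length(obs))
  repeat {
    d2 <- d
    d2[used_r, ] <- Inf; d2[, used_o] <- Inf
    if (all(!is.finite(d2)) || min(d2) >= tolerance) break
    # greedy: smallest distance; ties toward the lower-q observed peak
    best <- which(d2 == min(d2), arr.ind = TRUE)
    best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
    pairs <- rbind(pairs, data.frame(q_ref = q_ref[best[1]],
                                     q_obs = obs[best[2]],
                                     distance = d[best[1], best[2]]))
    used_r[best[1]] <- TRUE; used_o[best[2]] <- TRUE
  }
  if (nrow(pairs) == 0)
    stop("calibration impossible: no observed peak within tolerance of any reference")
  list(pairs = pairs[order(pairs$q_ref), ],
       unmatched_ref = q_ref[!used_r])
}

#' Calibrate the sample-to-detector distance against a powder calibrant
#'
#' Finds the SDD minimizing the sum of squared deviations between observed
#' calibrant peak positions and the reference positions `2*pi/d_i`.  For
#' each candidate SDD, the calibrant histogram is re-reduced with fine
#' binning (default 0.2 nm^-1), peaks are found and refined, and matched to
#' the references; unmatched references are penalized at the match
#' tolerance so that candidates explaining more peaks are preferred.  The
#' bracket `[0.5, 2] * sdd0` is scanned on a coarse grid and the best
#' neighborhood polished with [stats::optimize()].
#'
#' @param hist Calibrant `event_histogram`.
#' @param geom0 Initial [detector_geometry()] guess.
#' @param reference_d Reference d-spacings, nm.
#' @param reduction A [reduction_config()]; its `q_bin_width` is overridden
#'   by `fine_bin`.
#' @param fine_bin Fine q bin width for peak localization, nm^-1.
#' @param spectrum Optional source spectrum for acceptance normalization.
#' @param min_snr Peak-finding SNR threshold.
#' @param match_tolerance Peak-to-reference match tolerance, nm^-1.
#' @param n_grid Coarse-scan grid size over the SDD bracket.
#' @return Object of class `sdd_calibration`: `refined_sdd` (mm),
#'   `refined_beam_center`, `residual` (RMS of matched q deviations, nm^-1),
#'   `n_peaks_used`, `initial_sdd`, `initial_residual`.
#' @export
calibrate_sdd <- function(hist, geom0, reference_d,
                          reduction = reduction_config(),
                          fine_bin = 0.2, spectrum = NULL, min_snr = 3,
                          match_tolerance = 1.0, n_grid = 61) {
  validate_geometry(geom0)
  if (length(reference_d) == 0) stop("reference_d must be non-empty")
  cfg <- reduction
  cfg$q_bin_width <- fine_bin

  eval_sdd <- function(sdd) {
    geom <- geom0
    geom$sdd <- sdd
    prof <- radial_q_binning(hist, geom = geom, config = cfg,
                             spectrum = spectrum)
    pk <- tryCatch(find_peaks(prof, min_snr = min_snr, fit_refine = TRUE),
                   error = function(e) NULL)
    if (is.null(pk) || nrow(pk) == 0)
      return(list(sse = length(reference_d) * match_tolerance^2,
                  n = 0L, rms = NA_real_))
    m <- tryCatch(match_reference_peaks(pk$q_center, reference_d,
                                        tolerance = match_tolerance),
                  error = function(e) NULL)
    if (is.null(m))
      return(list(sse = length(reference_d) * match_tolerance^2,
                  n = 0L, rms = NA_real_))
    sse <- sum(m$pairs$distance^2) +
      length(m$unmatched_ref) * match_tolerance^2
    list(sse = sse, n = nrow(m$pairs),
         rms = sqrt(mean(m$pairs$distance^2)))
  }

  bracket <- c(0.5, 2) * geom0$sdd
  grid <- seq(bracket[1], bracket[2], length.out = n_grid)
  sse_grid <- vapply(grid, function(s) eval_sdd(s)$sse, numeric(1))
  i_best <- which.min(sse_grid)
  lo <- grid[max(1L, i_best - 1L)]
  hi <- grid[min(n_grid, i_best + 1L)]
  opt <- stats::optimize(function(s) eval_sdd(s)$sse, c(lo, hi),
                         tol = 1e-3 * geom0$sdd)
  best <- eval_sdd(opt$minimum)
  if (best$n == 0L)
    stop("calibration failed: no peaks matched at the optimal SDD; ",
         "check the calibrant data and reference spacings")
  init <- eval_sdd(geom0$sdd)
  structure(list(refined_sdd = opt$minimum,
                 refined_beam_center = geom0$beam_center,
                 residual = best$rms, n_peaks_used = best$n,
                 initial_sdd = geom0$sdd, initial_residual = init$rms),
            class = "sdd_calibration")
}

#' @export
print.sdd_calibration <- function(x, ...) {
  cat(sprintf("SDD calibration: %.2f mm (initial guess %.2f mm)\n",
              x$refined_sdd, x$initial_sdd))
  cat(sprintf("  RMS q residual %.4f nm^-1 over %d matched peak(s)\n",
              x$residual, x$n_peaks_used))
  invisible(x)
}
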