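# Synthetic ground truth and BOLD forward model. The simulator emulates the
# statistical structure the analysis assumes: per-direction Watson-shaped
# neural amplitudes by eccentricity band, first-order multiplicative
# carry-over modulation, reproducible per-frequency multi-vertex patterns,
# attention-event responses, slow drift, and white measurement noise.

#' Generate a synthetic vertex geometry table
#'
#' Stand-in for an anatomical retinotopy template: eccentricities are
#' log-uniform on \[0.5, 90\] degrees, polar angles uniform on \[0, 360),
#' and pRF width increases with eccentricity (a linear ramp plus positive
#' jitter).
#'
#' @param n_vertices Number of vertices (>= 1).
#' @param seed Integer seed.
#' @param area Area label(s) recycled across vertices (default `"V1"`).
#' @return Data frame with columns `vertex`, `eccentricity_deg`,
#'   `polar_angle_deg`, `prf_width_deg`, `area`.
#' @export
make_vertex_geometry <- function(n_vertices, seed = 1, area = "V1") {
  stopifnot(n_vertices >= 1)
  .with_seed(seed, {
    ecc <- 10^stats::runif(n_vertices, log10(0.5), log10(90))
    ang <- stats::runif(n_vertices, 0, 360)
    width <- 0.5 + 0.15 * ecc * (1 + 0.2 * abs(stats::rnorm(n_vertices)))
    data.frame(vertex = seq_len(n_vertices),
               eccentricity_deg = ecc,
               polar_angle_deg = ang,
               prf_width_deg = width,
               area = rep_len(area, n_vertices),
               stringsAsFactors = FALSE)
  })
}

# Default ground-truth Watson parameters per direction: peaks near 16 Hz
# (LMS), 12 Hz (LM), 8 Hz (S) with achromatic > chromatic peak amplitudes
# (%BOLD). These are simulator fixtures, not empirical claims.
.default_truth_watson <- function() {
  list(LMS = watson_params(G = 2.0 / 0.94471, tau_center = 0.002117,
                           tau_ratio = 1.7, G_surround = 0.85),
       LM = watson_params(G = 1.6 / 0.94471, tau_center = 0.002826,
                          tau_ratio = 1.7, G_surround = 0.85),
       S = watson_params(G = 1.2 / 0.94471, tau_center = 0.004240,
                         tau_ratio = 1.7, G_surround = 0.85))
}

#' Construct a simulation ground truth
#'
#' @param geometry Vertex geometry table ([make_vertex_geometry()]).
#' @param seed Seed for the per-frequency pattern templates.
#' @param watson Named list (per direction) of `watson_params`, or a list of
#'   6 such parameter sets per direction (one per eccentricity band). The
#'   default places peaks near 16/12/8 Hz for LMS/LM/S.
#' @param carryover_gain Named list with `achromatic` and `chromatic` 7 x 7
#'   multiplicative gain matrices (rows = prior frequency, columns = current
#'   frequency); the default all-ones matrices encode no adaptation.
#' @param pattern_sd SD (%BOLD) of the vertex x frequency pattern templates;
#'   0 disables patterns.
#' @param attention_amplitude Attention-event response amplitude (%BOLD).
#' @param noise_sd White-noise SD (%BOLD).
#' @param drift_amplitude,drift_freq_hz Slow sinusoidal drift spec; the
#'   frequency must lie below the 0.0387 Hz analysis cutoff.
#' @return A `ground_truth` list used by [simulate_bold()].
#' @export
ground_truth <- function(geometry, seed = 1,
                         watson = .default_truth_watson(),
                         carryover_gain = NULL,
                         pattern_sd = 0.15,
                         attention_amplitude = 0.5,
                         noise_sd = 0.5,
                         drift_amplitude = 1.0,
                         drift_freq_hz = 0.005) {
  n_freq <- length(stimulus_frequencies())
  if (is.null(carryover_gain)) {
    ones <- matrix(1, n_freq, n_freq,
                   dimnames = list(stimulus_frequencies(),
                                   stimulus_frequencies()))
    carryover_gain <- list(achromatic = ones, chromatic = ones)
  }
  stopifnot(all(dim(carryover_gain$achromatic) == c(n_freq, n_freq)),
            all(dim(carryover_gain$chromatic) == c(n_freq, n_freq)),
            drift_freq_hz < 0.0387)
  # expand per-direction params to per-band lists where needed
  bands <- eccentricity_bands()
  watson <- lapply(watson, function(w) {
    if (inherits(w, "watson_params")) rep(list(w), length(bands$edges) - 1)
    else w
  })
  nv <- nrow(geometry)
  templates <- .with_seed(seed, {
    out <- list()
    for (d in stimulus_directions())
      out[[d]] <- matrix(stats::rnorm(nv * 6, sd = pattern_sd), nv, 6,
                         dimnames = list(NULL, stimulus_frequencies()[-1]))
    out
  })
  structure(list(watson = watson, carryover_gain = carryover_gain,
                 pattern_templates = templates, pattern_sd = pattern_sd,
                 attention_amplitude = attention_amplitude,
                 noise_sd = noise_sd,
                 drift_spec = list(amplitude = drift_amplitude,
                                   freq_hz = drift_freq_hz),
                 geometry = geometry, seed = seed),
            class = "ground_truth")
}

#' Ground-truth neural response amplitude
#'
#' Watson-model amplitude for the eccentricity band containing the vertex,
#' multiplied by the first-order carry-over gain for the (prior, current)
#' frequency pair of the stimulus class. The 0 Hz condition yields 0 by
#' convention.
#'
#' @param truth A `ground_truth`.
#' @param direction Stimulus direction.
#' @param frequency Flicker frequency (Hz, member of the stimulus set).
#' @param eccentricity Vertex eccentricity in degrees.
#' @param prior_frequency Frequency of the immediately preceding trial, or
#'   `NA` for the first trial of an acquisition (gain 1).
#' @return Amplitude in %BOLD.
#' @export
neural_amplitude <- function(truth, direction, frequency, eccentricity,
                             prior_frequency = NA) {
  freqs <- stimulus_frequencies()
  stopifnot(frequency %in% freqs)
  if (frequency == 0) return(0)
  band <- assign_band(eccentricity)
  amp <- watson_amplitude(frequency, truth$watson[[direction]][[band]])
  gain <- 1
  if (!is.na(prior_frequency)) {
    cls <- if (direction == "LMS") "achromatic" else "chromatic"
    gain <- truth$carryover_gain[[cls]][match(prior_frequency, freqs),
                                        match(frequency, freqs)]
  }
  amp * gain
}

#' Simulate a BOLD dataset from a ground truth
#'
#' For each vertex, per-trial neural amplitudes (Watson band amplitude times
#' carry-over gain, plus the vertex's per-frequency pattern perturbation)
#' drive 12 s boxcars; attention events are unit impulses scaled by the
#' attention amplitude. The neural series is convolved per acquisition with
#' the HRF (normalized so a 12 s boxcar evokes a unit-peak response, the
#' same convention the fit uses, making amplitudes peak %BOLD), then slow
#' sinusoidal drift and white Gaussian noise are added.
#'
#' @param schedules List of `stimulus_schedule` objects.
#' @param truth A `ground_truth`.
#' @param basis An `hrf_basis`.
#' @param hrf_params HRF weights (default: canonical projection).
#' @param geometry Vertex geometry (default: from `truth`).
#' @param seed Integer seed for drift phase and noise.
#' @param keep_signal Keep the noiseless signal as element `signal`.
#' @return A `bold_dataset`: list with `data` (vertices x time, %BOLD),
#'   `schedules`, `geometry`, `acquisition_length`, `tr`, and optionally
#'   `signal`.
#' @export
simulate_bold <- function(schedules, truth, basis,
                          hrf_params = canonical_hrf_params(basis),
                          geometry = truth$geometry, seed = 1,
                          keep_signal = FALSE) {
  if (inherits(schedules, "stimulus_schedule")) schedules <- list(schedules)
  nv <- nrow(geometry)
  if (nv != nrow(truth$geometry))
    stop("geometry does not match the ground truth vertex count")
  kernel <- .unit_response_kernel(kernel_from_params(basis, hrf_params))
  if (is.null(kernel)) stop("degenerate HRF kernel (zero boxcar response)")
  n_acq <- length(schedules)
  n_t <- .ACQ_DUR
  freqs <- stimulus_frequencies()
  bands <- assign_band(geometry$eccentricity_deg)
  # band x direction x frequency amplitude lookup (no carry-over)
  base_amp <- array(0, c(max(bands), 3, length(freqs)),
                    dimnames = list(NULL, stimulus_directions(), freqs))
  for (b in sort(unique(bands)))
    for (d in stimulus_directions())
      base_amp[b, d, -1] <- watson_amplitude(freqs[-1],
                                             truth$watson[[d]][[b]])
  signal <- matrix(0, n_t * n_acq, nv)
  for (a in seq_len(n_acq)) {
    sch <- schedules[[a]]
    d <- sch$trials$direction[1]
    cls <- if (d == "LMS") "achromatic" else "chromatic"
    tf <- sch$trials$frequency_hz
    f_idx <- match(tf, freqs)
    gains <- rep(1, length(tf))
    if (length(tf) > 1) {
      gains[-1] <- truth$carryover_gain[[cls]][
        cbind(f_idx[-length(f_idx)], f_idx[-1])]
    }
    # vertices x trials amplitude matrix
    d_idx <- match(d, stimulus_directions())
    A <- matrix(base_amp[cbind(rep(bands, length(tf)), d_idx,
                               rep(f_idx, each = nv))], nv, length(tf))
    A <- sweep(A, 2, gains, `*`)
    nonzero <- tf > 0
    if (truth$pattern_sd > 0 && any(nonzero)) {
      pat_idx <- match(tf[nonzero], freqs[-1])
      A[, nonzero] <- A[, nonzero, drop = FALSE] +
        truth$pattern_templates[[d]][, pat_idx, drop = FALSE]
    }
    A[, !nonzero] <- 0
    neural <- matrix(0, n_t, nv)
    for (i in seq_along(tf)) {
      rows <- sch$trials$onset[i] + seq_len(.TRIAL_DUR)
      neural[rows, ] <- neural[rows, ] + rep(A[, i], each = .TRIAL_DUR)
    }
    att <- numeric(n_t)
    if (length(sch$attention_onsets) > 0) {
      bins <- floor(sch$attention_onsets) + 1L
      for (b in bins) att[b] <- att[b] + truth$attention_amplitude
    }
    blk <- apply(neural, 2, conv_trunc, kernel) +
      conv_trunc(att, kernel)
    signal[(a - 1L) * n_t + seq_len(n_t), ] <- blk
  }
  data <- .with_seed(seed, {
    out <- signal
    t_acq <- seq_len(n_t) - 1
    for (a in seq_len(n_acq)) {
      rows <- (a - 1L) * n_t + seq_len(n_t)
      if (truth$drift_spec$amplitude > 0) {
        phases <- stats::runif(nv, 0, 2 * pi)
        drift <- truth$drift_spec$amplitude *
          sin(outer(2 * pi * truth$drift_spec$freq_hz * t_acq, phases, `+`))
        out[rows, ] <- out[rows, ] + drift
      }
      if (truth$noise_sd > 0)
        out[rows, ] <- out[rows, ] +
          matrix(stats::rnorm(n_t * nv, sd = truth$noise_sd), n_t, nv)
    }
    out
  })
  res <- structure(list(data = t(data), schedules = schedules,
                        geometry = geometry, acquisition_length = n_t,
                        tr = .TR, seed = seed),
                   class = "bold_dataset")
  if (keep_signal) res$signal <- t(signal)
  res
}

#' Write a BOLD dataset as delimited text with a JSON sidecar
#'
#' @param bold A `bold_dataset`.
#' @param path Output TSV path (vertices in rows); geometry goes to
#'   `<path>.geometry.tsv`, metadata to `<path>.json`.
#' @return The path, invisibly.
#' @export
write_bold_tsv <- function(bold, path) {
  utils::write.table(bold$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(bold$geometry, paste0(path, ".geometry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_vertices = nrow(bold$data),
                            n_timepoints = ncol(bold$data),
                            acquisition_length = bold$acquisition_length,
                            tr = bold$tr, seed = bold$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
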