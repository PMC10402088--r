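# Eccentricity-integrated model of retinal ganglion cell (RGC) output to
# the flicker stimuli. Per-class temporal gain tables (spikes/s per %
# contrast, on/off averaged) at three eccentricity centers (5, 25, 40 deg)
# are converted to spike rates at the study's stimulus contrasts, combined
# into the three post-receptoral channels, and integrated over the RGC
# population (receptive-field density x class proportion x annular area).
#
# The packaged gain table is a synthetic fixture with plausible values
# emulating published macaque recordings; it is replaceable input, and all
# behavior is defined relative to whatever table is supplied.

#' Load an RGC gain table
#'
#' @param path Delimited text with columns `cell_class` (midget, parasol,
#'   bistratified), `channel` (achromatic, chromatic), `ecc_deg` (5, 25,
#'   40), `freq_hz`, `gain` (spikes/s per % contrast). Defaults to the
#'   packaged synthetic fixture.
#' @return Validated data frame of class `rgc_gain_table`.
#' @export
load_rgc_gains <- function(path = system.file("extdata",
                                              "rgc_gains_synthetic.tsv",
                                              package = "flickerfit")) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("cell_class", "channel", "ecc_deg", "freq_hz", "gain")
                %in% names(df)),
            all(df$gain >= 0),
            all(df$cell_class %in% c("midget", "parasol", "bistratified")))
  if (any(df$cell_class == "bistratified" & !(df$ecc_deg %in% c(5, 25))))
    stop("bistratified gains exist only for the 5 and 25 degree bins")
  class(df) <- c("rgc_gain_table", class(df))
  df
}

#' Stimulus contrasts per direction
#'
#' Nominal maximum contrast on the targeted post-receptoral channel:
#' approximately 90% for LMS, 8% for L-M, and 50% for S.
#'
#' @return Named numeric vector (percent).
#' @export
default_contrasts <- function() c(LMS = 90, LM = 8, S = 50)

#' Spike-rate response of one RGC class
#'
#' Gain times effective contrast, where parasol cells saturate at 25%
#' contrast (effective contrast = min(contrast, 25)) and the other classes
#' respond linearly.
#'
#' @param gain Gain in spikes/s per % contrast (vectorized).
#' @param stimulus_contrast_pct Stimulus contrast in percent (>= 0).
#' @param cell_class One of `"midget"`, `"parasol"`, `"bistratified"`.
#' @return Response in spikes/s.
#' @export
cell_response <- function(gain, stimulus_contrast_pct, cell_class) {
  stopifnot(all(stimulus_contrast_pct >= 0))
  if (!cell_class %in% c("midget", "parasol", "bistratified"))
    stop("unknown cell class: ", cell_class)
  eff <- if (cell_class == "parasol") pmin(stimulus_contrast_pct, 25)
         else stimulus_contrast_pct
  gain * eff
}

# Per-class spike-rate series at one eccentricity for one direction.
# Returns a list of data.frames (freq_hz, response) named by cell class,
# or NULL when the direction has no tabulated class at that eccentricity.
.class_responses <- function(gains, direction, eccentricity,
                             contrasts = default_contrasts()) {
  spec <- switch(direction,
                 LMS = list(midget = "achromatic", parasol = "achromatic"),
                 LM = list(midget = "chromatic"),
                 S = list(bistratified = "chromatic"),
                 stop("unknown direction: ", direction))
  out <- list()
  for (cls in names(spec)) {
    g <- gains[gains$cell_class == cls & gains$channel == spec[[cls]] &
                 gains$ecc_deg == eccentricity, ]
    if (nrow(g) == 0) return(NULL)
    g <- g[order(g$freq_hz), ]
    out[[cls]] <- data.frame(
      freq_hz = g$freq_hz,
      response = cell_response(g$gain, contrasts[[direction]], cls))
  }
  out
}

#' Channel response at one eccentricity
#'
#' LMS is the sum of the midget and parasol achromatic responses; L-M is
#' the midget chromatic response; S is the bistratified response. The S
#' direction is unavailable at 40 degrees (no bistratified recordings),
#' in which case the response column is `NA` and the result carries
#' `attr(, "unavailable") = TRUE`.
#'
#' @param gains An `rgc_gain_table`.
#' @param direction One of `"LMS"`, `"LM"`, `"S"`.
#' @param eccentricity Eccentricity center in degrees (5, 25, or 40).
#' @param contrasts Named contrast vector (default [default_contrasts()]).
#' @return Data frame with `freq_hz` and `response` (spikes/s).
#' @export
channel_response <- function(gains, direction, eccentricity,
                             contrasts = default_contrasts()) {
  per_class <- .class_responses(gains, direction, eccentricity, contrasts)
  if (is.null(per_class)) {
    out <- data.frame(freq_hz = sort(unique(gains$freq_hz)),
                      response = NA_real_)
    attr(out, "unavailable") <- TRUE
    return(out)
  }
  freq <- per_class[[1]]$freq_hz
  resp <- Reduce(`+`, lapply(per_class, function(d) d$response))
  data.frame(freq_hz = freq, response = resp)
}

#' Default population-integration configuration
#'
#' Receptive-field density is modeled as an exponential decline with
#' eccentricity; class proportions shift from midget-dominated centrally
#' toward a larger parasol share peripherally. Both are configuration, not
#' empirical claims, and can be replaced wholesale.
#'
#' @return List with `density` (`d0`, `scale_deg`), `proportions`
#'   (class x eccentricity matrix), `eccentricities`.
#' @export
default_retina_config <- function() {
  ecc <- c(5, 25, 40)
  prop <- rbind(midget = c(0.80, 0.55, 0.45),
                parasol = c(0.10, 0.20, 0.30),
                bistratified = c(0.06, 0.08, 0.08))
  colnames(prop) <- ecc
  list(density = list(d0 = 1, scale_deg = 20),
       proportions = prop,
       eccentricities = ecc)
}

.rf_density <- function(ecc, density) density$d0 * exp(-ecc / density$scale_deg)

# Log-quadratic interpolation of the peak of a coarse frequency series.
.interp_peak <- function(freq_hz, response) {
  i <- which.max(response)
  if (i == 1 || i == length(response))
    return(list(peak_freq_hz = freq_hz[i], peak_amp = response[i]))
  lx <- log10(freq_hz[(i - 1):(i + 1)])
  y <- response[(i - 1):(i + 1)]
  fit <- stats::lm.fit(cbind(1, lx, lx^2), y)
  b <- fit$coefficients
  if (b[3] >= 0) return(list(peak_freq_hz = freq_hz[i], peak_amp = response[i]))
  xv <- -b[2] / (2 * b[3])
  xv <- min(max(xv, lx[1]), lx[3])
  list(peak_freq_hz = 10^xv,
       peak_amp = drop(cbind(1, xv, xv^2) %*% b))
}

#' Integrate RGC responses over the population
#'
#' Scales each class's spike-rate response at each eccentricity by the
#' receptive-field density, the class proportion, and the annular area
#' (2 pi e in deg^2 per unit eccentricity ring), sums the classes
#' contributing to each direction, and extracts the interpolated peak of
#' the integrated response versus frequency. Peak amplitudes are
#' normalized so the across-eccentricity average of the LMS peak amplitudes
#' equals 1. The S direction is absent at 40 degrees.
#'
#' @param gains An `rgc_gain_table`.
#' @param config Configuration list (default [default_retina_config()]).
#' @param contrasts Named contrast vector (default [default_contrasts()]).
#' @return A `retinal_prediction`: list with `peaks` (data.frame:
#'   direction, ecc_deg, peak_freq_hz, peak_amp) and `responses` (list of
#'   integrated response data frames keyed `direction_ecc`).
#' @export
integrate_population <- function(gains, config = default_retina_config(),
                                 contrasts = default_contrasts()) {
  rows <- list()
  responses <- list()
  for (d in stimulus_directions()) {
    for (e in config$eccentricities) {
      per_class <- .class_responses(gains, d, e, contrasts)
      if (is.null(per_class)) next
      dens <- .rf_density(e, config$density)
      area <- 2 * pi * e
      total <- 0
      for (cls in names(per_class)) {
        p <- config$proportions[cls, as.character(e)]
        total <- total + per_class[[cls]]$response * dens * p * area
      }
      freq <- per_class[[1]]$freq_hz
      responses[[paste(d, e, sep = "_")]] <-
        data.frame(freq_hz = freq, response = total)
      pk <- .interp_peak(freq, total)
      rows[[paste(d, e, sep = "_")]] <- data.frame(
        direction = d, ecc_deg = e,
        peak_freq_hz = pk$peak_freq_hz, peak_amp = pk$peak_amp,
        stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  norm <- mean(peaks$peak_amp[peaks$direction == "LMS"])
  peaks$peak_amp <- peaks$peak_amp / norm
  responses <- lapply(responses, function(r) {
    r$response <- r$response / norm
    r
  })
  structure(list(peaks = peaks, responses = responses,
                 normalization = norm),
            class = "retinal_prediction")
}
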