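# Watson difference-of-exponentials temporal sensitivity model.
#
# The response to flicker at frequency omega (Hz) is modeled as the modulus
# of a center-minus-surround pair of cascaded low-pass filters:
#   Hcenter(w)   = (i 2 pi w tau_center + 1)^(-nc)
#   Hsurround(w) = G_surround (i 2 pi w tau_surround + 1)^(-ns)
#   H(w)         = G (Hcenter - Hsurround)
# with filter orders nc = 9 and ns = 10 held fixed and
# tau_surround = tau_ratio * tau_center.

.WATSON_NC <- 9
.WATSON_NS <- 10

# Bounds realizing the model's linear constraints.
.WATSON_BOUNDS <- list(log10_tau_center = c(-4, -1),
                       tau_ratio = c(1, 20),
                       G_surround = c(0, 1))

#' Construct Watson temporal-sensitivity parameters
#'
#' @param G Overall gain (response units, >= 0).
#' @param tau_center Center filter time constant in seconds (> 0).
#' @param tau_ratio Surround-to-center time-constant ratio (>= 1).
#' @param G_surround Surround gain relative to center (in \[0, 1\]).
#' @return A `watson_params` list; the filter orders (9 and 10) are fixed.
#' @export
watson_params <- function(G = 1, tau_center = 0.002, tau_ratio = 2,
                          G_surround = 0.8) {
  stopifnot(is.finite(G), G >= 0,
            is.finite(tau_center), tau_center > 0,
            is.finite(tau_ratio), tau_ratio >= 1,
            is.finite(G_surround), G_surround >= 0, G_surround <= 1)
  structure(list(G = G, tau_center = tau_center, tau_ratio = tau_ratio,
                 G_surround = G_surround, nc = .WATSON_NC, ns = .WATSON_NS),
            class = "watson_params")
}

#' Watson model response amplitude
#'
#' Evaluates `|G (Hcenter - Hsurround)|` at the given frequencies, using
#' complex filter arithmetic with the modulus taken at the end.
#'
#' @param freq_hz Frequencies in Hz (vector, >= 0).
#' @param params A `watson_params`.
#' @return Numeric amplitude vector.
#' @export
watson_amplitude <- function(freq_hz, params) {
  stopifnot(all(freq_hz >= 0))
  w <- 2i * pi * freq_hz
  hc <- (w * params$tau_center + 1)^(-.WATSON_NC)
  hs <- params$G_surround *
    (w * params$tau_center * params$tau_ratio + 1)^(-.WATSON_NS)
  Mod(params$G * (hc - hs))
}

#' Interpolation grid for peak extraction
#'
#' Log-spaced frequencies from 0.5 to 100 Hz with 0.01 log10 spacing.
#'
#' @return Numeric frequency vector.
#' @export
watson_peak_grid <- function() 10^seq(log10(0.5), 2, by = 0.01)

#' Interpolated peak of a Watson fit
#'
#' @param params A `watson_params`.
#' @param grid Frequency grid (default [watson_peak_grid()]).
#' @return List with `peak_freq_hz` and `peak_amp`.
#' @export
peak_of_fit <- function(params, grid = watson_peak_grid()) {
  a <- watson_amplitude(grid, params)
  i <- which.max(a)
  list(peak_freq_hz = grid[i], peak_amp = a[i])
}

# Unimodality on a grid: after the first decrease in the amplitude profile
# no subsequent increase is permitted (at most one maximal run).
.is_unimodal_profile <- function(amps, tol = 1e-9) {
  d <- diff(amps)
  scale <- max(abs(amps), 1e-300)
  first_fall <- which(d < -tol * scale)[1]
  if (is.na(first_fall)) return(TRUE)
  !any(d[first_fall:length(d)] > tol * scale)
}

#' Check unimodality of the Watson amplitude profile
#'
#' @param params A `watson_params`.
#' @param grid Frequency grid (default [watson_peak_grid()]).
#' @return `TRUE` if the amplitude profile has a single maximal run.
#' @export
is_unimodal <- function(params, grid = watson_peak_grid()) {
  .is_unimodal_profile(watson_amplitude(grid, params))
}

# --- fitting ---------------------------------------------------------------

# Map unconstrained coordinates to bounded parameters and back.
.watson_from_u <- function(u) {
  b <- .WATSON_BOUNDS
  s <- stats::plogis(u)
  list(tau_center = 10^(b$log10_tau_center[1] +
                          diff(b$log10_tau_center) * s[1]),
       tau_ratio = b$tau_ratio[1] + diff(b$tau_ratio) * s[2],
       G_surround = b$G_surround[1] + diff(b$G_surround) * s[3])
}

.watson_to_u <- function(tau_center, tau_ratio, G_surround) {
  b <- .WATSON_BOUNDS
  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  stats::qlogis(clamp(c(
    (log10(tau_center) - b$log10_tau_center[1]) / diff(b$log10_tau_center),
    (tau_ratio - b$tau_ratio[1]) / diff(b$tau_ratio),
    (G_surround - b$G_surround[1]) / diff(b$G_surround))))
}

# Penalized profile objective: gain G is profiled out analytically
# (non-negative least squares in one scalar); unimodality enters as a
# quadratic penalty on post-peak rises over a coarse log grid.
.watson_objective <- function(u, freq, amp, coarse_grid, penalty_scale) {
  p <- .watson_from_u(u)
  w <- 2i * pi * freq
  hc <- (w * p$tau_center + 1)^(-.WATSON_NC)
  hs <- p$G_surround * (w * p$tau_center * p$tau_ratio + 1)^(-.WATSON_NS)
  s <- Mod(hc - hs)
  ss <- sum(s^2)
  G <- if (ss > 1e-300) max(0, sum(amp * s) / ss) else 0
  sse <- sum((amp - G * s)^2)
  wg <- 2i * pi * coarse_grid
  prof <- Mod((wg * p$tau_center + 1)^(-.WATSON_NC) -
                p$G_surround *
                (wg * p$tau_center * p$tau_ratio + 1)^(-.WATSON_NS))
  d <- diff(prof)
  first_fall <- which(d < 0)[1]
  pen <- 0
  if (!is.na(first_fall)) {
    rises <- d[first_fall:length(d)]
    pen <- sum(pmax(rises, 0))^2 / max(max(prof)^2, 1e-300)
  }
  sse + penalty_scale * pen
}

# Complete a fitted parameter point: recompute profiled G and diagnostics.
.watson_finish <- function(u, freq, amp) {
  p <- .watson_from_u(u)
  base <- watson_params(1, p$tau_center, p$tau_ratio, p$G_surround)
  s <- watson_amplitude(freq, base)
  ss <- sum(s^2)
  G <- if (ss > 1e-300) max(0, sum(amp * s) / ss) else 0
  out <- watson_params(G, p$tau_center, p$tau_ratio, p$G_surround)
  attr(out, "sse") <- sum((amp - G * s)^2)
  out
}

#' Fit the Watson model to amplitude-versus-frequency data
#'
#' Constrained least squares with the filter orders fixed at 9 and 10, the
#' gain profiled out analytically, bound constraints on the remaining three
#' parameters, and unimodality of the amplitude profile enforced via a
#' penalty (verified on the dense interpolation grid before returning).
#' A seeded multi-start lattice over the bounded parameters guards against
#' local minima; supplying `init` replaces the lattice with a single start
#' (used by the bootstrap for speed).
#'
#' @param frequencies Frequencies in Hz (>= 4 values).
#' @param amplitudes Response amplitudes (may be negative; fit as-is).
#' @param init Optional `watson_params` used as the only start.
#' @param seed Seed for start-point jitter.
#' @param penalty_scale Weight of the unimodality penalty, relative to the
#'   squared data scale.
#' @return A fitted `watson_params` with attributes `sse` and `feasible`.
#' @export
fit_tsf <- function(frequencies, amplitudes, init = NULL, seed = 1,
                    penalty_scale = 1e4) {
  stopifnot(length(frequencies) == length(amplitudes),
            length(frequencies) >= 4, all(frequencies >= 0))
  coarse <- 10^seq(log10(0.5), 2, length.out = 41)
  scale2 <- max(sum(amplitudes^2), 1e-12)
  pen <- penalty_scale * scale2
  starts <- if (!is.null(init)) {
    list(.watson_to_u(init$tau_center, init$tau_ratio,
                      max(init$G_surround, 1e-4)))
  } else {
    lat <- expand.grid(l10tc = c(-3, -2.3, -1.7, -1.2),
                       ratio = c(1.5, 3, 8),
                       gs = c(0.3, 0.9))
    lapply(seq_len(nrow(lat)), function(i) {
      .watson_to_u(10^lat$l10tc[i], lat$ratio[i], lat$gs[i])
    })
  }
  warm <- !is.null(init)
  best <- NULL
  for (u0 in starts) {
    o <- stats::optim(u0, .watson_objective, freq = frequencies,
                      amp = amplitudes, coarse_grid = coarse,
                      penalty_scale = pen, method = "Nelder-Mead",
                      control = list(maxit = if (warm) 300 else 400,
                                     reltol = if (warm) 1e-9 else 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!warm) {
    # polish the winner
    o <- stats::optim(best$par, .watson_objective, freq = frequencies,
                      amp = amplitudes, coarse_grid = coarse,
                      penalty_scale = pen, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-12))
    if (o$value <= best$value) best <- o
  }
  fit <- .watson_finish(best$par, frequencies, amplitudes)
  feasible <- is_unimodal(fit)
  if (!feasible) {
    # escalate the penalty from the current point
    o2 <- stats::optim(best$par, .watson_objective, freq = frequencies,
                       amp = amplitudes, coarse_grid = watson_peak_grid(),
                       penalty_scale = pen * 100, method = "Nelder-Mead",
                       control = list(maxit = 800, reltol = 1e-12))
    fit2 <- .watson_finish(o2$par, frequencies, amplitudes)
    if (is_unimodal(fit2)) {
      fit <- fit2
      feasible <- TRUE
    }
  }
  if (!feasible)
    stop("no feasible (unimodal) Watson fit found; best SSE = ",
         format(attr(fit, "sse")), ", params: tau_center = ",
         format(fit$tau_center), ", tau_ratio = ", format(fit$tau_ratio),
         ", G_surround = ", format(fit$G_surround))
  attr(fit, "feasible") <- feasible
  fit
}

#' Bootstrap temporal sensitivity summary
#'
#' Resamples acquisitions with replacement `n_boot` times; for each
#' replicate, averages the relative amplitudes per frequency across the
#' resampled acquisitions, fits the Watson model (warm-started from the fit
#' to the full data), and extracts the interpolated peak. Reports
#' per-frequency medians and interquartile ranges of the replicate means,
#' and the median/IQR of the peak frequency and amplitude.
#'
#' @param table Data frame with columns `acquisition`, `frequency_hz`,
#'   `amplitude` (relative to the 0 Hz condition), and optionally
#'   `direction`.
#' @param direction Optional direction filter applied to `table`.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return An object of class `tsf`: frequencies, per-frequency median
#'   amplitude and IQR bounds, peak medians and IQRs, the full-data fit, and
#'   the replicate draws.
#' @export
bootstrap_tsf <- function(table, direction = NULL, n_boot = 1000L, seed = 1) {
  if (!is.null(direction) && "direction" %in% names(table))
    table <- table[table$direction == direction, , drop = FALSE]
  table <- table[table$frequency_hz > 0, , drop = FALSE]
  acqs <- sort(unique(table$acquisition))
  if (length(acqs) < 2) stop("need >= 2 acquisitions per frequency")
  freqs <- sort(unique(table$frequency_hz))
  # acquisition x frequency amplitude matrix
  A <- matrix(NA_real_, length(acqs), length(freqs),
              dimnames = list(acqs, freqs))
  idx <- cbind(match(table$acquisition, acqs),
               match(table$frequency_hz, freqs))
  A[idx] <- table$amplitude
  if (anyNA(A)) stop("missing (acquisition x frequency) amplitude cells")
  full_mean <- colMeans(A)
  full_fit <- fit_tsf(freqs, full_mean, seed = seed)
  draws_amp <- matrix(NA_real_, n_boot, length(freqs))
  draws_peakf <- numeric(n_boot)
  draws_peaka <- numeric(n_boot)
  .with_seed(seed, {
    for (b in seq_len(n_boot)) {
      take <- sample(length(acqs), replace = TRUE)
      m <- colMeans(A[take, , drop = FALSE])
      draws_amp[b, ] <- m
      fit <- fit_tsf(freqs, m, init = full_fit)
      pk <- peak_of_fit(fit)
      draws_peakf[b] <- pk$peak_freq_hz
      draws_peaka[b] <- pk$peak_amp
    }
  })
  q <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  amp_q <- apply(draws_amp, 2, q)
  pf <- q(draws_peakf); pa <- q(draws_peaka)
  structure(list(
    frequencies_hz = freqs,
    amplitude = amp_q[2, ],
    iqr_lo = amp_q[1, ], iqr_hi = amp_q[3, ],
    peak_freq_hz = pf[2], peak_freq_iqr = pf[c(1, 3)],
    peak_amp = pa[2], peak_amp_iqr = pa[c(1, 3)],
    n_boot = n_boot, direction = direction, fit = full_fit,
    draws = list(peak_freq_hz = draws_peakf, peak_amp = draws_peaka)),
    class = "tsf")
}

#' Write a bootstrap TSF summary as TSV
#'
#' One row per frequency (median and IQR bounds) plus a `peak` summary row.
#'
#' @param tsf A `tsf` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsf_tsv <- function(tsf, path) {
  df <- data.frame(
    quantity = c(paste0("amplitude_", tsf$frequencies_hz, "Hz"),
                 "peak_freq_hz", "peak_amp"),
    median = c(tsf$amplitude, tsf$peak_freq_hz, tsf$peak_amp),
    iqr_lo = c(tsf$iqr_lo, tsf$peak_freq_iqr[1], tsf$peak_amp_iqr[1]),
    iqr_hi = c(tsf$iqr_hi, tsf$peak_freq_iqr[2], tsf$peak_amp_iqr[2]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
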