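# First-order carry-over (adaptation) analysis: regression of the
# region-averaged residual of the main time-series fit on 49 covariates
# modeling the effect of each prior stimulus frequency on the response to
# each subsequent frequency.

#' Residual time series after the main fit
#'
#' Region-averaged, high-pass-filtered data minus the full fitted model
#' (stimulus plus attention components), averaged across the requested
#' vertices. Per vertex the residual is orthogonal to that vertex's fitted
#' covariates (ordinary-least-squares property).
#'
#' @param bold A `bold_dataset`.
#' @param fit A `fit_result`.
#' @param schedules Schedules (default: from `bold`).
#' @param vertices Vertices to average (default: all fitted).
#' @return Numeric residual series over the concatenated study timeline.
#' @export
residual_signal <- function(bold, fit, schedules = bold$schedules,
                            vertices = fit$vertices) {
  prep <- fit$prep
  n_t <- prep$n_t
  p <- prep$ncol_per
  Q <- prep$Q
  sel <- match(vertices, fit$vertices)
  if (anyNA(sel)) stop("requested vertices were not fitted")
  Y <- t(bold$data[vertices, , drop = FALSE])
  res <- matrix(0, nrow(Y), length(vertices))
  for (a in seq_len(prep$n_acq)) {
    rows <- (a - 1L) * n_t + seq_len(n_t)
    Y[rows, ] <- Y[rows, , drop = FALSE] -
      Q %*% crossprod(Q, Y[rows, , drop = FALSE])
  }
  for (j in seq_along(vertices)) {
    vi <- sel[j]
    v <- fit$vertices[vi]
    w <- fit$hrf_weights[vi, ]
    cw <- .boxcar_peak(kernel_from_params(fit$basis, w))
    amps <- fit$amplitudes[fit$amplitudes$vertex == v, ]
    atts <- fit$attention[fit$attention$vertex == v, ]
    for (a in seq_len(prep$n_acq)) {
      X <- .combine_block(prep, a, w) / cw
      beta <- c(amps$amplitude[amps$acquisition == a],
                atts$amplitude[atts$acquisition == a])
      rows <- (a - 1L) * n_t + seq_len(n_t)
      res[rows, j] <- Y[rows, j] - drop(X %*% beta)
    }
  }
  rowMeans(res)
}

#' Build the 49 prior-by-subsequent carry-over covariates
#'
#' One covariate per ordered (prior, subsequent) frequency pair: a 12 s
#' boxcar over every trial whose own frequency is `subsequent` and whose
#' immediately preceding trial within the same acquisition had frequency
#' `prior`. Covariates are built over the full provided timeline but take
#' support only in acquisitions of the requested stimulus class (achromatic
#' = LMS trials; chromatic = L-M and S trials pooled). The first trial of
#' each acquisition is excluded (it has no prior). Each column is convolved
#' with the supplied HRF kernel within its acquisition.
#'
#' @param schedules List of `stimulus_schedule` objects.
#' @param stimulus_class `"achromatic"` or `"chromatic"`.
#' @param hrf_kernel Numeric kernel; `NULL` leaves covariates unconvolved.
#' @return Matrix (time x 49) with a `labels` attribute (data.frame:
#'   column, prior_hz, subsequent_hz) and a `support_s` attribute giving
#'   the unconvolved support of each column in seconds.
#' @export
build_carryover_covariates <- function(schedules,
                                       stimulus_class = c("achromatic",
                                                          "chromatic"),
                                       hrf_kernel = NULL) {
  stimulus_class <- match.arg(stimulus_class)
  if (inherits(schedules, "stimulus_schedule")) schedules <- list(schedules)
  freqs <- stimulus_frequencies()
  nf <- length(freqs)
  n_acq <- length(schedules)
  n_t <- .ACQ_DUR
  X <- matrix(0, n_t * n_acq, nf * nf)
  for (a in seq_len(n_acq)) {
    sch <- schedules[[a]]
    d <- sch$trials$direction[1]
    in_class <- if (stimulus_class == "achromatic") d == "LMS"
                else d %in% c("LM", "S")
    if (!in_class) next
    tf <- sch$trials$frequency_hz
    row0 <- (a - 1L) * n_t
    block <- matrix(0, n_t, nf * nf)
    for (i in seq_along(tf)[-1]) {
      col <- (match(tf[i - 1L], freqs) - 1L) * nf + match(tf[i], freqs)
      rows <- sch$trials$onset[i] + seq_len(.TRIAL_DUR)
      block[rows, col] <- 1
    }
    if (!is.null(hrf_kernel)) block <- apply(block, 2, conv_trunc, hrf_kernel)
    X[row0 + seq_len(n_t), ] <- block
  }
  labels <- data.frame(column = seq_len(nf * nf),
                       prior_hz = rep(freqs, each = nf),
                       subsequent_hz = rep(freqs, nf))
  attr(X, "labels") <- labels
  attr(X, "stimulus_class") <- stimulus_class
  X
}

#' Regress the residual on the carry-over covariates
#'
#' Covariates (and the residual, idempotently) are high-pass filtered
#' consistently with the main fit; coefficients are arranged into a 7 x 7
#' matrix (rows = prior frequency, columns = subsequent frequency). Pairs
#' with no supporting trials in the class's schedule yield `NA` cells.
#'
#' @param residual Residual series from [residual_signal()].
#' @param covariates Matrix from [build_carryover_covariates()].
#' @param acquisition_length Samples per acquisition (default 336).
#' @param cutoff_hz High-pass cutoff (default 0.0387).
#' @return A `carryover_matrix`: list with `values` (7 x 7, labeled by
#'   frequency), `stimulus_class`.
#' @export
fit_carryover <- function(residual, covariates, acquisition_length = 336L,
                          cutoff_hz = 0.0387) {
  labels <- attr(covariates, "labels")
  freqs <- stimulus_frequencies()
  nf <- length(freqs)
  Xf <- highpass_project(covariates, cutoff_hz,
                         acquisition_length = acquisition_length)
  rf <- highpass_project(residual, cutoff_hz,
                         acquisition_length = acquisition_length)
  supported <- colSums(covariates != 0) > 0
  vals <- rep(NA_real_, nf * nf)
  if (any(supported)) {
    f <- stats::lm.fit(Xf[, supported, drop = FALSE], rf)
    vals[supported] <- f$coefficients
  }
  m <- matrix(NA_real_, nf, nf, dimnames = list(prior = freqs,
                                                subsequent = freqs))
  m[cbind(match(labels$prior_hz, freqs),
          match(labels$subsequent_hz, freqs))] <- vals
  structure(list(values = m,
                 stimulus_class = attr(covariates, "stimulus_class")),
            class = "carryover_matrix")
}

#' Flag reliable carry-over cells across participants
#'
#' @param matrices List of `carryover_matrix` objects (or bare 7 x 7
#'   matrices), one per participant (>= 2).
#' @return List with `mean`, `sem`, and logical `flags` matrices; a cell is
#'   flagged where |mean| exceeds twice the standard error of the mean
#'   across participants.
#' @export
flag_cells <- function(matrices) {
  vals <- lapply(matrices, function(m) {
    if (inherits(m, "carryover_matrix")) m$values else m
  })
  if (length(vals) < 2) stop("need >= 2 participant matrices")
  arr <- simplify2array(vals)
  mu <- apply(arr, c(1, 2), mean)
  sem <- apply(arr, c(1, 2), stats::sd) / sqrt(length(vals))
  list(mean = mu, sem = sem, flags = abs(mu) > 2 * sem)
}

#' Write a carry-over matrix (and optional flags) as TSV
#'
#' @param cm A `carryover_matrix`.
#' @param path Output path for the 7 x 7 value matrix with frequency labels.
#' @param flags Optional logical matrix written to `<path>.flags.tsv`.
#' @return The path, invisibly.
#' @export
write_carryover_tsv <- function(cm, path, flags = NULL) {
  utils::write.table(cm$values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  if (!is.null(flags))
    utils::write.table(flags, paste0(path, ".flags.tsv"), sep = "\t",
                       quote = FALSE, row.names = TRUE, col.names = NA)
  invisible(path)
}
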