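# Hemodynamic response model: a 3-weight combination of an orthonormal
# temporal basis derived (by SVD) from a family of double-gamma responses.

#' Double-gamma hemodynamic response
#'
#' Canonical difference-of-gammas impulse response: a positive response gamma
#' minus a scaled undershoot gamma.
#'
#' @param t Time in seconds (vector).
#' @param peak_delay Time-to-peak of the positive lobe (s).
#' @param under_delay Time-to-peak of the undershoot (s).
#' @param dispersion Scale (width) of the positive lobe.
#' @param under_dispersion Scale of the undershoot.
#' @param ratio Undershoot amplitude relative to the positive lobe.
#' @return Numeric vector of the response at `t`.
#' @export
double_gamma_hrf <- function(t, peak_delay = 6, under_delay = 16,
                             dispersion = 1, under_dispersion = 1,
                             ratio = 1 / 6) {
  stats::dgamma(t, shape = peak_delay / dispersion, scale = dispersion) -
    ratio * stats::dgamma(t, shape = under_delay / under_dispersion,
                          scale = under_dispersion)
}

#' Default double-gamma family ranges for basis construction
#'
#' @return Named list of 2-vectors (min, max) for `peak_delay`,
#'   `under_delay`, `dispersion`, and `ratio`.
#' @export
default_hrf_family <- function() {
  list(peak_delay = c(4, 8), under_delay = c(12, 18),
       dispersion = c(0.6, 1.4), ratio = c(0.1, 0.5))
}

#' Build a 3-component orthonormal HRF basis
#'
#' Samples `n_samples` double-gamma responses over the family ranges,
#' evaluates them on a 0-27 s grid at 1 s resolution, and extracts the top
#' `n_components` right singular vectors as orthonormal temporal kernels.
#' Signs are fixed so the first component correlates positively with the
#' family mean and each remaining kernel has a positive element of largest
#' magnitude; the construction is deterministic given `family_spec` and
#' `seed`.
#'
#' @param family_spec Parameter ranges, as from [default_hrf_family()].
#' @param n_components Number of basis kernels (default 3).
#' @param n_samples Number of sampled family members (>= 500 by default).
#' @param seed Integer seed for family sampling.
#' @return An `hrf_basis`: list with `kernels` (28 x n_components matrix,
#'   orthonormal columns), `t` (0:27), `mean_hrf`, `family_spec`, `seed`.
#' @export
build_orthonormal_basis <- function(family_spec = default_hrf_family(),
                                    n_components = 3L, n_samples = 512L,
                                    seed = 1) {
  t <- 0:27
  draw <- function(range, n) stats::runif(n, range[1], range[2])
  H <- .with_seed(seed, {
    p1 <- draw(family_spec$peak_delay, n_samples)
    p2 <- draw(family_spec$under_delay, n_samples)
    p3 <- draw(family_spec$dispersion, n_samples)
    p4 <- draw(family_spec$ratio, n_samples)
    t(vapply(seq_len(n_samples), function(i) {
      double_gamma_hrf(t, p1[i], p2[i], p3[i], p4[i])
    }, numeric(length(t))))
  })
  if (max(apply(H, 2, stats::sd)) < 1e-12)
    stop("degenerate HRF family: all sampled responses identical")
  sv <- svd(H, nu = 0, nv = n_components)
  kernels <- sv$v
  mean_hrf <- colMeans(H)
  for (j in seq_len(n_components)) {
    s <- if (j == 1) sign(sum(kernels[, j] * mean_hrf))
         else sign(kernels[which.max(abs(kernels[, j])), j])
    if (s < 0) kernels[, j] <- -kernels[, j]
  }
  structure(list(kernels = kernels, t = t, mean_hrf = mean_hrf,
                 family_spec = family_spec, seed = seed,
                 n_samples = n_samples),
            class = "hrf_basis")
}

#' Kernel from basis weights
#'
#' @param basis An `hrf_basis`.
#' @param params Numeric vector of weights, one per basis kernel.
#' @return Numeric kernel (length 28), the weighted sum of basis kernels.
#' @export
kernel_from_params <- function(basis, params) {
  stopifnot(length(params) == ncol(basis$kernels), all(is.finite(params)))
  drop(basis$kernels %*% params)
}

#' Canonical HRF weights for a basis
#'
#' Projection of the canonical double-gamma response onto the basis,
#' normalized to unit norm. Used as the default simulation truth and the
#' initialization of the time-series fit.
#'
#' @param basis An `hrf_basis`.
#' @return Numeric weight vector of unit norm.
#' @export
canonical_hrf_params <- function(basis) {
  h <- double_gamma_hrf(basis$t)
  w <- drop(crossprod(basis$kernels, h))
  w / sqrt(sum(w^2))
}

# Peak of the response to a 12 s unit boxcar; used as the amplitude
# normalization so that stimulus amplitudes are expressed as the peak
# percent-signal-change evoked by one 12 s trial.
.boxcar_peak <- function(kernel, dur = 12L) {
  max(stats::convolve(c(rep(1, dur), numeric(length(kernel))), rev(kernel),
                      type = "open"))
}

# Kernel scaled so a 12 s boxcar evokes a unit-peak response. This fixes the
# HRF-scale / amplitude-scale degeneracy of the joint fit.
.unit_response_kernel <- function(kernel) {
  pk <- .boxcar_peak(kernel)
  if (!is.finite(pk) || pk < 1e-9) return(NULL)
  kernel / pk
}

#' Write an HRF basis as TSV plus a JSON sidecar
#'
#' @param basis An `hrf_basis`.
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @return The path, invisibly.
#' @export
write_hrf_basis <- function(basis, path) {
  m <- basis$kernels
  colnames(m) <- paste0("component", seq_len(ncol(m)))
  utils::write.table(cbind(t = basis$t, m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(family_spec = basis$family_spec,
                            seed = basis$seed, n_samples = basis$n_samples),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an HRF basis written by [write_hrf_basis()]
#'
#' @param path TSV path with `<path>.json` sidecar.
#' @return An `hrf_basis` (without the sampled-family mean).
#' @export
read_hrf_basis <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(kernels = as.matrix(df[, -1, drop = FALSE]), t = df$t,
                 mean_hrf = NULL, family_spec = side$family_spec,
                 seed = side$seed, n_samples = side$n_samples),
            class = "hrf_basis")
}
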