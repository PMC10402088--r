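# Joint HRF + amplitude estimation. The model for each vertex is linear in
# the per-acquisition stimulus/attention amplitudes given the HRF weights,
# so the fit is separable: amplitudes are profiled out by ordinary least
# squares (via per-acquisition normal equations on precomputed
# cross-products, exploiting the block-diagonal design) while a Nelder-Mead
# search runs over the three HRF weights shared across acquisitions.

# Precompute filtered per-acquisition design blocks for each basis kernel,
# their cross-products, and the drift projector.
.prepare_fit <- function(schedules, basis, cutoff_hz = 0.0387) {
  n_acq <- length(schedules)
  nb <- ncol(basis$kernels)
  dms <- lapply(seq_len(nb), function(k) {
    build_design_matrix(schedules, hrf_kernel = basis$kernels[, k])
  })
  labels <- dms[[1]]$labels
  n_t <- dms[[1]]$acquisition_length
  ncol_per <- sum(labels$acquisition == 1)
  Q <- .dct_drift_basis(n_t, cutoff_hz)
  blocks <- vector("list", n_acq)
  gram <- vector("list", n_acq)
  for (a in seq_len(n_acq)) {
    rows <- (a - 1L) * n_t + seq_len(n_t)
    cols <- (a - 1L) * ncol_per + seq_len(ncol_per)
    C <- matrix(0, n_t, ncol_per * nb)
    for (k in seq_len(nb)) {
      Bk <- dms[[k]]$matrix[rows, cols, drop = FALSE]
      Bk <- Bk - Q %*% crossprod(Q, Bk)
      C[, (k - 1L) * ncol_per + seq_len(ncol_per)] <- Bk
    }
    blocks[[a]] <- C
    gram[[a]] <- crossprod(C)
  }
  list(blocks = blocks, gram = gram, labels = labels, Q = Q,
       n_t = n_t, ncol_per = ncol_per, nb = nb, n_acq = n_acq,
       schedules = schedules, basis = basis)
}

# Contract a stacked (nb*p x nb*p) Gram matrix with weights -> p x p.
.contract_gram <- function(G, w, p) {
  nb <- length(w)
  R <- matrix(0, nb * p, p)
  for (k in seq_len(nb))
    R <- R + w[k] * G[, (k - 1L) * p + seq_len(p), drop = FALSE]
  M <- matrix(0, p, p)
  for (j in seq_len(nb))
    M <- M + w[j] * R[(j - 1L) * p + seq_len(p), , drop = FALSE]
  M
}

# SSE over acquisitions for HRF weights w given per-acquisition
# cross-products h (p x nb) and data sum-of-squares yty.
.sep_sse <- function(w, prep, h_list, yty) {
  p <- prep$ncol_per
  sse <- 0
  for (a in seq_len(prep$n_acq)) {
    M <- .contract_gram(prep$gram[[a]], w, p)
    b <- drop(h_list[[a]] %*% w)
    beta <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(beta)) return(1e300)
    sse <- sse + yty[a] - sum(b * beta)
  }
  sse + (sum(w^2) - 1)^2
}

#' Jointly fit HRF weights and stimulus amplitudes
#'
#' For each vertex, finds the three HRF basis weights and the
#' per-acquisition covariate amplitudes minimizing the L2 norm of the
#' difference between observed and modeled time series, after subjecting
#' both to the 0.0387 Hz high-pass filter. One HRF is shared across all
#' acquisitions of a vertex. Amplitudes are reported in peak
#' percent-signal-change units (the fitted kernel is normalized so a 12 s
#' boxcar evokes a unit-peak response, resolving the HRF/amplitude scale
#' degeneracy).
#'
#' @param bold A `bold_dataset` in percent-signal-change units.
#' @param basis An `hrf_basis`.
#' @param schedules Schedules (default: from `bold`).
#' @param vertex_mask Optional integer vector of vertices to fit (mirrors
#'   restricting analysis to a cortical subregion).
#' @param init Initial HRF weights (default: canonical projection).
#' @param cutoff_hz High-pass cutoff (default 0.0387).
#' @param control List: `maxit` (Nelder-Mead iterations per pass, default
#'   400), `restarts` (additional polish passes, default 1).
#' @return A `fit_result`: list with `vertices`, `hrf_weights` (V x 3, unit
#'   norm), `amplitudes` (data.frame: vertex, acquisition, direction,
#'   frequency_hz, amplitude), `attention` (vertex, acquisition, amplitude),
#'   `r2` (per vertex, computed on attention-cleaned averaged data),
#'   `sse`, and the preprocessing context needed by downstream stages.
#' @export
fit_timeseries <- function(bold, basis, schedules = bold$schedules,
                           vertex_mask = NULL, init = NULL,
                           cutoff_hz = 0.0387, control = list()) {
  maxit <- control$maxit %||% 400L
  restarts <- control$restarts %||% 1L
  prep <- .prepare_fit(schedules, basis, cutoff_hz)
  n_t <- prep$n_t
  Y <- t(bold$data)  # time x vertices
  if (nrow(Y) != n_t * prep$n_acq)
    stop("data has ", nrow(Y), " time points; schedules imply ",
         n_t * prep$n_acq)
  vertices <- vertex_mask %||% seq_len(ncol(Y))
  if (is.null(init)) init <- canonical_hrf_params(basis)
  # rank check at the initial weights
  for (a in seq_len(prep$n_acq)) {
    Xa <- .combine_block(prep, a, init)
    if (qr(Xa)$rank < prep$ncol_per)
      stop("rank-deficient filtered design in acquisition ", a)
  }
  # filter data once, per acquisition
  Q <- prep$Q
  for (a in seq_len(prep$n_acq)) {
    rows <- (a - 1L) * n_t + seq_len(n_t)
    Y[rows, ] <- Y[rows, , drop = FALSE] -
      Q %*% crossprod(Q, Y[rows, , drop = FALSE])
  }
  nv <- length(vertices)
  W <- matrix(NA_real_, nv, prep$nb)
  SSE <- numeric(nv)
  amp_rows <- vector("list", nv)
  att_rows <- vector("list", nv)
  freqs <- stimulus_frequencies()
  dirs <- vapply(schedules, function(s) s$trials$direction[1], character(1))
  for (vi in seq_len(nv)) {
    v <- vertices[vi]
    y <- Y[, v]
    h_list <- vector("list", prep$n_acq)
    yty <- numeric(prep$n_acq)
    for (a in seq_len(prep$n_acq)) {
      rows <- (a - 1L) * n_t + seq_len(n_t)
      ya <- y[rows]
      hh <- crossprod(prep$blocks[[a]], ya)  # (nb*p) x 1
      h_list[[a]] <- matrix(hh, prep$ncol_per, prep$nb)
      yty[a] <- sum(ya^2)
    }
    if (max(yty) < 1e-20) {
      # zero-variance data: amplitudes 0 by convention
      W[vi, ] <- init
      SSE[vi] <- 0
      beta_all <- matrix(0, prep$ncol_per, prep$n_acq)
    } else {
      w <- init
      for (pass in seq_len(restarts + 1L)) {
        o <- stats::optim(w, .sep_sse, prep = prep, h_list = h_list,
                          yty = yty, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-14))
        w <- o$par
      }
      w <- w / sqrt(sum(w^2))
      W[vi, ] <- w
      SSE[vi] <- .sep_sse(w, prep, h_list, yty)
      cw <- .boxcar_peak(kernel_from_params(basis, w))
      beta_all <- vapply(seq_len(prep$n_acq), function(a) {
        M <- .contract_gram(prep$gram[[a]], w, prep$ncol_per)
        cw * solve(M, drop(h_list[[a]] %*% w))
      }, numeric(prep$ncol_per))
    }
    amp_rows[[vi]] <- data.frame(
      vertex = v,
      acquisition = rep(seq_len(prep$n_acq), each = length(freqs)),
      direction = rep(dirs, each = length(freqs)),
      frequency_hz = rep(freqs, prep$n_acq),
      amplitude = as.vector(beta_all[seq_along(freqs), ]),
      stringsAsFactors = FALSE)
    att_rows[[vi]] <- data.frame(
      vertex = v, acquisition = seq_len(prep$n_acq),
      amplitude = beta_all[length(freqs) + 1L, ],
      stringsAsFactors = FALSE)
  }
  fit <- structure(list(
    vertices = vertices,
    hrf_weights = W,
    amplitudes = do.call(rbind, amp_rows),
    attention = do.call(rbind, att_rows),
    sse = SSE,
    prep = prep,
    basis = basis),
    class = "fit_result")
  avg <- clean_and_average(bold, fit, schedules)
  fit$r2 <- avg$r2
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Filtered design block for acquisition a at HRF weights w.
.combine_block <- function(prep, a, w) {
  p <- prep$ncol_per
  C <- prep$blocks[[a]]
  X <- matrix(0, nrow(C), p)
  for (k in seq_len(prep$nb))
    X <- X + w[k] * C[, (k - 1L) * p + seq_len(p), drop = FALSE]
  X
}

#' Attention-cleaned, A/B-averaged data and goodness of fit
#'
#' Subtracts the fitted attention component from the (high-pass filtered)
#' data, averages the six acquisitions per direction with stimulus ordering
#' "A" and the six with ordering "B", concatenates these per direction, and
#' computes the R^2 of the equally averaged stimulus model against the
#' result. Variance attributable to the attention task is thereby excluded
#' from R^2. Zero-variance averaged data yields R^2 = 0.
#'
#' @param bold A `bold_dataset`.
#' @param fit A `fit_result` from [fit_timeseries()].
#' @param schedules Schedules (default: from `bold`).
#' @return List with `average` and `model` (vertices x concatenated-time
#'   matrices), `segments` (data.frame: direction, sequence_label per 336 s
#'   segment), and `r2` (per fitted vertex).
#' @export
clean_and_average <- function(bold, fit, schedules = bold$schedules) {
  prep <- fit$prep
  n_t <- prep$n_t
  p <- prep$ncol_per
  Q <- prep$Q
  dirs <- vapply(schedules, function(s) s$trials$direction[1], character(1))
  labs <- vapply(schedules, function(s) s$trials$sequence_label[1],
                 character(1))
  seg <- expand.grid(sequence_label = c("A", "B"),
                     direction = stimulus_directions(),
                     stringsAsFactors = FALSE)[, 2:1]
  for (i in seq_len(nrow(seg))) {
    if (!any(dirs == seg$direction[i] & labs == seg$sequence_label[i]))
      stop("missing acquisitions for ", seg$direction[i], "_",
           seg$sequence_label[i])
  }
  nv <- length(fit$vertices)
  avg <- matrix(0, nv, n_t * nrow(seg))
  mod <- matrix(0, nv, n_t * nrow(seg))
  r2 <- numeric(nv)
  Y <- t(bold$data)
  for (a in seq_len(prep$n_acq)) {
    rows <- (a - 1L) * n_t + seq_len(n_t)
    Y[rows, ] <- Y[rows, , drop = FALSE] -
      Q %*% crossprod(Q, Y[rows, , drop = FALSE])
  }
  for (vi in seq_len(nv)) {
    v <- fit$vertices[vi]
    w <- fit$hrf_weights[vi, ]
    cw <- .boxcar_peak(kernel_from_params(fit$basis, w))
    amps <- fit$amplitudes[fit$amplitudes$vertex == v, ]
    atts <- fit$attention[fit$attention$vertex == v, ]
    for (i in seq_len(nrow(seg))) {
      sel <- which(dirs == seg$direction[i] & labs == seg$sequence_label[i])
      cols <- (i - 1L) * n_t + seq_len(n_t)
      acc_d <- numeric(n_t)
      acc_m <- numeric(n_t)
      for (a in sel) {
        X <- .combine_block(prep, a, w) / cw
        beta_f <- amps$amplitude[amps$acquisition == a]
        beta_att <- atts$amplitude[atts$acquisition == a]
        rows <- (a - 1L) * n_t + seq_len(n_t)
        acc_d <- acc_d + Y[rows, v] - X[, p] * beta_att
        acc_m <- acc_m + drop(X[, seq_len(p - 1L), drop = FALSE] %*% beta_f)
      }
      avg[vi, cols] <- acc_d / length(sel)
      mod[vi, cols] <- acc_m / length(sel)
    }
    sst <- sum(avg[vi, ]^2)
    r2[vi] <- if (sst < 1e-20) 0 else 1 - sum((avg[vi, ] - mod[vi, ])^2) / sst
  }
  list(average = avg, model = mod, segments = seg, r2 = r2)
}

#' Select vertices by goodness of fit
#'
#' @param fit A `fit_result`, or a numeric vector of R^2 values.
#' @param threshold Strict lower bound on R^2 (default 0.1).
#' @return Integer vector of selected vertex ids (possibly empty).
#' @export
select_vertices <- function(fit, threshold = 0.1) {
  r2 <- if (inherits(fit, "fit_result")) fit$r2 else fit
  v <- if (inherits(fit, "fit_result")) fit$vertices else seq_along(r2)
  v[which(r2 > threshold)]
}

#' Amplitudes relative to the 0 Hz condition
#'
#' Subtracts, within each (vertex, acquisition), the 0 Hz amplitude from
#' every frequency's amplitude; 0 Hz entries become 0.
#'
#' @param table Amplitude data frame with columns `vertex` (optional),
#'   `acquisition`, `direction`, `frequency_hz`, `amplitude`.
#' @return The table with `amplitude` replaced by its 0 Hz-relative value.
#' @export
relative_amplitudes <- function(table) {
  key <- if ("vertex" %in% names(table))
    interaction(table$vertex, table$acquisition, drop = TRUE)
  else factor(table$acquisition)
  base <- stats::ave(ifelse(table$frequency_hz == 0, table$amplitude, NA),
                     key, FUN = function(x) {
                       b <- x[!is.na(x)]
                       if (length(b) == 0)
                         stop("0 Hz amplitude missing in an acquisition")
                       b[1]
                     })
  table$amplitude <- table$amplitude - base
  table
}

#' Measure counts per condition crossing
#'
#' @param table An amplitude data frame.
#' @return Table of counts per (direction x frequency), per vertex averaged;
#'   for the full 36-acquisition study every crossing has 12 measures.
#' @export
n_measures <- function(table) {
  nv <- if ("vertex" %in% names(table))
    length(unique(table$vertex)) else 1L
  tab <- table(table$direction, table$frequency_hz)
  tab / nv
}

#' Write an amplitude table as TSV
#'
#' @param table Amplitude data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_amplitudes_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
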