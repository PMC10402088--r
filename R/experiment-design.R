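#' @keywords internal
"_PACKAGE"

# Stimulus constants shared across the package.
# Frequencies are the seven log-spaced flicker rates (0 Hz = steady field);
# directions are the three post-receptoral channels: achromatic light flux
# (LMS), red-green (LM, i.e. L minus M), and blue-yellow (S).

#' Stimulus flicker frequencies (Hz)
#'
#' The seven flicker frequencies used by the experimental design, including
#' the 0 Hz (steady background) condition.
#'
#' @return Numeric vector of length 7.
#' @export
stimulus_frequencies <- function() c(0, 2, 4, 8, 16, 32, 64)

#' Post-receptoral stimulus directions
#'
#' @return Character vector: `"LMS"` (achromatic light flux), `"LM"`
#'   (red-green, L minus M), `"S"` (blue-yellow).
#' @export
stimulus_directions <- function() c("LMS", "LM", "S")

.TRIAL_DUR <- 12
.N_TRIALS <- 28
.ACQ_DUR <- 336
.TR <- 1

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a first-order counterbalanced condition sequence
#'
#' Constructs an ordered sequence over `K` conditions in which every ordered
#' pair of conditions (including immediate repeats) occurs exactly once among
#' consecutive elements. Such a sequence has length `K^2 + 1` and corresponds
#' to an Eulerian circuit on the complete directed graph with self-loops over
#' the `K` conditions; the circuit is found by a seeded randomized Hierholzer
#' search, so the result is reproducible given `seed`.
#'
#' @param K Number of conditions (positive integer).
#' @param seed Integer seed for the randomized search.
#' @param max_restarts Bound on seeded restarts before giving up.
#' @return An object of class `counterbalanced_sequence`: a list with
#'   `elements` (integer vector of length `K^2 + 1`, values in `1:K`) and `K`.
#' @examples
#' s <- make_counterbalanced_sequence(7, seed = 1)
#' length(s$elements)  # 50
#' @export
make_counterbalanced_sequence <- function(K, seed = 1, max_restarts = 50L) {
  stopifnot(is.numeric(K), length(K) == 1, K >= 1, K == round(K))
  K <- as.integer(K)
  for (attempt in seq_len(max_restarts)) {
    elements <- .with_seed(seed + attempt - 1L, .euler_sequence(K))
    cand <- structure(list(elements = elements, K = K),
                      class = "counterbalanced_sequence")
    if (is_counterbalanced(cand)) return(cand)
  }
  stop("no valid counterbalanced sequence found within ", max_restarts,
       " seeded restarts")
}

# Randomized Hierholzer walk on the complete digraph with self-loops.
# The graph is balanced and strongly connected, so an Eulerian circuit
# always exists; random edge choices give a pseudo-random ordering.
.euler_sequence <- function(K) {
  remaining <- matrix(TRUE, K, K)  # remaining[i, j]: edge i -> j unused
  start <- sample.int(K, 1)
  stack <- integer(K * K + 1L)
  stack[1] <- start
  top <- 1L
  circuit <- integer(K * K + 1L)
  ncirc <- 0L
  while (top > 0L) {
    v <- stack[top]
    out <- which(remaining[v, ])
    if (length(out) > 0L) {
      u <- if (length(out) == 1L) out else sample(out, 1)
      remaining[v, u] <- FALSE
      top <- top + 1L
      stack[top] <- u
    } else {
      ncirc <- ncirc + 1L
      circuit[ncirc] <- v
      top <- top - 1L
    }
  }
  rev(circuit[seq_len(ncirc)])
}

#' Check the first-order counterbalance property
#'
#' @param seq A `counterbalanced_sequence` (or a list with `elements`, `K`).
#' @return `TRUE` if the consecutive-pair count matrix is exactly the
#'   all-ones `K` x `K` matrix and the length is `K^2 + 1`.
#' @export
is_counterbalanced <- function(seq) {
  e <- seq$elements; K <- seq$K
  if (length(e) != K^2 + 1L) return(FALSE)
  counts <- pair_counts(seq)
  all(counts == 1L)
}

#' Consecutive-pair count matrix of a sequence
#'
#' @param seq A `counterbalanced_sequence`.
#' @return `K` x `K` integer matrix; entry (i, j) counts occurrences of the
#'   ordered pair (i, j) among consecutive elements.
#' @export
pair_counts <- function(seq) {
  e <- seq$elements; K <- seq$K
  counts <- matrix(0L, K, K)
  for (i in seq_len(length(e) - 1L)) {
    counts[e[i], e[i + 1L]] <- counts[e[i], e[i + 1L]] + 1L
  }
  counts
}

#' Split a 50-element master sequence into padded A/B trial lists
#'
#' The master sequence is divided into its first and second 25 elements; each
#' sub-sequence is padded with three 0 Hz trials at the end, yielding two
#' 28-trial lists.
#'
#' @param seq A `counterbalanced_sequence` of length 50 over 7 conditions.
#' @return List with `A` and `B`: numeric vectors of 28 flicker frequencies
#'   (Hz).
#' @export
split_and_pad <- function(seq) {
  if (length(seq$elements) != 50L)
    stop("split_and_pad requires a 50-element master sequence, got ",
         length(seq$elements))
  freqs <- stimulus_frequencies()
  a <- c(freqs[seq$elements[1:25]], rep(0, 3))
  b <- c(freqs[seq$elements[26:50]], rep(0, 3))
  list(A = a, B = b)
}

#' Build one acquisition's stimulus schedule
#'
#' @param frequencies Vector of 28 trial flicker frequencies (Hz).
#' @param direction One of `stimulus_directions()`.
#' @param sequence_label `"A"` or `"B"`.
#' @param attention_prob Per-trial probability of an attention event.
#' @return A `stimulus_schedule`: list with `trials` (data.frame: onset,
#'   duration, frequency_hz, direction, sequence_label), `attention_onsets`
#'   (seconds; each event lasts 0.25 s and is constrained to avoid the first
#'   and last 2 s of its trial), and `acquisition_duration` (336 s).
#' @export
make_schedule <- function(frequencies, direction, sequence_label,
                          attention_prob = 0.33) {
  stopifnot(length(frequencies) == .N_TRIALS,
            all(frequencies %in% stimulus_frequencies()),
            direction %in% stimulus_directions(),
            sequence_label %in% c("A", "B"))
  onsets <- (seq_len(.N_TRIALS) - 1L) * .TRIAL_DUR
  trials <- data.frame(
    onset = onsets,
    duration = .TRIAL_DUR,
    frequency_hz = frequencies,
    direction = direction,
    sequence_label = sequence_label,
    stringsAsFactors = FALSE
  )
  has_event <- stats::runif(.N_TRIALS) < attention_prob
  # event is 0.25 s; excluded from the first and last 2 s of the trial
  att <- stats::runif(sum(has_event),
                      min = onsets[has_event] + 2,
                      max = onsets[has_event] + .TRIAL_DUR - 2 - 0.25)
  structure(list(trials = trials,
                 attention_onsets = sort(att),
                 acquisition_duration = .ACQ_DUR),
            class = "stimulus_schedule")
}

# Master sequence for the study: counterbalanced, rotated so that element
# 26 (the first element of sub-sequence B) is the 0 Hz condition — which
# preserves support for every ordered frequency pair after the A/B split —
# and with every condition present in both halves, so that each
# acquisition's design matrix is full rank. Rotating a closed Eulerian
# circuit preserves the exactly-once pair property; candidate rotations and
# fresh seeds are tried until both constraints hold.
.study_master_sequence <- function(seed, max_restarts = 50L) {
  for (attempt in 0:(max_restarts - 1L)) {
    master <- make_counterbalanced_sequence(7, seed = seed + 1009L * attempt)
    cyc <- master$elements[-length(master$elements)]
    m <- length(cyc)
    for (p in which(cyc == 1L)) {
      s <- ((p - 26L) %% m) + 1L
      rotated <- cyc[((s - 1L + seq_len(m) - 1L) %% m) + 1L]
      e <- c(rotated, rotated[1])
      if (e[26] == 1L && all(1:7 %in% e[1:25]) && all(1:7 %in% e[26:50])) {
        out <- structure(list(elements = e, K = 7L),
                         class = "counterbalanced_sequence")
        if (is_counterbalanced(out)) return(out)
      }
    }
  }
  stop("no counterbalanced master sequence with full-rank halves found ",
       "within ", max_restarts, " seeded restarts")
}

#' Build the full 36-acquisition study schedule
#'
#' Generates one counterbalanced master sequence (rotated so that element 26
#' is the 0 Hz condition, which preserves support for every ordered frequency
#' pair after the A/B split, and constrained so every frequency occurs in
#' both halves, keeping each acquisition's design full rank), splits and
#' pads it, and lays out 6 blocks of 6 acquisitions in the fixed
#' within-block order LMS_A, LM_A, S_A, S_B, LM_B, LMS_B. Attention events
#' are drawn per trial with probability 0.33.
#'
#' @param seed Integer seed controlling both the sequence search and the
#'   attention events.
#' @param n_blocks Number of blocks (default 6).
#' @return List of `6 * n_blocks` `stimulus_schedule` objects, with
#'   attributes `master_sequence` and `block` / ordering metadata on each
#'   schedule (`$block` element).
#' @export
build_study_schedule <- function(seed = 1, n_blocks = 6L) {
  master <- .study_master_sequence(seed)
  ab <- split_and_pad(master)
  order_tab <- data.frame(
    direction = c("LMS", "LM", "S", "S", "LM", "LMS"),
    label = c("A", "A", "A", "B", "B", "B"),
    stringsAsFactors = FALSE
  )
  schedules <- .with_seed(seed, {
    out <- vector("list", 6L * n_blocks)
    k <- 0L
    for (b in seq_len(n_blocks)) {
      for (i in seq_len(6L)) {
        k <- k + 1L
        sch <- make_schedule(ab[[order_tab$label[i]]],
                             order_tab$direction[i], order_tab$label[i])
        sch$block <- b
        sch$acquisition <- k
        out[[k]] <- sch
      }
    }
    out
  })
  attr(schedules, "master_sequence") <- master
  schedules
}

#' Build the stimulus/attention design matrix
#'
#' One covariate per flicker frequency per acquisition (a 0/1 step function
#' with 12 s support over every trial of that frequency) plus one attention
#' covariate per acquisition (unit impulses at the volume containing each
#' event). With `hrf_kernel` supplied, every column is convolved with the
#' kernel within its acquisition (responses do not bleed across acquisition
#' boundaries).
#'
#' @param schedules A `stimulus_schedule` or list of them (contiguous
#'   acquisitions, TR = 1 s).
#' @param hrf_kernel Optional numeric kernel sampled at 1 s.
#' @return An object of class `design_matrix`: list with `matrix`
#'   (time x covariates), `labels` (data.frame: column, acquisition,
#'   direction, type, frequency_hz), `convolved`, `acquisition_length`.
#' @export
build_design_matrix <- function(schedules, hrf_kernel = NULL) {
  if (inherits(schedules, "stimulus_schedule")) schedules <- list(schedules)
  freqs <- stimulus_frequencies()
  n_acq <- length(schedules)
  n_t <- .ACQ_DUR
  ncol_per <- length(freqs) + 1L
  X <- matrix(0, n_t * n_acq, ncol_per * n_acq)
  labels <- vector("list", n_acq)
  for (a in seq_len(n_acq)) {
    sch <- schedules[[a]]
    bad <- !(sch$trials$frequency_hz %in% freqs)
    if (any(bad))
      stop("unknown frequency value in acquisition ", a, ": ",
           paste(unique(sch$trials$frequency_hz[bad]), collapse = ", "))
    row0 <- (a - 1L) * n_t
    col0 <- (a - 1L) * ncol_per
    block <- matrix(0, n_t, ncol_per)
    for (i in seq_len(nrow(sch$trials))) {
      f_idx <- match(sch$trials$frequency_hz[i], freqs)
      rows <- sch$trials$onset[i] + seq_len(.TRIAL_DUR)
      block[rows, f_idx] <- 1
    }
    if (length(sch$attention_onsets) > 0) {
      bins <- floor(sch$attention_onsets) + 1L
      for (b in bins) block[b, ncol_per] <- block[b, ncol_per] + 1
    }
    if (!is.null(hrf_kernel)) block <- apply(block, 2, conv_trunc, hrf_kernel)
    X[row0 + seq_len(n_t), col0 + seq_len(ncol_per)] <- block
    labels[[a]] <- data.frame(
      column = col0 + seq_len(ncol_per),
      acquisition = a,
      direction = sch$trials$direction[1],
      type = c(rep("frequency", length(freqs)), "attention"),
      frequency_hz = c(freqs, NA),
      stringsAsFactors = FALSE
    )
  }
  structure(list(matrix = X,
                 labels = do.call(rbind, labels),
                 convolved = !is.null(hrf_kernel),
                 acquisition_length = n_t),
            class = "design_matrix")
}

#' Causal convolution truncated to the input length
#'
#' @param x Numeric series.
#' @param kernel Numeric kernel (impulse response at the series' sampling).
#' @return Numeric series of `length(x)`.
#' @export
conv_trunc <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(kernel))), rev(kernel),
                         type = "open")
  out[seq_len(n)]
}

# Discrete-cosine (DCT-II) regressor set for drift below `cutoff_hz`,
# orthonormalized; includes the constant term (k = 0).
.dct_drift_basis <- function(n, cutoff_hz, tr = 1) {
  kmax <- floor(2 * n * tr * cutoff_hz) + 1L
  k <- 0:kmax
  k <- k[k / (2 * n * tr) < cutoff_hz]
  t <- seq_len(n) - 1L
  B <- vapply(k, function(kk) cos(pi * kk * (t + 0.5) / n), numeric(n))
  qr.Q(qr(B))
}

#' High-pass filter by projection onto a discrete cosine drift set
#'
#' Removes the component of the signal spanned by a constant plus
#' discrete-cosine regressors with frequency below `cutoff_hz`, applied
#' independently to each acquisition-length segment. The operation is an
#' orthogonal projection and therefore idempotent.
#'
#' @param signal Numeric vector or matrix (time in rows, series in columns).
#' @param cutoff_hz Cutoff frequency (default 0.0387 Hz).
#' @param acquisition_length Segment length in samples; defaults to the whole
#'   series.
#' @param tr Sampling interval in seconds (default 1).
#' @return Filtered signal, same shape as the input.
#' @export
highpass_project <- function(signal, cutoff_hz = 0.0387,
                             acquisition_length = NULL, tr = 1) {
  vec <- is.null(dim(signal))
  x <- if (vec) matrix(signal, ncol = 1) else as.matrix(signal)
  if (nrow(x) == 0 || length(x) == 0) stop("empty signal")
  n <- nrow(x)
  if (is.null(acquisition_length)) acquisition_length <- n
  if (n %% acquisition_length != 0)
    stop("signal length ", n, " is not a multiple of acquisition_length ",
         acquisition_length)
  Q <- .dct_drift_basis(acquisition_length, cutoff_hz, tr)
  for (a in seq_len(n %/% acquisition_length)) {
    rows <- (a - 1L) * acquisition_length + seq_len(acquisition_length)
    x[rows, ] <- x[rows, , drop = FALSE] -
      Q %*% crossprod(Q, x[rows, , drop = FALSE])
  }
  if (vec) drop(x) else x
}

#' Write schedules as a BIDS-style events TSV
#'
#' @param schedules List of `stimulus_schedule` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(schedules, path) {
  if (inherits(schedules, "stimulus_schedule")) schedules <- list(schedules)
  rows <- lapply(seq_along(schedules), function(a) {
    sch <- schedules[[a]]
    tr <- sch$trials
    att <- vapply(seq_len(nrow(tr)), function(i) {
      in_trial <- sch$attention_onsets >= tr$onset[i] &
        sch$attention_onsets < tr$onset[i] + tr$duration[i]
      paste(format(sch$attention_onsets[in_trial], digits = 10),
            collapse = ";")
    }, character(1))
    cbind(acquisition = a, tr, attention_onsets = att)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read schedules from a BIDS-style events TSV
#'
#' @param path File written by [write_events_tsv()].
#' @return List of `stimulus_schedule` objects.
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = list(attention_onsets = "character"))
  lapply(split(df, df$acquisition), function(d) {
    d <- d[order(d$onset), ]
    att <- unlist(lapply(strsplit(d$attention_onsets[nzchar(d$attention_onsets)],
                                  ";"), as.numeric))
    if (is.null(att)) att <- numeric(0)
    structure(list(trials = data.frame(
      onset = d$onset, duration = d$duration,
      frequency_hz = d$frequency_hz, direction = d$direction,
      sequence_label = d$sequence_label, stringsAsFactors = FALSE),
      attention_onsets = sort(att),
      acquisition_duration = .ACQ_DUR,
      acquisition = d$acquisition[1]),
      class = "stimulus_schedule")
  })
}

#' Export a design matrix as delimited text
#'
#' @param dm A `design_matrix`.
#' @param path Output path. Columns are labeled
#'   `acq<NN>_<direction>_<freq|att>`.
#' @return The path, invisibly.
#' @export
write_design_matrix <- function(dm, path) {
  lab <- dm$labels
  nm <- ifelse(lab$type == "attention",
               sprintf("acq%02d_%s_att", lab$acquisition, lab$direction),
               sprintf("acq%02d_%s_%gHz", lab$acquisition, lab$direction,
                       lab$frequency_hz))
  m <- dm$matrix
  colnames(m) <- nm
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
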