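# Multi-vertex pattern analysis: standardization, split-half similarity
# matrices over the six non-zero frequencies, and best-match decoding of a
# target frequency.

#' Build a patterns array from an amplitude table
#'
#' Converts a long amplitude table (relative to the 0 Hz condition) into a
#' vertices x frequency x acquisition array for one direction or a pooled
#' class, keeping the six non-zero frequencies.
#'
#' @param table Amplitude data frame with `vertex`, `acquisition`,
#'   `frequency_hz`, `amplitude` (0 Hz-relative), optionally filtered by
#'   direction beforehand.
#' @return Numeric array \[vertex, frequency, acquisition\] with frequency
#'   dimnames.
#' @export
patterns_from_amplitudes <- function(table) {
  table <- table[table$frequency_hz > 0, , drop = FALSE]
  verts <- sort(unique(table$vertex))
  freqs <- sort(unique(table$frequency_hz))
  acqs <- sort(unique(table$acquisition))
  arr <- array(NA_real_, c(length(verts), length(freqs), length(acqs)),
               dimnames = list(NULL, freqs, acqs))
  arr[cbind(match(table$vertex, verts), match(table$frequency_hz, freqs),
            match(table$acquisition, acqs))] <- table$amplitude
  if (anyNA(arr)) stop("incomplete vertex x frequency x acquisition table")
  arr
}

#' Standardize multi-vertex patterns
#'
#' Within each (acquisition, frequency), the across-vertex amplitude pattern
#' is standardized to mean zero and unit standard deviation (population SD,
#' i.e. the n-denominator form).
#'
#' @param patterns Array \[vertex, frequency, acquisition\].
#' @return Array of the same shape with standardized patterns.
#' @export
standardize_patterns <- function(patterns) {
  if (dim(patterns)[1] < 2) stop("need >= 2 vertices to standardize")
  out <- patterns
  for (a in seq_len(dim(patterns)[3])) {
    for (f in seq_len(dim(patterns)[2])) {
      x <- patterns[, f, a]
      s <- sqrt(mean((x - mean(x))^2))
      if (!is.finite(s) || s < 1e-300)
        stop("zero across-vertex variance for frequency ",
             dimnames(patterns)[[2]][f], " (degenerate pattern)")
      out[, f, a] <- (x - mean(x)) / s
    }
  }
  out
}

# All unordered split-half partitions of n acquisitions: a matrix with one
# half per column (the complement is implied); acquisition 1 is always in
# the returned half, so each unordered partition appears exactly once.
.split_halves <- function(n) {
  if (n %% 2 != 0) stop("odd acquisition count; split-half requires even")
  cmb <- utils::combn(n, n %/% 2)
  cmb[, cmb[1, ] == 1, drop = FALSE]
}

#' Split-half pattern similarity matrix
#'
#' For each unordered partition of the acquisitions into halves, patterns
#' are averaged within each half and every frequency pair is correlated
#' across halves (Pearson); each partition's matrix is symmetrized by
#' averaging with its transpose (equivalently, with the complementary
#' ordering) and matrices are averaged over all partitions (all C(12,6)/2 =
#' 462 for the full design).
#'
#' @param patterns Array \[vertex, frequency, acquisition\] (standardized
#'   patterns; an even number of acquisitions).
#' @param label Optional direction / class label to carry along.
#' @return A `pattern_similarity`: list with `values` (frequency x
#'   frequency), `n_partitions`, `label`.
#' @export
split_half_similarity <- function(patterns, label = NULL) {
  n <- dim(patterns)[3]
  halves <- .split_halves(n)
  nf <- dim(patterns)[2]
  acc <- matrix(0, nf, nf)
  for (j in seq_len(ncol(halves))) {
    h1 <- halves[, j]
    h2 <- setdiff(seq_len(n), h1)
    m1 <- apply(patterns[, , h1, drop = FALSE], c(1, 2), mean)
    m2 <- apply(patterns[, , h2, drop = FALSE], c(1, 2), mean)
    M <- stats::cor(m1, m2)
    acc <- acc + (M + t(M)) / 2
  }
  values <- acc / ncol(halves)
  dimnames(values) <- dimnames(patterns)[c(2, 2)]
  structure(list(values = values, n_partitions = ncol(halves),
                 label = label),
            class = "pattern_similarity")
}

# Strict best-match rule: the target wins only if its correlation strictly
# exceeds every competitor (ties count as incorrect).
.best_match_correct <- function(cors, target_idx) {
  cors[target_idx] > max(cors[-target_idx])
}

#' Best-match decoding of a target frequency
#'
#' For every split-half partition (both orientations: each half serves once
#' as the held-out set), the target frequency's averaged pattern in one half
#' is correlated with the held-out half's patterns for all candidate
#' frequencies; the case is correct when the target frequency is the
#' strictly best match. Returns the proportion of correct cases.
#'
#' @param patterns Array \[vertex, frequency, acquisition\].
#' @param target_freq Target frequency in Hz (default 64).
#' @param vertices Optional integer subset of the vertex dimension (e.g. an
#'   eccentricity band); must be non-empty.
#' @return List with `proportion_correct` and `n_cases`.
#' @export
decode_target <- function(patterns, target_freq = 64, vertices = NULL) {
  if (!is.null(vertices)) {
    if (length(vertices) == 0) stop("empty vertex subset")
    patterns <- patterns[vertices, , , drop = FALSE]
  }
  freqs <- as.numeric(dimnames(patterns)[[2]])
  if (length(freqs) < 2) stop("need >= 2 candidate frequencies")
  t_idx <- match(target_freq, freqs)
  if (is.na(t_idx)) stop("target frequency not among the patterns")
  n <- dim(patterns)[3]
  halves <- .split_halves(n)
  correct <- 0L
  total <- 0L
  for (j in seq_len(ncol(halves))) {
    h1 <- halves[, j]
    h2 <- setdiff(seq_len(n), h1)
    m1 <- apply(patterns[, , h1, drop = FALSE], c(1, 2), mean)
    m2 <- apply(patterns[, , h2, drop = FALSE], c(1, 2), mean)
    for (ori in 1:2) {
      template <- if (ori == 1) m1[, t_idx] else m2[, t_idx]
      held <- if (ori == 1) m2 else m1
      cors <- drop(stats::cor(template, held))
      correct <- correct + .best_match_correct(cors, t_idx)
      total <- total + 1L
    }
  }
  list(proportion_correct = unname(correct / total), n_cases = total)
}

#' Null Monte-Carlo chance level for best-match decoding
#'
#' Draws i.i.d. Gaussian target and candidate patterns and applies the same
#' strict best-match rule as [decode_target()]; with `n_freq` candidates the
#' expected proportion correct is `1 / n_freq` (0.167 for six).
#'
#' @param n_draws Number of simulated decoding cases.
#' @param n_vertices Pattern length per draw.
#' @param n_freq Number of candidate frequencies (default 6).
#' @param seed Integer seed.
#' @return Proportion of correct best matches over the draws.
#' @export
decode_chance_mc <- function(n_draws = 1e5, n_vertices = 20, n_freq = 6,
                             seed = 1) {
  .with_seed(seed, {
    centre <- function(m) sweep(m, 2, colMeans(m))
    Tm <- centre(matrix(stats::rnorm(n_vertices * n_draws),
                        n_vertices, n_draws))
    Tn <- sqrt(colSums(Tm^2))
    score <- matrix(0, n_draws, n_freq)
    for (f in seq_len(n_freq)) {
      C <- centre(matrix(stats::rnorm(n_vertices * n_draws),
                         n_vertices, n_draws))
      score[, f] <- colSums(Tm * C) / (Tn * sqrt(colSums(C^2)))
    }
    target_idx <- 1L
    wins <- score[, target_idx] >
      apply(score[, -target_idx, drop = FALSE], 1, max)
    mean(wins)
  })
}

#' Write a pattern similarity matrix as labeled TSV
#'
#' @param sim A `pattern_similarity`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  utils::write.table(sim$values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
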