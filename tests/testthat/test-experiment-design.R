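test_that("counterbalanced sequences contain every ordered pair exactly once", {
  # K = 1: the only ordered pair (1,1) once
  s1 <- make_counterbalanced_sequence(1, seed = 1)
  expect_identical(s1$elements, c(1L, 1L))

  # K = 2: length 5, the 4 consecutive pairs are exactly the 4 ordered pairs;
  # cross-check against exhaustive enumeration of all 2^5 candidate sequences
  s2 <- make_counterbalanced_sequence(2, seed = 1)
  expect_length(s2$elements, 5)
  valid <- list()
  for (code in 0:(2^5 - 1)) {
    e <- as.integer(intToBits(code)[1:5]) + 1L
    cand <- structure(list(elements = e, K = 2L),
                      class = "counterbalanced_sequence")
    if (is_counterbalanced(cand)) valid[[length(valid) + 1]] <- e
  }
  expect_gt(length(valid), 0)
  expect_true(any(vapply(valid, identical, logical(1), s2$elements)))

  # K = 2..7, several seeds: pair-count matrix is exactly all ones
  for (K in 2:7) {
    for (seed in 1:3) {
      s <- make_counterbalanced_sequence(K, seed = seed)
      expect_length(s$elements, K^2 + 1)
      expect_true(all(pair_counts(s) == 1L))
    }
  }

  # K = 7 master sequence has the study's 50 elements
  expect_length(make_counterbalanced_sequence(7, seed = 5)$elements, 50)

  # seeded search is reproducible
  expect_identical(make_counterbalanced_sequence(7, seed = 2)$elements,
                   make_counterbalanced_sequence(7, seed = 2)$elements)
})

test_that("split_and_pad yields two padded 28-trial lists partitioning the master", {
  s <- make_counterbalanced_sequence(7, seed = 1)
  ab <- split_and_pad(s)
  expect_length(ab$A, 28)
  expect_length(ab$B, 28)
  expect_identical(ab$A[26:28], rep(0, 3))
  expect_identical(ab$B[26:28], rep(0, 3))
  expect_identical(c(ab$A[1:25], ab$B[1:25]),
                   stimulus_frequencies()[s$elements])
  short <- structure(list(elements = rep(1L, 10), K = 3L),
                     class = "counterbalanced_sequence")
  expect_error(split_and_pad(short), "50-element")
})

test_that("the study schedule has 36 acquisitions with the block structure", {
  sch <- fx_schedules()
  expect_length(sch, 36)
  dirs <- vapply(sch, function(s) s$trials$direction[1], character(1))
  labs <- vapply(sch, function(s) s$trials$sequence_label[1], character(1))
  blocks <- vapply(sch, function(s) s$block, numeric(1))
  for (b in 1:6) {
    expect_equal(as.vector(table(dirs[blocks == b])[c("LM", "LMS", "S")]),
                 c(2L, 2L, 2L))
    expect_identical(dirs[blocks == b],
                     c("LMS", "LM", "S", "S", "LM", "LMS"))
    expect_identical(labs[blocks == b], c("A", "A", "A", "B", "B", "B"))
  }
  for (s in sch) {
    expect_equal(nrow(s$trials), 28)
    expect_equal(s$acquisition_duration, 336)
    expect_identical(s$trials$frequency_hz[26:28], rep(0, 3))
  }
  # total study duration
  expect_equal(sum(vapply(sch, function(s) s$acquisition_duration,
                          numeric(1))), 36 * 336)
  # same seed reproduces the schedule exactly
  expect_identical(build_study_schedule(seed = 1), sch)
})

test_that("attention events respect the trial window and the 0.33 rate", {
  # Monte-Carlo over many seeded acquisitions
  n_events <- withr::with_seed(42, {
    vapply(1:1200, function(i) {
      s <- make_schedule(rep(stimulus_frequencies(), 4), "LMS", "A")
      for (a in s$attention_onsets) {
        trial_on <- 12 * floor(a / 12)
        expect_gte(a, trial_on + 2)
        expect_lte(a + 0.25, trial_on + 10)
      }
      length(s$attention_onsets)
    }, numeric(1))
  })
  expect_equal(mean(n_events), 0.33 * 28, tolerance = 0.02)
})

test_that("design matrices have the expected shape and support", {
  sch <- fx_schedules()
  dm <- build_design_matrix(sch)
  expect_equal(ncol(dm$matrix), 288)
  expect_equal(nrow(dm$matrix), 12096)
  dm1 <- build_design_matrix(sch[[1]])
  expect_equal(ncol(dm1$matrix), 8)
  # unconvolved frequency column sum = 12 s x number of trials
  lab <- dm1$labels
  for (f in stimulus_frequencies()) {
    n_tr <- sum(sch[[1]]$trials$frequency_hz == f)
    col <- lab$column[lab$type == "frequency" & lab$frequency_hz == f]
    expect_equal(sum(dm1$matrix[, col]), 12 * n_tr)
  }
  # column count law for arbitrary schedule subsets
  dm5 <- build_design_matrix(sch[1:5])
  expect_equal(ncol(dm5$matrix), (7 + 1) * 5)
  # convolution stays within the acquisition block
  kern <- double_gamma_hrf(0:27)
  dmc <- build_design_matrix(sch[1:2], hrf_kernel = kern)
  acq1_cols <- dmc$labels$column[dmc$labels$acquisition == 1]
  expect_true(all(dmc$matrix[337:672, acq1_cols] == 0))
  # unknown frequency raises
  bad <- toy_schedule(c(3, rep(0, 27)))
  expect_error(build_design_matrix(bad), "unknown frequency")
})

test_that("high-pass projection removes drift and passes the stimulus band", {
  n <- 336
  t <- 0:(n - 1)
  # constant -> zero
  expect_lt(max(abs(highpass_project(rep(2.5, n)))), 1e-10)
  # idempotent
  x <- sin(2 * pi * 0.03 * t) + rnorm(n)
  once <- highpass_project(x)
  expect_lt(max(abs(highpass_project(once) - once)), 1e-10)
  # matches an independent lm()-based projection oracle
  kmax <- 26
  B <- sapply(0:kmax, function(k) cos(pi * k * (t + 0.5) / n))
  oracle <- stats::residuals(stats::lm(x ~ B - 1))
  expect_lt(max(abs(once - oracle)), 1e-10)
  # 0.01 Hz drift: residual power below 5% of input power
  d <- sin(2 * pi * 0.01 * t)
  r <- highpass_project(d)
  expect_lt(sum(r^2) / sum(d^2), 0.05)
  # an above-cutoff DCT mode passes through exactly (orthogonality)
  hi <- cos(pi * 67 * (t + 0.5) / n)  # 0.0997 Hz
  expect_lt(max(abs(highpass_project(hi) - hi)), 1e-10)
  # a generic 0.1 Hz sinusoid keeps most of its power
  s01 <- sin(2 * pi * 0.1 * t)
  expect_gt(sum(highpass_project(s01)^2) / sum(s01^2), 0.95)
  expect_error(highpass_project(numeric(0)), "empty")
})

test_that("events TSVs round-trip schedules", {
  sch <- fx_schedules()[1:3]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(sch, path)
  back <- read_events_tsv(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(back[[i]]$trials, sch[[i]]$trials)
    expect_equal(back[[i]]$attention_onsets, sch[[i]]$attention_onsets,
                 tolerance = 1e-8)
  }
})
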