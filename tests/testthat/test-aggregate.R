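test_that("eccentricity band assignment partitions the visual field", {
  expect_equal(assign_band(1), 1)
  expect_equal(assign_band(64), 6)
  expect_equal(assign_band(2.8), 2)   # half-open convention
  expect_equal(assign_band(90), 6)    # upper edge included
  expect_equal(assign_band(0), 1)
  expect_true(is.na(assign_band(95)))
  ecc <- withr::with_seed(6, runif(500, 0, 90))
  b <- assign_band(ecc)
  expect_false(anyNA(b))
  expect_equal(sum(table(b)), 500)
  edges <- eccentricity_bands()$edges
  for (i in 1:6)
    expect_true(all(ecc[b == i] >= edges[i] & ecc[b == i] <= edges[i + 1]))
})

test_that("band averages match a brute-force group-by", {
  geom <- make_vertex_geometry(60, seed = 7)
  tab <- withr::with_seed(8, expand.grid(vertex = 1:60, acquisition = 1:4,
                                         direction = c("LMS", "LM"),
                                         frequency_hz = c(0, 16, 64),
                                         stringsAsFactors = FALSE))
  tab$amplitude <- withr::with_seed(9, rnorm(nrow(tab)))
  r2 <- withr::with_seed(10, runif(60, 0, 0.5))
  ba <- band_average(tab, geom, r2, threshold = 0.1)
  sel <- geom$vertex[r2 > 0.1]
  band <- assign_band(geom$eccentricity_deg)
  for (i in sample(nrow(ba), 40)) {
    vs <- sel[band[sel] == ba$band[i]]
    rows <- tab$vertex %in% vs & tab$direction == ba$direction[i] &
      tab$frequency_hz == ba$frequency_hz[i] &
      tab$acquisition == ba$acquisition[i]
    if (length(vs) == 0) {
      expect_true(is.na(ba$amplitude[i]))
    } else {
      expect_equal(ba$amplitude[i], mean(tab$amplitude[rows]))
    }
  }
  # empty band yields explicit NA, not zero
  geom2 <- geom
  geom2$eccentricity_deg <- pmin(geom2$eccentricity_deg, 40)  # empty band 6
  ba2 <- band_average(tab, geom2, r2, threshold = 0.1)
  expect_true(all(is.na(ba2$amplitude[ba2$band == 6])))
  expect_true(all(ba2$n_vertices[ba2$band == 6] == 0))
})

test_that("relative peak maps z-score per direction then average", {
  pf <- withr::with_seed(11, {
    cbind(LMS = 10^runif(50, 0.5, 1.5), LM = 10^runif(50, 0.3, 1.3),
          S = 10^runif(50, 0.2, 1.2))
  })
  rpm <- relative_peak_map(pf)
  for (d in 1:3) {
    expect_lt(abs(mean(rpm$z[, d])), 1e-12)
    expect_equal(sd(rpm$z[, d]), 1, tolerance = 1e-12)
  }
  # identical per-direction maps average to any one of them
  pf2 <- cbind(pf[, 1], pf[, 1], pf[, 1])
  rpm2 <- relative_peak_map(pf2)
  expect_equal(rpm2$map, rpm2$z[, 1])
  # doubling every peak frequency leaves the map unchanged
  rpm3 <- relative_peak_map(2 * pf)
  expect_equal(rpm3$map, rpm$map)
  expect_error(relative_peak_map(matrix(3, 5, 3)), "zero variance")
})

test_that("vertices with faster ground-truth peaks score higher on the map", {
  # label-known generative check: per-vertex amplitude tables built from
  # Watson truths with two distinct peak groups, plus measurement noise
  freqs <- c(2, 4, 8, 16, 32, 64)
  slow <- watson_params(2, 0.004240, 1.7, 0.85)   # ~8 Hz
  fast <- watson_params(2, 0.002117, 1.7, 0.85)   # ~16 Hz
  nv <- 20
  is_fast <- rep(c(FALSE, TRUE), each = nv / 2)
  tab <- withr::with_seed(12, {
    rows <- list()
    for (v in 1:nv) {
      p <- if (is_fast[v]) fast else slow
      for (d in c("LMS", "LM", "S")) {
        for (a in 1:4) {
          rows[[length(rows) + 1]] <- data.frame(
            vertex = v, acquisition = a, direction = d,
            frequency_hz = freqs,
            amplitude = watson_amplitude(freqs, p) + rnorm(6, sd = 0.1))
        }
      }
    }
    do.call(rbind, rows)
  })
  pf <- vertex_peak_frequencies(tab, seed = 1)
  rpm <- relative_peak_map(pf)
  # point-biserial association with the known fast/slow labels
  expect_gt(cor(rpm$map, as.numeric(is_fast)), 0.9)
  expect_gt(min(rpm$map[is_fast]), max(rpm$map[!is_fast]))
})

test_that("visual-field projection matches an analytic Gaussian render", {
  grid <- list(n = 61, half_width = 30, weight_floor = 1e-6)
  # single vertex: the deposited weight peaks at its field location and the
  # normalized image equals the vertex value over covered pixels
  g1 <- data.frame(vertex = 1, eccentricity_deg = 10, polar_angle_deg = 0,
                   prf_width_deg = 3, area = "V1")
  f1 <- project_to_visual_field(5, g1, grid)
  ij <- which(f1$weight == max(f1$weight), arr.ind = TRUE)
  expect_equal(f1$x[ij[2]], 10, tolerance = 1.1)  # x-position ~ ecc
  expect_equal(f1$y[ij[1]], 0, tolerance = 1.1)
  expect_equal(max(f1$image, na.rm = TRUE), 5)
  expect_equal(min(f1$image, na.rm = TRUE), 5)
  # constant values -> constant image over covered pixels
  g2 <- make_vertex_geometry(15, seed = 13)
  g2$eccentricity_deg <- pmin(g2$eccentricity_deg, 25)
  f2 <- project_to_visual_field(rep(2.5, 15), g2, grid)
  expect_equal(range(f2$image, na.rm = TRUE), c(2.5, 2.5))
  # two distant vertices reproduce two separable analytic Gaussian bumps
  g3 <- data.frame(vertex = 1:2, eccentricity_deg = c(15, 15),
                   polar_angle_deg = c(0, 180), prf_width_deg = c(2, 2),
                   area = "V1")
  f3 <- project_to_visual_field(c(1, 3), g3, grid)
  ax <- f3$x
  gauss <- function(x0, y0, s) {
    exp(-outer((ax - y0)^2, (ax - x0)^2, `+`) / (2 * s^2))
  }
  gA <- gauss(15, 0, 2); gB <- gauss(-15, 0, 2)
  analytic <- (1 * gA + 3 * gB) / (gA + gB)
  keep <- !is.na(f3$image)
  expect_equal(f3$image[keep], analytic[keep], tolerance = 1e-10)
})
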