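# Eccentricity banding, band-averaged amplitude summaries, z-scored
# relative peak-frequency maps, and projection of per-vertex values into
# the visual field.

#' Log-spaced eccentricity bands
#'
#' Division edges 0, 2.8, 5.6, 11.25, 22.5, 45, and 90 degrees; intervals
#' are half-open \[lo, hi) with the 90 degree edge included in the last
#' band.
#'
#' @return List with `edges` (length 7) and `centers` (geometric midpoints,
#'   with the innermost band's center the arithmetic midpoint).
#' @export
eccentricity_bands <- function() {
  edges <- c(0, 2.8, 5.6, 11.25, 22.5, 45, 90)
  centers <- sqrt(edges[-length(edges)] * edges[-1])
  centers[1] <- mean(edges[1:2])
  list(edges = edges, centers = centers)
}

#' Assign eccentricities to bands
#'
#' @param eccentricity Eccentricities in degrees.
#' @param edges Band edges (default [eccentricity_bands()]).
#' @return Integer band index (1-6); values outside \[0, 90\] give `NA`.
#' @export
assign_band <- function(eccentricity, edges = eccentricity_bands()$edges) {
  b <- findInterval(eccentricity, edges, rightmost.closed = TRUE)
  b[eccentricity < edges[1] | eccentricity > edges[length(edges)]] <- NA
  b
}

#' Band-averaged amplitude table
#'
#' Averages amplitudes over R^2-selected vertices within each eccentricity
#' band, per direction x frequency x acquisition. Bands with no selected
#' vertex yield explicit `NA` rows.
#'
#' @param amplitudes Amplitude data frame with a `vertex` column.
#' @param geometry Vertex geometry table.
#' @param r2 Per-vertex R^2 named/ordered like `geometry$vertex` (or a
#'   `fit_result`).
#' @param threshold Strict R^2 selection threshold (default 0.1).
#' @param edges Band edges.
#' @return Data frame: band, direction, frequency_hz, acquisition,
#'   amplitude, n_vertices.
#' @export
band_average <- function(amplitudes, geometry, r2, threshold = 0.1,
                         edges = eccentricity_bands()$edges) {
  if (inherits(r2, "fit_result")) {
    sel_v <- select_vertices(r2, threshold)
  } else {
    sel_v <- geometry$vertex[r2 > threshold]
  }
  band <- assign_band(geometry$eccentricity_deg, edges)
  names(band) <- geometry$vertex
  amp <- amplitudes[amplitudes$vertex %in% sel_v, , drop = FALSE]
  amp$band <- band[as.character(amp$vertex)]
  full <- expand.grid(band = seq_len(length(edges) - 1L),
                      direction = unique(amplitudes$direction),
                      frequency_hz = unique(amplitudes$frequency_hz),
                      acquisition = unique(amplitudes$acquisition),
                      stringsAsFactors = FALSE)
  if (nrow(amp) > 0) {
    agg <- stats::aggregate(amplitude ~ band + direction + frequency_hz +
                              acquisition, data = amp, FUN = mean)
    cnt <- stats::aggregate(vertex ~ band, data = unique(amp[, c("vertex",
                                                                 "band")]),
                            FUN = length)
    names(cnt)[2] <- "n_vertices"
  } else {
    agg <- cbind(full[0, ], amplitude = numeric(0))
    cnt <- data.frame(band = integer(0), n_vertices = integer(0))
  }
  out <- merge(full, agg, all.x = TRUE, sort = FALSE)
  out <- merge(out, cnt, all.x = TRUE, sort = FALSE)
  out$n_vertices[is.na(out$n_vertices)] <- 0L
  out[order(out$band, out$direction, out$acquisition, out$frequency_hz), ]
}

#' Relative peak temporal-frequency map
#'
#' Per direction, log10 peak frequencies across vertices are z-transformed
#' (mean subtracted, divided by the SD); the three per-direction z-maps are
#' then averaged per vertex into a single relative peak-sensitivity map.
#'
#' @param peak_freqs Matrix (vertices x directions) of interpolated peak
#'   frequencies in Hz, columns named by direction.
#' @return List with `map` (per-vertex averaged z) and `z` (per-direction
#'   z-map matrix).
#' @export
relative_peak_map <- function(peak_freqs) {
  peak_freqs <- as.matrix(peak_freqs)
  if (nrow(peak_freqs) < 2) stop("need >= 2 vertices")
  lg <- log10(peak_freqs)
  z <- apply(lg, 2, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s < 1e-300)
      stop("zero variance in a direction's peak frequencies")
    (x - mean(x)) / s
  })
  list(map = rowMeans(z), z = z)
}

#' Project per-vertex values into the visual field
#'
#' Each vertex deposits a 2-D Gaussian (sigma = its pRF width) at its
#' visual-field location (from eccentricity and polar angle); the image is
#' the weight-normalized sum, with pixels whose total Gaussian weight falls
#' below the floor flagged empty (`NA`).
#'
#' @param values Per-vertex values.
#' @param geometry Vertex geometry (eccentricity_deg, polar_angle_deg,
#'   prf_width_deg).
#' @param grid_spec List: `n` (pixels per side, default 181), `half_width`
#'   (degrees, default 90), `weight_floor` (default 1e-6).
#' @return List with `image` (n x n matrix, NA where empty), `x`, `y`
#'   (axis coordinates in degrees), `weight` (total weight image).
#' @export
project_to_visual_field <- function(values, geometry,
                                    grid_spec = list(n = 181,
                                                     half_width = 90,
                                                     weight_floor = 1e-6)) {
  n <- grid_spec$n %||% 181
  hw <- grid_spec$half_width %||% 90
  floor_w <- grid_spec$weight_floor %||% 1e-6
  stopifnot(length(values) == nrow(geometry))
  ax <- seq(-hw, hw, length.out = n)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  x0 <- geometry$eccentricity_deg * cospi(geometry$polar_angle_deg / 180)
  y0 <- geometry$eccentricity_deg * sinpi(geometry$polar_angle_deg / 180)
  for (i in seq_along(values)) {
    s2 <- 2 * geometry$prf_width_deg[i]^2
    g <- exp(-outer((ax - y0[i])^2, (ax - x0[i])^2, `+`) / s2)
    num <- num + values[i] * g
    den <- den + g
  }
  img <- num / den
  img[den < floor_w] <- NA
  list(image = img, x = ax, y = ax, weight = den)
}

#' Per-vertex interpolated peak frequencies
#'
#' Fits the Watson model to each vertex's across-acquisition mean relative
#' amplitudes, per direction, and extracts the interpolated peak frequency.
#' Fits are warm-started from a shared fit to the vertex-average data for
#' speed and stability.
#'
#' @param rel_amplitudes 0 Hz-relative amplitude table with a `vertex`
#'   column.
#' @param seed Seed for the shared warm-start fit.
#' @return Matrix (vertices x directions) of peak frequencies in Hz, with
#'   vertex ids as rownames.
#' @export
vertex_peak_frequencies <- function(rel_amplitudes, seed = 1) {
  tab <- rel_amplitudes[rel_amplitudes$frequency_hz > 0, , drop = FALSE]
  verts <- sort(unique(tab$vertex))
  dirs <- stimulus_directions()
  out <- matrix(NA_real_, length(verts), length(dirs),
                dimnames = list(verts, dirs))
  for (d in dirs) {
    td <- tab[tab$direction == d, ]
    m <- stats::aggregate(amplitude ~ vertex + frequency_hz, data = td,
                          FUN = mean)
    pool <- stats::aggregate(amplitude ~ frequency_hz, data = m, FUN = mean)
    shared <- fit_tsf(pool$frequency_hz, pool$amplitude, seed = seed)
    for (v in verts) {
      mv <- m[m$vertex == v, ]
      mv <- mv[order(mv$frequency_hz), ]
      fit <- fit_tsf(mv$frequency_hz, mv$amplitude, init = shared)
      out[as.character(v), d] <- peak_of_fit(fit)$peak_freq_hz
    }
  }
  out
}
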