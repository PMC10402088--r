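# End-to-end orchestration: simulate -> fit -> TSF -> carry-over ->
# patterns -> retina -> aggregate, from a single serializable configuration
# with fixed seeds, writing every intermediate artifact plus a manifest.

#' Default pipeline configuration
#'
#' All fields are plain values, so a run is reproducible from the
#' configuration alone. Sizes default to a desk-scale study: the full
#' 36-acquisition design with a modest vertex count.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return A named list (`run_config`).
#' @export
default_config <- function(seed = 1) {
  list(seed = seed,
       n_vertices = 36,
       n_blocks = 6,
       noise_sd = 0.5,
       drift_amplitude = 1.0,
       drift_freq_hz = 0.005,
       pattern_sd = 0.15,
       attention_amplitude = 0.5,
       carryover = list(suppression = 0.9, prior_hz = 64),
       n_boot = 1000,
       r2_threshold = 0.1,
       band_edges = eccentricity_bands()$edges,
       field_grid_n = 61,
       contrasts = as.list(default_contrasts()))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order and writes every intermediate artifact to
#' `out_dir` along with `manifest.json` (configuration, seeds, file
#' hashes). Re-running with the same configuration reproduces identical
#' outputs; a stage failure aborts with the stage name while keeping the
#' artifacts of completed stages on disk.
#'
#' @param config Configuration list from [default_config()] (possibly
#'   modified).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- character(0)
  keep <- function(p) paths[[length(paths) + 1L]] <<- p

  # 1: experimental design
  schedules <- stage("design", {
    s <- build_study_schedule(seed = config$seed, n_blocks = config$n_blocks)
    keep(write_events_tsv(s, file.path(out_dir, "events.tsv")))
    s
  })

  # 2: simulation
  sim <- stage("simulate", {
    basis <- build_orthonormal_basis(seed = config$seed)
    keep(write_hrf_basis(basis, file.path(out_dir, "hrf_basis.tsv")))
    keep(file.path(out_dir, "hrf_basis.tsv.json"))
    geom <- make_vertex_geometry(config$n_vertices, seed = config$seed + 1)
    gain <- matrix(1, 7, 7)
    gain[match(config$carryover$prior_hz, stimulus_frequencies()), ] <-
      config$carryover$suppression
    truth <- ground_truth(
      geom, seed = config$seed + 2,
      carryover_gain = list(achromatic = gain, chromatic = gain),
      pattern_sd = config$pattern_sd,
      attention_amplitude = config$attention_amplitude,
      noise_sd = config$noise_sd,
      drift_amplitude = config$drift_amplitude,
      drift_freq_hz = config$drift_freq_hz)
    bold <- simulate_bold(schedules, truth, basis, seed = config$seed + 3)
    keep(write_bold_tsv(bold, file.path(out_dir, "bold.tsv")))
    keep(file.path(out_dir, "bold.tsv.geometry.tsv"))
    keep(file.path(out_dir, "bold.tsv.json"))
    list(bold = bold, basis = basis, truth = truth, geom = geom)
  })

  # 3: time-series fit
  fit <- stage("fit", {
    f <- fit_timeseries(sim$bold, sim$basis)
    keep(write_amplitudes_tsv(f$amplitudes,
                              file.path(out_dir, "amplitudes.tsv")))
    hw <- data.frame(vertex = f$vertices, f$hrf_weights, r2 = f$r2)
    names(hw)[2:4] <- paste0("w", 1:3)
    utils::write.table(hw, file.path(out_dir, "hrf_weights_r2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    keep(file.path(out_dir, "hrf_weights_r2.tsv"))
    f
  })

  rel <- relative_amplitudes(fit$amplitudes)
  selected <- select_vertices(fit, config$r2_threshold)

  # 4: temporal sensitivity functions (region-average, per direction)
  tsfs <- stage("tsf", {
    out <- list()
    for (d in stimulus_directions()) {
      td <- rel[rel$direction == d & rel$vertex %in% selected, ]
      region <- stats::aggregate(amplitude ~ acquisition + frequency_hz,
                                 data = td, FUN = mean)
      ts <- bootstrap_tsf(region, n_boot = config$n_boot,
                          seed = config$seed + 10)
      keep(write_tsf_tsv(ts, file.path(out_dir,
                                       paste0("tsf_", d, ".tsv"))))
      out[[d]] <- ts
    }
    out
  })

  # 5: carry-over
  stage("carryover", {
    resid <- residual_signal(sim$bold, fit, vertices = selected)
    hrf_region <- kernel_from_params(sim$basis,
                                     colMeans(fit$hrf_weights))
    for (cls in c("achromatic", "chromatic")) {
      cov <- build_carryover_covariates(schedules, cls, hrf_region)
      cm <- fit_carryover(resid, cov)
      keep(write_carryover_tsv(cm, file.path(out_dir,
                                             paste0("carryover_", cls,
                                                    ".tsv"))))
    }
  })

  # 6: patterns (similarity per direction; decoding by band)
  stage("patterns", {
    dec_rows <- list()
    for (d in stimulus_directions()) {
      td <- rel[rel$direction == d, ]
      pat <- standardize_patterns(patterns_from_amplitudes(td))
      sim_m <- split_half_similarity(pat, label = d)
      keep(write_similarity_tsv(sim_m,
                                file.path(out_dir,
                                          paste0("similarity_", d,
                                                 ".tsv"))))
      bands <- assign_band(sim$geom$eccentricity_deg, config$band_edges)
      for (b in sort(unique(bands))) {
        vs <- which(bands == b)
        if (length(vs) < 2) next
        dec <- decode_target(pat, 64, vertices = vs)
        dec_rows[[paste(d, b)]] <- data.frame(
          direction = d, band = b,
          proportion_correct = dec$proportion_correct,
          n_vertices = length(vs))
      }
    }
    dec <- do.call(rbind, dec_rows)
    utils::write.table(dec, file.path(out_dir, "decoding_by_band.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    keep(file.path(out_dir, "decoding_by_band.tsv"))
  })

  # 7: retina model + aggregation maps
  stage("retina_aggregate", {
    gains <- load_rgc_gains()
    pred <- integrate_population(gains,
                                 contrasts = unlist(config$contrasts))
    utils::write.table(pred$peaks, file.path(out_dir, "retina_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    keep(file.path(out_dir, "retina_peaks.tsv"))
    ba <- band_average(fit$amplitudes, sim$geom, fit,
                       threshold = config$r2_threshold)
    utils::write.table(ba, file.path(out_dir, "band_amplitudes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    keep(file.path(out_dir, "band_amplitudes.tsv"))
    if (length(selected) >= 2) {
      pf <- vertex_peak_frequencies(rel[rel$vertex %in% selected, ],
                                    seed = config$seed + 20)
      rpm <- relative_peak_map(pf)
      geom_sel <- sim$geom[sim$geom$vertex %in% selected, ]
      fld <- project_to_visual_field(rpm$map, geom_sel,
                                     list(n = config$field_grid_n,
                                          half_width = 90,
                                          weight_floor = 1e-6))
      utils::write.table(fld$image, file.path(out_dir, "peak_map_field.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      keep(file.path(out_dir, "peak_map_field.tsv"))
      jsonlite::write_json(list(n = config$field_grid_n, half_width = 90,
                                weight_floor = 1e-6),
                           file.path(out_dir, "peak_map_field.json"),
                           auto_unbox = TRUE, digits = NA)
      keep(file.path(out_dir, "peak_map_field.json"))
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("flickerfit")),
    config = config,
    outputs = lapply(stats::setNames(paths, basename(unlist(paths))),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
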