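#' Generate an on-disk synthetic dataset
#'
#' Writes a reproducible synthetic fixture set for smoke runs: a bundle of
#' corticofugal-like streamlines, a convex voxel mask standing in for the
#' STN near the electrode, and a run configuration referencing both. All
#' content is deterministic given `seed`.
#'
#' @param dir Output directory (created if missing).
#' @param n_streamlines Number of streamlines (split evenly between the
#'   fibers-of-passage and hyperdirect populations by the default config).
#' @param seed Integer seed.
#' @param bundle_spec Bundle geometry passed to [generate_streamlines()].
#' @param jitter_sd_mm Per-point jitter (mm).
#' @return Invisibly, the paths written (`streamlines`, `stn_mask`,
#'   `config`).
#' @export
make_fixtures <- function(dir, n_streamlines = 50, seed = 1,
                          bundle_spec = list(start = c(4, 0, 28),
                                             end = c(7, 3, -28),
                                             bow_mm = 3, bundle_sd_mm = 1.5,
                                             n_points = 113),
                          jitter_sd_mm = 0.3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sl <- generate_streamlines(n_streamlines, bundle_spec, jitter_sd_mm,
                             seed = seed)
  sl_path <- file.path(dir, "streamlines.txt")
  write_streamlines(sl, sl_path)

  # convex (ellipsoidal) voxel mask near the electrode
  vox <- 0.5
  gr <- as.matrix(expand.grid(x = seq(-3, 6, by = vox),
                              y = seq(-3, 4, by = vox),
                              z = seq(-3.5, 3.5, by = vox)))
  ctr <- c(1.5, 0.5, 0)
  semi <- c(3.5, 2.5, 3)
  keep <- rowSums(sweep(gr, 2, ctr)^2 / matrix(semi^2, nrow(gr), 3,
                                               byrow = TRUE)) <= 1
  mask <- gr[keep, , drop = FALSE]
  mask_path <- file.path(dir, "stn_mask.txt")
  con <- file(mask_path, "w")
  writeLines(sprintf("# pamsim voxel mask v1, voxel_size_mm: %g", vox), con)
  utils::write.table(format(mask, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  close(con)

  cfg <- list(
    seed = seed,
    electrode = list(active_contact = 2),
    circuit = list(c_block_uF = 10, r_wires_ohm = 55, c_parasitic_nF = 3,
                   r_parasitic_ohm = 20000),
    field = list(type = "analytic", sigma_tissue_S_m = 0.2,
                 sigma_enc_S_m = 0.1),
    pathways = list(streamlines = "streamlines.txt",
                    stn_mask = "stn_mask.txt", voxel_size_mm = vox,
                    n_total = min(n_streamlines, 50),
                    split = rep(min(n_streamlines, 50) %/% 2, 2) +
                      c(min(n_streamlines, 50) %% 2, 0),
                    resample_step_mm = 0.5),
    protocol = list(pulse_widths_us = 60, frequency_hz = 130, n_pulses = 3,
                    dt_us = 1),
    threshold = list(resolution_V = 0.01, cap_V = 150, guard = 3),
    recruitment = list(amplitude_max_V = 10, amplitude_step_V = 0.25,
                       n_pop = 100, pop_size = 1000),
    sd = list(hyperdirect_target = c(15, 5), passage_target = c(10, 5)),
    output_dir = "results")
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(streamlines = sl_path, stn_mask = mask_path,
                 config = cfg_path))
}

#' Read a voxel mask
#'
#' Reads either the plain-text voxel-center format written by
#' [make_fixtures()] or, when the file ends in `.nii`/`.nii.gz` (and the
#' RNifti package is available), a NIfTI volume whose non-zero voxels form
#' the mask; voxel indices are mapped to world coordinates (mm) through
#' the image orientation.
#'
#' @param path Mask file path.
#' @return Matrix of voxel centers (mm) with attribute `voxel_size_mm`.
#' @export
read_voxel_mask <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI masks requires the RNifti package")
    img <- RNifti::readNifti(path)
    idx <- which(img != 0, arr.ind = TRUE)
    if (!nrow(idx)) stop("mask is empty")
    xf <- RNifti::xform(img)
    world <- cbind(idx - 1, 1) %*% t(xf)
    m <- world[, 1:3, drop = FALSE]
    colnames(m) <- NULL
    attr(m, "voxel_size_mm") <- mean(RNifti::pixdim(img)[1:3])
    return(m)
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  vox <- as.numeric(sub(".*voxel_size_mm: *", "", hdr[1]))
  m <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")]))
  colnames(m) <- NULL
  attr(m, "voxel_size_mm") <- vox
  m
}

#' Read and validate a run configuration
#'
#' YAML configuration with explicit seeds and unit-annotated keys; missing
#' blocks receive the documented defaults, and the fully resolved
#' configuration (no hidden defaults) is echoed into the run manifest by
#' [run_pipeline()].
#'
#' @param path YAML file path.
#' @return A validated config list with attribute `base_dir`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1,
    electrode = list(active_contact = 2),
    circuit = list(),
    field = list(type = "analytic", sigma_tissue_S_m = 0.2,
                 sigma_enc_S_m = 0.1),
    pathways = list(voxel_size_mm = 0.5, n_total = 50, split = c(25, 25),
                    resample_step_mm = 0.5),
    protocol = list(pulse_widths_us = 60, frequency_hz = 130, n_pulses = 3,
                    dt_us = 1),
    threshold = list(resolution_V = 0.01, cap_V = 150, guard = 3),
    recruitment = list(amplitude_max_V = 10, amplitude_step_V = 0.25,
                       n_pop = 100, pop_size = 1000),
    sd = list(hyperdirect_target = c(15, 5), passage_target = c(10, 5)),
    output_dir = "results")
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      for (kk in names(defaults[[k]]))
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- defaults[[k]][[kk]]
  }
  if (is.null(cfg$pathways$streamlines))
    stop("config must name a streamlines file under pathways$streamlines")
  if (sum(cfg$pathways$split) != cfg$pathways$n_total)
    stop("pathways$split must sum to pathways$n_total")
  attr(cfg, "base_dir") <- dirname(normalizePath(path))
  cfg
}

#' Run the full pathway-activation pipeline
#'
#' Orchestrates waveform, field, pathway construction, threshold search and
#' recruitment/strength-duration analysis from a validated configuration:
#' the spec of a complete patient-style run at synthetic scale. Writes
#' per-axon thresholds, recruitment curves, strength-duration points and a
#' manifest (configuration echo, input hashes, stage timings, exclusion
#' counts) into the configured output directory.
#'
#' @param config A [read_run_config()] result (or an equivalent list with a
#'   `base_dir` attribute).
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with `thresholds` (data.frame),
#'   `recruitment` (list of curves), `sd` (data.frame or NULL), and
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  base <- attr(config, "base_dir")
  if (is.null(base)) base <- "."
  out_dir <- file.path(base, config$output_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    log("stage %-12s %8.2f s", name, timings[[name]])
    r
  }

  set.seed(config$seed)
  electrode <- do.call(electrode_spec, config$electrode)

  field <- stage("field", {
    fc <- config$field
    if (identical(fc$type, "grid"))
      load_field_grid(file.path(base, fc$path))
    else
      build_analytic_field(electrode, fc$sigma_tissue_S_m, fc$sigma_enc_S_m)
  })

  circ_args <- config$circuit
  circ_args$r_tissue_ohm <- field$access_resistance_ohm
  params <- do.call(circuit_params, circ_args)

  pws <- config$protocol$pulse_widths_us
  protocols <- lapply(pws, function(pw)
    stimulus_protocol(amplitude_V = 1, pulse_width_us = pw,
                      frequency_hz = config$protocol$frequency_hz,
                      n_pulses = config$protocol$n_pulses,
                      dt_us = config$protocol$dt_us))
  names(protocols) <- pws
  waveforms <- stage("waveform", lapply(protocols, function(pr)
    simulate_tissue_waveform(params, pr)))

  sl_path <- file.path(base, config$pathways$streamlines)
  mask_path <- file.path(base, config$pathways$stn_mask)
  axons <- stage("pathways", {
    sl <- read_streamlines(sl_path)
    mask <- read_voxel_mask(mask_path)
    anatomy <- anatomy_context(mask, config$pathways$voxel_size_mm, electrode)
    pop <- sample_population(sl, config$pathways$n_total,
                             config$pathways$split)
    main_geom <- fiber_geometry(5.7)
    coll_geom <- fiber_geometry(1.8)
    smooth_one <- function(i)
      fit_smoothing_spline(sl[[i]],
                           resample_step_mm = config$pathways$resample_step_mm)
    fop <- lapply(pop$fibers_of_passage, function(i)
      build_axon(compartmentalize(axon_trajectory(smooth_one(i)),
                                  main_geom, coll_geom)))
    hd <- lapply(pop$hyperdirect, function(i)
      build_axon(compartmentalize(
        build_collateral(smooth_one(i), main_geom, anatomy),
        main_geom, coll_geom)))
    list(fibers_of_passage = fop, hyperdirect = hd,
         ids = pop)
  })

  thresholds <- stage("thresholds", {
    rows <- list()
    for (pathway in c("fibers_of_passage", "hyperdirect")) {
      for (j in seq_along(axons[[pathway]])) {
        ax <- axons[[pathway]][[j]]
        for (pw in as.character(pws)) {
          r <- find_threshold(ax, field, waveforms[[pw]], protocols[[pw]],
                              resolution_V = config$threshold$resolution_V,
                              cap_V = config$threshold$cap_V,
                              guard = config$threshold$guard)
          r$pathway <- pathway
          r$axon_id <- axons$ids[[pathway]][j]
          r$pulse_width_us <- as.numeric(pw)
          rows[[length(rows) + 1]] <- r
        }
      }
    }
    do.call(rbind, rows)
  })
  utils::write.csv(thresholds, file.path(out_dir, "thresholds.csv"),
                   row.names = FALSE)

  recruitment <- stage("recruitment", {
    amps <- seq(0, config$recruitment$amplitude_max_V,
                by = config$recruitment$amplitude_step_V)
    res <- list()
    for (pathway in c("fibers_of_passage", "hyperdirect")) {
      for (pw in as.character(pws)) {
        sub <- thresholds[thresholds$pathway == pathway &
                            thresholds$pulse_width_us == as.numeric(pw), ]
        surv <- apply_exclusions(sub)
        key <- paste(pathway, pw, sep = "_")
        res[[key]] <- if (nrow(surv))
          bootstrap_recruitment(surv$threshold_V, amps,
                                n_pop = config$recruitment$n_pop,
                                pop_size = config$recruitment$pop_size)
        else NULL
        attr(res[[key]], "exclusions") <-
          attr(surv, "exclusion_counts")
      }
    }
    res
  })
  rec_rows <- do.call(rbind, lapply(names(recruitment), function(k) {
    cv <- recruitment[[k]]
    if (is.null(cv)) return(NULL)
    cbind(population = k, as.data.frame(cv))
  }))
  utils::write.csv(rec_rows, file.path(out_dir, "recruitment.csv"),
                   row.names = FALSE)

  sd_out <- NULL
  if (length(pws) > 1) {
    sd_out <- stage("sdcurve", {
      mk <- function(pathway, target) {
        curves <- recruitment[paste(pathway, pws, sep = "_")]
        names(curves) <- pws
        sdp <- strength_duration(curves, target[1], target[2])
        wf_factory <- function(pw) {
          pr <- stimulus_protocol(amplitude_V = 1, pulse_width_us = pw,
                                  frequency_hz = config$protocol$frequency_hz,
                                  n_pulses = 1,
                                  dt_us = config$protocol$dt_us)
          simulate_tissue_waveform(params, pr)
        }
        cbind(pathway = pathway,
              charge_duration(sdp, wf_factory, params$r_tissue_ohm))
      }
      rbind(mk("hyperdirect", config$sd$hyperdirect_target),
            mk("fibers_of_passage", config$sd$passage_target))
    })
    utils::write.csv(sd_out, file.path(out_dir, "sd_curves.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pamsim")),
    config = config,
    inputs = as.list(tools::md5sum(c(streamlines = sl_path,
                                     stn_mask = mask_path))),
    outputs = as.list(tools::md5sum(list.files(out_dir, "\\.csv$",
                                               full.names = TRUE))),
    access_resistance_ohm = field$access_resistance_ohm,
    exclusion_counts = lapply(recruitment, function(cv)
      as.list(attr(cv, "exclusions"))),
    timings_s = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  log("pipeline complete: %s", out_dir)
  invisible(list(thresholds = thresholds, recruitment = recruitment,
                 sd = sd_out, manifest = manifest))
}
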