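# End-to-end pipeline plumbing: image and table I/O, fixtures, run manifest.

#' Write / read a multichannel image as multipage TIFF + JSON channel map
#'
#' Planes are stored as 32-bit float TIFF pages scaled to `[0, 1]`; the JSON
#' sidecar records channel names, per-channel scale factors and exposure
#' metadata (`fluor:`/`marker:` naming is preserved verbatim).
#'
#' @param image an `mchan_image` (or any named list of matrices with an
#'   `exposures` entry).
#' @param tif_path,json_path output paths.
#' @export
write_channels_tiff <- function(image, tif_path, json_path) {
  chans <- names(image$channels)
  scales <- vapply(image$channels, function(m) max(max(m), 1e-12), 0)
  pages <- lapply(seq_along(chans), function(i) image$channels[[i]] / scales[i])
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(channels = chans, scales = as.list(setNames(scales, chans)),
               exposures = as.list(image$exposures), filters = image$filters)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tif_path)
}

#' @rdname write_channels_tiff
#' @export
read_channels_tiff <- function(tif_path, json_path) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  channels <- lapply(seq_along(meta$channels), function(i)
    pages[[i]] * meta$scales[[meta$channels[i]]])
  names(channels) <- meta$channels
  structure(list(channels = channels,
                 exposures = unlist(meta$exposures)[meta$channels],
                 filters = meta$filters),
            class = "mchan_image")
}

#' Scene truth CSV + config JSON sidecar
#' @param truth a `scene_truth`; @param csv_path,json_path output paths.
#' @export
write_scene_csv <- function(truth, csv_path, json_path = NULL) {
  ab <- attr(truth, "abundance")
  df <- as.data.frame(truth)
  if (nrow(df)) for (m in colnames(ab)) df[[paste0("abund_", m)]] <- ab[, m]
  write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    cfg <- attr(truth, "config")
    cfg$hotspots <- lapply(cfg$hotspots, function(h)
      list(center = h$center, radius = h$radius))
    jsonlite::write_json(unclass(cfg), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Bundled deterministic fixtures
#'
#' Small ground-truthed scenes used by the test-suite and the acceptance
#' analyses, regenerated deterministically from fixed seeds:
#' * `sparse-mp1` — 300 well-separated MP1 cells, no artefacts, no noise.
#' * `hotspot-mp1` — two CD20-dominant lymphoid hotspots with nonspecific
#'   CD20-CD8 co-stain (`nu` = 0.3) and neighbour spillover (`kappa` = 0.3).
#' * `mp2` — sparse MP2 scene (different-compartment co-expression only).
#' * `overlap-spectra` — configuration pairing CD20 with Opal650 (emission
#'   overlapping CD8-Opal690) versus the spectrally separated Opal570 pairing.
#' * `thick-section` — a thick (`tau` = 5) section and its `tau` = 1 twin.
#'
#' @param name fixture name.
#' @return a list bundle; unknown names raise an error listing valid names.
#' @export
make_fixture <- function(name) {
  valid <- c("sparse-mp1", "hotspot-mp1", "mp2", "overlap-spectra",
             "thick-section")
  if (!name %in% valid)
    stop("unknown fixture '", name, "'; valid fixtures: ",
         paste(valid, collapse = ", "))
  build <- function(config) {
    profiles <- default_profiles(config$panel)
    truth <- simulate_scene(config, profiles)
    rp <- render_truth_planes(truth, config)
    library <- opal_library(unname(config$pairing))
    image <- mix_to_channels(rp$planes, rp$af, library,
                             filter_set(config$filters), config$exposures,
                             config$noise_sigma, seed = config$seed,
                             pairing = config$pairing)
    list(config = config, profiles = profiles, truth = truth,
         planes = rp$planes, af = rp$af, library = library, image = image)
  }
  switch(name,
    "sparse-mp1" = c(list(name = name),
      build(scene_config(panel = "MP1", dim = c(512, 512), n_cells = 300,
                         kappa = 0, nu = 0, noise_sigma = 0, seed = 101))),
    "hotspot-mp1" = c(list(name = name),
      build(scene_config(panel = "MP1", dim = c(512, 512), n_cells = 300,
                         hotspots = list(list(center = c(127.5, 127.5), radius = 70),
                                         list(center = c(383.5, 383.5), radius = 70)),
                         hotspot_multiplier = 4, kappa = 0.3, nu = 0.3,
                         noise_sigma = 0.5, seed = 202))),
    "mp2" = c(list(name = name),
      build(scene_config(panel = "MP2", dim = c(384, 384), n_cells = 200,
                         kappa = 0, nu = 0, noise_sigma = 0.5, seed = 303))),
    "overlap-spectra" = {
      cfg <- scene_config(panel = "MP1", dim = c(224, 224), n_cells = 60,
                          kappa = 0, nu = 0, noise_sigma = 0.5, seed = 404)
      pairing_overlap <- default_pairing("MP1", overlap_cd20 = TRUE)
      pairing_motif <- default_pairing("MP1")
      list(name = name, config = cfg,
           pairings = list(overlap = pairing_overlap, motif = pairing_motif),
           libraries = list(overlap = opal_library(unname(pairing_overlap)),
                            motif = opal_library(unname(pairing_motif))))
    },
    "thick-section" = {
      mk <- function(tau) scene_config(panel = "MP1", dim = c(192, 192),
                                       n_cells = 60, kappa = 0, nu = 0,
                                       noise_sigma = 0, tau = tau, seed = 505)
      list(name = name, thick = build(mk(5)), thin = build(mk(1)))
    })
}

#' Singleplex acquisition set for a scene
#'
#' Re-renders a scene keeping one marker at a time (plus autofluorescence) and
#' mixes each into channels, emulating library/control slides where a single
#' fluorophore is present. With `flat_af = TRUE` the autofluorescence plane is
#' replaced by its spatial mean (controlled library-slide references), which
#' makes signature estimation by background subtraction exact.
#'
#' @param config a `scene_config`; @param library,pairing acquisition setup.
#' @param markers markers to include (default: all paired markers).
#' @param flat_af flatten the autofluorescence plane.
#' @return list with `scenes` (named by fluorophore) and `af_image`.
#' @export
singleplex_scene_set <- function(config, library, pairing,
                                 markers = NULL, flat_af = FALSE) {
  if (is.null(markers)) markers <- names(pairing)
  profiles <- default_profiles(config$panel)
  truth <- simulate_scene(config, profiles)
  rp <- render_truth_planes(truth, config)
  af <- if (flat_af) matrix(mean(rp$af), nrow(rp$af), ncol(rp$af)) else rp$af
  filters <- filter_set(config$filters)
  scenes <- list()
  for (m in markers) {
    scenes[[pairing[[m]]]] <- mix_to_channels(rp$planes[m], af, library,
      filters, config$exposures, config$noise_sigma,
      seed = substream_seed(config$seed, paste0("singleplex-", m)),
      pairing = pairing)
  }
  zero <- matrix(0, nrow(af), ncol(af))
  af_image <- mix_to_channels(list(DAPI = zero), af, library, filters,
    config$exposures, config$noise_sigma,
    seed = substream_seed(config$seed, "af-only"), pairing = pairing)
  list(scenes = scenes, af_image = af_image, truth = truth)
}

#' Run the full pipeline
#'
#' simulate -> acquire -> unmix (+QC) -> segment -> measure -> phenotype ->
#' validate, persisting every intermediate under `out_dir` and returning a run
#' manifest with per-file MD5 checksums. A QC exclusion halts the pipeline
#' after unmixing: no cell table is produced for an excluded image and the
#' manifest records the partial state.
#'
#' @param config a `scene_config`.
#' @param out_dir output directory (created).
#' @param params a [seg_params()].
#' @param thresholds named `marker_threshold` list; default
#'   [default_thresholds()].
#' @param tree,order classification program; defaults per panel.
#' @param qc list (`max_af_counts`, `max_residual`) for
#'   [qc_autofluorescence()].
#' @param grid validation grid (`c(rows, cols)` tiles).
#' @return a `run_manifest` (invisibly written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir,
                         params = seg_params(),
                         thresholds = default_thresholds(config$panel),
                         tree = default_tree(config$panel),
                         order = default_orders(config$panel)$final,
                         qc = list(max_af_counts = 15, max_residual = 2),
                         grid = c(4, 4)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  add_stage <- function(name, files, status = "completed", extra = NULL) {
    files <- files[file.exists(files)]
    stages[[name]] <<- c(list(stage = name, status = status,
                              outputs = as.list(setNames(
                                unname(tools::md5sum(files)), basename(files))),
                              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                         extra)
  }

  profiles <- default_profiles(config$panel)
  truth <- simulate_scene(config, profiles)
  f_truth <- file.path(out_dir, "scene_truth.csv")
  f_cfg <- file.path(out_dir, "scene_config.json")
  write_scene_csv(truth, f_truth, f_cfg)
  add_stage("simulate", c(f_truth, f_cfg))

  rp <- render_truth_planes(truth, config)
  library <- opal_library(unname(config$pairing))
  image <- mix_to_channels(rp$planes, rp$af, library, filter_set(config$filters),
                           config$exposures, config$noise_sigma,
                           seed = config$seed, pairing = config$pairing)
  f_img <- file.path(out_dir, "image.tif")
  f_imgj <- file.path(out_dir, "image_channels.json")
  write_channels_tiff(image, f_img, f_imgj)
  add_stage("acquire", c(f_img, f_imgj))

  un <- unmix(image, library)
  un <- qc_autofluorescence(un, qc$max_af_counts, qc$max_residual)
  f_un <- file.path(out_dir, "unmixed.tif")
  f_unj <- file.path(out_dir, "unmixed_channels.json")
  un_planes <- c(un$abundance, list(AF = un$af, residual = un$residual))
  write_channels_tiff(list(channels = un_planes,
                           exposures = setNames(rep(1, length(un_planes)),
                                                names(un_planes)),
                           filters = image$filters), f_un, f_unj)
  add_stage("unmix", c(f_un, f_unj),
            status = if (is.null(un$exclusion)) "completed" else "qc-excluded",
            extra = list(qc = un$qc, exclusion = un$exclusion))

  manifest_path <- file.path(out_dir, "manifest.json")
  finish <- function(status) {
    man <- list(status = status, seed = config$seed, panel = config$panel,
                stages = unname(stages))
    jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    class(man) <- "run_manifest"
    man
  }
  if (!is.null(un$exclusion)) return(finish("qc-excluded"))

  mplanes <- marker_planes(un, config$pairing)
  labels <- detect_nuclei(mplanes$DAPI, params)
  geo <- expand_cells(labels, params$expansion)
  cells <- measure_cells(labels, geo$cells, geo$rings, mplanes)
  f_cells <- file.path(out_dir, "cells.csv")
  write.csv(cells, f_cells, row.names = FALSE)
  add_stage("segment", character(0), extra = list(n_nuclei = max(labels)))
  add_stage("measure", f_cells, extra = list(n_cells = nrow(cells)))

  calls <- classify_hierarchical(cells, thresholds, order, tree)
  f_calls <- file.path(out_dir, "calls.csv")
  write.csv(as.data.frame(calls), f_calls, row.names = FALSE)
  add_stage("phenotype", f_calls)

  # grid-tile units: truth positivity (abundance > 0) vs class-derived calls
  tile <- function(y, x, d) {
    pmin(grid[1], floor(y / d[1] * grid[1]) + 1) * 100 +
      pmin(grid[2], floor(x / d[2] * grid[2]) + 1)
  }
  markers <- setdiff(panel_markers(config$panel), "DAPI")
  ab <- attr(truth, "abundance")
  ref <- data.frame(unit = tile(truth$y, truth$x, config$dim))
  for (m in markers) ref[[m]] <- ab[, m] > 0
  tst <- data.frame(unit = tile(cells$y, cells$x, config$dim))
  for (m in markers)
    tst[[m]] <- grepl(paste0("(^|/)", m, "\\+"), calls$class)
  shared <- intersect(unique(ref$unit), unique(tst$unit))
  vres <- validate_panel(ref[ref$unit %in% shared, ],
                         tst[tst$unit %in% shared, ], markers)
  f_val <- file.path(out_dir, "validation.csv")
  write.csv(vres, f_val, row.names = FALSE)
  add_stage("validate", f_val)

  finish("completed")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", x$status, "-", length(x$stages), "stages\n")
  for (s in x$stages) cat("  ", s$stage, ": ", s$status, "\n", sep = "")
  invisible(x)
}
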