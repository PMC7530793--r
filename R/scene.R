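#' Panel definitions and marker-fluorophore pairings
#'
#' `MP1` is the 6-plex T/B-cell panel (CD3, CD4, CD8, CD20, CK, DAPI) where
#' CD3 co-localises with CD4 and CD8 in the T-cell membrane; `MP2` is the
#' 5-plex panel (CD4, CD68, FOXP3, CK, DAPI) where CD4 (membrane) and FOXP3
#' (nucleus) co-express in regulatory T cells in different compartments.
#'
#' @param panel `"MP1"` or `"MP2"`.
#' @return character vector of marker names (DAPI included).
#' @export
panel_markers <- function(panel) {
  switch(panel,
         MP1 = c("DAPI", "CK", "CD3", "CD4", "CD8", "CD20"),
         MP2 = c("DAPI", "CK", "CD68", "CD4", "FOXP3"),
         stop("configuration error: unknown panel '", panel, "'"))
}

#' @rdname panel_markers
#' @param overlap_cd20 if `TRUE`, pair CD20 with Opal650 (its emission peak
#'   overlaps CD8-Opal690 within the Cy5 range) instead of the spectrally
#'   separated Opal570 pairing.
#' @return named character vector marker -> fluorophore.
#' @export
default_pairing <- function(panel, overlap_cd20 = FALSE) {
  p <- switch(panel,
    MP1 = c(DAPI = "DAPI", CK = "Opal480", CD3 = "Opal520", CD20 = "Opal570",
            CD4 = "Opal620", CD8 = "Opal690"),
    MP2 = c(DAPI = "DAPI", CK = "Opal480", CD68 = "Opal570", CD4 = "Opal620",
            FOXP3 = "Opal690"),
    stop("configuration error: unknown panel '", panel, "'"))
  if (overlap_cd20) {
    if (panel != "MP1") stop("overlap pairing is defined for MP1 only")
    p["CD20"] <- "Opal650"
  }
  p
}

#' @rdname panel_markers
#' @return named character vector marker -> compartment (`"nucleus"` or
#'   `"membrane"`). DAPI and FOXP3 are nuclear; all other panel markers are
#'   membranous.
#' @export
marker_compartments <- function(panel) {
  m <- panel_markers(panel)
  setNames(ifelse(m %in% c("DAPI", "FOXP3"), "nucleus", "membrane"), m)
}

#' Default phenotype profiles for a panel
#'
#' Each profile maps markers to mean abundances (counts) with a shared
#' lognormal dispersion, and carries per-context frequencies (`sparse`,
#' `hotspot`) that are normalised to sum to one. Positive-marker means are
#' calibrated so measured per-cell intensities land in the 20-25 count target
#' band with every fluorophore below 30 counts; CD20, a low-expressing target
#' paired with a bright fluorophore, sits at the top of the band. Every profile
#' has nuclear DAPI so cells are always detectable.
#'
#' @param panel `"MP1"` or `"MP2"`.
#' @param sigma lognormal sigma of per-cell abundance draws.
#' @return list of `phenotype_profile` objects.
#' @export
default_profiles <- function(panel, sigma = 0.2) {
  mk <- function(label, levels, sparse, hotspot) {
    structure(list(label = label,
                   levels = c(DAPI = 22, levels),
                   sigma = sigma,
                   frequency = c(sparse = sparse, hotspot = hotspot)),
              class = "phenotype_profile")
  }
  profs <- switch(panel,
    MP1 = list(
      mk("CK+",               c(CK = 22),            0.25, 0.00),
      mk("CD3+/CD4+",         c(CD3 = 22, CD4 = 22), 0.15, 0.16),
      mk("CD3+/CD8+",         c(CD3 = 22, CD8 = 20), 0.10, 0.15),
      mk("CD3+ (CD4-CD8-)",   c(CD3 = 22),           0.05, 0.04),
      mk("CD20+",             c(CD20 = 25),          0.10, 0.55),
      mk("negative",          numeric(0),            0.35, 0.10)),
    MP2 = list(
      mk("CK+",               c(CK = 22),                 0.30, 0.00),
      mk("CD68+",             c(CD68 = 22),               0.10, 0.20),
      mk("CD4+",              c(CD4 = 22),                0.15, 0.30),
      mk("CD4+/FOXP3+",       c(CD4 = 22, FOXP3 = 22),    0.07, 0.20),
      mk("FOXP3+",            c(FOXP3 = 22),              0.03, 0.05),
      mk("negative",          numeric(0),                 0.35, 0.25)),
    stop("configuration error: unknown panel '", panel, "'"))
  # normalise per-context frequencies to sum to exactly 1
  for (ctx in c("sparse", "hotspot")) {
    tot <- sum(vapply(profs, function(p) p$frequency[[ctx]], 0))
    profs <- lapply(profs, function(p) { p$frequency[[ctx]] <- p$frequency[[ctx]] / tot; p })
  }
  comp <- marker_compartments(panel)
  bad <- unlist(lapply(profs, function(p) setdiff(names(p$levels), names(comp))))
  if (length(bad)) stop("profile markers outside panel: ", paste(bad, collapse = ", "))
  names(profs) <- vapply(profs, `[[`, "", "label")
  profs
}

#' Scene configuration
#'
#' @param panel `"MP1"` or `"MP2"`.
#' @param dim image size `c(rows, cols)` in pixels.
#' @param n_cells total cells to place.
#' @param hotspots list of `list(center = c(y, x), radius = px)` dense lymphoid
#'   regions (germinal-centre analogues); empty for sparse scenes.
#' @param hotspot_multiplier density multiplier of hotspots relative to sparse
#'   tissue (drives the share of cells allocated to hotspots).
#' @param nu nonspecific co-stain coefficient: fraction of a hotspot cell's
#'   CD20 abundance added to its rendered CD8 signal (MP1).
#' @param kappa spillover coefficient: fraction of a neighbouring cell's
#'   membrane abundances contaminating a cell whose annulus overlaps it; the
#'   weaker co-located membrane marker of crowded cells is attenuated by
#'   `1 - kappa/2` (masking).
#' @param tau thickness factor (>= 0) scaling autofluorescence.
#' @param af_baseline,af_texture autofluorescence baseline level (counts) and
#'   low-frequency texture amplitude; the rendered plane is
#'   `tau * pmax(baseline + texture * smooth_noise, 0)`.
#' @param exposures named per-channel exposure times (ms); defaults to 10 ms
#'   for DAPI and 50 ms elsewhere.
#' @param noise_sigma Gaussian read-noise scale; the per-channel sd is
#'   `noise_sigma * sqrt(exposure)` in raw units.
#' @param nucleus_radius integer range `c(min, max)` of nucleus radii in px.
#' @param annulus_width painted membrane annulus width in px.
#' @param min_sep,min_sep_hotspot minimum centroid separations (px) outside and
#'   inside hotspots; defaults keep sparse annuli disjoint and hotspot annuli
#'   overlapping while nuclei stay disjoint.
#' @param filters filter set mode name.
#' @param pairing marker -> fluorophore map; defaults per panel.
#' @param seed integer seed fixing all randomness end-to-end.
#' @return A validated `scene_config`.
#' @export
scene_config <- function(panel = "MP1", dim = c(256, 256), n_cells = 150,
                         hotspots = list(), hotspot_multiplier = 4,
                         nu = 0.3, kappa = 0.3, tau = 1,
                         af_baseline = 4, af_texture = 1.5,
                         exposures = NULL, noise_sigma = 0,
                         nucleus_radius = c(4, 5), annulus_width = 3,
                         min_sep = NULL, min_sep_hotspot = NULL,
                         filters = "motif7", pairing = NULL, seed = 1) {
  if (tau < 0) stop("tau must be >= 0")
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]")
  if (nu < 0 || nu > 1) stop("nu must be in [0, 1]")
  if (n_cells < 0) stop("n_cells must be >= 0")
  panel_markers(panel)  # validates panel
  fl <- filter_set(filters)
  if (is.null(exposures))
    exposures <- setNames(ifelse(names(fl) == "DAPI", 10, 50), names(fl))
  if (is.null(pairing)) pairing <- default_pairing(panel)
  rmax <- nucleus_radius[2]
  if (is.null(min_sep)) min_sep <- 2 * rmax + 2 * annulus_width + 1
  if (is.null(min_sep_hotspot)) min_sep_hotspot <- 2 * rmax + 2
  for (h in hotspots) {
    if (h$center[1] - h$radius < 0 || h$center[1] + h$radius > dim[1] - 1 ||
        h$center[2] - h$radius < 0 || h$center[2] + h$radius > dim[2] - 1)
      stop("hotspot does not fit inside the image")
  }
  structure(list(panel = panel, dim = dim, n_cells = n_cells,
                 hotspots = hotspots, hotspot_multiplier = hotspot_multiplier,
                 nu = nu, kappa = kappa, tau = tau,
                 af_baseline = af_baseline, af_texture = af_texture,
                 exposures = exposures, noise_sigma = noise_sigma,
                 nucleus_radius = nucleus_radius, annulus_width = annulus_width,
                 min_sep = min_sep, min_sep_hotspot = min_sep_hotspot,
                 filters = filters, pairing = pairing, seed = as.integer(seed)),
            class = "scene_config")
}

# rejection placement with a minimum-separation constraint
place_points <- function(n, sampler, accepted, min_sep_fun, max_attempts) {
  pts <- accepted
  placed <- 0L
  attempts <- 0L
  out <- matrix(NA_real_, n, 2)
  while (placed < n) {
    if (attempts > max_attempts)
      stop("generation error: cannot place ", n, " cells at the requested ",
           "minimum separation; density infeasible")
    attempts <- attempts + 1L
    p <- sampler()
    if (is.null(p)) next
    if (nrow(pts)) {
      d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2
      if (min(d2) < min_sep_fun(p)^2) next
    }
    placed <- placed + 1L
    out[placed, ] <- p
    pts <- rbind(pts, p)
  }
  out
}

#' Simulate a ground-truthed tissue scene
#'
#' Places cells with a minimum separation outside hotspots and at elevated
#' density inside them, assigns phenotypes per tissue context from the profile
#' frequencies, and draws per-marker abundances from mean-preserving lognormal
#' distributions. Deterministic given `config$seed`.
#'
#' @param config a `scene_config`.
#' @param profiles list from [default_profiles()].
#' @return A `scene_truth`: data.frame (id, y, x, radius, phenotype, context;
#'   coordinates 0-based pixel centres) with the abundance matrix, marker
#'   compartments and panel attached as attributes.
#' @export
simulate_scene <- function(config, profiles = default_profiles(config$panel)) {
  markers <- panel_markers(config$panel)
  dimg <- config$dim
  empty <- function() {
    tr <- data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                     radius = numeric(0), phenotype = character(0),
                     context = character(0), stringsAsFactors = FALSE)
    attr(tr, "abundance") <- matrix(0, 0, length(markers), dimnames = list(NULL, markers))
    attr(tr, "compartments") <- marker_compartments(config$panel)
    attr(tr, "panel") <- config$panel
    attr(tr, "config") <- config
    class(tr) <- c("scene_truth", "data.frame")
    tr
  }
  if (config$n_cells == 0) return(empty())

  hot_area <- sum(vapply(config$hotspots, function(h) pi * h$radius^2, 0))
  img_area <- prod(dimg)
  w_hot <- if (hot_area > 0)
    config$hotspot_multiplier * hot_area /
      (config$hotspot_multiplier * hot_area + (img_area - hot_area)) else 0
  n_hot <- round(config$n_cells * w_hot)
  n_sparse <- config$n_cells - n_hot

  in_hotspot <- function(p) {
    for (h in config$hotspots)
      if ((p[1] - h$center[1])^2 + (p[2] - h$center[2])^2 <= h$radius^2) return(TRUE)
    FALSE
  }

  pts <- with_substream(config$seed, "placement", {
    acc <- matrix(numeric(0), 0, 2)
    hot_pts <- NULL
    if (n_hot > 0) {
      areas <- vapply(config$hotspots, function(h) h$radius^2, 0)
      nh <- floor(n_hot * areas / sum(areas))
      rem <- n_hot - sum(nh)
      if (rem > 0) nh[seq_len(rem)] <- nh[seq_len(rem)] + 1
      for (i in seq_along(config$hotspots)) {
        h <- config$hotspots[[i]]
        sampler <- function() {
          a <- runif(1, 0, 2 * pi); r <- h$radius * sqrt(runif(1))
          c(h$center[1] + r * sin(a), h$center[2] + r * cos(a))
        }
        newp <- place_points(nh[i], sampler, acc,
                             function(p) config$min_sep_hotspot,
                             max_attempts = 2000 * max(nh[i], 1))
        acc <- rbind(acc, newp)
        hot_pts <- rbind(hot_pts, newp)
      }
    }
    sp_pts <- NULL
    if (n_sparse > 0) {
      m <- config$nucleus_radius[2] + config$annulus_width
      sampler <- function() {
        p <- c(runif(1, m, dimg[1] - 1 - m), runif(1, m, dimg[2] - 1 - m))
        if (in_hotspot(p)) NULL else p
      }
      sp_pts <- place_points(n_sparse, sampler, acc,
                             function(p) config$min_sep,
                             max_attempts = 2000 * n_sparse)
    }
    rbind(hot_pts, sp_pts)
  })
  context <- rep(c("hotspot", "sparse"), c(n_hot, n_sparse))

  labs <- names(profiles)
  freq <- vapply(profiles, function(p) p$frequency, numeric(2))  # sparse, hotspot rows
  pheno <- with_substream(config$seed, "phenotypes", {
    vapply(context, function(ctx)
      sample(labs, 1, prob = freq[ctx, ]), "")
  })
  radius <- with_substream(config$seed, "radii", {
    sample(seq(config$nucleus_radius[1], config$nucleus_radius[2]),
           config$n_cells, replace = TRUE)
  })
  abund <- with_substream(config$seed, "abundance", {
    A <- matrix(0, config$n_cells, length(markers), dimnames = list(NULL, markers))
    for (i in seq_len(config$n_cells)) {
      p <- profiles[[pheno[i]]]
      for (m in names(p$levels)) {
        z <- rnorm(1)
        A[i, m] <- p$levels[[m]] * exp(p$sigma * z - p$sigma^2 / 2)
      }
    }
    A
  })

  tr <- data.frame(id = seq_len(config$n_cells), y = pts[, 1], x = pts[, 2],
                   radius = radius, phenotype = pheno, context = context,
                   stringsAsFactors = FALSE)
  attr(tr, "abundance") <- abund
  attr(tr, "compartments") <- marker_compartments(config$panel)
  attr(tr, "panel") <- config$panel
  attr(tr, "config") <- config
  class(tr) <- c("scene_truth", "data.frame")
  tr
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("scene_truth:", nrow(x), "cells (",
      sum(x$context == "hotspot"), "hotspot /",
      sum(x$context == "sparse"), "sparse ), panel",
      attr(x, "panel"), "\n")
  invisible(x)
}

#' Render ground-truth abundance planes
#'
#' Paints nuclear markers as filled discs and membrane markers as annuli of the
#' configured width. Three artefacts act at the signal level: (i) inside
#' hotspots each cell's rendered CD8 receives `nu` times its CD20 abundance
#' (nonspecific co-stain); (ii) cells whose annuli overlap a neighbour's
#' receive `kappa`-weighted contributions of the neighbour's membrane
#' abundances (spillover) and have their own weaker co-located membrane marker
#' attenuated by `1 - kappa/2` (masking); (iii) the autofluorescence plane is
#' the thickness factor `tau` times a fixed baseline-plus-texture pattern, so
#' doubling `tau` exactly doubles the plane.
#'
#' @param truth a `scene_truth`.
#' @param config the matching `scene_config`.
#' @return list with `planes` (named marker matrices, counts) and `af`.
#' @export
render_truth_planes <- function(truth, config) {
  markers <- panel_markers(config$panel)
  comp <- attr(truth, "compartments")
  dimg <- config$dim
  planes <- lapply(markers, function(m) matrix(0, dimg[1], dimg[2]))
  names(planes) <- markers

  n <- nrow(truth)
  if (n > 0) {
    A <- attr(truth, "abundance")
    w <- config$annulus_width
    outer_r <- truth$radius + w
    # nonspecific CD20 -> CD8 co-stain inside hotspots
    if (config$panel == "MP1" && config$nu > 0) {
      hot <- truth$context == "hotspot"
      A[hot, "CD8"] <- A[hot, "CD8"] + config$nu * A[hot, "CD20"]
    }
    memb <- names(comp)[comp == "membrane"]
    nuc <- names(comp)[comp == "nucleus"]
    # annulus overlap graph
    if (n > 1) {
      d <- as.matrix(stats::dist(cbind(truth$y, truth$x)))
      ov <- d < outer(outer_r, outer_r, "+")
      diag(ov) <- FALSE
    } else ov <- matrix(FALSE, 1, 1)
    crowded <- rowSums(ov) > 0
    Aeff <- A
    if (config$kappa > 0 && any(crowded)) {
      Am <- A[, memb, drop = FALSE]
      for (i in which(crowded)) {
        mx <- max(Am[i, ])
        weaker <- Am[i, ] > 0 & Am[i, ] < mx
        Aeff[i, memb][weaker] <- Am[i, weaker] * (1 - config$kappa / 2)
      }
      spill <- config$kappa * ((ov * 1) %*% A[, memb, drop = FALSE])
      Aeff[, memb] <- Aeff[, memb] + spill
    }
    for (i in seq_len(n)) {
      di <- disc_index(truth$y[i], truth$x[i], truth$radius[i], dimg)
      ai <- shape_index(truth$y[i], truth$x[i], truth$radius[i], outer_r[i], dimg)
      for (m in nuc) if (Aeff[i, m] > 0)
        planes[[m]][di] <- planes[[m]][di] + Aeff[i, m]
      for (m in memb) if (Aeff[i, m] > 0)
        planes[[m]][ai] <- planes[[m]][ai] + Aeff[i, m]
    }
  }

  pattern <- with_substream(config$seed, "autofluorescence", {
    z <- matrix(rnorm(prod(dimg)), dimg[1], dimg[2])
    z <- EBImage::gblur(z, sigma = max(8, round(min(dimg) / 16)))
    z <- (z - mean(z)) / sd(z)
    pmax(config$af_baseline + config$af_texture * z, 0)
  })
  list(planes = planes, af = config$tau * pattern)
}

#' Mix abundance planes into acquisition channels
#'
#' Channel plane `c` is `sum_f M[c, f] * abundance_f * exposure_c` plus
#' Gaussian read noise with sd `noise_sigma * sqrt(exposure_c)`, clipped at
#' zero. `M` is the exposure-free sensing matrix of the library under the
#' filter set. Per-channel exposures are carried in the result's metadata.
#'
#' @param planes named list of per-marker abundance matrices (counts).
#' @param af autofluorescence plane (counts).
#' @param library `spectral_library` containing every paired fluorophore.
#' @param filters `filter_set`.
#' @param exposures named per-channel exposures (ms).
#' @param noise_sigma Gaussian noise scale (0 = noiseless).
#' @param seed seed for the noise substream.
#' @param pairing marker -> fluorophore map.
#' @return An `mchan_image`: named channel matrices + exposure metadata.
#' @export
mix_to_channels <- function(planes, af, library, filters, exposures,
                            noise_sigma = 0, seed = 1,
                            pairing = NULL) {
  if (is.null(pairing)) stop("configuration error: a marker->fluorophore pairing is required")
  miss <- setdiff(names(planes), names(pairing))
  if (length(miss)) stop("configuration error: no fluorophore assigned to marker ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unname(pairing[names(planes)]), library$names)
  if (length(bad)) stop("configuration error: fluorophore ", paste(bad, collapse = ", "),
                        " not in library")
  M <- sensing_matrix(library, filters)
  dimg <- dim(planes[[1]])
  X <- matrix(0, length(library$names), prod(dimg),
              dimnames = list(library$names, NULL))
  for (m in names(planes)) {
    f <- pairing[[m]]
    X[f, ] <- X[f, ] + as.vector(planes[[m]])
  }
  X[library$af_name, ] <- X[library$af_name, ] + as.vector(af)
  Y <- M %*% X
  chans <- rownames(M)
  noise <- NULL
  if (noise_sigma > 0) {
    noise <- with_substream(seed, "noise", {
      matrix(rnorm(length(chans) * prod(dimg)), length(chans))
    })
  }
  channels <- lapply(seq_along(chans), function(ci) {
    e <- exposures[[chans[ci]]]
    y <- Y[ci, ] * e
    if (!is.null(noise)) y <- y + noise[ci, ] * noise_sigma * sqrt(e)
    matrix(pmax(y, 0), dimg[1], dimg[2])
  })
  names(channels) <- chans
  structure(list(channels = channels, exposures = exposures[chans],
                 filters = filter_mode(filters)),
            class = "mchan_image")
}

#' @export
print.mchan_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("mchan_image:", length(x$channels), "channels,", d[1], "x", d[2], "px\n")
  invisible(x)
}

#' Rescale a scene to a different pixel scale
#'
#' Models acquiring the same tissue at a different magnification: centroids,
#' radii, annulus width, hotspot geometry and image dimensions are multiplied
#' by `scale`. Abundances (counts) are unchanged.
#'
#' @param truth a `scene_truth`; @param scale positive scale factor.
#' @return list with scaled `truth` and `config`.
#' @export
scale_scene <- function(truth, scale) {
  config <- attr(truth, "config")
  config$dim <- round(config$dim * scale)
  config$nucleus_radius <- config$nucleus_radius * scale
  config$annulus_width <- config$annulus_width * scale
  config$min_sep <- config$min_sep * scale
  config$min_sep_hotspot <- config$min_sep_hotspot * scale
  config$hotspots <- lapply(config$hotspots, function(h)
    list(center = h$center * scale, radius = h$radius * scale))
  tr <- truth
  tr$y <- tr$y * scale; tr$x <- tr$x * scale; tr$radius <- tr$radius * scale
  attr(tr, "config") <- config
  list(truth = tr, config = config)
}
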