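test_that("default profiles encode the panel design", {
  p1 <- default_profiles("MP1")
  expect_true("CD3+ (CD4-CD8-)" %in% names(p1))
  expect_true(all(c("CK+", "CD20+", "CD3+/CD4+", "CD3+/CD8+", "negative") %in%
                    names(p1)))
  p2 <- default_profiles("MP2")
  expect_true(all(c("CK+", "CD68+", "CD4+", "CD4+/FOXP3+", "FOXP3+",
                    "negative") %in% names(p2)))
  comp <- marker_compartments("MP2")
  expect_equal(comp[["FOXP3"]], "nucleus")
  expect_equal(comp[["CD4"]], "membrane")
  for (pp in list(p1, p2)) {
    for (ctx in c("sparse", "hotspot"))
      expect_equal(sum(vapply(pp, function(q) q$frequency[[ctx]], 0)), 1,
                   tolerance = 1e-9)
    for (q in pp) {
      expect_true(all(q$levels >= 0))
      expect_gt(q$levels[["DAPI"]], 0)
    }
  }
  expect_error(default_profiles("MP9"), "unknown panel")
})

test_that("scene simulation is deterministic, respects empty and infeasible cases", {
  cfg <- scene_config(panel = "MP1", dim = c(128, 128), n_cells = 20, seed = 3)
  t1 <- simulate_scene(cfg)
  t2 <- simulate_scene(cfg)
  expect_identical(t1, t2)
  expect_false(anyDuplicated(t1$id) > 0)
  expect_true(all(t1$y >= 0 & t1$y <= 127 & t1$x >= 0 & t1$x <= 127))

  t0 <- simulate_scene(scene_config(panel = "MP1", n_cells = 0))
  expect_equal(nrow(t0), 0)

  expect_error(simulate_scene(scene_config(panel = "MP1", dim = c(64, 64),
                                           n_cells = 200, seed = 1)),
               "minimum separation")
})

test_that("hotspots elevate local density (nearest-neighbour statistic)", {
  cfg <- scene_config(panel = "MP1", dim = c(320, 320), n_cells = 120,
                      hotspots = list(list(center = c(100, 100), radius = 60)),
                      hotspot_multiplier = 4, seed = 5)
  tr <- simulate_scene(cfg)
  expect_gt(sum(tr$context == "hotspot"), 10)
  nn <- function(sub) {
    d <- as.matrix(dist(cbind(sub$y, sub$x)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  d_all <- as.matrix(dist(cbind(tr$y, tr$x))); diag(d_all) <- Inf
  nn_all <- apply(d_all, 1, min)
  expect_lt(mean(nn_all[tr$context == "hotspot"]),
            mean(nn_all[tr$context == "sparse"]))
})

test_that("autofluorescence scales exactly with the thickness factor", {
  cfg1 <- scene_config(panel = "MP1", dim = c(96, 96), n_cells = 5, tau = 1,
                       seed = 9)
  cfg2 <- scene_config(panel = "MP1", dim = c(96, 96), n_cells = 5, tau = 2,
                       seed = 9)
  tr <- simulate_scene(cfg1)
  r1 <- render_truth_planes(tr, cfg1)
  r2 <- render_truth_planes(tr, cfg2)
  expect_equal(r2$af, 2 * r1$af, tolerance = 1e-12)
  for (m in names(r1$planes)) expect_identical(r1$planes[[m]], r2$planes[[m]])
  expect_true(all(r1$af >= 0))
})

test_that("without artefacts each annulus contains only its own profile's markers", {
  cfg <- scene_config(panel = "MP1", dim = c(256, 256), n_cells = 40,
                      kappa = 0, nu = 0, seed = 12)
  tr <- simulate_scene(cfg)
  rp <- render_truth_planes(tr, cfg)
  ab <- attr(tr, "abundance")
  memb <- names(which(marker_compartments("MP1") == "membrane"))
  for (i in seq_len(nrow(tr))) {
    idx <- mplexpheno:::shape_index(tr$y[i], tr$x[i], tr$radius[i],
                                    tr$radius[i] + cfg$annulus_width, cfg$dim)
    for (m in memb) {
      if (ab[i, m] == 0) expect_equal(max(rp$planes[[m]][idx]), 0)
      else expect_equal(unique(rp$planes[[m]][idx]), ab[i, m],
                        ignore_attr = TRUE)
    }
  }
})

test_that("nonspecific co-stain adds nu x CD20 to the CD8 plane inside hotspots", {
  cfg <- scene_config(panel = "MP1", dim = c(160, 160), n_cells = 1,
                      hotspots = list(list(center = c(80, 80), radius = 40)),
                      hotspot_multiplier = 1e6, nu = 0.3, kappa = 0, seed = 21)
  tr <- simulate_scene(cfg)
  expect_equal(tr$context, "hotspot")
  ab <- attr(tr, "abundance")
  # force a pure CD20+ cell
  ab[1, ] <- 0; ab[1, "DAPI"] <- 22; ab[1, "CD20"] <- 25
  attr(tr, "abundance") <- ab
  rp <- render_truth_planes(tr, cfg)
  idx <- mplexpheno:::shape_index(tr$y[1], tr$x[1], tr$radius[1],
                                  tr$radius[1] + cfg$annulus_width, cfg$dim)
  expect_equal(unique(rp$planes$CD8[idx]), 0.3 * 25)
  expect_equal(unique(rp$planes$CD20[idx]), 25)
})

test_that("rendered abundance is conserved without artefacts", {
  cfg <- scene_config(panel = "MP1", dim = c(256, 256), n_cells = 30,
                      kappa = 0, nu = 0, seed = 14)
  tr <- simulate_scene(cfg)
  rp <- render_truth_planes(tr, cfg)
  ab <- attr(tr, "abundance")
  comp <- marker_compartments("MP1")
  # independent pixel-count oracle from the distance definition
  count_px <- function(cy, cx, r_in, r_out, d) {
    ys <- seq_len(d[1]) - 1; xs <- seq_len(d[2]) - 1
    d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
    sum(d2 <= r_out^2 & d2 > r_in^2)
  }
  for (m in names(rp$planes)) {
    expected <- 0
    for (i in seq_len(nrow(tr))) {
      if (ab[i, m] == 0) next
      n_px <- if (comp[[m]] == "nucleus")
        count_px(tr$y[i], tr$x[i], -1, tr$radius[i], cfg$dim)
      else count_px(tr$y[i], tr$x[i], tr$radius[i],
                    tr$radius[i] + cfg$annulus_width, cfg$dim)
      expected <- expected + ab[i, m] * n_px
    }
    expect_equal(sum(rp$planes[[m]]), unname(expected), tolerance = 1e-9)
  }
})

test_that("channel mixing is linear, exposure-scaled and seed-deterministic", {
  cfg <- scene_config(panel = "MP1", dim = c(96, 96), n_cells = 10, seed = 17)
  lib <- opal_library(unname(cfg$pairing))
  fl <- filter_set("motif7")
  tr <- simulate_scene(cfg)
  rp <- render_truth_planes(tr, cfg)
  zero <- lapply(rp$planes, function(p) p * 0)

  # zero abundances, zero noise -> all-zero channels
  img0 <- mix_to_channels(zero, rp$af * 0, lib, fl, cfg$exposures, 0, 1, cfg$pairing)
  expect_true(all(vapply(img0$channels, max, 0) == 0))

  # channel vector at any pixel of a single-fluorophore scene is proportional
  # to that fluorophore's sensing column
  one <- zero; one$CD4 <- rp$planes$CD4
  img1 <- mix_to_channels(one, rp$af * 0, lib, fl, cfg$exposures, 0, 1, cfg$pairing)
  M <- sensing_matrix(lib, fl)
  px <- which(rp$planes$CD4 > 0)[1]
  v <- vapply(names(img1$channels), function(ch)
    img1$channels[[ch]][px] / cfg$exposures[[ch]], 0)
  expect_equal(unname(v), unname(M[, "Opal620"] * rp$planes$CD4[px]),
               tolerance = 1e-9)

  # linearity: image of a sum of abundance fields = sum of the images
  imgA <- mix_to_channels(rp$planes, rp$af, lib, fl, cfg$exposures, 0, 1, cfg$pairing)
  both <- Map(`+`, rp$planes, one)
  imgB <- mix_to_channels(both, rp$af, lib, fl, cfg$exposures, 0, 1, cfg$pairing)
  for (ch in names(imgA$channels))
    expect_equal(imgB$channels[[ch]], imgA$channels[[ch]] + img1$channels[[ch]],
                 tolerance = 1e-9)

  # doubling one exposure doubles that channel only (zero noise)
  e2 <- cfg$exposures; e2[["ch620"]] <- 2 * e2[["ch620"]]
  img2 <- mix_to_channels(rp$planes, rp$af, lib, fl, e2, 0, 1, cfg$pairing)
  expect_equal(img2$channels$ch620, 2 * imgA$channels$ch620, tolerance = 1e-9)
  expect_equal(img2$channels$ch570, imgA$channels$ch570)

  # identical seed -> bit-identical noisy image
  n1 <- mix_to_channels(rp$planes, rp$af, lib, fl, cfg$exposures, 0.5, 33, cfg$pairing)
  n2 <- mix_to_channels(rp$planes, rp$af, lib, fl, cfg$exposures, 0.5, 33, cfg$pairing)
  expect_identical(n1, n2)
  expect_error(mix_to_channels(list(BAD = zero$CK), rp$af, lib, fl,
                               cfg$exposures, 0, 1, cfg$pairing),
               "no fluorophore")
})

test_that("scene configuration validates artefact coefficients and hotspot fit", {
  expect_error(scene_config(tau = -1), "tau")
  expect_error(scene_config(kappa = 1.5), "kappa")
  expect_error(scene_config(nu = -0.1), "nu")
  expect_error(scene_config(dim = c(100, 100),
                            hotspots = list(list(center = c(90, 90), radius = 40))),
               "fit")
})
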