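test_that("NNLS unmixing matches the unconstrained least-squares oracle on noiseless data", {
  pairing <- default_pairing("MP1")
  lib <- opal_library(unname(pairing))
  fl <- filter_set("motif7")
  M <- sensing_matrix(lib, fl)
  set.seed(61)
  X <- matrix(runif(7 * 500, 0, 30), 7)
  Y <- M %*% X
  fit <- mplexpheno:::.nnls_multi(M, Y)
  # pseudoinverse oracle (true solution is nonnegative, so they must agree)
  Xp <- solve(crossprod(M), crossprod(M, Y))
  expect_lt(max(abs(fit$x - Xp)), 1e-6)
  expect_lt(max(abs(fit$x - X)), 1e-6)
  # independent NNLS oracle on a handful of pixels
  skip_if_not_installed("pracma")
  for (j in 1:5)
    expect_equal(unname(fit$x[, j]), pracma::lsqnonneg(M, Y[, j])$x,
                 tolerance = 1e-8)
})

test_that("unmix recovers truth planes exactly and separates autofluorescence", {
  pr <- processed_fixture("sparse-mp1")
  fx <- pr$fx
  for (m in names(fx$planes)) {
    f <- fx$config$pairing[[m]]
    expect_lt(max(abs(pr$un$abundance[[f]] - fx$planes[[m]])), 1e-6)
  }
  expect_lt(max(abs(pr$un$af - fx$af)), 1e-6)
  expect_lt(max(pr$un$residual), 1e-6)
})

test_that("an all-zero image unmixes to zero abundances and residual", {
  lib <- opal_library(unname(default_pairing("MP1")))
  fl <- filter_set("motif7")
  z <- matrix(0, 32, 32)
  img <- structure(list(channels = setNames(rep(list(z), 7), names(fl)),
                        exposures = setNames(rep(10, 7), names(fl)),
                        filters = "motif7"), class = "mchan_image")
  u <- unmix(img, lib)
  expect_true(all(vapply(u$abundance, max, 0) == 0))
  expect_equal(max(u$residual), 0)
})

test_that("thickness changes autofluorescence but not marker abundances (noise-free)", {
  mk <- function(tau) scene_config(panel = "MP1", dim = c(128, 128),
                                   n_cells = 15, kappa = 0, nu = 0,
                                   noise_sigma = 0, tau = tau, seed = 77)
  cfg1 <- mk(1); cfg3 <- mk(3)
  tr <- simulate_scene(cfg1)
  lib <- opal_library(unname(cfg1$pairing))
  fl <- filter_set("motif7")
  u <- lapply(list(cfg1, cfg3), function(cfg) {
    rp <- render_truth_planes(tr, cfg)
    unmix(mix_to_channels(rp$planes, rp$af, lib, fl, cfg$exposures, 0, 77,
                          cfg$pairing), lib)
  })
  for (f in names(u[[1]]$abundance))
    expect_lt(max(abs(u[[1]]$abundance[[f]] - u[[2]]$abundance[[f]])), 1e-6)
  expect_equal(mean(u[[2]]$af) / mean(u[[1]]$af), 3, tolerance = 1e-6)
})

test_that("unmixing the same scene at different exposures yields identical counts", {
  fx <- fixture("sparse-mp1")
  exp2 <- fx$config$exposures * c(2, 0.5, 1, 3, 1, 0.25, 4)
  img2 <- mix_to_channels(fx$planes, fx$af, fx$library, filter_set("motif7"),
                          exp2, 0, fx$config$seed, fx$config$pairing)
  u1 <- processed_fixture("sparse-mp1")$un
  u2 <- unmix(img2, fx$library)
  for (f in names(u1$abundance))
    expect_lt(max(abs(u1$abundance[[f]] - u2$abundance[[f]])), 1e-6)
})

test_that("crosstalk is identity for perfect unmixing and flags dropout scenes", {
  pairing <- default_pairing("MP1")
  lib <- opal_library(unname(pairing))
  cfg <- scene_config(panel = "MP1", dim = c(160, 160), n_cells = 30,
                      kappa = 0, nu = 0, noise_sigma = 0, seed = 31)
  sp <- singleplex_scene_set(cfg, lib, pairing,
                             markers = c("CD20", "CD8", "CD3"))
  K <- crosstalk_matrix(sp$scenes, lib)
  got <- !is.na(K[, 1])
  expect_equal(unname(diag(K)[got]), rep(1, sum(got)))
  off <- K[got, , drop = FALSE]; diag_idx <- cbind(which(got), which(got))
  for (f in rownames(off))
    for (g in colnames(off))
      if (f != g && !is.na(off[f, g])) expect_lt(off[f, g], 1e-6)
  # a dropout acquisition (fluorophore omitted) has ~zero row total and is flagged
  zero <- lapply(sp$scenes[[1]]$channels, function(m) m * 0)
  af_only <- mix_to_channels(list(DAPI = matrix(0, 160, 160)),
                             matrix(4, 160, 160), lib, filter_set("motif7"),
                             cfg$exposures, 0, 1, pairing)
  K2 <- crosstalk_matrix(list(Opal690 = af_only), lib)
  expect_true("Opal690" %in% attr(K2, "flagged"))
  expect_true(all(is.na(K2["Opal690", ])))
})

test_that("autofluorescence QC excludes thick sections with a named reason", {
  fx <- fixture("thick-section")
  thick <- qc_autofluorescence(unmix(fx$thick$image, fx$thick$library))
  thin <- qc_autofluorescence(unmix(fx$thin$image, fx$thin$library))
  expect_null(thin$exclusion)
  expect_match(thick$exclusion, "autofluorescence bound")
  expect_match(thick$exclusion, "by 1")  # states by how much
  # an image unmixed with a wrong-peak library fails the residual bound
  shifted <- opal_library(unname(default_pairing("MP1")))
  shifted$spectra$Opal520 <- parametric_spectrum("Opal520", 545, 40)
  shifted$spectra$Opal570 <- parametric_spectrum("Opal570", 600, 40)
  shifted$spectra$Opal620 <- parametric_spectrum("Opal620", 655, 40)
  wrong <- qc_autofluorescence(unmix(fx$thin$image, shifted))
  expect_match(wrong$exclusion, "residual bound")
})

test_that("unmixing refuses rank-deficient configurations and mismatched dims", {
  lib <- opal_library(unname(default_pairing("MP1", overlap_cd20 = TRUE)))
  fx <- fixture("thick-section")
  img5 <- structure(list(channels = setNames(rep(list(matrix(0, 8, 8)), 5),
                                             names(filter_set("standard5"))),
                         exposures = setNames(rep(10, 5),
                                              names(filter_set("standard5"))),
                         filters = "standard5"), class = "mchan_image")
  expect_error(suppressWarnings(unmix(img5, lib)), "rank deficient")
  bad <- fx$thin$image
  bad$channels[[2]] <- matrix(0, 8, 8)
  expect_error(unmix(bad, fx$thin$library), "dimension")
})
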