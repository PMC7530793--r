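test_that("threshold derivation: manual, quantile-match and otsu behave as specified", {
  cells <- toy_cells(cbind(CD3 = rep(10, 20)))
  th <- derive_threshold(cells, "CD3", "manual", value = 5)
  expect_equal(mean(classify_singleplex(cells, "CD3", th)), 1)

  set.seed(8)
  cells2 <- toy_cells(cbind(CD3 = runif(97, 0, 30)))
  th2 <- derive_threshold(cells2, "CD3", "quantile-match",
                          reference_positive_fraction = 0.25)
  called <- mean(classify_singleplex(cells2, "CD3", th2))
  expect_lte(abs(called - 0.25), 1 / 97)

  # bimodal column: otsu lands between the modes (histogram oracle)
  set.seed(9)
  x <- c(rnorm(150, 5, 1), rnorm(150, 20, 1))
  cells3 <- toy_cells(cbind(CD3 = pmax(x, 0)))
  th3 <- derive_threshold(cells3, "CD3", "otsu")
  expect_gt(th3$threshold, 8)
  expect_lt(th3$threshold, 17)

  expect_error(derive_threshold(cells, "CD3", "quantile-match"),
               "reference fraction")
  expect_error(derive_threshold(cells, "CD3", "manual"), "value")
})

test_that("singleplex detection is independent, bounded and deterministic", {
  set.seed(10)
  cells <- toy_cells(cbind(CD20 = runif(50, 0, 30), CD8 = runif(50, 0, 30)))
  expect_equal(sum(classify_singleplex(cells, "CD20", 31)), 0)
  a <- classify_singleplex(cells, "CD20", 12)
  b <- classify_singleplex(cells, "CD20", 12)
  expect_identical(a, b)
  # altering the other marker's column changes nothing
  cells2 <- cells; cells2$CD8_membrane_mean <- 0
  expect_identical(classify_singleplex(cells2, "CD20", 12), a)
})

test_that("hierarchical classification follows the detection order and tree rules", {
  tree <- default_tree("MP1")
  th <- default_thresholds("MP1")
  final <- default_orders("MP1")$final
  # B cell with nonspecific CD8 co-stain: CD20 before CD8 keeps it CD20+
  cells <- toy_cells(list(c(CD20 = 25, CD8 = 7)), "MP1")
  cl <- classify_hierarchical(cells, th, final, tree)
  expect_equal(cl$class, "CD20+")
  # the same cell under a CD8-before-CD20 order is claimed CD8+
  cl2 <- classify_hierarchical(cells, th, c("CK", "CD4", "CD3", "CD8", "CD20"),
                               tree)
  expect_equal(cl2$class, "CD8+")
  # a CK-only cell is CK+ under every shipped order
  ck <- toy_cells(list(c(CK = 22)), "MP1")
  for (o in default_orders("MP1"))
    expect_equal(classify_hierarchical(ck, th, o, tree)$class, "CK+")
  # dense-region CD4/CD8 dual positive: script 1 leaves the CD4 branch,
  # script 2 reclassifies to CD4+/CD8+
  dual <- toy_cells(list(c(CD4 = 20, CD8 = 18)), "MP1")
  s1 <- classify_hierarchical(dual, th, final, strip_unexpected(tree))
  s2 <- classify_hierarchical(dual, th, final, tree)
  expect_equal(s1$class, "CD4+")
  expect_equal(s2$class, "CD4+/CD8+")
  # audit trail records the firing step
  expect_match(s2$rule, "compound:CD8")
  expect_error(classify_hierarchical(dual, th, c("CK", "CD4"), tree),
               "permutation")
})

test_that("multilabel classification is order-free and labels raw sets", {
  th <- default_thresholds("MP1")
  cells <- toy_cells(list(c(CD3 = 20, CD4 = 20),
                          c(CD20 = 25, CD8 = 7),
                          c(CK = 22),
                          c(CD3 = 0)), "MP1")
  ml <- classify_multilabel(cells, th, panel = "MP1")
  expect_equal(ml$class, c("CD3+/CD4+", "CD20+/CD8+", "CK+", "unclassified"))
  # contrast with the hierarchy: the dual CD20/CD8 cell is CD20+ there
  hi <- classify_hierarchical(cells, th, default_orders("MP1")$final,
                              default_tree("MP1"))
  expect_equal(hi$class[2], "CD20+")
  # permuting the threshold (marker evaluation) order changes nothing
  ml2 <- classify_multilabel(cells, rev(th), panel = "MP1")
  expect_identical(ml$class, ml2$class)
})

test_that("random-forest classification reaches resubstitution accuracy and is seeded", {
  pr <- processed_fixture("sparse-mp1")
  mm <- match_cells(pr$cells, pr$fx$truth)
  labels <- truth_class(pr$fx$truth)[match(mm$matches$truth, pr$fx$truth$id)]
  training <- data.frame(id = mm$matches$detected, label = labels)
  cl <- classify_learned(pr$cells, training, seed = 5)
  acc <- mean(cl$class[match(training$id, cl$id)] == training$label)
  expect_gte(acc, 0.99)
  cl2 <- classify_learned(pr$cells, training, seed = 5)
  expect_identical(cl$class, cl2$class)
  expect_error(classify_learned(pr$cells,
                                data.frame(id = training$id[1:5],
                                           label = rep("CK+", 5))),
               "training error")
})

test_that("every cell receives exactly one label and scripts conserve the unclassified set", {
  pr <- processed_fixture("hotspot-mp1")
  th <- default_thresholds("MP1")
  tree <- default_tree("MP1")
  cl <- classify_hierarchical(pr$cells, th, default_orders("MP1")$final, tree)
  expect_equal(nrow(cl), nrow(pr$cells))
  expect_true(all(cl$class %in% c(mplexpheno:::tree_vocabulary(tree),
                                  "unclassified")))
  classified <- cl$class != "unclassified"
  fr <- table(cl$class[classified]) / sum(classified)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  cs <- compare_scripts(pr$cells, th, default_orders("MP1")$final, tree)
  expect_identical(cs$calls1$class == "unclassified",
                   cs$calls2$class == "unclassified")
})

test_that("order sweep: sparse artefact-free scenes are order-free, dense scenes are not", {
  pr <- processed_fixture("sparse-mp1")
  th <- quantile_thresholds(pr$fx, pr$cells)
  tree <- default_tree("MP1")
  sw <- order_sweep(pr$cells, th, tree)
  for (o in rownames(sw$fractions))
    expect_equal(sw$fractions[o, ], sw$fractions["final", ], tolerance = 1e-12)

  prh <- processed_fixture("hotspot-mp1")
  swh <- order_sweep(prh$cells, default_thresholds("MP1"), tree)
  cd8_cols <- grepl("CD8", colnames(swh$fractions))
  cd8 <- rowSums(swh$fractions[, cd8_cols, drop = FALSE])
  expect_gt(max(cd8) - min(cd8), 0)
})

test_that("masking over-calls the first-ordered membrane marker in dense scenes", {
  pr <- processed_fixture("hotspot-mp1")
  tree <- default_tree("MP1")
  cl <- classify_hierarchical(pr$cells, default_thresholds("MP1"),
                              default_orders("MP1")$order1_cd20_first, tree)
  cd20_frac <- mean(grepl("CD20\\+", cl$class))
  true_cd20 <- mean(attr(pr$fx$truth, "abundance")[, "CD20"] > 0)
  expect_gte(cd20_frac, true_cd20)
})

test_that("script comparison is empty when no unexpected rules can fire", {
  pr <- processed_fixture("sparse-mp1")
  th <- quantile_thresholds(pr$fx, pr$cells)
  t1 <- strip_unexpected(default_tree("MP1"))
  cs <- compare_scripts(pr$cells, th, default_orders("MP1")$final, t1)
  expect_equal(nrow(cs$report), 0)
  expect_length(cs$reclassified, 0)
})

test_that("hierarchical fractions recover the simulated phenotype mix", {
  pr <- processed_fixture("sparse-mp1")
  th <- quantile_thresholds(pr$fx, pr$cells)
  cl <- classify_hierarchical(pr$cells, th, default_orders("MP1")$final,
                              default_tree("MP1"))
  got <- table(cl$class[cl$class != "unclassified"])
  got <- got / sum(got)
  want <- truth_class(pr$fx$truth)
  want <- table(want[want != "unclassified"])
  want <- want / sum(want)
  for (k in union(names(got), names(want))) {
    g <- if (k %in% names(got)) got[[k]] else 0
    w <- if (k %in% names(want)) want[[k]] else 0
    expect_lt(abs(g - w), 0.02)
  }
})
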