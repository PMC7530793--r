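# Sequential binary hierarchical phenotyping: marker thresholds, decision
# trees with expected/unexpected compound classes, detection orders, and the
# order-sweep / script-comparison analyses.

#' Measurement column used for a marker
#'
#' Thresholding acts on a single measurement per marker: the membrane-ring
#' mean for membranous markers and the nucleus mean for nuclear markers
#' (FOXP3).
#' @param marker marker name; @param panel panel name.
#' @export
marker_measurement <- function(marker, panel) {
  comp <- marker_compartments(panel)[[marker]]
  paste0(marker, "_", ifelse(comp == "nucleus", "nucleus", "membrane"), "_mean")
}

#' Derive a classification threshold for one marker
#'
#' `"manual"` returns the configured value. `"quantile-match"` returns the
#' threshold whose positive fraction equals a reference fraction (the stand-in
#' for matching thresholds against the chromogenic reference arm): the
#' midpoint between the k-th and (k+1)-th largest measurement, `k = round(f*n)`.
#' `"otsu"` returns the between-class-variance split of the measurement
#' histogram.
#'
#' @param cells `cell_records`; @param marker marker name.
#' @param method `"manual"`, `"quantile-match"` or `"otsu"`.
#' @param value manual threshold (counts).
#' @param reference_positive_fraction target positive fraction for
#'   quantile-match.
#' @param panel panel name (selects the measurement compartment).
#' @return a `marker_threshold`: list (marker, column, threshold, provenance).
#' @export
derive_threshold <- function(cells, marker,
                             method = c("manual", "quantile-match", "otsu"),
                             value = NULL, reference_positive_fraction = NULL,
                             panel = "MP1") {
  method <- match.arg(method)
  column <- marker_measurement(marker, panel)
  if (!column %in% names(cells)) stop("marker column ", column, " not present")
  x <- cells[[column]]
  thr <- switch(method,
    manual = {
      if (is.null(value)) stop("configuration error: manual method needs a value")
      value
    },
    `quantile-match` = {
      f <- reference_positive_fraction
      if (is.null(f)) stop("configuration error: quantile-match needs a reference fraction")
      n <- length(x)
      k <- round(f * n)
      s <- sort(x, decreasing = TRUE)
      if (k <= 0) max(x) + 1
      else if (k >= n) min(x) - 1e-9
      else (s[k] + s[k + 1]) / 2
    },
    otsu = {
      r <- range(x)
      if (diff(r) <= 0) stop("otsu threshold undefined for a constant column")
      bins <- 256
      h <- tabulate(pmin(bins, floor((x - r[1]) / diff(r) * bins) + 1L), bins)
      p <- h / sum(h)
      omega <- cumsum(p); mu <- cumsum(p * seq_len(bins))
      mu_t <- mu[bins]
      bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
      bcv[!is.finite(bcv)] <- 0
      # empty gaps give a flat maximal plateau; take its midpoint
      plateau <- which(bcv >= max(bcv) - 1e-12)
      cut <- floor(mean(range(plateau)))
      r[1] + cut / bins * diff(r)
    })
  if (thr <= 0 && method != "quantile-match") stop("threshold must be > 0")
  structure(list(marker = marker, column = column, threshold = thr,
                 provenance = if (method == "manual") "manual" else "auto"),
            class = "marker_threshold")
}

#' Default manual thresholds for a panel
#'
#' 4 counts for every marker: roughly 20% of the calibrated positive signal,
#' well above unmixed background yet low enough that nonspecific co-stain and
#' neighbour spillover in dense regions are detected, as the assay observes.
#'
#' @param panel panel name; @param value threshold counts.
#' @return named list of `marker_threshold` (DAPI excluded).
#' @export
default_thresholds <- function(panel, value = 4) {
  mk <- setdiff(panel_markers(panel), "DAPI")
  out <- lapply(mk, function(m)
    structure(list(marker = m, column = marker_measurement(m, panel),
                   threshold = value, provenance = "manual"),
              class = "marker_threshold"))
  names(out) <- mk
  out
}

threshold_value <- function(thresholds, marker) thresholds[[marker]]$threshold

# cells x markers logical positivity matrix (strict inequality: ties at the
# threshold are negative)
positivity_matrix <- function(cells, thresholds) {
  mk <- names(thresholds)
  P <- vapply(mk, function(m) cells[[thresholds[[m]]$column]] > thresholds[[m]]$threshold,
              logical(nrow(cells)))
  if (nrow(cells) == 1) P <- matrix(P, 1, dimnames = list(NULL, mk))
  P
}

#' Singleplex detection of one marker
#'
#' Positive iff the marker's compartment mean strictly exceeds the threshold;
#' independent of every other marker.
#'
#' @param cells `cell_records`; @param marker marker name;
#' @param threshold a `marker_threshold` or numeric counts value.
#' @param panel panel name (used when `threshold` is numeric).
#' @return logical vector.
#' @export
classify_singleplex <- function(cells, marker, threshold, panel = "MP1") {
  if (is.numeric(threshold))
    threshold <- structure(list(marker = marker,
                                column = marker_measurement(marker, panel),
                                threshold = threshold, provenance = "manual"),
                           class = "marker_threshold")
  cells[[threshold$column]] > threshold$threshold
}

#' Phenotype decision trees
#'
#' A tree is the classification program of the sequential binary classifier:
#' per marker a base class for unclaimed positive cells, plus compound rules
#' `(existing class, marker) -> new class` tagged `expected` or `unexpected`.
#' Removing the unexpected-tagged rules yields "script 1" (expected phenotypes
#' only); the full tree is "script 2".
#'
#' The default MP1 tree carries base classes CK+, CD4+, CD3+, CD20+, CD8+,
#' expected compounds CD3+/CD4+ and CD3+/CD8+, and unexpected compound
#' CD4+/CD8+ (dual-positive cells of dense immune regions). The default MP2
#' tree carries CK+, CD68+, CD4+, FOXP3+, expected compound CD4+/FOXP3+ and
#' unexpected compound CD4+/CD68+.
#'
#' @param panel `"MP1"` or `"MP2"`.
#' @return a `phenotype_tree`.
#' @export
default_tree <- function(panel) {
  if (panel == "MP1") {
    # expected compound rules are directional pairs so that true co-expressing
    # phenotypes resolve identically under every detection order; there is
    # deliberately no compound involving CD20, so cells claimed CD20+ (or
    # claimed CD8+ before the CD20 step) keep that class, which is where the
    # detection-order effect of dense B-cell regions comes from
    steps <- c(CK = "CK+", CD4 = "CD4+", CD3 = "CD3+", CD20 = "CD20+", CD8 = "CD8+")
    rules <- data.frame(
      class = c("CD4+", "CD3+", "CD3+", "CD8+", "CD3+/CD4+", "CD4+"),
      marker = c("CD3", "CD4", "CD8", "CD3", "CD8", "CD8"),
      new_class = c("CD3+/CD4+", "CD3+/CD4+", "CD3+/CD8+", "CD3+/CD8+",
                    "CD4+/CD8+", "CD4+/CD8+"),
      unexpected = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE)
  } else if (panel == "MP2") {
    steps <- c(CK = "CK+", CD68 = "CD68+", CD4 = "CD4+", FOXP3 = "FOXP3+")
    rules <- data.frame(
      class = c("CD4+", "FOXP3+", "CD4+", "CD68+"),
      marker = c("FOXP3", "CD4", "CD68", "CD4"),
      new_class = c("CD4+/FOXP3+", "CD4+/FOXP3+", "CD4+/CD68+", "CD4+/CD68+"),
      unexpected = c(FALSE, FALSE, TRUE, TRUE),
      stringsAsFactors = FALSE)
  } else stop("configuration error: unknown panel '", panel, "'")
  structure(list(panel = panel, steps = steps, rules = rules,
                 fallback = "unclassified"),
            class = "phenotype_tree")
}

#' @rdname default_tree
#' @param tree a `phenotype_tree`.
#' @return the tree with all unexpected-tagged compound rules removed
#'   ("script 1").
#' @export
strip_unexpected <- function(tree) {
  tree$rules <- tree$rules[!tree$rules$unexpected, , drop = FALSE]
  tree
}

tree_vocabulary <- function(tree) unique(c(tree$steps, tree$rules$new_class))

#' Default detection orders
#'
#' The final order places the weak, spatially confined markers last, with CD20
#' before CD8 so B lymphocytes with nonspecific CD8 co-stain are claimed as
#' CD20+ rather than CD8+. The list reconstructs a progression from the naive
#' CD20-first order (the staining order) to the final order; only the first
#' and final orders are canonical, the intermediates are labelled
#' reconstructions.
#'
#' @param panel panel name.
#' @return named list of marker orders (DAPI excluded).
#' @export
default_orders <- function(panel) {
  if (panel == "MP1") {
    list(order1_cd20_first  = c("CD20", "CD3", "CK", "CD8", "CD4"),
         order2_recon       = c("CD20", "CK", "CD3", "CD4", "CD8"),
         order3_recon       = c("CD3", "CK", "CD4", "CD20", "CD8"),
         order4_recon       = c("CK", "CD3", "CD4", "CD20", "CD8"),
         order5_recon       = c("CK", "CD4", "CD3", "CD8", "CD20"),
         final              = c("CK", "CD4", "CD3", "CD20", "CD8"))
  } else if (panel == "MP2") {
    list(final = c("CK", "CD68", "CD4", "FOXP3"))
  } else stop("configuration error: unknown panel '", panel, "'")
}

validate_order <- function(order, tree) {
  mk <- names(tree$steps)
  if (!setequal(order, mk) || anyDuplicated(order))
    stop("configuration error: detection order must be a permutation of the ",
         "tree's markers (", paste(mk, collapse = ", "), ")")
  invisible(TRUE)
}

#' Sequential binary hierarchical classification
#'
#' Markers are processed in the given detection order. At each step, unclaimed
#' cells above the marker's threshold receive the step's base class;
#' already-classified cells above the threshold are relabelled through a
#' matching compound rule if one exists, otherwise their existing class is
#' retained (positivity ignored). Compound matching checks the cell's current
#' class only. The audit trail records which step or rule fired for every
#' cell. Deterministic.
#'
#' @param cells `cell_records`; @param thresholds named `marker_threshold`
#'   list; @param order marker order; @param tree a `phenotype_tree`.
#' @return a `phenotype_call`: data.frame (id, class, rule) with the tree
#'   attached.
#' @export
classify_hierarchical <- function(cells, thresholds, order, tree) {
  validate_order(order, tree)
  P <- positivity_matrix(cells, thresholds)
  n <- nrow(cells)
  cls <- rep(tree$fallback, n)
  rule <- rep(NA_character_, n)
  for (m in order) {
    pos <- P[, m]
    unclaimed <- cls == tree$fallback & pos
    if (any(unclaimed)) {
      cls[unclaimed] <- tree$steps[[m]]
      rule[unclaimed] <- paste0("base:", m)
    }
    claimed <- cls != tree$fallback & !unclaimed & pos
    if (any(claimed)) {
      rr <- tree$rules[tree$rules$marker == m, , drop = FALSE]
      if (nrow(rr)) {
        hit <- match(cls[claimed], rr$class)
        idx <- which(claimed)[!is.na(hit)]
        if (length(idx)) {
          nc <- rr$new_class[hit[!is.na(hit)]]
          cls[idx] <- nc
          rule[idx] <- paste0("compound:", m)
        }
      }
    }
  }
  out <- data.frame(id = cells$id, class = cls, rule = rule,
                    stringsAsFactors = FALSE)
  attr(out, "tree") <- tree
  attr(out, "order") <- order
  class(out) <- c("phenotype_call", "data.frame")
  out
}

#' Nonhierarchical multilabel classification
#'
#' Each cell's positive-marker set is computed independently and mapped to the
#' phenotype vocabulary through `label_map`; unmapped sets are labelled by the
#' raw marker set (e.g. `"CD20+/CD8+"`). The marker evaluation order is
#' provably irrelevant.
#'
#' @param cells,thresholds as in [classify_hierarchical()].
#' @param label_map named character: names are sorted `+`-joined marker sets
#'   (e.g. `"CD3+CD4"`), values are class labels. Defaults per panel map the
#'   tree vocabulary.
#' @param panel panel name used for the default map.
#' @return a `phenotype_call`.
#' @export
classify_multilabel <- function(cells, thresholds, label_map = NULL,
                                panel = "MP1") {
  if (is.null(label_map)) label_map <- default_label_map(panel)
  P <- positivity_matrix(cells, thresholds)
  mk <- sort(colnames(P))
  key <- apply(P[, mk, drop = FALSE], 1, function(p) paste(mk[p], collapse = "+"))
  cls <- ifelse(key == "", "unclassified",
                ifelse(key %in% names(label_map), label_map[key],
                       vapply(strsplit(key, "\\+"), function(s)
                         paste0(s, "+", collapse = "/"), "")))
  out <- data.frame(id = cells$id, class = unname(cls),
                    rule = paste0("set:", key), stringsAsFactors = FALSE)
  class(out) <- c("phenotype_call", "data.frame")
  out
}

#' @rdname classify_multilabel
#' @export
default_label_map <- function(panel) {
  if (panel == "MP1") {
    c("CK" = "CK+", "CD20" = "CD20+", "CD3" = "CD3+", "CD4" = "CD4+",
      "CD8" = "CD8+", "CD3+CD4" = "CD3+/CD4+", "CD3+CD8" = "CD3+/CD8+",
      "CD4+CD8" = "CD4+/CD8+")
  } else if (panel == "MP2") {
    c("CK" = "CK+", "CD68" = "CD68+", "CD4" = "CD4+", "FOXP3" = "FOXP3+",
      "CD4+FOXP3" = "CD4+/FOXP3+", "CD4+CD68" = "CD4+/CD68+")
  } else stop("configuration error: unknown panel '", panel, "'")
}

#' Supervised multi-measurement classification (random forest)
#'
#' Trains a random forest on all compartment means of a painted training
#' subset and applies it to every cell. Ties in the forest vote are resolved
#' by the forest's deterministic majority vote under the fixed seed. The
#' feature list is recorded in the audit attribute.
#'
#' @param cells `cell_records`; @param training data.frame (id, label) for the
#'   painted subset; @param feature_set measurement columns (default: all
#'   `_mean` columns); @param seed training seed; @param ntree forest size.
#' @return a `phenotype_call` with attribute `features`.
#' @export
classify_learned <- function(cells, training, feature_set = NULL, seed = 1,
                             ntree = 200) {
  if (length(unique(training$label)) < 2)
    stop("training error: need at least 2 classes in the painted labels")
  if (is.null(feature_set))
    feature_set <- grep("_mean$", names(cells), value = TRUE)
  Xall <- cells[, feature_set, drop = FALSE]
  tr_idx <- match(training$id, cells$id)
  if (anyNA(tr_idx)) stop("training ids not present in the cell table")
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = Xall[tr_idx, , drop = FALSE],
                                    y = factor(training$label), ntree = ntree)
  pred <- as.character(predict(fit, Xall))
  out <- data.frame(id = cells$id, class = pred, rule = "random-forest",
                    stringsAsFactors = FALSE)
  attr(out, "features") <- feature_set
  class(out) <- c("phenotype_call", "data.frame")
  out
}

# fraction of cells whose class label includes each marker as positive
marker_fraction_from_calls <- function(calls, markers) {
  vapply(markers, function(m)
    mean(grepl(paste0("(^|/)", m, "\\+"), calls$class)), 0)
}

#' Detection-order sweep
#'
#' Runs one hierarchical classification per order and tabulates class
#' fractions over classified (non-fallback) cells, plus each order's summed
#' absolute deviation of per-marker positives (derived from the class labels,
#' over all cells) from the singleplex detection fractions.
#'
#' @param cells,thresholds,tree as in [classify_hierarchical()].
#' @param orders named list of marker orders.
#' @return list: `fractions` (order x class matrix), `deviation` (named
#'   vector), `singleplex` (per-marker fractions), `calls` (list of
#'   `phenotype_call`).
#' @export
order_sweep <- function(cells, thresholds, tree,
                        orders = default_orders(tree$panel)) {
  for (o in orders) validate_order(o, tree)
  markers <- names(tree$steps)
  singleplex <- vapply(markers, function(m)
    mean(classify_singleplex(cells, m, thresholds[[m]])), 0)
  vocab <- tree_vocabulary(tree)
  fr <- matrix(0, length(orders), length(vocab),
               dimnames = list(names(orders), vocab))
  dev <- setNames(numeric(length(orders)), names(orders))
  calls <- list()
  for (oname in names(orders)) {
    cl <- classify_hierarchical(cells, thresholds, orders[[oname]], tree)
    calls[[oname]] <- cl
    classified <- cl$class != tree$fallback
    if (any(classified)) {
      tab <- table(factor(cl$class[classified], levels = vocab))
      fr[oname, ] <- as.numeric(tab) / sum(classified)
    }
    mf <- marker_fraction_from_calls(cl, markers)
    dev[oname] <- sum(abs(mf - singleplex))
  }
  list(fractions = fr, deviation = dev, singleplex = singleplex, calls = calls)
}

#' Compare expected-only and full decision trees
#'
#' Runs "script 1" (unexpected compound rules stripped) and "script 2" (full
#' tree) under the same detection order, and reports per-context
#' reclassification: which script-1 classes were reassigned, to what, and in
#' which tissue context, verifying the spatial property that reassigned cells
#' lie in dense contexts.
#'
#' @param cells,thresholds,order as in [classify_hierarchical()].
#' @param tree_with_unexpected full `phenotype_tree` ("script 2").
#' @param context character vector of per-cell tissue contexts
#'   (`"hotspot"`/`"sparse"`); defaults to all-sparse.
#' @return list: `report` (data.frame context, from, to, n, fraction_of_from),
#'   `reclassified` ids, `calls1`, `calls2`.
#' @export
compare_scripts <- function(cells, thresholds, order, tree_with_unexpected,
                            context = NULL) {
  if (is.null(context)) context <- rep("sparse", nrow(cells))
  t2 <- tree_with_unexpected
  t1 <- strip_unexpected(t2)
  c1 <- classify_hierarchical(cells, thresholds, order, t1)
  c2 <- classify_hierarchical(cells, thresholds, order, t2)
  moved <- c1$class != c2$class
  if (!any(moved)) {
    return(list(report = data.frame(context = character(0), from = character(0),
                                    to = character(0), n = integer(0),
                                    fraction_of_from = numeric(0)),
                reclassified = integer(0), calls1 = c1, calls2 = c2))
  }
  rep_df <- do.call(rbind, lapply(split(which(moved), list(context[moved],
                    c1$class[moved], c2$class[moved]), drop = TRUE),
    function(idx) {
      ctx <- context[idx[1]]; from <- c1$class[idx[1]]
      data.frame(context = ctx, from = from, to = c2$class[idx[1]],
                 n = length(idx),
                 fraction_of_from = length(idx) /
                   sum(c1$class == from & context == ctx),
                 stringsAsFactors = FALSE)
    }))
  rownames(rep_df) <- NULL
  list(report = rep_df, reclassified = c1$id[moved], calls1 = c1, calls2 = c2)
}
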