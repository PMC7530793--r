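# Shared fixture cache: scenes are deterministic, so each is built once per
# test run and reused across files.

.cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (is.null(.cache[[name]])) .cache[[name]] <- make_fixture(name)
  .cache[[name]]
}

# unmix + segment + measure a fixture, cached
processed_fixture <- function(name) {
  key <- paste0(name, "#processed")
  if (is.null(.cache[[key]])) {
    fx <- fixture(name)
    un <- qc_autofluorescence(unmix(fx$image, fx$library))
    mp <- marker_planes(un, fx$config$pairing)
    labels <- detect_nuclei(mp$DAPI)
    geo <- expand_cells(labels, seg_params()$expansion)
    cells <- measure_cells(labels, geo$cells, geo$rings, mp)
    .cache[[key]] <- list(fx = fx, un = un, planes = mp, labels = labels,
                          geo = geo, cells = cells)
  }
  .cache[[key]]
}

# quantile-matched thresholds against the scene's true positive fractions
quantile_thresholds <- function(fx, cells) {
  ab <- attr(fx$truth, "abundance")
  mk <- setdiff(panel_markers(fx$config$panel), "DAPI")
  th <- lapply(mk, function(m)
    derive_threshold(cells, m, "quantile-match",
                     reference_positive_fraction = mean(ab[, m] > 0),
                     panel = fx$config$panel))
  names(th) <- mk
  th
}

# tissue context of detected cells: inside a hotspot circle (+2 px margin)
detected_context <- function(fx, cells) {
  ctx <- rep("sparse", nrow(cells))
  for (h in fx$config$hotspots) {
    inh <- (cells$y - h$center[1])^2 + (cells$x - h$center[2])^2 <=
      (h$radius + 2)^2
    ctx[inh] <- "hotspot"
  }
  ctx
}

# truth phenotype label mapped to the tree vocabulary
truth_class <- function(truth) {
  map <- c("CK+" = "CK+", "CD3+/CD4+" = "CD3+/CD4+", "CD3+/CD8+" = "CD3+/CD8+",
           "CD3+ (CD4-CD8-)" = "CD3+", "CD20+" = "CD20+",
           "CD68+" = "CD68+", "CD4+" = "CD4+", "CD4+/FOXP3+" = "CD4+/FOXP3+",
           "FOXP3+" = "FOXP3+", "negative" = "unclassified")
  unname(map[truth$phenotype])
}

# minimal hand-built cell table for classifier unit tests; rows is a matrix
# with marker columns, or a list of named per-cell abundance vectors
toy_cells <- function(rows, panel = "MP1") {
  if (is.list(rows)) {
    nm <- unique(unlist(lapply(rows, names)))
    m <- matrix(0, length(rows), length(nm), dimnames = list(NULL, nm))
    for (i in seq_along(rows)) m[i, names(rows[[i]])] <- rows[[i]]
    rows <- m
  }
  mk <- setdiff(panel_markers(panel), "DAPI")
  comp <- marker_compartments(panel)
  out <- data.frame(id = seq_len(nrow(rows)))
  for (m in mk) {
    col <- paste0(m, "_", ifelse(comp[[m]] == "nucleus", "nucleus", "membrane"),
                  "_mean")
    out[[col]] <- if (m %in% colnames(rows)) rows[, m] else 0
  }
  out
}

# all permutations of seq_len(n), for brute-force statistic oracles
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  out
}
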