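#' Segmentation parameters
#'
#' @param sigma Gaussian smoothing sigma (px) applied to the DAPI plane.
#' @param threshold DAPI threshold in counts, or `"auto"` for the triangle
#'   method on the smoothed plane (robust for sparse foreground,
#'   deterministic).
#' @param min_area minimum nucleus area in px^2.
#' @param watershed split touching nuclei by distance-transform watershed.
#' @param expansion cell expansion radius in px (>= 1); the membrane ring is
#'   the expanded cell minus the nucleus.
#' @export
seg_params <- function(sigma = 1, threshold = "auto", min_area = 20,
                       watershed = TRUE, expansion = 2) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (min_area < 1) stop("min_area must be >= 1")
  if (expansion < 1) stop("expansion radius must be >= 1")
  structure(list(sigma = sigma, threshold = threshold, min_area = min_area,
                 watershed = watershed, expansion = expansion),
            class = "seg_params")
}

# Triangle threshold on a 256-bin histogram: maximise the distance between the
# histogram and the line from the peak to the far tail.
triangle_threshold <- function(x, bins = 256) {
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  h <- tabulate(pmin(bins, floor((x - r[1]) / diff(r) * bins) + 1L), bins)
  pk <- which.max(h)
  tail_bin <- max(which(h > 0))
  if (tail_bin <= pk) tail_bin <- bins
  # perpendicular distance below the line from (pk, h[pk]) to (tail_bin, 0)
  span <- pk:tail_bin
  nx <- -h[pk]; ny <- -(tail_bin - pk)
  dist <- (nx * (span - pk) + ny * (h[span] - h[pk])) / sqrt(nx^2 + ny^2)
  cut <- span[which.max(dist)]
  r[1] + (cut - 0.5) / bins * diff(r)
}

#' Detect nuclei on a DAPI abundance plane
#'
#' Gaussian smoothing, thresholding (fixed counts or triangle `"auto"`),
#' small-object removal, and optional distance-transform watershed splitting
#' of touching blobs. Deterministic; an empty plane yields zero labels.
#'
#' @param dapi_plane non-negative matrix of DAPI abundance (counts).
#' @param params a [seg_params()].
#' @return integer label matrix (0 = background, 1..n nuclei).
#' @export
detect_nuclei <- function(dapi_plane, params = seg_params()) {
  if (min(dapi_plane) < 0) stop("DAPI plane must be non-negative")
  sm <- if (params$sigma > 0) EBImage::gblur(dapi_plane, params$sigma) else dapi_plane
  thr <- if (identical(params$threshold, "auto")) triangle_threshold(sm) else params$threshold
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(dapi_plane), ncol(dapi_plane)))
  # trim the smoothing halo before any splitting: the triangle/fixed threshold
  # separates foreground from background, but Gaussian blur extends each blob
  # below-threshold well past its true edge. Keep only pixels above half of
  # the blob's bright-interior level (90th percentile), i.e. the half-maximum
  # edge, which restores the true nucleus radius.
  blobs <- as.matrix(EBImage::bwlabel(mask))
  nz <- which(blobs > 0)
  lab <- blobs[nz]
  v <- dapi_plane[nz]  # refine on the unsmoothed plane: blur rounds concave
                       # waists between touching nuclei and would erase the
                       # distance-transform saddle the watershed needs
  ref <- vapply(split(v, lab), quantile, 0, probs = 0.9, names = FALSE)
  drop <- v <= 0.5 * ref[match(lab, sort(unique(lab)))]
  refined <- matrix(FALSE, nrow(mask), ncol(mask))
  refined[nz[!drop]] <- TRUE
  if (!any(refined)) return(matrix(0L, nrow(dapi_plane), ncol(dapi_plane)))
  labels <- if (params$watershed) {
    d <- EBImage::distmap(refined)
    EBImage::watershed(d, tolerance = 1, ext = 1)
  } else {
    EBImage::bwlabel(refined)
  }
  labels <- as.matrix(labels)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= params$min_area)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  nz <- labels > 0
  out[nz] <- relab[labels[nz]]
  out
}

#' Expand nuclei to cells and membrane rings
#'
#' Each nucleus is dilated by `radius` without crossing a neighbour's
#' expansion: contested pixels go to the geodesically nearest nucleus
#' (deterministic tie-break). The membrane ring is the expanded cell minus the
#' nucleus.
#'
#' @param labels nucleus label matrix from [detect_nuclei()].
#' @param radius expansion radius in px (>= 1).
#' @return list with `cells` (cell label matrix) and `rings` (ring label
#'   matrix; 0 where no ring).
#' @export
expand_cells <- function(labels, radius) {
  if (radius < 1) stop("expansion radius must be >= 1")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!any(labels > 0))
    return(list(cells = labels, rings = labels))
  d <- EBImage::distmap(matrix(as.numeric(labels == 0), nrow(labels), ncol(labels)))
  mask <- labels > 0 | d <= radius
  cells <- EBImage::propagate(matrix(0, nrow(labels), ncol(labels)),
                              seeds = labels, mask = mask, lambda = 1)
  cells <- matrix(as.integer(round(as.matrix(cells))), nrow(labels), ncol(labels))
  rings <- cells
  rings[labels > 0] <- 0L
  list(cells = cells, rings = rings)
}

#' Measure per-cell, per-marker compartment intensities
#'
#' Mean counts per compartment (nucleus, membrane ring, whole cell) for every
#' marker plane; the whole-cell value is the area-weighted mean of nucleus and
#' ring. Centroids are reported 0-based. The table is sorted by cell id with
#' stable column naming `<marker>_<compartment>_mean`.
#'
#' @param labels nucleus labels; @param cells,rings from [expand_cells()].
#' @param planes named list of marker abundance planes (counts).
#' @return data.frame `cell_records`: id, y, x, nucleus_area and measurement
#'   columns.
#' @export
measure_cells <- function(labels, cells, rings, planes) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) {
    out <- data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                      nucleus_area = integer(0))
    for (m in names(planes))
      for (cp in c("nucleus", "membrane", "cell"))
        out[[paste0(m, "_", cp, "_mean")]] <- numeric(0)
    class(out) <- c("cell_records", "data.frame")
    return(out)
  }
  if (!setequal(unique(cells[cells > 0]), ids))
    stop("integrity error: cell geometry labels do not match nucleus labels")
  for (pl in planes) if (!identical(dim(pl), dim(labels)))
    stop("integrity error: plane dimensions do not match geometry")

  nuc_idx <- which(labels > 0)
  nuc_lab <- labels[nuc_idx]
  ring_idx <- which(rings > 0)
  ring_lab <- rings[ring_idx]
  cell_idx <- which(cells > 0)
  cell_lab <- cells[cell_idx]

  nuc_area <- tabulate(nuc_lab, max(ids))[ids]
  ring_area <- tabulate(ring_lab, max(ids))[ids]
  cell_area <- tabulate(cell_lab, max(ids))[ids]
  if (any(nuc_area == 0))
    stop("integrity error: label present in geometry but empty nucleus mask")

  ys <- row(labels)[nuc_idx]; xs <- col(labels)[nuc_idx]
  cy <- rowsum(ys, nuc_lab)[, 1] / nuc_area - 1  # 0-based centroids
  cx <- rowsum(xs, nuc_lab)[, 1] / nuc_area - 1

  out <- data.frame(id = ids, y = as.numeric(cy), x = as.numeric(cx),
                    nucleus_area = nuc_area)
  for (m in names(planes)) {
    v <- planes[[m]]
    nm <- rowsum(v[nuc_idx], nuc_lab)[, 1] / nuc_area
    rm_ <- if (length(ring_idx))
      rowsum(v[ring_idx], ring_lab)[, 1][as.character(ids)] else rep(NA_real_, length(ids))
    rm_ <- ifelse(is.na(rm_) | ring_area == 0, 0, rm_ / ring_area)
    cm <- rowsum(v[cell_idx], cell_lab)[, 1] / cell_area
    out[[paste0(m, "_nucleus_mean")]] <- as.numeric(nm)
    out[[paste0(m, "_membrane_mean")]] <- as.numeric(rm_)
    out[[paste0(m, "_cell_mean")]] <- as.numeric(cm)
  }
  out <- out[order(out$id), ]
  rownames(out) <- NULL
  class(out) <- c("cell_records", "data.frame")
  out
}

#' Match detected cells to ground-truth cells
#'
#' Mutual nearest-centroid matching within one nucleus radius, used by the
#' recovery tests: a detected cell and a true cell match when each is the
#' other's nearest centroid and their distance is at most the true nucleus
#' radius.
#'
#' @param records `cell_records`; @param truth `scene_truth`.
#' @return list with `matches` (data.frame detected id, truth id, distance),
#'   `precision`, `recall`.
#' @export
match_cells <- function(records, truth) {
  if (nrow(records) == 0 || nrow(truth) == 0)
    return(list(matches = data.frame(), precision = 0, recall = 0))
  D <- outer(records$y, truth$y, "-")^2 + outer(records$x, truth$x, "-")^2
  near_t <- apply(D, 1, which.min)   # nearest truth per detection
  near_d <- apply(D, 2, which.min)   # nearest detection per truth
  di <- seq_len(nrow(records))
  mutual <- near_d[near_t] == di
  dist <- sqrt(D[cbind(di, near_t)])
  ok <- mutual & dist <= truth$radius[near_t]
  m <- data.frame(detected = records$id[ok], truth = truth$id[near_t][ok],
                  distance = dist[ok])
  list(matches = m,
       precision = nrow(m) / nrow(records),
       recall = nrow(m) / nrow(truth))
}
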