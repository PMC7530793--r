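#' Spectral unmixing with autofluorescence subtraction
#'
#' Solves, per pixel, a non-negative least-squares problem of the exposure-
#' normalised channel vector against the library's sensing matrix (fluorophore
#' endmembers plus one autofluorescence endmember). Abundances are therefore in
#' counts regardless of the acquisition exposures. The autofluorescence
#' coefficient is returned as its own plane, and the residual plane holds the
#' per-pixel reconstruction error norm.
#'
#' @param image an `mchan_image`.
#' @param library a `spectral_library` (must yield a full-column-rank sensing
#'   matrix for the filter set).
#' @param filters `filter_set`; defaults to the mode recorded on the image.
#' @return An `unmixed_image`: named `abundance` planes (fluorophores), `af`
#'   plane, `residual` plane, and an `exclusion` slot filled by
#'   [qc_autofluorescence()].
#' @export
unmix <- function(image, library, filters = NULL) {
  if (is.null(filters)) filters <- filter_set(image$filters)
  chans <- names(filters)
  if (!all(chans %in% names(image$channels)))
    stop("input error: image channels do not match the filter set")
  M <- sensing_matrix(library, filters)
  if (isTRUE(attr(M, "ill_posed")))
    stop("unmixing error: sensing matrix is rank deficient for this filter set")
  dimg <- dim(image$channels[[1]])
  Y <- vapply(chans, function(ch) {
    pl <- image$channels[[ch]]
    if (!identical(dim(pl), dimg)) stop("input error: channel dimension mismatch")
    as.vector(pl) / image$exposures[[ch]]
  }, numeric(prod(dimg)))
  fit <- .nnls_multi(M, t(Y))
  X <- fit$x
  rownames(X) <- colnames(M)
  fluors <- setdiff(library$names, library$af_name)
  abundance <- lapply(fluors, function(f) matrix(X[f, ], dimg[1], dimg[2]))
  names(abundance) <- fluors
  structure(list(abundance = abundance,
                 af = matrix(X[library$af_name, ], dimg[1], dimg[2]),
                 residual = matrix(fit$residual, dimg[1], dimg[2]),
                 provenance = library$provenance,
                 exclusion = NULL),
            class = "unmixed_image")
}

#' @export
print.unmixed_image <- function(x, ...) {
  d <- dim(x$af)
  cat("unmixed_image:", length(x$abundance), "fluorophore planes + AF,",
      d[1], "x", d[2], "px")
  if (!is.null(x$exclusion)) cat(" [EXCLUDED: ", x$exclusion, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Relabel unmixed fluorophore planes by marker
#'
#' @param unmixed an `unmixed_image`; @param pairing marker -> fluorophore map.
#' @return named list of marker abundance planes.
#' @export
marker_planes <- function(unmixed, pairing) {
  pairing <- pairing[pairing %in% names(unmixed$abundance)]
  out <- lapply(names(pairing), function(m) unmixed$abundance[[pairing[[m]]]])
  names(out) <- names(pairing)
  out
}

#' Crosstalk matrix from singleplex scenes
#'
#' Entry `[f, g]` is the total abundance assigned to fluorophore `g` when only
#' `f` is present, divided by the total assigned to `f` itself; the diagonal is
#' 1 by construction. Rows for empty scenes (no signal assigned to the scene's
#' own fluorophore) are returned as `NA` and flagged.
#'
#' @param scenes named list of `mchan_image`, one singleplex scene per
#'   fluorophore (name = the fluorophore present).
#' @param library,filters passed to [unmix()].
#' @return square matrix with attribute `flagged` naming undefined rows.
#' @export
crosstalk_matrix <- function(scenes, library, filters = NULL) {
  fluors <- setdiff(library$names, library$af_name)
  K <- matrix(NA_real_, length(fluors), length(fluors),
              dimnames = list(fluors, fluors))
  flagged <- character(0)
  for (f in names(scenes)) {
    u <- unmix(scenes[[f]], library, filters)
    tot <- vapply(u$abundance, sum, 0)
    if (!f %in% names(tot) || tot[[f]] <= 0) {
      flagged <- c(flagged, f)
      next
    }
    K[f, names(tot)] <- tot / tot[[f]]
  }
  attr(K, "flagged") <- flagged
  K
}

#' Autofluorescence / residual quality-control gate
#'
#' Excludes an unmixed image when tissue autofluorescence exceeds what the
#' single representative autofluorescence endmember can subtract: the upper-
#' quartile mean of the autofluorescence plane must stay below
#' `max_af_counts`, and the upper-quartile mean of the residual plane below
#' `max_residual` (incomplete unmixing). The reason states which bound failed
#' and by how much.
#'
#' @param unmixed an `unmixed_image`.
#' @param max_af_counts autofluorescence bound (counts).
#' @param max_residual residual-norm bound (counts).
#' @return the `unmixed_image` with `exclusion` set to `NULL` (pass) or a
#'   reason string.
#' @export
qc_autofluorescence <- function(unmixed, max_af_counts = 15, max_residual = 2) {
  af_uq <- upper_quartile_mean(unmixed$af)
  res_uq <- upper_quartile_mean(unmixed$residual)
  reasons <- character(0)
  if (af_uq > max_af_counts)
    reasons <- c(reasons, sprintf(
      "autofluorescence bound exceeded: upper-quartile mean %.2f > %.2f counts (by %.2f)",
      af_uq, max_af_counts, af_uq - max_af_counts))
  if (res_uq > max_residual)
    reasons <- c(reasons, sprintf(
      "residual bound exceeded: upper-quartile mean %.2f > %.2f counts (by %.2f)",
      res_uq, max_residual, res_uq - max_residual))
  unmixed$exclusion <- if (length(reasons)) paste(reasons, collapse = "; ") else NULL
  unmixed$qc <- list(af_upper_quartile_mean = af_uq,
                     residual_upper_quartile_mean = res_uq,
                     max_af_counts = max_af_counts, max_residual = max_residual)
  unmixed
}
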