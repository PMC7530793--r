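#' Parametric Gaussian emission spectrum
#'
#' Builds a unimodal emission curve on a uniform wavelength grid, peak value 1
#' at `peak_nm`. Gaussian stand-ins keyed to nominal Opal peak wavelengths are
#' used throughout because exact measured Opal emission curves are not
#' available; the width is controlled through the full width at half maximum.
#'
#' @param name fluorophore name, e.g. `"Opal690"`.
#' @param peak_nm emission peak in nm; must lie on/within the grid.
#' @param fwhm_nm full width at half maximum in nm (> 0).
#' @param grid ascending, uniformly spaced wavelength grid in nm.
#' @return An `emission_spectrum`: list with `name`, `wavelength`, `intensity`.
#' @export
parametric_spectrum <- function(name, peak_nm, fwhm_nm,
                                grid = wavelength_grid()) {
  stopifnot(is.numeric(grid), length(grid) > 2)
  if (fwhm_nm <= 0) stop("fwhm_nm must be > 0")
  if (peak_nm < min(grid) || peak_nm > max(grid))
    stop("configuration error: peak ", peak_nm, " nm outside wavelength grid for ", name)
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  intensity <- exp(-(grid - peak_nm)^2 / (2 * sigma^2))
  intensity <- intensity / max(intensity)
  structure(list(name = name, wavelength = grid, intensity = intensity),
            class = "emission_spectrum")
}

#' Default wavelength grid (400-800 nm, 2 nm step)
#' @param from,to,step grid limits and spacing in nm.
#' @export
wavelength_grid <- function(from = 400, to = 800, step = 2) seq(from, to, by = step)

# nominal emission peaks; Opal names carry their peak wavelength
fluor_peak <- function(name) {
  if (name == "DAPI") return(461)
  if (name == "AF") return(540)
  if (grepl("^Opal[0-9]+$", name)) return(as.numeric(sub("^Opal", "", name)))
  stop("unknown fluorophore name: ", name)
}

default_fwhm <- function(name) {
  if (name == "AF") return(200)  # broad tissue autofluorescence
  if (name == "DAPI") return(60)
  40
}

#' Bundle spectra into a spectral library
#'
#' A library holds one emission spectrum per fluorophore (including DAPI) plus
#' one autofluorescence endmember, mirroring library slides built from a slide
#' per single fluorophore, a DAPI-only slide and an unstained autofluorescence
#' slide. Libraries may alternatively carry channel-space signatures (one unit-
#' maximum column per member for a specific filter set), which is the form
#' produced by [build_library_from_singleplex()].
#'
#' @param fluors character vector of fluorophore names (must include the panel
#'   fluorophores; `"AF"` is appended automatically).
#' @param grid wavelength grid.
#' @param fwhm optional named numeric vector of per-fluorophore FWHM overrides.
#' @param provenance `"synthetic"` (parametric) or `"measured"`.
#' @return A `spectral_library`.
#' @export
opal_library <- function(fluors, grid = wavelength_grid(), fwhm = NULL,
                         provenance = "synthetic") {
  fluors <- unique(c(fluors, "AF"))
  if (length(fluors) < 2) stop("library needs at least 2 members")
  spectra <- lapply(fluors, function(f) {
    w <- if (!is.null(fwhm) && f %in% names(fwhm)) fwhm[[f]] else default_fwhm(f)
    parametric_spectrum(f, fluor_peak(f), w, grid)
  })
  names(spectra) <- fluors
  structure(list(names = fluors, spectra = spectra, signatures = NULL,
                 filter_mode = NULL, provenance = provenance,
                 af_name = "AF"),
            class = "spectral_library")
}

signature_library <- function(signatures, filter_mode, provenance = "measured") {
  structure(list(names = colnames(signatures), spectra = NULL,
                 signatures = signatures, filter_mode = filter_mode,
                 provenance = provenance, af_name = "AF"),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("spectral_library (", x$provenance, "): ",
      paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Acquisition filter sets
#'
#' `"standard5"` models the five standard epifluorescence filters (DAPI, FITC,
#' Cy3, Texas Red, Cy5); `"motif7"` models the 7-colour whole-slide unmixing
#' filter configuration with one band per Opal peak. Bands may overlap.
#'
#' @param mode `"standard5"` or `"motif7"`.
#' @return A `filter_set`: named list of `c(low, high)` nm bands.
#' @export
filter_set <- function(mode = c("motif7", "standard5")) {
  mode <- match.arg(mode)
  bands <- switch(mode,
    standard5 = list(DAPI = c(430, 490), FITC = c(500, 550), Cy3 = c(550, 610),
                     TexasRed = c(600, 660), Cy5 = c(660, 740)),
    motif7 = list(DAPI = c(430, 490), ch480 = c(462, 502), ch520 = c(504, 544),
                  ch570 = c(552, 592), ch620 = c(602, 642), ch690 = c(672, 712),
                  ch780 = c(762, 802)))
  structure(bands, class = "filter_set", mode = mode)
}

filter_mode <- function(filters) attr(filters, "mode") %||% "custom"

# trapezoid integral of a spectrum over one band
band_integral <- function(spec, band) {
  w <- spec$wavelength
  keep <- w >= band[1] & w <= band[2]
  if (sum(keep) < 2) return(0)
  ww <- w[keep]; ii <- spec$intensity[keep]
  sum(diff(ww) * (head(ii, -1) + ii[-1]) / 2)
}

#' Sensing matrix for a library under a filter configuration
#'
#' Entry `[c, f]` is the band-`c` integral of spectrum `f` (trapezoid rule),
#' optionally scaled per-row by exposure. Columns are normalised to unit
#' maximum so that unmixed abundances are expressed in counts of the
#' fluorophore's brightest channel, making counts comparable across libraries.
#' A rank-deficient matrix is flagged with attribute `ill_posed` and a warning.
#'
#' @param library a `spectral_library`.
#' @param filters a `filter_set`.
#' @param exposures optional named vector of per-channel exposures (ms); rows
#'   are multiplied by them.
#' @return channels x members matrix with attribute `ill_posed`.
#' @export
sensing_matrix <- function(library, filters, exposures = NULL) {
  chans <- names(filters)
  if (!is.null(library$signatures)) {
    if (!identical(library$filter_mode, filter_mode(filters)))
      stop("signature library was built for filter mode '", library$filter_mode,
           "', not '", filter_mode(filters), "'")
    M <- library$signatures[chans, , drop = FALSE]
  } else {
    for (s in library$spectra) {
      rng <- range(s$wavelength)
      for (b in filters) if (b[1] < rng[1] || b[2] > rng[2]) {
        # grid must cover all bands in use; tolerate 2 nm slack at the edges
        if (b[1] < rng[1] - 2 || b[2] > rng[2] + 2)
          stop("wavelength grid of ", s$name, " does not cover band ",
               b[1], "-", b[2], " nm")
      }
    }
    M <- vapply(library$names, function(f)
      vapply(filters, function(b) band_integral(library$spectra[[f]], b), 0),
      numeric(length(chans)))
    rownames(M) <- chans
  }
  cm <- apply(M, 2, max)
  if (any(cm <= 0)) stop("library error: fluorophore ",
                         paste(library$names[cm <= 0], collapse = ", "),
                         " has no signal in any band")
  M <- sweep(M, 2, cm, "/")
  if (!is.null(exposures)) {
    if (!all(chans %in% names(exposures))) stop("missing exposures for some channels")
    M <- M * as.numeric(exposures[chans])
  }
  r <- qr(M)$rank
  ill <- r < ncol(M)
  if (ill) warning("sensing matrix is rank deficient (rank ", r, " < ",
                   ncol(M), "); unmixing will be ill-posed")
  attr(M, "ill_posed") <- ill
  M
}

#' Estimate a spectral library from singleplex acquisitions
#'
#' For each singleplex image (one fluorophore plus autofluorescence present),
#' the channel-space signature is the mean exposure-normalised channel vector
#' of the top-intensity pixel quantile minus the mean background vector (pixels
#' below the median total intensity), which removes the shared autofluorescence
#' term; the autofluorescence signature is the mean vector of the unstained
#' image. Signatures are normalised to unit maximum.
#'
#' @param singleplex named list of `mchan_image`, one per fluorophore.
#' @param af_image unstained `mchan_image` (autofluorescence only).
#' @param filters the `filter_set` the images were acquired with.
#' @param top_quantile quantile defining the bright-pixel set.
#' @return A `spectral_library` carrying channel-space signatures.
#' @export
build_library_from_singleplex <- function(singleplex, af_image, filters,
                                          top_quantile = 0.99) {
  chans <- names(filters)
  counts_mat <- function(img) {
    vapply(chans, function(ch) as.vector(img$channels[[ch]]) / img$exposures[[ch]],
           numeric(length(img$channels[[1]])))
  }
  af_mean <- colMeans(counts_mat(af_image))
  if (max(af_mean) <= 0) stop("library error: autofluorescence image is all zeros")
  sig <- matrix(0, length(chans), length(singleplex) + 1,
                dimnames = list(chans, c(names(singleplex), "AF")))
  for (f in names(singleplex)) {
    Y <- counts_mat(singleplex[[f]])
    tot <- rowSums(Y)
    if (max(tot) <= 0) stop("library error: singleplex image for ", f, " is all zeros")
    top <- tot >= quantile(tot, top_quantile)
    bg <- tot <= quantile(tot, 0.5)
    v <- colMeans(Y[top, , drop = FALSE]) - colMeans(Y[bg, , drop = FALSE])
    v[v < 0] <- 0
    if (max(v) <= 0) stop("library error: no foreground signal for ", f)
    sig[, f] <- v / max(v)
  }
  sig[, "AF"] <- af_mean / max(af_mean)
  signature_library(sig, filter_mode(filters), provenance = "measured")
}

#' Spectrum CSV I/O
#'
#' Two-column CSV (`wavelength_nm`, `intensity`) per fluorophore.
#' @param spec an `emission_spectrum`; `path` a file path.
#' @export
write_spectrum_csv <- function(spec, path) {
  write.csv(data.frame(wavelength_nm = spec$wavelength, intensity = spec$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param name fluorophore name to attach on read.
#' @export
read_spectrum_csv <- function(path, name) {
  d <- read.csv(path)
  structure(list(name = name, wavelength = d$wavelength_nm,
                 intensity = d$intensity / max(d$intensity)),
            class = "emission_spectrum")
}

#' Cosine similarity of two emission spectra or sensing columns
#' @param a,b numeric vectors or `emission_spectrum` objects.
#' @export
cosine_similarity <- function(a, b) {
  if (inherits(a, "emission_spectrum")) a <- a$intensity
  if (inherits(b, "emission_spectrum")) b <- b$intensity
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
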