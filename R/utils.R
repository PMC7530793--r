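# Internal helpers: deterministic seed fan-out and raster geometry.

# One global seed fans out to per-stage substreams with fixed labels, so that
# changing one stage's draws never perturbs another stage.
substream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) * 2654435
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}

# Pixel-centre raster helpers. External tables use 0-based (y, x); internally
# matrices are 1-based, so painting adds 1 to centroids.
pixel_patch <- function(cy, cx, rmax, dim) {
  y0 <- max(1L, floor(cy + 1 - rmax)); y1 <- min(dim[1], ceiling(cy + 1 + rmax))
  x0 <- max(1L, floor(cx + 1 - rmax)); x1 <- min(dim[2], ceiling(cx + 1 + rmax))
  if (y0 > y1 || x0 > x1) return(NULL)
  ys <- y0:y1; xs <- x0:x1
  d2 <- outer((ys - (cy + 1))^2, (xs - (cx + 1))^2, "+")
  list(ys = ys, xs = xs, d2 = d2)
}

# linear indices of disc (d <= r) or annulus (r_in < d <= r_out) pixels
shape_index <- function(cy, cx, r_in, r_out, dim) {
  p <- pixel_patch(cy, cx, r_out + 1, dim)
  if (is.null(p)) return(integer(0))
  sel <- p$d2 <= r_out^2 & p$d2 > r_in^2
  if (!any(sel)) return(integer(0))
  idx <- which(sel, arr.ind = TRUE)
  (p$xs[idx[, 2]] - 1L) * dim[1] + p$ys[idx[, 1]]
}

disc_index <- function(cy, cx, r, dim) shape_index(cy, cx, -1, r, dim)

upper_quartile_mean <- function(x) {
  q <- quantile(x, 0.75, names = FALSE, type = 7)
  mean(x[x >= q])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
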