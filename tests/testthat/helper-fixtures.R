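# Shared helpers: phantom view sets, independent oracles, raster utilities.

# render a full half-turn view set of masks, named by angle
render_view_set <- function(spec, step = 30, px_per_cm = 20, ...) {
  angles <- seq(0, 180, by = step)
  masks <- lapply(angles, function(a) render_view(spec, a, px_per_cm, ...))
  names(masks) <- angles
  masks
}

measure_preset <- function(name, step = 30, px_per_cm = 20, stature_cm = 15,
                           config = measure_config()) {
  spec <- phantom_preset(name, stature_cm)
  measure_subject(render_view_set(spec, step, px_per_cm),
                  stature_cm = stature_cm, config = config)
}

# independent arc-length oracle for an ellipse (p = 2), plain quadrature on
# the standard parametrisation -- kept separate from the package's
# superellipse machinery on purpose
ellipse_arc_quadrature <- function(a, b) {
  stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                   0, 2 * pi, rel.tol = 1e-10)$value
}

# exact radial fan of projected half-widths for one superellipse section
support_fan <- function(a, b, p, step_deg) {
  angles <- seq(0, 180, by = step_deg)
  radial_fan(angles, superellipse_support(a, b, p, angles * pi / 180))
}

# 4-connected morphological inner boundary of a logical matrix
inner_boundary <- function(m) {
  h <- nrow(m); w <- ncol(m)
  er <- m &
    rbind(FALSE, m[-h, , drop = FALSE]) & rbind(m[-1, , drop = FALSE], FALSE) &
    cbind(FALSE, m[, -w, drop = FALSE]) & cbind(m[, -1, drop = FALSE], FALSE)
  m & !er
}

# symmetric Hausdorff distance (px) between the TRUE pixels of two matrices
hausdorff_px <- function(a, b) {
  pa <- which(a, arr.ind = TRUE); pb <- which(b, arr.ind = TRUE)
  if (!nrow(pa) || !nrow(pb)) return(Inf)
  d <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}

# white canvas with a dark filled rectangle (rows x cols), returns image
rect_photo <- function(height = 30, width = 40, r0 = 6, nrows = 20,
                       c0 = 11, ncols = 10, fg = 0.1, bg = 0.95) {
  img <- matrix(bg, height, width)
  img[r0:(r0 + nrows - 1), c0:(c0 + ncols - 1)] <- fg
  img
}

rect_mask <- function(height = 30, width = 40, r0 = 6, nrows = 20,
                      c0 = 11, ncols = 10) {
  m <- matrix(FALSE, height, width)
  m[r0:(r0 + nrows - 1), c0:(c0 + ncols - 1)] <- TRUE
  binary_mask(m)
}

disk_image <- function(n = 120, centre = 60, radius = 50, fg = 0.1, bg = 0.95) {
  d <- outer(seq_len(n), seq_len(n),
             function(r, c) sqrt((r - centre)^2 + (c - centre)^2))
  list(img = ifelse(d <= radius, fg, bg), mask = d <= radius, dist = d)
}
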