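# Silhouette extraction: threshold segmentation, connected components, hole
# filling, Canny edges and per-row width profiles. All raster operations are
# implemented on plain logical/numeric matrices (row 1 = top of image).

#' Binary silhouette mask
#'
#' Thin wrapper marking a logical matrix as a foreground/background mask.
#'
#' @param m logical matrix, TRUE = foreground.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(m) {
  if (is.numeric(m)) m <- m > 0.5
  if (!is.matrix(m) || !is.logical(m))
    stop("binary_mask: expected a logical matrix")
  if (anyNA(m)) stop("binary_mask: NA entries are not allowed")
  structure(m, class = c("binary_mask", "matrix"))
}

unclass_mask <- function(mask) {
  m <- unclass(mask)
  attr(m, "meta") <- NULL
  m
}

#' @export
print.binary_mask <- function(x, ...) {
  m <- unclass_mask(x)
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px (%.1f%%)\n",
              nrow(m), ncol(m), sum(m), 100 * mean(m)))
  meta <- attr(x, "meta")
  if (!is.null(meta$warnings) && length(meta$warnings))
    cat(" warnings:", paste(meta$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Otsu's threshold
#'
#' Maximises between-class variance over a 256-bin histogram of intensities
#' in `[0, 1]`.
#'
#' @param x numeric vector or matrix of intensities in `[0, 1]`.
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("otsu_threshold: no finite intensities")
  nbins <- 256L
  bin <- pmin(pmax(floor(x * nbins) + 1L, 1L), nbins)
  h <- tabulate(bin, nbins)
  w <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # the maximum is a plateau when the histogram has a gap between modes:
  # take the plateau middle, and return the upper edge of the chosen bin so
  # that the dark mode itself falls below the threshold
  cand <- which(sigma_b >= max(sigma_b) - 1e-12)
  cand[ceiling(length(cand) / 2)] / nbins
}

# Run-based connected-component labelling (4- or 8-connectivity) with
# union-find over row runs. Returns an integer matrix (0 = background).
label_components <- function(mask, connectivity = 4L) {
  m <- unclass_mask(mask)
  h <- nrow(m); w <- ncol(m)
  runs <- vector("list", h)
  nrun <- 0L
  for (r in seq_len(h)) {
    v <- m[r, ]
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    s <- starts[keep]; e <- ends[keep]
    ids <- nrun + seq_along(s)
    nrun <- nrun + length(s)
    runs[[r]] <- cbind(start = s, end = e, id = ids)
  }
  if (nrun == 0L) return(matrix(0L, h, w))
  parent <- seq_len(nrun)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8L) 1L else 0L
  for (r in seq_len(h - 1L)) {
    a <- runs[[r]]; b <- runs[[r + 1L]]
    if (is.null(a) || is.null(b)) next
    for (i in seq_len(nrow(a))) {
      ov <- which(b[, "start"] <= a[i, "end"] + slack &
                  b[, "end"] >= a[i, "start"] - slack)
      for (j in ov) {
        ra <- find(a[i, "id"]); rb <- find(b[j, "id"])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(nrun), find, integer(1))
  labels <- match(roots, unique(roots))
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    a <- runs[[r]]
    if (is.null(a)) next
    for (i in seq_len(nrow(a)))
      out[r, a[i, "start"]:a[i, "end"]] <- labels[a[i, "id"]]
  }
  out
}

# Keep only the largest 4-connected foreground component.
largest_component <- function(mask) {
  lab <- label_components(mask, 4L)
  if (!any(lab > 0L)) return(binary_mask(lab > 0L))
  counts <- tabulate(lab[lab > 0L])
  binary_mask(lab == which.max(counts))
}

#' Fill interior background holes of a mask
#'
#' Background regions (4-connected) that do not touch the image border are
#' converted to foreground.
#'
#' @param mask a `binary_mask` or logical matrix.
#' @return A `binary_mask` without interior holes.
#' @export
fill_holes <- function(mask) {
  m <- unclass_mask(binary_mask(mask))
  lab <- label_components(!m, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  hole <- lab > 0L & !(lab %in% border)
  binary_mask(m | hole)
}

#' Segment the body silhouette from a photograph
#'
#' The subject is assumed darker than the (light, ideally white) background.
#' Pixels below a luminance threshold (Otsu's method by default) are taken as
#' foreground; the largest 4-connected component is kept and interior holes
#' are filled, yielding a single solid silhouette. Deterministic for fixed
#' options.
#'
#' A logical-matrix / `binary_mask` input (e.g. a manually prepared mask) is
#' validated, cleaned the same way and returned; no thresholding is applied.
#'
#' @param image matrix or `H x W x 3` array in `[0, 1]`, or a logical mask.
#' @param threshold luminance threshold in `(0, 1)`; `NULL` (default) uses
#'   [otsu_threshold()].
#' @param max_foreground if more than this fraction of pixels is foreground
#'   after thresholding, a "background assumption violated" warning is issued
#'   and recorded in the mask metadata (default 0.6).
#' @return A `binary_mask` with metadata attribute `meta` (threshold used,
#'   warnings).
#' @export
segment_foreground <- function(image, threshold = NULL, max_foreground = 0.6) {
  warnings <- character(0)
  if (is.logical(image) || inherits(image, "binary_mask")) {
    fg <- unclass_mask(binary_mask(image))
    thr <- NA_real_
  } else {
    g <- to_gray(image)
    if (is.null(threshold)) threshold <- otsu_threshold(g)
    thr <- threshold
    fg <- g < threshold
    if (any(fg) && mean(fg) > max_foreground) {
      # only meaningful when we thresholded a photograph ourselves
      msg <- sprintf("background assumption violated: %.0f%% foreground",
                     100 * mean(fg))
      warnings <- c(warnings, msg)
      warning("segment_foreground: ", msg)
    }
  }
  if (!any(fg)) stop("segment_foreground: empty silhouette ",
                     "(no pixel below the threshold)")
  out <- fill_holes(largest_component(binary_mask(fg)))
  attr(out, "meta") <- list(threshold = thr, warnings = warnings)
  out
}

# separable Gaussian smoothing with edge replication
gaussian_smooth <- function(g, sigma) {
  if (sigma <= 0) return(g)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) ncol(m) else nrow(m)
    idx <- function(shift) pmin(pmax(seq_len(n) + shift, 1L), n)
    out <- 0
    for (i in seq_along(k)) {
      sh <- i - r - 1L
      out <- out + k[i] * (if (along_rows) m[, idx(sh), drop = FALSE]
                           else m[idx(sh), , drop = FALSE])
    }
    out
  }
  conv1(conv1(g, TRUE), FALSE)
}

# 3x3 Sobel gradients via shifted matrices (replicated edges)
sobel_gradients <- function(g) {
  h <- nrow(g); w <- ncol(g)
  up <- g[pmax(seq_len(h) - 1L, 1L), , drop = FALSE]
  dn <- g[pmin(seq_len(h) + 1L, h), , drop = FALSE]
  shl <- function(m) m[, pmax(seq_len(w) - 1L, 1L), drop = FALSE]
  shr <- function(m) m[, pmin(seq_len(w) + 1L, w), drop = FALSE]
  gx <- (shr(up) + 2 * shr(g) + shr(dn)) - (shl(up) + 2 * shl(g) + shl(dn))
  gy <- (shl(dn) + 2 * dn + shr(dn)) - (shl(up) + 2 * up + shr(up))
  list(gx = gx, gy = gy)
}

#' Canny edge detection
#'
#' Standard chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantised gradient direction, double-threshold
#' hysteresis (weak edges are kept only when 8-connected to a strong edge).
#' Kept as an inspectable stage for parity with classical silhouette
#' pipelines; the measurement path derives widths from the filled mask, which
#' is hole-robust (see [width_profile()]).
#'
#' @param gray single-channel matrix in `[0, 1]`.
#' @param sigma Gaussian smoothing scale in pixels (default 2).
#' @param low,high hysteresis thresholds as fractions of the maximum gradient
#'   magnitude, `0 <= low < high` (defaults 0.1 / 0.3).
#' @return A `binary_mask` edge map.
#' @export
detect_edges <- function(gray, sigma = 2, low = 0.1, high = 0.3) {
  if (!is.matrix(gray) || !is.numeric(gray))
    stop("detect_edges: grayscale required (single-channel numeric matrix)")
  if (!(low >= 0 && low < high))
    stop("detect_edges: need 0 <= low < high")
  g <- gaussian_smooth(gray, sigma)
  gr <- sobel_gradients(g)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  mx <- max(mag)
  if (mx <= .Machine$double.eps)
    return(binary_mask(matrix(FALSE, nrow(gray), ncol(gray))))
  h <- nrow(mag); w <- ncol(mag)
  # interpolated non-maximum suppression: the neighbour magnitude along the
  # gradient is linearly interpolated between the two bracketing pixels
  # (row axis points down, gy = d/drow)
  shift2 <- function(m, dr, dc)
    m[pmin(pmax(seq_len(h) + dr, 1L), h), pmin(pmax(seq_len(w) + dc, 1L), w), drop = FALSE]
  ax <- abs(gr$gx); ay <- abs(gr$gy)
  sx <- ifelse(gr$gx >= 0, 1L, -1L)
  sy <- ifelse(gr$gy >= 0, 1L, -1L)
  pickx <- function(s) ifelse(s > 0, shift2(mag, 0, 1), shift2(mag, 0, -1))
  picky <- function(s) ifelse(s > 0, shift2(mag, 1, 0), shift2(mag, -1, 0))
  pickd <- function(sr, sc) {
    out <- matrix(0, h, w)
    for (dr in c(-1L, 1L)) for (dc in c(-1L, 1L)) {
      sel <- sr == dr & sc == dc
      if (any(sel)) out[sel] <- shift2(mag, dr, dc)[sel]
    }
    out
  }
  horiz <- ax >= ay
  wgt <- ifelse(horiz, ifelse(ax > 0, ay / pmax(ax, .Machine$double.xmin), 0),
                       ax / pmax(ay, .Machine$double.xmin))
  diagA <- pickd(sy, sx); diagB <- pickd(-sy, -sx)
  nA <- ifelse(horiz, (1 - wgt) * pickx(sx) + wgt * diagA,
                      (1 - wgt) * picky(sy) + wgt * diagA)
  nB <- ifelse(horiz, (1 - wgt) * pickx(-sx) + wgt * diagB,
                      (1 - wgt) * picky(-sy) + wgt * diagB)
  nms <- mag > nA & mag >= nB & mag > 0 # strict on one side: 1-px ridge on ties
  strong <- nms & (mag >= high * mx)
  weak <- nms & (mag >= low * mx)
  if (!any(strong))
    return(binary_mask(matrix(FALSE, h, w)))
  lab <- label_components(binary_mask(weak), 8L)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0L]
  binary_mask(lab %in% keep & weak)
}

#' Per-row width profile of a silhouette
#'
#' For every image row, the width is the horizontal extent of the foreground:
#' `rightmost - leftmost column + 1`, or 0 where the row has no foreground.
#' The silhouette pixel height (`chv_px`, the CHV scale anchor) is the span
#' between the first and last foreground rows.
#'
#' Landmark rows are also expressible as normalised height-from-ground
#' fractions `h = (bottom_row - row) / (chv_px - 1)`, with row 1 at the top
#' of the image.
#'
#' @param mask a `binary_mask` (single silhouette).
#' @param view_angle_deg the view angle this silhouette was taken at
#'   (recorded in the profile; default 0).
#' @return An object of class `width_profile`: `view_angle_deg`,
#'   `row_widths_px` (one integer per image row), `top_row`, `bottom_row`
#'   (1-based) and `chv_px`.
#' @export
width_profile <- function(mask, view_angle_deg = 0) {
  m <- unclass_mask(binary_mask(mask))
  if (!any(m)) stop("width_profile: empty mask")
  widths <- integer(nrow(m))
  rows_fg <- which(rowSums(m) > 0L)
  for (r in rows_fg) {
    cols <- which(m[r, ])
    widths[r] <- cols[length(cols)] - cols[1L] + 1L
  }
  top <- rows_fg[1L]
  bottom <- rows_fg[length(rows_fg)]
  structure(list(view_angle_deg = view_angle_deg,
                 row_widths_px = widths,
                 top_row = top, bottom_row = bottom,
                 chv_px = bottom - top + 1L),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf("<width_profile> angle %g deg, chv %d px (rows %d..%d), max width %d px\n",
              x$view_angle_deg, x$chv_px, x$top_row, x$bottom_row,
              max(x$row_widths_px)))
  invisible(x)
}

#' Silhouette pixel height (CHV)
#'
#' @param mask a `binary_mask`.
#' @return Integer height in pixels: `bottom_row - top_row + 1`.
#' @export
silhouette_height_px <- function(mask) {
  m <- unclass_mask(binary_mask(mask))
  if (!any(m)) stop("silhouette_height_px: empty mask")
  rows_fg <- which(rowSums(m) > 0L)
  rows_fg[length(rows_fg)] - rows_fg[1L] + 1L
}

#' Write a width profile to CSV with a JSON sidecar
#'
#' The CSV has columns `row` (0-based, row 0 = top of image) and `width_px`;
#' the sidecar `<path>.json` records the view angle, `chv_px` and the
#' (0-based) top and bottom rows.
#'
#' @param profile a `width_profile`.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_width_profile <- function(profile, path) {
  df <- data.frame(row = seq_along(profile$row_widths_px) - 1L,
                   width_px = profile$row_widths_px)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(view_angle_deg = profile$view_angle_deg,
                            chv_px = profile$chv_px,
                            top_row = profile$top_row - 1L,
                            bottom_row = profile$bottom_row - 1L),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
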