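# From per-view width profiles to physical-unit girths: pixel-to-cm scaling
# anchored on the subject's known stature, row alignment across views,
# per-row perimeter estimation by both methods, and waist/hip landmark
# location.

#' Measurement configuration
#'
#' @param n_rows number of normalised body rows the views are resampled onto
#'   (default 500).
#' @param waist_band,hip_band normalised height-from-ground intervals searched
#'   for the waist (girth minimum; default 0.55-0.70) and the hip (girth
#'   maximum; default 0.42-0.55). Bands must lie in `[0, 1]`, must not
#'   overlap, and the waist band must sit above the hip band. The defaults
#'   follow standard anthropometric practice (natural waist above the iliac
#'   crest, hips at the widest gluteal level).
#' @param smooth_rows odd width of the running-mean window applied to the
#'   girth profile before landmark search; `NULL` (default) uses about 2% of
#'   `n_rows`. Smoothing suppresses pixel-quantisation jitter so that a
#'   single noisy row cannot capture the band extremum.
#' @param threshold segmentation threshold passed to [segment_foreground()]
#'   (`NULL` = Otsu).
#' @param canny list of Canny options (`sigma`, `low`, `high`) kept with the
#'   configuration for the inspectable edge stage.
#' @return An object of class `measure_config`.
#' @export
measure_config <- function(n_rows = 500L,
                           waist_band = c(0.55, 0.70),
                           hip_band = c(0.42, 0.55),
                           smooth_rows = NULL,
                           threshold = NULL,
                           canny = list(sigma = 2, low = 0.1, high = 0.3)) {
  n_rows <- as.integer(n_rows)
  if (n_rows < 2L) stop("measure_config: 'n_rows' must be at least 2")
  chk_band <- function(b, nm) {
    if (length(b) != 2L || anyNA(b) || b[1] < 0 || b[2] > 1 || b[1] >= b[2])
      stop("measure_config: '", nm, "' must be an interval within [0, 1]")
  }
  chk_band(waist_band, "waist_band")
  chk_band(hip_band, "hip_band")
  if (waist_band[1] < hip_band[2])
    stop("measure_config: bands overlap or are misordered; ",
         "the waist band must lie strictly above the hip band")
  if (!is.null(smooth_rows)) {
    smooth_rows <- as.integer(smooth_rows)
    if (smooth_rows < 1L || smooth_rows %% 2L == 0L)
      stop("measure_config: 'smooth_rows' must be a positive odd integer")
  }
  structure(list(n_rows = n_rows, waist_band = waist_band,
                 hip_band = hip_band, smooth_rows = smooth_rows,
                 threshold = threshold, canny = canny),
            class = "measure_config")
}

#' Convert a pixel measurement to centimetres
#'
#' Scale anchoring on known stature: a quantity of `value_px` pixels measured
#' on a silhouette of pixel height `chv_px` belonging to a subject of true
#' stature `ahv_cm` corresponds to `ahv_cm * value_px / chv_px` cm. Linear in
#' `value_px`.
#'
#' @param ahv_cm true subject stature in cm (positive).
#' @param value_px measured pixel quantity (non-negative; vectorised).
#' @param chv_px silhouette pixel height (>= 1).
#' @return Length(s) in cm.
#' @examples
#' px_to_cm(15, 100, 300) # 5
#' @export
px_to_cm <- function(ahv_cm, value_px, chv_px) {
  if (anyNA(ahv_cm) || any(ahv_cm <= 0)) stop("px_to_cm: 'ahv_cm' must be positive")
  if (anyNA(chv_px) || any(chv_px < 1)) stop("px_to_cm: 'chv_px' must be >= 1")
  if (anyNA(value_px) || any(value_px < 0)) stop("px_to_cm: 'value_px' must be non-negative")
  ahv_cm * value_px / chv_px
}

#' Bundle per-view width profiles with the subject's stature
#'
#' @param profiles list of [width_profile()] objects, either named by their
#'   angle in degrees or carrying `view_angle_deg`. Angles must form a
#'   uniform grid `0, step, ..., 180` with a step dividing 180 and at least 3
#'   views.
#' @param stature_cm the subject's true height (AHV), positive.
#' @return An object of class `view_set` (profiles sorted by angle).
#' @export
view_set <- function(profiles, stature_cm) {
  if (!is.numeric(stature_cm) || length(stature_cm) != 1L || stature_cm <= 0)
    stop("view_set: 'stature_cm' must be a positive scalar")
  angles <- vapply(profiles, function(p) as.numeric(p$view_angle_deg), numeric(1))
  ord <- order(angles)
  profiles <- profiles[ord]; angles <- angles[ord]
  if (length(angles) < 3L)
    stop("view_set: at least 3 views are required")
  if (anyDuplicated(angles))
    stop("view_set: duplicated view angles")
  step <- diff(angles)
  if (max(step) - min(step) > 1e-9)
    stop("view_set: view angles must be uniformly spaced")
  step <- step[1]
  if (abs(angles[1]) > 1e-9 || abs(angles[length(angles)] - 180) > 1e-9 ||
      abs(180 / step - round(180 / step)) > 1e-9)
    stop("view_set: angles must run from 0 to 180 with a step dividing 180")
  structure(list(profiles = profiles, angles_deg = angles,
                 step_deg = step, stature_cm = stature_cm),
            class = "view_set")
}

#' Align views onto a common normalised-height grid of half-widths
#'
#' Each view's widths are scaled to cm with [px_to_cm()] (anchored on that
#' view's own silhouette pixel height, since the apparent height may differ
#' slightly between views), halved into radii, and linearly interpolated from
#' the view's own foreground span onto `n_rows` height fractions running from
#' ground (`h = 0`) to head (`h = 1`).
#'
#' @param vs a [view_set()].
#' @param n_rows number of normalised rows (default 500).
#' @return An object of class `radial_matrix`: `half_widths_cm`
#'   (`n_rows x n_angles`), `height_frac`, `angles_deg`, `step_deg`,
#'   `stature_cm`.
#' @export
align_views <- function(vs, n_rows = 500L) {
  if (!inherits(vs, "view_set")) stop("align_views: expected a view_set")
  n_rows <- as.integer(n_rows)
  if (n_rows < 2L) stop("align_views: 'n_rows' must be at least 2")
  hgrid <- seq(0, 1, length.out = n_rows)
  cols <- lapply(vs$profiles, function(p) {
    rows <- p$top_row:p$bottom_row
    wid <- p$row_widths_px[rows]
    if (!any(wid > 0))
      stop("align_views: empty profile for view at ", p$view_angle_deg, " degrees")
    h <- (p$bottom_row - rows) / max(p$chv_px - 1L, 1L)
    half_cm <- px_to_cm(vs$stature_cm, wid, p$chv_px) / 2
    stats::approx(rev(h), rev(half_cm), xout = hgrid, rule = 2)$y
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("deg", vs$angles_deg)
  structure(list(half_widths_cm = m, height_frac = hgrid,
                 angles_deg = vs$angles_deg, step_deg = vs$step_deg,
                 stature_cm = vs$stature_cm),
            class = "radial_matrix")
}

#' Girth profiles by the cosine-polygon and ellipse methods
#'
#' Per normalised row, the cosine girth is the doubled half-perimeter of the
#' law-of-cosines polygon over that row's radial fan, and the ellipse girth
#' applies the `2*pi*sqrt((a^2+b^2)/2)` formula to the half-widths of the 0
#' and 90 degree views (which must be present).
#'
#' @param m a `radial_matrix` from [align_views()].
#' @return Data frame with columns `height_frac`, `girth_cosine_cm`,
#'   `girth_ellipse_cm`.
#' @export
girth_profile <- function(m) {
  if (!inherits(m, "radial_matrix")) stop("girth_profile: expected a radial_matrix")
  hw <- m$half_widths_cm
  k <- ncol(hw)
  sides <- 0
  for (j in seq_len(k - 1L))
    sides <- sides + cosine_side(hw[, j], hw[, j + 1L], m$step_deg)
  cosine <- 2 * sides
  i0 <- which(abs(m$angles_deg - 0) < 1e-9)
  i90 <- which(abs(m$angles_deg - 90) < 1e-9)
  if (!length(i0) || !length(i90))
    stop("girth_profile: the ellipse method requires the 0 and 90 degree views")
  ellipse <- ellipse_perimeter_value(hw[, i0], hw[, i90])
  data.frame(height_frac = m$height_frac,
             girth_cosine_cm = cosine,
             girth_ellipse_cm = ellipse)
}

# centred running mean with replicated edges
running_mean <- function(x, window) {
  if (window <= 1L) return(x)
  r <- (window - 1L) %/% 2L
  n <- length(x)
  xp <- c(rep(x[1], r), x, rep(x[n], r))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[(r + 1L):(r + n)]
}

default_smooth_rows <- function(n_rows) {
  w <- max(1L, as.integer(round(0.02 * n_rows)))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

#' Locate the waist and hip rows on a girth profile
#'
#' The waist is the row of minimum cosine girth within the waist band; the
#' hip is the row of maximum cosine girth within the hip band. The profile is
#' smoothed with a short running mean first (see [measure_config()]), and
#' ties are broken towards the band centre -- so a featureless profile (e.g.
#' a cylinder) lands on the band-centre row.
#'
#' @param profile data frame from [girth_profile()].
#' @param config a [measure_config()].
#' @return List with `waist_row_frac`, `hip_row_frac`, the corresponding row
#'   indices `waist_idx`, `hip_idx`, and the smoothed profile columns used.
#' @export
find_landmarks <- function(profile, config = measure_config()) {
  if (!nrow(profile)) stop("find_landmarks: empty profile")
  win <- if (is.null(config$smooth_rows)) default_smooth_rows(nrow(profile))
         else config$smooth_rows
  sc <- running_mean(profile$girth_cosine_cm, win)
  se <- running_mean(profile$girth_ellipse_cm, win)
  h <- profile$height_frac
  pick <- function(band, maximise) {
    idx <- which(h >= band[1] - 1e-12 & h <= band[2] + 1e-12)
    if (!length(idx)) stop("find_landmarks: band [", band[1], ", ", band[2],
                           "] contains no profile rows")
    v <- sc[idx]
    target <- if (maximise) max(v) else min(v)
    cand <- idx[abs(v - target) < 1e-12]
    centre <- mean(band)
    cand[which.min(abs(h[cand] - centre))]
  }
  wi <- pick(config$waist_band, maximise = FALSE)
  hi <- pick(config$hip_band, maximise = TRUE)
  list(waist_row_frac = h[wi], hip_row_frac = h[hi],
       waist_idx = wi, hip_idx = hi,
       smoothed_cosine = sc, smoothed_ellipse = se)
}

load_view_mask <- function(x, config) {
  if (inherits(x, "binary_mask") || is.logical(x))
    return(segment_foreground(binary_mask(x))) # clean: largest component + fill
  if (is.character(x)) x <- read_image(x)
  g <- to_gray(x)
  if (length(unique(round(as.numeric(g), 6))) <= 2L) # already binary: a mask
    return(segment_foreground(binary_mask(g > 0.5)))
  segment_foreground(g, threshold = config$threshold)
}

parse_view_inputs <- function(input, angles, stature_cm) {
  # returns list(items = list of paths/objects, angles, stature_cm)
  if (is.character(input) && length(input) == 1L) {
    manifest <- NULL
    if (dir.exists(input)) {
      mf <- file.path(input, "manifest.json")
      if (file.exists(mf)) manifest <- mf
      else {
        files <- list.files(input, pattern = "^view_[0-9]+\\.(png|pgm|pbm|jpg|jpeg)$",
                            full.names = TRUE)
        if (!length(files))
          stop("measure_subject [input]: no manifest.json or view_<angle> files in ", input)
        ang <- as.numeric(sub("^view_([0-9]+)\\..*$", "\\1", basename(files)))
        return(list(items = as.list(files[order(ang)]), angles = sort(ang),
                    stature_cm = stature_cm))
      }
    } else if (file.exists(input) && file_ext_lower(input) == "json") {
      manifest <- input
    } else stop("measure_subject [input]: '", input, "' is not a directory or manifest")
    mobj <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    base <- dirname(manifest)
    ang <- as.numeric(names(mobj$masks))
    paths <- file.path(base, unlist(mobj$masks))
    ord <- order(ang)
    return(list(items = as.list(paths[ord]), angles = ang[ord],
                stature_cm = if (is.null(stature_cm)) mobj$stature_cm else stature_cm))
  }
  if (is.list(input)) {
    if (is.null(angles)) angles <- as.numeric(names(input))
    if (is.null(angles) || anyNA(angles))
      stop("measure_subject [input]: view angles missing (name the list or pass 'angles')")
    ord <- order(angles)
    return(list(items = input[ord], angles = angles[ord], stature_cm = stature_cm))
  }
  stop("measure_subject [input]: unsupported input type")
}

#' Measure a subject from multi-angle silhouettes
#'
#' Full pipeline: load or accept each view (photograph or binary mask),
#' segment, extract per-row widths, scale to cm via the known stature, align
#' views onto a common normalised-height grid, compute per-row girths by the
#' cosine-polygon and ellipse methods, and locate the waist and hip
#' landmarks. Deterministic for fixed inputs and configuration.
#'
#' @param input one of: a directory containing `manifest.json` (as written by
#'   [make_fixture_set()]) or files named `view_<angle>.<ext>`; a manifest
#'   JSON path; or a list of images/masks (named by angle, or with `angles`
#'   given). Grayscale/colour images are segmented; two-level images are
#'   taken as masks directly.
#' @param angles view angles in degrees matching a list input.
#' @param stature_cm the subject's true stature (cm); may come from the
#'   manifest.
#' @param config a [measure_config()].
#' @return An object of class `body_measurements`: `stature_cm`,
#'   `angles_deg`, `profile` (the girth-profile data frame), `waist_cm` and
#'   `hip_cm` (each a list with `cosine` and `ellipse` circumferences, cm),
#'   `waist_row_frac`, `hip_row_frac`, and the `config` used.
#' @examples
#' spec <- phantom_preset("cylinder")
#' masks <- lapply(seq(0, 180, 30), function(a) render_view(spec, a, 20))
#' names(masks) <- seq(0, 180, 30)
#' m <- measure_subject(masks, stature_cm = 15)
#' m$waist_cm$cosine # close to 2*pi
#' @export
measure_subject <- function(input, angles = NULL, stature_cm = NULL,
                            config = measure_config()) {
  pv <- parse_view_inputs(input, angles, stature_cm)
  if (is.null(pv$stature_cm))
    stop("measure_subject [input]: 'stature_cm' is required")
  profiles <- Map(function(item, ang) {
    mask <- load_view_mask(item, config)
    width_profile(mask, view_angle_deg = ang)
  }, pv$items, pv$angles)
  vs <- view_set(profiles, pv$stature_cm)
  rm_ <- align_views(vs, config$n_rows)
  prof <- girth_profile(rm_)
  lm <- find_landmarks(prof, config)
  structure(list(
    stature_cm = pv$stature_cm,
    angles_deg = vs$angles_deg,
    profile = prof,
    waist_cm = list(cosine = lm$smoothed_cosine[lm$waist_idx],
                    ellipse = lm$smoothed_ellipse[lm$waist_idx]),
    hip_cm = list(cosine = lm$smoothed_cosine[lm$hip_idx],
                  ellipse = lm$smoothed_ellipse[lm$hip_idx]),
    waist_row_frac = lm$waist_row_frac,
    hip_row_frac = lm$hip_row_frac,
    config = config[c("n_rows", "waist_band", "hip_band", "smooth_rows")]
  ), class = "body_measurements")
}

#' @export
print.body_measurements <- function(x, ...) {
  cat(sprintf("<body_measurements> stature %.1f cm, %d views\n",
              x$stature_cm, length(x$angles_deg)))
  cat(sprintf("  waist (h = %.2f): cosine %.2f cm, ellipse %.2f cm\n",
              x$waist_row_frac, x$waist_cm$cosine, x$waist_cm$ellipse))
  cat(sprintf("  hip   (h = %.2f): cosine %.2f cm, ellipse %.2f cm\n",
              x$hip_row_frac, x$hip_cm$cosine, x$hip_cm$ellipse))
  invisible(x)
}

#' Write / read body measurements as JSON
#'
#' The JSON stores the landmark circumferences, landmark heights, stature,
#' angles and configuration at full precision (the per-row girth profile goes
#' to CSV via [write_girth_profile()]).
#'
#' @param bm a `body_measurements`.
#' @param path JSON path.
#' @return `write_measurements` invisibly returns `path`;
#'   `read_measurements` returns a `body_measurements` (without the profile).
#' @export
write_measurements <- function(bm, path) {
  obj <- bm[c("stature_cm", "angles_deg", "waist_cm", "hip_cm",
              "waist_row_frac", "hip_row_frac", "config")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$config <- as.list(obj$config)
  obj$waist_cm <- as.list(obj$waist_cm)
  obj$hip_cm <- as.list(obj$hip_cm)
  structure(obj, class = "body_measurements")
}

#' Write the per-row girth profile as CSV
#'
#' Columns: `height_frac`, `girth_cosine_cm`, `girth_ellipse_cm`.
#'
#' @param bm a `body_measurements`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_girth_profile <- function(bm, path) {
  utils::write.csv(bm$profile, path, row.names = FALSE)
  invisible(path)
}
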