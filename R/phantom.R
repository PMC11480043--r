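# Parametric body phantoms. A phantom is a stack of superellipse
# cross-sections |x/a|^p + |y/b|^p = 1 whose parameters (a, b, p) are linearly
# interpolated between named height levels (h = 0 ground, h = 1 head). The
# family is convex for p >= 1, has a closed-form projected ("support")
# half-width at every view angle, and an arc length computable to high
# accuracy by quadrature -- so every rendered silhouette comes with exact
# ground truth.

#' Exact perimeter of a superellipse
#'
#' Arc length of `|x/a|^p + |y/b|^p = 1` by adaptive quadrature on the
#' parametrisation `x = a*cos(t)^(2/p)`, `y = b*sin(t)^(2/p)`. The integrand
#' has integrable endpoint singularities for `p > 2`; the substitution
#' `t = s^(p/2)` (applied symmetrically at both ends, in log space) removes
#' them, so the quadrature stays accurate up to the square limit
#' (p of several hundred).
#'
#' @param a,b positive semi-axes.
#' @param p superellipse exponent, `p >= 1` (2 = ellipse, large = rectangle).
#' @param rel.tol relative tolerance of the quadrature (default 1e-9).
#' @return Perimeter in the unit of `a` and `b`.
#' @examples
#' superellipse_perimeter(1, 1, 2) # 2*pi
#' @export
superellipse_perimeter <- function(a, b, p, rel.tol = 1e-9) {
  if (a <= 0 || b <= 0) stop("superellipse_perimeter: 'a' and 'b' must be positive")
  if (p < 1) stop("superellipse_perimeter: 'p' must be >= 1 (convex)")
  k <- p / 2
  e <- 2 / p - 1
  gfun <- function(s, swap) {
    vapply(s, function(si) {
      if (si <= 0) si <- .Machine$double.xmin
      ls <- log(si)
      t <- exp(k * ls)
      tt <- if (swap) pi / 2 - t else t
      ct <- cos(tt); st <- sin(tt)
      # the factor that vanishes at the endpoint, kept in log space
      near <- if (swap) abs(ct) else abs(st)
      lognear <- if (t < 1e-8) k * ls else log(near)
      coef <- (if (swap) a else b) * (2 / p) * (if (swap) abs(st) else abs(ct))
      sing <- coef * exp(e * lognear + (k - 1) * ls)
      reg <- (if (swap) b else a) * (2 / p) *
        (if (swap) abs(st) else abs(ct))^e * near * exp((k - 1) * ls)
      k * sqrt(sing^2 + reg^2)
    }, numeric(1))
  }
  up <- (pi / 4)^(1 / k)
  4 * (stats::integrate(function(s) gfun(s, FALSE), 0, up, rel.tol = rel.tol)$value +
       stats::integrate(function(s) gfun(s, TRUE), 0, up, rel.tol = rel.tol)$value)
}

#' Projected half-width of a superellipse
#'
#' Half the width of the shadow of `|x/a|^p + |y/b|^p = 1` when viewed from
#' angle `theta`: the support function in the direction perpendicular to the
#' view, which for the superellipse is the dual-norm expression
#' `(|a cos(theta)|^q + |b sin(theta)|^q)^(1/q)` with `1/p + 1/q = 1`.
#' For `p = 2` this is the familiar `sqrt(a^2 cos^2 + b^2 sin^2)`.
#'
#' @param a,b positive semi-axes.
#' @param p exponent `>= 1` (`p = 1` uses the max-norm limit).
#' @param theta_rad view angle(s) in radians (vectorised).
#' @return Half-width(s), same unit as `a`, `b`.
#' @export
superellipse_support <- function(a, b, p, theta_rad) {
  n <- max(length(a), length(b), length(p), length(theta_rad))
  a <- rep_len(a, n); b <- rep_len(b, n)
  p <- rep_len(p, n); theta_rad <- rep_len(theta_rad, n)
  x <- abs(a * cos(theta_rad))
  y <- abs(b * sin(theta_rad))
  q <- ifelse(p > 1, p / (p - 1), Inf)
  out <- pmax(x, y) # the p = 1 (dual max-norm) limit
  fin <- is.finite(q)
  out[fin] <- (x[fin]^q[fin] + y[fin]^q[fin])^(1 / q[fin])
  out
}

#' Define a body phantom
#'
#' @param stature_cm total phantom height in cm (default 15, the scale of a
#'   1/16 desk model; any positive value works since the pipeline is
#'   scale-anchored by stature).
#' @param levels data frame with columns `h` (height fraction, strictly
#'   increasing from 0 to 1), `a`, `b` (positive semi-axes, cm) and `p`
#'   (exponent `>= 1`). Cross-sections between levels are linearly
#'   interpolated in all three parameters.
#' @param name optional label.
#' @return An object of class `phantom_spec`.
#' @seealso [phantom_preset()] for ready-made shapes.
#' @export
phantom_spec <- function(stature_cm, levels, name = "custom") {
  if (!is.numeric(stature_cm) || length(stature_cm) != 1L || stature_cm <= 0)
    stop("phantom_spec: 'stature_cm' must be a positive scalar")
  levels <- as.data.frame(levels)
  need <- c("h", "a", "b", "p")
  if (!all(need %in% names(levels)))
    stop("phantom_spec: 'levels' needs columns h, a, b, p")
  levels <- levels[order(levels$h), need]
  if (nrow(levels) < 2L || any(diff(levels$h) <= 0))
    stop("phantom_spec: level heights must be strictly increasing")
  if (abs(levels$h[1]) > 1e-9 || abs(levels$h[nrow(levels)] - 1) > 1e-9)
    stop("phantom_spec: levels must span h = 0 to h = 1")
  if (any(levels$a <= 0) || any(levels$b <= 0))
    stop("phantom_spec: semi-axes must be positive")
  if (any(levels$p < 1))
    stop("phantom_spec: exponents must be >= 1 (convex sections)")
  structure(list(stature_cm = stature_cm, levels = levels, name = name),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> '%s', stature %.4g cm, %d levels, max half-width %.3g cm\n",
              x$name, x$stature_cm, nrow(x$levels), max(x$levels$a, x$levels$b)))
  invisible(x)
}

# interpolated (a, b, p) at height fractions h
level_at <- function(spec, h) {
  if (any(h < -1e-9) || any(h > 1 + 1e-9))
    stop("phantom level: height fraction must lie in [0, 1]")
  h <- pmin(pmax(h, 0), 1)
  lv <- spec$levels
  list(a = stats::approx(lv$h, lv$a, h, rule = 2)$y,
       b = stats::approx(lv$h, lv$b, h, rule = 2)$y,
       p = stats::approx(lv$h, lv$p, h, rule = 2)$y)
}

#' Built-in phantom presets
#'
#' * `cylinder`: circular cylinder, radius 1 cm -- every girth is `2*pi`.
#' * `elliptic`: elliptic cylinder with semi-axes 1.2 x 0.8 cm (aspect 1.5).
#' * `hourglass`: a torso-like phantom with a designed hip bulge at height
#'   fraction 0.50 and a designed waist minimum at 0.60, plus legs, shoulders
#'   and a head.
#' * `thin` / `overweight`: the hourglass with all torso levels (height
#'   fractions 0.40-0.88) rescaled so that the designed waist girths are
#'   4.7 cm and 6.0 cm -- a matched pair differing only by the torso scale
#'   factor, with a designed waist difference of 1.3 cm.
#'
#' All presets default to 15 cm stature, the size of a 1/16-scale desk model.
#'
#' @param name one of `"cylinder"`, `"elliptic"`, `"hourglass"`, `"thin"`,
#'   `"overweight"`.
#' @param stature_cm phantom height (default 15).
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(name = c("cylinder", "elliptic", "hourglass",
                                    "thin", "overweight"),
                           stature_cm = 15) {
  name <- match.arg(name)
  hourglass_levels <- data.frame(
    h = c(0.00, 0.40, 0.50, 0.60, 0.75, 0.88, 0.92, 1.00),
    a = c(0.50, 0.95, 1.30, 0.90, 1.10, 1.15, 0.50, 0.55),
    b = c(0.40, 0.70, 0.95, 0.68, 0.80, 0.82, 0.45, 0.50),
    p = 2
  )
  torso <- hourglass_levels$h >= 0.40 & hourglass_levels$h <= 0.88
  scaled_hourglass <- function(waist_girth_cm) {
    base_waist <- superellipse_perimeter(0.90, 0.68, 2)
    k <- waist_girth_cm / base_waist
    lv <- hourglass_levels
    lv$a[torso] <- lv$a[torso] * k
    lv$b[torso] <- lv$b[torso] * k
    lv
  }
  lv <- switch(name,
    cylinder = data.frame(h = c(0, 1), a = 1, b = 1, p = 2),
    elliptic = data.frame(h = c(0, 1), a = 1.2, b = 0.8, p = 2),
    hourglass = hourglass_levels,
    thin = scaled_hourglass(4.7),
    overweight = scaled_hourglass(6.0)
  )
  phantom_spec(stature_cm, lv, name = name)
}

#' True cross-section girth of a phantom
#'
#' Exact perimeter of the interpolated superellipse section at height
#' fraction `h`, by adaptive quadrature (relative tolerance 1e-8). This is
#' the ground-truth oracle the measured girths are validated against.
#'
#' @param spec a `phantom_spec`.
#' @param h height fraction(s) in `[0, 1]` (vectorised).
#' @return Girth(s) in cm.
#' @export
true_girth <- function(spec, h) {
  lv <- level_at(spec, h)
  vapply(seq_along(lv$a), function(i)
    superellipse_perimeter(lv$a[i], lv$b[i], lv$p[i], rel.tol = 1e-8),
    numeric(1))
}

#' Analytic projected half-width of a phantom section
#'
#' The exact counterpart of a measured half-width: half the silhouette width
#' of the section at height fraction `h` seen from `angle_deg`.
#'
#' @param spec a `phantom_spec`.
#' @param h height fraction in `[0, 1]`.
#' @param angle_deg view angle(s) in degrees (vectorised).
#' @return Half-width(s) in cm.
#' @export
support_half_width <- function(spec, h, angle_deg) {
  if (length(h) != 1L) stop("support_half_width: 'h' must be a scalar")
  lv <- level_at(spec, h)
  superellipse_support(lv$a, lv$b, lv$p, angle_deg * pi / 180)
}

#' Render a phantom silhouette at a view angle
#'
#' Produces the binary silhouette an ideal camera would see: per image row,
#' the foreground run is `round(2 * half_width * px_per_cm)` pixels, centred.
#' Orthographic projection uses the support half-width directly; the pinhole
#' mode scales each row's half-width by the tangent-ray magnification
#' `d / sqrt(d^2 - w^2)` for a camera at distance `d` from the body axis
#' (closer cameras see strictly wider silhouettes). No perspective
#' correction exists in the measurement path, so pinhole renders let the
#' distance effect be studied, not removed. Deterministic.
#'
#' @param spec a `phantom_spec`.
#' @param angle_deg view angle in degrees.
#' @param px_per_cm rendering scale; the phantom must come out at least 20 px
#'   tall.
#' @param projection `"orthographic"` (default) or `"pinhole"`.
#' @param dist_cm camera distance for pinhole projection; must exceed the
#'   largest half-width.
#' @param margin_px background margin around the silhouette (default 8).
#' @return A `binary_mask`.
#' @export
render_view <- function(spec, angle_deg, px_per_cm,
                        projection = c("orthographic", "pinhole"),
                        dist_cm = NULL, margin_px = 8L) {
  projection <- match.arg(projection)
  if (px_per_cm <= 0) stop("render_view: 'px_per_cm' must be positive")
  chv <- round(spec$stature_cm * px_per_cm)
  if (chv < 20) stop("render_view: insufficient resolution ",
                     "(stature below 20 px; increase px_per_cm)")
  hfrac <- (chv - seq_len(chv)) / (chv - 1) # row 1 = head end of the body box
  lv <- level_at(spec, hfrac)
  w <- superellipse_support(lv$a, lv$b, lv$p, angle_deg * pi / 180)
  if (projection == "pinhole") {
    if (is.null(dist_cm)) stop("render_view: pinhole projection needs 'dist_cm'")
    if (dist_cm <= max(w)) stop("render_view: 'dist_cm' must exceed the ",
                                "largest body half-width")
    w <- w * dist_cm / sqrt(dist_cm^2 - w^2)
  }
  wpx <- as.integer(round(2 * w * px_per_cm))
  width <- max(wpx) + 2L * margin_px
  height <- chv + 2L * margin_px
  m <- matrix(FALSE, height, width)
  cx <- ceiling(width / 2)
  for (i in seq_len(chv)) {
    if (wpx[i] < 1L) next
    left <- cx - wpx[i] %/% 2L
    m[margin_px + i, left:(left + wpx[i] - 1L)] <- TRUE
  }
  binary_mask(m)
}

#' Render a phantom view as a grayscale photograph
#'
#' Dark subject on a light background, optionally degraded with Gaussian
#' pixel noise -- the input [segment_foreground()] expects.
#'
#' @inheritParams render_view
#' @param fg,bg foreground / background intensities in `[0, 1]`
#'   (defaults 0.15 and 0.95).
#' @param noise_sd standard deviation of additive Gaussian noise (0 = none);
#'   seed the RNG for reproducibility. Intensities are clipped to `[0, 1]`.
#' @return A numeric matrix in `[0, 1]`.
#' @export
render_photo <- function(spec, angle_deg, px_per_cm, fg = 0.15, bg = 0.95,
                         noise_sd = 0, ...) {
  mask <- render_view(spec, angle_deg, px_per_cm, ...)
  g <- matrix(bg, nrow(mask), ncol(mask))
  g[unclass_mask(mask)] <- fg
  if (noise_sd > 0)
    g <- pmin(pmax(g + stats::rnorm(length(g), 0, noise_sd), 0), 1)
  g
}

#' Ground-truth table for a phantom
#'
#' True girths and projected half-widths on a grid of height fractions --
#' the oracle against which measured girth profiles are scored.
#'
#' @param spec a `phantom_spec`.
#' @param height_fracs grid of height fractions (default every 0.02).
#' @param angles_deg view angles whose half-widths to tabulate
#'   (default 0 to 180 by 30).
#' @return Data frame: `height_frac`, `girth_cm`, then one
#'   `halfwidth_<angle>_cm` column per angle.
#' @export
truth_table <- function(spec, height_fracs = seq(0, 1, by = 0.02),
                        angles_deg = seq(0, 180, by = 30)) {
  out <- data.frame(height_frac = height_fracs,
                    girth_cm = true_girth(spec, height_fracs))
  for (ang in angles_deg)
    out[[sprintf("halfwidth_%g_cm", ang)]] <-
      vapply(height_fracs, function(h) support_half_width(spec, h, ang),
             numeric(1))
  out
}

#' Write a complete measurement fixture set for a phantom
#'
#' Renders silhouette masks at the requested angles, optionally corrupts
#' them with seeded salt-and-pepper pixel flips, and writes everything a
#' measurement run needs: the mask files (`view_<angle>.pgm` or `.png`), a
#' `manifest.json` (stature, scale, angle-to-file map) consumable by
#' [measure_subject()], and a `truth.csv` ground-truth table. Outputs are
#' byte-identical for identical inputs and seed.
#'
#' @param spec a `phantom_spec`.
#' @param angles_deg view angles (default 0 to 180 by 30).
#' @param px_per_cm rendering scale (default 20).
#' @param out_dir output directory (created if missing).
#' @param seed RNG seed for the noise (default 42; only consulted when
#'   `noise > 0`).
#' @param noise per-pixel flip probability in `[0, 1)` (default 0, clean
#'   masks).
#' @param format `"pgm"` (plain text, default) or `"png"`.
#' @param ... passed to [render_view()] (e.g. `projection`, `dist_cm`).
#' @return Invisibly, a list with `manifest` (path), `truth` (path) and
#'   `masks` (named vector of mask paths).
#' @export
make_fixture_set <- function(spec, angles_deg = seq(0, 180, by = 30),
                             px_per_cm = 20, out_dir, seed = 42L, noise = 0,
                             format = c("pgm", "png"), ...) {
  format <- match.arg(format)
  if (noise < 0 || noise >= 1) stop("make_fixture_set: 'noise' must be in [0, 1)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (noise > 0) set.seed(seed)
  paths <- character(0)
  for (ang in angles_deg) {
    mask <- render_view(spec, ang, px_per_cm, ...)
    if (noise > 0) {
      m <- unclass_mask(mask)
      flip <- stats::runif(length(m)) < noise
      mask <- binary_mask(xor(m, matrix(flip, nrow(m), ncol(m))))
    }
    fn <- file.path(out_dir, sprintf("view_%03d.%s", as.integer(ang), format))
    write_mask(mask, fn)
    paths[as.character(ang)] <- fn
  }
  truth <- truth_table(spec, angles_deg = angles_deg)
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE)
  manifest <- list(stature_cm = spec$stature_cm,
                   px_per_cm = px_per_cm,
                   phantom = spec$name,
                   angles_deg = as.numeric(angles_deg),
                   masks = as.list(basename(paths)),
                   truth = basename(truth_path))
  names(manifest$masks) <- names(paths)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest_path, truth = truth_path, masks = paths))
}

#' Read a phantom specification from YAML or JSON
#'
#' The file either names a preset (`preset: hourglass`, optional
#' `stature_cm`) or gives `stature_cm` plus a `levels` table with fields
#' `h`, `a`, `b`, `p`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  ext <- file_ext_lower(path)
  obj <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("read_phantom_spec: expected a .yaml/.yml or .json file")
  )
  if (!is.null(obj$preset))
    return(phantom_preset(obj$preset,
                          stature_cm = if (is.null(obj$stature_cm)) 15
                                       else obj$stature_cm))
  if (is.null(obj$stature_cm) || is.null(obj$levels))
    stop("read_phantom_spec: need 'preset' or both 'stature_cm' and 'levels'")
  lv <- obj$levels
  if (!is.data.frame(lv)) {
    if (all(c("h", "a", "b", "p") %in% names(lv))) {
      lv <- as.data.frame(lv) # column-wise (YAML) layout
    } else {
      lv <- do.call(rbind.data.frame, lv) # row-wise list layout
    }
  }
  phantom_spec(obj$stature_cm, lv,
               name = if (is.null(obj$name)) "custom" else obj$name)
}

#' Write a phantom specification to YAML or JSON
#'
#' @param spec a `phantom_spec`.
#' @param path output `.yaml`/`.yml` or `.json` path.
#' @return Invisibly, `path`.
#' @export
write_phantom_spec <- function(spec, path) {
  obj <- list(name = spec$name, stature_cm = spec$stature_cm,
              levels = spec$levels)
  ext <- file_ext_lower(path)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path)
  } else if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  } else stop("write_phantom_spec: expected a .yaml/.yml or .json path")
  invisible(path)
}
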