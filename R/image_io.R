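# Image reading/writing.
#
# Photographs: PNG and JPEG via the png/jpeg packages; portable anymaps
# (PGM/PPM/PBM, ASCII or binary) via a small built-in parser so that test
# fixtures can be committed as plain text. TIFF is not supported (no reader
# in the dependency set).

file_ext_lower <- function(path) tolower(sub(".*\\.", "", basename(path)))

#' Read an image file
#'
#' Reads PNG, JPEG or portable anymap (PBM/PGM/PPM, magic P1-P3/P5-P6)
#' images. Intensities are returned in `[0, 1]`.
#'
#' @param path file path; format is chosen by extension
#'   (`png`, `jpg`/`jpeg`, `pbm`/`pgm`/`ppm`/`pnm`).
#' @return A numeric matrix (grayscale) or an `height x width x 3` array
#'   (colour; any alpha channel is dropped).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  ext <- file_ext_lower(path)
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    pbm = ,
    pgm = ,
    ppm = ,
    pnm = read_pnm(path),
    tif = ,
    tiff = stop("read_image: TIFF is not supported; convert to PNG or PGM"),
    stop("read_image: unrecognised image extension '", ext, "'")
  )
  if (length(dim(img)) == 3 && dim(img)[3] == 2) img <- img[, , 1] # gray+alpha
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' Convert an image to grayscale luminance
#'
#' Rec. 601 luma weights (0.299, 0.587, 0.114). Grayscale input is returned
#' unchanged.
#'
#' @param img matrix or `H x W x 3` array with intensities in `[0, 1]`.
#' @return A numeric matrix in `[0, 1]`.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3)
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  stop("to_gray: expected a matrix or H x W x 3 array")
}

#' Read a binary silhouette mask
#'
#' Masks are stored as 8-bit grayscale images with 0 = background and
#' 255 = foreground; any pixel above half intensity is taken as foreground.
#'
#' @param path PNG or PGM/PBM file path.
#' @return A `binary_mask` (logical matrix, TRUE = foreground).
#' @export
read_mask <- function(path) {
  g <- to_gray(read_image(path))
  binary_mask(g > 0.5)
}

#' Write a binary silhouette mask
#'
#' @param mask a `binary_mask` or logical matrix.
#' @param path output path; `.png` writes 8-bit PNG, `.pgm` writes an ASCII
#'   (P2) portable graymap, which is a plain-text file.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  m <- unclass_mask(mask)
  ext <- file_ext_lower(path)
  if (ext == "png") {
    png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  } else if (ext == "pgm") {
    write_pnm_ascii(matrix(ifelse(m, 255L, 0L), nrow(m), ncol(m)), path, maxval = 255L)
  } else {
    stop("write_mask: unsupported extension '", ext, "' (use .png or .pgm)")
  }
  invisible(path)
}

# ---- portable anymap (Netpbm) ----

read_pnm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  # tokenizer over the header: whitespace-separated, '#' starts a comment
  pos <- 1L
  next_token <- function() {
    tok <- character(0)
    while (pos <= length(raw)) {
      ch <- rawToChar(raw[pos])
      if (ch == "#") {
        while (pos <= length(raw) && rawToChar(raw[pos]) != "\n") pos <<- pos + 1L
      } else if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break
        pos <<- pos + 1L
      } else {
        tok <- c(tok, ch)
        pos <<- pos + 1L
      }
    }
    paste(tok, collapse = "")
  }
  magic <- next_token()
  if (!magic %in% c("P1", "P2", "P3", "P5", "P6"))
    stop("read_pnm: unsupported magic '", magic, "'")
  w <- as.integer(next_token())
  h <- as.integer(next_token())
  maxval <- if (magic == "P1") 1L else as.integer(next_token())
  if (is.na(w) || is.na(h) || w < 1 || h < 1 || is.na(maxval) || maxval < 1)
    stop("read_pnm: malformed header")
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L # single whitespace byte after maxval
    if (maxval > 255) stop("read_pnm: 16-bit binary maps are not supported")
    vals <- as.integer(raw[pos:(pos + n - 1L)])
  } else {
    txt <- rawToChar(raw[pos:length(raw)])
    txt <- gsub("#[^\n]*", " ", txt)
    vals <- as.integer(scan(text = txt, what = integer(), n = n, quiet = TRUE))
  }
  if (length(vals) < n) stop("read_pnm: truncated pixel data")
  if (magic == "P1") vals <- 1L - vals # PBM: 1 = black; map to intensity
  x <- vals / maxval
  if (nch == 1L) {
    matrix(x, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, c(h, w, 3))
    for (k in 1:3)
      a[, , k] <- matrix(x[seq(k, n, by = 3)], nrow = h, ncol = w, byrow = TRUE)
    a
  }
}

write_pnm_ascii <- function(m, path, maxval = 255L) {
  stopifnot(is.matrix(m))
  con <- file(path, "wb") # write LF line endings regardless of platform
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  apply(m, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
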