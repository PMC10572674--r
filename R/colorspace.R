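#' Load an 8-bit RGB image
#'
#' Reads a PNG or JPEG file into an `H x W x 3` integer array with values in
#' `[0, 255]`. Grayscale sources are replicated to three identical channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An integer array of dimension `H x W x 3` (class `dermtex_image`
#'   attribute is not attached; any such array is a valid image).
#' @examples
#' img <- make_lesion_image(lesion_fixture_spec(seed = 1), class_id = 0, index = 1)
#' f <- tempfile(fileext = ".png")
#' write_image_png(img, f)
#' identical(load_image(f), img)
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    stop_dermtex(paste0("image file not found: ", path), "dermtex_input_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      # fall back on content sniffing for extension-less files
      tryCatch(png::readPNG(path), error = function(e) jpeg::readJPEG(path))
    ),
    error = function(e) {
      stop_dermtex(paste0("cannot decode image: ", path, " (", conditionMessage(e), ")"),
                   "dermtex_format_error")
    }
  )
  if (length(dim(raw)) == 2) {
    raw <- array(raw, dim = c(dim(raw), 3)) # grayscale -> replicate
  } else if (dim(raw)[3] >= 3) {
    raw <- raw[, , 1:3, drop = FALSE] # drop alpha
  } else if (dim(raw)[3] == 1) {
    raw <- array(raw[, , 1], dim = c(dim(raw)[1:2], 3))
  } else {
    stop_dermtex("unsupported channel count", "dermtex_format_error")
  }
  if (any(dim(raw)[1:2] < 3)) {
    stop_dermtex("image smaller than 3x3", "dermtex_size_error")
  }
  img <- round_clip_255(raw * 255)
  storage.mode(img) <- "integer"
  img
}

#' Write an image array as PNG
#'
#' @param img `H x W x 3` integer array in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  check_image(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

check_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop_dermtex("image must be an H x W x 3 array", "dermtex_input_error")
  }
  if (any(dim(img)[1:2] < 3)) {
    stop_dermtex("image smaller than 3x3", "dermtex_size_error")
  }
  if (min(img) < 0 || max(img) > 255) {
    stop_dermtex("image values must lie in [0, 255]", "dermtex_input_error")
  }
  invisible(img)
}

#' Color spaces understood by the pipeline
#' @return Character vector of identifiers.
#' @export
color_spaces <- function() c("GRAY", "LAB", "HSV", "YCBCR")

#' Convert an RGB image to channel planes of a color space
#'
#' Decomposes an 8-bit RGB image into the scalar channel planes that the
#' descriptors consume. All planes are integer matrices in `[0, 255]` with
#' the same height/width as the input; rounding is half-away-from-zero.
#'
#' Conventions (the source data are 8-bit sRGB):
#' \itemize{
#'   \item `GRAY`: one plane, BT.601 luma `0.299 R + 0.587 G + 0.114 B`.
#'   \item `YCBCR`: full-range BT.601 `Y`, `Cb`, `Cr` (chroma offset +128).
#'   \item `HSV`: hue rescaled from `[0, 360)` degrees to `[0, 255]`;
#'     saturation and value rescaled from `[0, 1]` to `[0, 255]`. Hue is
#'     treated as an ordinary scalar plane even though it is circular.
#'   \item `LAB`: sRGB (D65) to CIE L*a*b*; `L*` scaled by `255/100`,
#'     `a*` and `b*` offset by `+128`.
#' }
#'
#' @param img `H x W x 3` integer array in `[0, 255]`.
#' @param space One of `"GRAY"`, `"LAB"`, `"HSV"`, `"YCBCR"`.
#' @return Named list of integer matrices: 1 plane for `GRAY`, 3 otherwise,
#'   in fixed channel order (`L,A,B` / `H,S,V` / `Y,Cb,Cr`).
#' @examples
#' img <- array(200L, dim = c(4, 4, 3))
#' pl <- to_planes(img, "YCBCR")
#' stopifnot(all(pl$Y == 200), all(pl$Cb == 128), all(pl$Cr == 128))
#' @export
to_planes <- function(img, space) {
  check_image(img)
  if (!is.character(space) || length(space) != 1 || !(space %in% color_spaces())) {
    stop_dermtex(paste0("unknown color space: ", paste(space, collapse = ",")),
                 "dermtex_config_error")
  }
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  storage.mode(R) <- "double"; storage.mode(G) <- "double"; storage.mode(B) <- "double"
  out <- switch(space,
    GRAY = list(GRAY = 0.299 * R + 0.587 * G + 0.114 * B),
    YCBCR = list(
      Y  = 0.299 * R + 0.587 * G + 0.114 * B,
      Cb = 128 - 0.168736 * R - 0.331264 * G + 0.5 * B,
      Cr = 128 + 0.5 * R - 0.418688 * G - 0.081312 * B
    ),
    HSV = rgb_to_hsv_planes(R, G, B),
    LAB = rgb_to_lab_planes(R, G, B)
  )
  lapply(out, function(p) {
    p <- round_clip_255(p)
    storage.mode(p) <- "integer"
    p
  })
}

rgb_to_hsv_planes <- function(R, G, B) {
  mx <- pmax(R, G, B)
  mn <- pmin(R, G, B)
  d <- mx - mn
  h <- matrix(0, nrow(R), ncol(R))
  nz <- d > 0
  r_is <- nz & (mx == R)
  g_is <- nz & (mx == G) & !r_is
  b_is <- nz & (mx == B) & !r_is & !g_is
  h[r_is] <- ((G[r_is] - B[r_is]) / d[r_is]) %% 6
  h[g_is] <- (B[g_is] - R[g_is]) / d[g_is] + 2
  h[b_is] <- (R[b_is] - G[b_is]) / d[b_is] + 4
  h <- h * 60 # degrees in [0, 360)
  s <- matrix(0, nrow(R), ncol(R))
  pos <- mx > 0
  s[pos] <- d[pos] / mx[pos]
  list(H = h * 255 / 360, S = s * 255, V = mx)
}

rgb_to_lab_planes <- function(R, G, B) {
  lin <- function(c) {
    c <- c / 255
    ifelse(c <= 0.04045, c / 12.92, ((c + 0.055) / 1.055)^2.4)
  }
  r <- lin(R); g <- lin(G); b <- lin(B)
  # sRGB D65 reference primaries
  X <- 0.4124564 * r + 0.3575761 * g + 0.1804375 * b
  Y <- 0.2126729 * r + 0.7151522 * g + 0.0721750 * b
  Z <- 0.0193339 * r + 0.1191920 * g + 0.9503041 * b
  Xn <- 0.95047; Yn <- 1; Zn <- 1.08883
  eps <- 216 / 24389; kap <- 24389 / 27
  f <- function(t) ifelse(t > eps, t^(1 / 3), (kap * t + 16) / 116)
  fx <- f(X / Xn); fy <- f(Y / Yn); fz <- f(Z / Zn)
  Lst <- 116 * fy - 16
  ast <- 500 * (fx - fy)
  bst <- 200 * (fy - fz)
  list(L = Lst * 255 / 100, A = ast + 128, B = bst + 128)
}
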