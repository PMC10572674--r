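# Deterministic synthetic lesion-image generator. Each image is a
# skin-toned background plus a textured elliptical "lesion" whose color
# distribution, border irregularity and sinusoidal texture frequency are
# class-dependent, with additive Gaussian pixel noise. The class signal is
# placed dominantly in color (class mean colors are far apart in RGB but
# close in luma, and one class carries a chroma-only texture component that
# cancels under the BT.601 luma weights) plus a texture-frequency
# difference, so that per-channel color features genuinely carry more
# information than the grayscale pathway.

#' Specification of a synthetic lesion-image set
#'
#' @param n_classes 2 (benign/malignant-style) or 7 (multi-category style).
#' @param counts Per-class image counts; a single number is recycled.
#'   Unequal counts produce an imbalanced set for exercising SMOTE.
#' @param size Image side in pixels. Defaults to 224 for 2 classes and 28
#'   for 7 classes, the two resolutions the pipeline targets.
#' @param noise_sd Additive Gaussian pixel noise, gray-levels (default 8).
#' @param seed Integer seed; together with `(class_id, index)` it fully
#'   determines every image.
#' @return List of class `dermtex_fixture_spec` with a `class_params`
#'   tibble (mean RGB, texture frequency/amplitude, chroma texture
#'   amplitude, border irregularity).
#' @export
lesion_fixture_spec <- function(n_classes = 2L, counts = 100L, size = NULL,
                                noise_sd = 8, seed = 42L) {
  if (!(n_classes %in% c(2L, 7L))) {
    stop_dermtex("n_classes must be 2 or 7", "dermtex_config_error")
  }
  size <- as.integer(size %||% if (n_classes == 2L) 224L else 28L)
  if (size < 16L) stop_dermtex("size must be >= 16", "dermtex_config_error")
  counts <- as.integer(rep(counts, length.out = n_classes))
  if (any(counts < 1L)) stop_dermtex("per-class count must be >= 1", "dermtex_config_error")
  params2 <- tibble::tibble(
    class_id = 0:1,
    r = c(135, 40), g = c(95, 120), b = c(80, 160),
    tex_freq = c(0.08, 0.24), tex_amp = c(14, 14),
    chroma_amp = c(8, 16), irregularity = c(0.05, 0.15)
  )
  params7 <- tibble::tibble(
    class_id = 0:6,
    r = c(135, 60, 180, 90, 40, 200, 120),
    g = c(95, 60, 120, 140, 120, 80, 40),
    b = c(80, 120, 60, 60, 160, 160, 140),
    tex_freq = c(0.08, 0.12, 0.16, 0.20, 0.24, 0.28, 0.32),
    tex_amp = rep(14, 7),
    chroma_amp = rep(10, 7),
    irregularity = c(0.04, 0.07, 0.10, 0.13, 0.16, 0.10, 0.07)
  )
  spec <- list(
    n_classes = n_classes, counts = counts, size = size,
    noise_sd = noise_sd, seed = as.integer(seed),
    class_params = if (n_classes == 2L) params2 else params7
  )
  class(spec) <- "dermtex_fixture_spec"
  spec
}

#' Render one synthetic lesion image
#'
#' @param spec A [lesion_fixture_spec()].
#' @param class_id Class in `0..n_classes-1`.
#' @param index Image index within the class (1-based).
#' @return `size x size x 3` integer array in `[0, 255]`, bit-identical for
#'   identical `(spec, class_id, index)`.
#' @export
make_lesion_image <- function(spec, class_id, index) {
  if (!inherits(spec, "dermtex_fixture_spec")) {
    stop_dermtex("spec must be a lesion_fixture_spec", "dermtex_input_error")
  }
  if (class_id < 0 || class_id >= spec$n_classes) {
    stop_dermtex(sprintf("class_id %s outside 0..%d", class_id, spec$n_classes - 1),
                 "dermtex_input_error")
  }
  p <- spec$class_params[spec$class_params$class_id == class_id, ]
  S <- spec$size
  set.seed(mix_seed(spec$seed, class_id, index))

  # skin-toned background with mild per-image color jitter
  bg <- c(205, 170, 145) + stats::rnorm(3, 0, 5)
  img <- array(rep(bg, each = S * S), dim = c(S, S, 3))

  # irregular ellipse: radius modulated by low-order harmonics
  cx <- S / 2 + stats::rnorm(1, 0, S * 0.03)
  cy <- S / 2 + stats::rnorm(1, 0, S * 0.03)
  a <- S * stats::runif(1, 0.24, 0.32)
  b <- S * stats::runif(1, 0.20, 0.28)
  rot <- stats::runif(1, 0, pi)
  amp <- p$irregularity * stats::runif(3, 0.5, 1.5)
  phs <- stats::runif(3, 0, 2 * pi)
  xs <- matrix(seq_len(S), S, S, byrow = TRUE) - cx
  ys <- matrix(seq_len(S), S, S) - cy
  xr <- xs * cos(rot) + ys * sin(rot)
  yr <- -xs * sin(rot) + ys * cos(rot)
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  ang <- atan2(yr / b, xr / a)
  edge <- 1 + amp[1] * cos(2 * ang + phs[1]) +
    amp[2] * cos(3 * ang + phs[2]) + amp[3] * cos(4 * ang + phs[3])
  mask <- rho < edge

  lesion_col <- c(p$r, p$g, p$b) + stats::rnorm(3, 0, 6)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- lesion_col[ch]
    img[, , ch] <- plane
  }

  # sinusoidal texture inside the lesion: a luma component with a shared,
  # class-independent frequency (same in all channels), plus a chroma
  # component at the class-dependent frequency whose channel weights cancel
  # under 0.299 R + 0.587 G + 0.114 B — the texture-frequency class signal
  # lives in the chroma planes, invisible to the grayscale path
  alpha <- stats::runif(1, 0, pi)
  beta <- stats::runif(1, 0, pi)
  luma_carrier <- sin(2 * pi * 0.15 * (xs * cos(alpha) + ys * sin(alpha)))
  chroma_carrier <- sin(2 * pi * p$tex_freq * (xs * cos(beta) + ys * sin(beta)))
  chroma_w <- c(1, -(0.299 + 0.114) / 0.587, 1) # BT.601 luma-null direction
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- plane[mask] +
      p$tex_amp * luma_carrier[mask] +
      p$chroma_amp * chroma_w[ch] * chroma_carrier[mask]
    img[, , ch] <- plane
  }

  if (spec$noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  }
  img <- round_clip_255(img)
  storage.mode(img) <- "integer"
  img
}

#' Generate a full synthetic dataset
#'
#' Renders every image of the spec and returns a manifest tibble. When
#' `dir` is given the images are written as PNG files and a
#' `manifest.csv` (`path,label`) is written alongside them.
#'
#' @param spec A [lesion_fixture_spec()].
#' @param dir Optional output directory for PNGs + manifest.
#' @param keep_images Keep the pixel arrays in the `image` list-column
#'   (default `TRUE`; set `FALSE` with `dir` to save memory).
#' @return Tibble with columns `class_id` (label), `index`, `image`
#'   (list-column of arrays, unless dropped) and `path` (if written).
#' @export
make_lesion_dataset <- function(spec, dir = NULL, keep_images = TRUE) {
  if (!inherits(spec, "dermtex_fixture_spec")) {
    stop_dermtex("spec must be a lesion_fixture_spec", "dermtex_input_error")
  }
  rows <- purrr::map2(rep(0:(spec$n_classes - 1L), spec$counts),
                      unlist(lapply(spec$counts, seq_len)),
                      function(cl, idx) {
    img <- make_lesion_image(spec, cl, idx)
    path <- NA_character_
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      path <- file.path(dir, sprintf("class%d_%04d.png", cl, idx))
      write_image_png(img, path)
    }
    tibble::tibble(class_id = cl, index = idx,
                   image = if (keep_images) list(img) else list(NULL),
                   path = path)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    readr::write_csv(dplyr::tibble(path = out$path, label = out$class_id),
                     file.path(dir, "manifest.csv"))
  }
  out
}

#' Read a `path,label` manifest into a dataset tibble
#'
#' @param manifest Path to a CSV with header `path,label`; relative image
#'   paths are resolved against the manifest's directory.
#' @return Tibble with `class_id`, `index`, `image` (list-column), `path`.
#' @export
read_manifest <- function(manifest) {
  df <- readr::read_csv(manifest, show_col_types = FALSE)
  if (!all(c("path", "label") %in% names(df))) {
    stop_dermtex("manifest must have columns path,label", "dermtex_input_error")
  }
  base <- dirname(manifest)
  paths <- ifelse(file.exists(df$path), df$path, file.path(base, df$path))
  tibble::tibble(
    class_id = as.integer(df$label),
    index = seq_len(nrow(df)),
    image = lapply(paths, load_image),
    path = paths
  )
}
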