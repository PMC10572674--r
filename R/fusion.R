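# Feature fusion: "colored" features concatenate one descriptor across the
# three channels of a color space; "hybrid" features concatenate several
# descriptor vectors. Both keep a provenance table (segment boundaries) so
# a fused vector can always be sliced back into its parts.

new_feature_vector <- function(values, provenance) {
  structure(as.numeric(values), provenance = provenance)
}

#' Provenance of a fused feature vector
#'
#' @param x A feature vector produced by [colored_feature()] or
#'   [hybrid_feature()].
#' @return A tibble with columns `channel`, `descriptor`, `start`, `end`.
#' @export
feature_provenance <- function(x) {
  attr(x, "provenance")
}

#' Colored feature: one descriptor over all channels of a color space
#'
#' Extracts `descriptor` from each of the three channel planes of `space`
#' (fixed channel order of [to_planes()]) and concatenates the per-channel
#' histograms, e.g. colored LBP over YCbCr is `(LBP_Y, LBP_Cb, LBP_Cr)` with
#' length `3 * 256 = 768`.
#'
#' @param img `H x W x 3` integer array in `[0, 255]`.
#' @param descriptor Descriptor id.
#' @param space A 3-channel color space (`"LAB"`, `"HSV"` or `"YCBCR"`).
#' @param cfg A [descriptor_config()].
#' @return Numeric vector of length `3 * descriptor_length(descriptor)` with
#'   a provenance attribute (see [feature_provenance()]).
#' @export
colored_feature <- function(img, descriptor, space, cfg = descriptor_config()) {
  check_descriptor_id(descriptor)
  if (identical(space, "GRAY")) {
    stop_dermtex("colored features need a 3-channel color space, not GRAY",
                 "dermtex_config_error")
  }
  planes <- to_planes(img, space)
  parts <- lapply(planes, extract_descriptor, d = descriptor, cfg = cfg)
  lens <- unname(lengths(parts))
  ends <- cumsum(lens)
  prov <- tibble::tibble(
    channel = names(planes), descriptor = descriptor,
    start = ends - lens + 1L, end = ends
  )
  new_feature_vector(unlist(parts, use.names = FALSE), prov)
}

#' Grayscale feature: one descriptor on the luma plane
#'
#' The classical single-channel pathway the colored features are compared
#' against: BT.601 luma, then one descriptor.
#'
#' @inheritParams colored_feature
#' @return Numeric vector of length `descriptor_length(descriptor)`.
#' @export
gray_feature <- function(img, descriptor, cfg = descriptor_config()) {
  check_descriptor_id(descriptor)
  plane <- to_planes(img, "GRAY")[[1]]
  v <- extract_descriptor(plane, descriptor, cfg)
  prov <- tibble::tibble(channel = "GRAY", descriptor = descriptor,
                         start = 1L, end = length(v))
  new_feature_vector(v, prov)
}

#' Hybrid feature: concatenation of descriptor vectors
#'
#' Concatenates two or more feature vectors in the given order (e.g.
#' LBP + MBC on grayscale gives `256 + 3072 = 3328` values). No reweighting
#' or reordering is performed.
#'
#' @param parts List of at least two numeric vectors (plain vectors or
#'   outputs of [colored_feature()]/[gray_feature()]).
#' @return Numeric vector of length `sum(lengths(parts))`, provenance
#'   concatenated from the parts.
#' @export
hybrid_feature <- function(parts) {
  if (!is.list(parts) || length(parts) < 2) {
    stop_dermtex("hybrid fusion needs at least two parts", "dermtex_usage_error")
  }
  provs <- vector("list", length(parts))
  offset <- 0L
  for (i in seq_along(parts)) {
    p <- feature_provenance(parts[[i]])
    if (is.null(p)) {
      p <- tibble::tibble(channel = NA_character_,
                          descriptor = paste0("part", i),
                          start = 1L, end = length(parts[[i]]))
    }
    p$start <- p$start + offset
    p$end <- p$end + offset
    offset <- offset + length(parts[[i]])
    provs[[i]] <- p
  }
  new_feature_vector(unlist(parts, use.names = FALSE), dplyr::bind_rows(provs))
}

#' Persist a feature matrix with sidecar metadata
#'
#' Writes features as a plain CSV (one row per sample, one column per
#' feature, plus a `label` column) and a JSON sidecar recording descriptor,
#' color space, segment boundaries and a configuration hash.
#'
#' @param X Numeric matrix `N x D`.
#' @param y Integer labels of length `N`.
#' @param path Output CSV path; the sidecar is `<path>.json`.
#' @param meta Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, y, path, meta = list()) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$label <- as.integer(y)
  readr::write_csv(df, path)
  meta$n <- nrow(X)
  meta$d <- ncol(X)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path CSV path.
#' @return List with `X` (matrix), `y` (integer vector) and `meta` (list).
#' @export
read_features <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  y <- df$label
  X <- as.matrix(df[setdiff(names(df), "label")])
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  list(X = X, y = as.integer(y), meta = meta)
}
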