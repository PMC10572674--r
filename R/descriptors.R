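# Histogram-based local descriptors. Each descriptor codes every interior
# pixel (full 3x3 neighbourhood available; borders are excluded, never
# padded) as a small integer and returns the histogram of codes. With
# normalize = FALSE the histogram mass therefore equals the interior pixel
# count (H-2)(W-2) for the code-per-pixel descriptors.

#' Descriptor identifiers
#' @return Character vector `c("LBP","LDN","PHOG","LDIP","MBC")`.
#' @export
descriptor_ids <- function() c("LBP", "LDN", "PHOG", "LDIP", "MBC")

#' Per-channel descriptor lengths
#'
#' The fixed output lengths of the five descriptors on a single channel
#' plane: 256 (LBP), 56 (LDN), 168 (PHOG), 56 (LDiP) and 3072 (MBC).
#'
#' @param d Descriptor id, or `NULL` for the full named vector.
#' @return Integer vector of lengths.
#' @export
descriptor_length <- function(d = NULL) {
  len <- c(LBP = 256L, LDN = 56L, PHOG = 168L, LDIP = 56L, MBC = 3072L)
  if (is.null(d)) return(len)
  check_descriptor_id(d)
  unname(len[d])
}

check_descriptor_id <- function(d) {
  if (!is.character(d) || length(d) != 1 || !(d %in% descriptor_ids())) {
    stop_dermtex(paste0("unknown descriptor id: ", paste(d, collapse = ",")),
                 "dermtex_config_error")
  }
  invisible(d)
}

#' Descriptor configuration
#'
#' Bundles the tunable parameters of the five descriptors. The defaults
#' reproduce the fixed per-channel lengths of [descriptor_length()]; a
#' configuration whose geometry implies different lengths is rejected at
#' extraction time.
#'
#' @param lbp_radius,lbp_neighbors LBP sampling geometry (only the 3x3,
#'   8-neighbour case is implemented).
#' @param phog_levels Finest pyramid level; levels `0..phog_levels` each use
#'   a `2^l x 2^l` cell grid.
#' @param phog_bins Orientation bins over the signed range `[0, 360)`.
#' @param mbc_blocks Side of the spatial block grid for MBC histograms.
#' @param mbc_bins Histogram bins per MBC block (8-bit codes: 256).
#' @param mbc_scales Number of log-Gabor scales; per-scale histograms are
#'   summed bin-wise, so the output length does not depend on this.
#' @param mbc_wavelength Centre wavelength (pixels) of the first scale.
#' @param mbc_sigma_on_f Log-Gabor bandwidth parameter (sigma/f ratio).
#' @param normalize L1-normalise each histogram segment (recommended: the
#'   downstream margin classifiers are scale-sensitive).
#' @return A list of class `dermtex_descriptor_config`.
#' @export
descriptor_config <- function(lbp_radius = 1L, lbp_neighbors = 8L,
                              phog_levels = 2L, phog_bins = 8L,
                              mbc_blocks = 2L, mbc_bins = 256L,
                              mbc_scales = 1L, mbc_wavelength = 4,
                              mbc_sigma_on_f = 0.65,
                              normalize = TRUE) {
  cfg <- list(
    lbp_radius = as.integer(lbp_radius), lbp_neighbors = as.integer(lbp_neighbors),
    phog_levels = as.integer(phog_levels), phog_bins = as.integer(phog_bins),
    mbc_blocks = as.integer(mbc_blocks), mbc_bins = as.integer(mbc_bins),
    mbc_scales = as.integer(mbc_scales), mbc_wavelength = mbc_wavelength,
    mbc_sigma_on_f = mbc_sigma_on_f, normalize = isTRUE(normalize)
  )
  if (cfg$lbp_radius != 1L || cfg$lbp_neighbors != 8L) {
    stop_dermtex("only radius-1, 8-neighbour LBP is supported", "dermtex_config_error")
  }
  if (cfg$mbc_scales < 1L) stop_dermtex("mbc_scales must be >= 1", "dermtex_config_error")
  class(cfg) <- "dermtex_descriptor_config"
  cfg
}

check_plane <- function(plane, min_side = 3L) {
  if (is.null(dim(plane)) || length(dim(plane)) != 2) {
    stop_dermtex("channel plane must be a matrix", "dermtex_input_error")
  }
  if (nrow(plane) < min_side || ncol(plane) < min_side) {
    stop_dermtex(sprintf("plane smaller than %dx%d", min_side, min_side),
                 "dermtex_size_error")
  }
  invisible(plane)
}

# 8-neighbour offsets, clockwise from top-left; bit i (weight 2^i) is the
# i-th neighbour in this order.
lbp_offsets <- function() {
  list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1), c(1, 1), c(1, 0), c(1, -1), c(0, -1))
}

shift_interior <- function(plane, dr, dc) {
  h <- nrow(plane); w <- ncol(plane)
  plane[(2 + dr):(h - 1 + dr), (2 + dc):(w - 1 + dc), drop = FALSE]
}

# 8-bit neighbour-comparison code map (neighbour >= centre sets the bit),
# shared by LBP and the three MBC component maps.
neighbor_code_map <- function(plane) {
  centre <- shift_interior(plane, 0, 0)
  code <- matrix(0, nrow(centre), ncol(centre))
  offs <- lbp_offsets()
  for (i in seq_along(offs)) {
    code <- code + (shift_interior(plane, offs[[i]][1], offs[[i]][2]) >= centre) * 2^(i - 1)
  }
  code
}

finish_hist <- function(counts, normalize) {
  s <- sum(counts)
  if (normalize && s > 0) counts / s else counts
}

#' Local Binary Pattern histogram
#'
#' Codes every interior pixel with the 8-bit pattern of `neighbour >= centre`
#' comparisons (clockwise from the top-left neighbour, which carries bit 0)
#' and returns the 256-bin histogram of codes.
#'
#' @param plane Numeric matrix (values any scale; only order matters).
#' @param normalize L1-normalise the histogram (default `TRUE`).
#' @return Numeric vector of length 256.
#' @examples
#' lbp(matrix(5, 3, 3))[256] # all neighbours >= centre: code 255
#' @export
lbp <- function(plane, normalize = TRUE) {
  check_plane(plane)
  code <- neighbor_code_map(plane)
  finish_hist(tabulate(code + 1, nbins = 256), normalize)
}

#' Kirsch compass-mask responses
#'
#' Correlates a plane with the eight 3x3 Kirsch compass masks. Mask 1 is the
#' East mask `[[-3,-3,5],[-3,0,5],[-3,-3,5]]`; each subsequent mask rotates
#' the ring of coefficients 45 degrees counterclockwise (E, NE, N, NW, W,
#' SW, S, SE). Responses are defined on interior pixels only.
#'
#' @param plane Numeric matrix, at least 3x3.
#' @return `(H-2) x (W-2) x 8` numeric array of signed responses.
#' @export
kirsch_responses <- function(plane) {
  check_plane(plane)
  masks <- kirsch_masks()
  h <- nrow(plane) - 2; w <- ncol(plane) - 2
  out <- array(0, dim = c(h, w, 8))
  for (k in 1:8) {
    m <- masks[[k]]
    acc <- matrix(0, h, w)
    for (dr in -1:1) for (dc in -1:1) {
      co <- m[dr + 2, dc + 2]
      if (co != 0) acc <- acc + co * shift_interior(plane, dr, dc)
    }
    out[, , k] <- acc
  }
  out
}

kirsch_masks <- function() {
  # ring positions counterclockwise starting East: (row, col) in the 3x3 mask
  ring_pos <- list(c(2, 3), c(1, 3), c(1, 2), c(1, 1), c(2, 1), c(3, 1), c(3, 2), c(3, 3))
  base <- c(5, 5, -3, -3, -3, -3, -3, 5) # E, NE, ..., SE values of the East mask
  lapply(0:7, function(k) {
    m <- matrix(0, 3, 3)
    vals <- base[((seq_len(8) - 1 - k) %% 8) + 1]
    for (i in 1:8) m[ring_pos[[i]][1], ring_pos[[i]][2]] <- vals[i]
    m
  })
}

#' Local Directional Number pattern histogram
#'
#' Per interior pixel, takes the index of the maximum and of the minimum of
#' the eight Kirsch responses (ties broken by the lowest index; when both
#' coincide, the minimum index is reassigned to the lowest index different
#' from the maximum) and forms the compact code `i_max * 7 + rank(i_min)`,
#' giving 56 possible codes.
#'
#' @inheritParams lbp
#' @return Numeric vector of length 56.
#' @export
ldn <- function(plane, normalize = TRUE) {
  check_plane(plane)
  resp <- kirsch_responses(plane)
  n <- prod(dim(resp)[1:2])
  R <- matrix(resp, nrow = n, ncol = 8)
  imax <- max.col(R, ties.method = "first")
  imin <- max.col(-R, ties.method = "first")
  clash <- imin == imax
  imin[clash] <- ifelse(imax[clash] == 1L, 2L, 1L)
  code <- (imax - 1L) * 7L + ifelse(imin < imax, imin - 1L, imin - 2L)
  finish_hist(tabulate(code + 1L, nbins = 56), normalize)
}

#' Local Directional Pattern histogram
#'
#' Per interior pixel, ranks the eight Kirsch responses by absolute value
#' (ties broken by the lower direction index) and sets the bits of the top
#' three directions, producing an 8-bit code with exactly three set bits.
#' The `choose(8, 3) = 56` valid codes are binned in ascending code order.
#'
#' @inheritParams lbp
#' @return Numeric vector of length 56.
#' @export
ldip <- function(plane, normalize = TRUE) {
  check_plane(plane)
  resp <- kirsch_responses(plane)
  n <- prod(dim(resp)[1:2])
  A <- abs(matrix(resp, nrow = n, ncol = 8))
  code <- integer(n)
  for (r in 1:3) {
    top <- max.col(A, ties.method = "first")
    code <- code + 2L^(top - 1L)
    A[cbind(seq_len(n), top)] <- -Inf
  }
  finish_hist(tabulate(match(code, ldip_codes()), nbins = 56), normalize)
}

ldip_codes <- function() {
  codes <- which(vapply(0:255, function(c) sum(bitwAnd(c, 2^(0:7)) > 0) == 3L, logical(1))) - 1L
  sort(codes)
}

#' Pyramid Histogram of Oriented Gradients
#'
#' Centred-difference gradients give per-pixel magnitude and signed
#' orientation in `[0, 360)` degrees. For pyramid levels `l = 0, 1, 2` the
#' gradient field is tiled into a `2^l x 2^l` cell grid; each cell
#' accumulates a magnitude-weighted 8-bin orientation histogram (45-degree
#' bins). Concatenation over cells (row-major) and levels gives
#' `8 * (1 + 4 + 16) = 168` values.
#'
#' @param plane Numeric matrix, at least 4x4.
#' @param normalize L1-normalise the whole vector; if the total gradient
#'   magnitude is zero the zero vector is returned.
#' @param levels,bins Pyramid depth and orientation bins (defaults pinned by
#'   the 168-length contract).
#' @return Numeric vector of length `bins * sum(4^(0:levels))` (168 by
#'   default).
#' @export
phog <- function(plane, normalize = TRUE, levels = 2L, bins = 8L) {
  check_plane(plane, min_side = 4L)
  storage.mode(plane) <- "double"
  gx <- (shift_interior(plane, 0, 1) - shift_interior(plane, 0, -1)) / 2
  gy <- (shift_interior(plane, 1, 0) - shift_interior(plane, -1, 0)) / 2
  mag <- sqrt(gx^2 + gy^2)
  theta <- (atan2(gy, gx) * 180 / pi) %% 360
  bin <- pmin(floor(theta / (360 / bins)), bins - 1)
  h <- nrow(mag); w <- ncol(mag)
  out <- numeric(0)
  rows <- row(mag); cols <- col(mag)
  for (l in 0:levels) {
    g <- 2^l
    cr <- pmin(ceiling(rows * g / h), g)
    cc <- pmin(ceiling(cols * g / w), g)
    cell <- (cr - 1) * g + cc # row-major cell index, 1-based
    idx <- (cell - 1) * bins + bin + 1
    acc <- numeric(g * g * bins)
    sums <- rowsum(as.vector(mag), as.vector(idx))
    acc[as.integer(rownames(sums))] <- sums
    out <- c(out, acc)
  }
  s <- sum(out)
  if (normalize) {
    if (s > 0) out / s else out * 0
  } else {
    out
  }
}

#' Monogenic Binary Coding histogram
#'
#' Band-passes the plane with an isotropic log-Gabor filter and applies the
#' Riesz transform in the frequency domain, yielding the even part `e` and
#' the odd pair `(r1, r2)` of the monogenic signal. The local amplitude
#' `A = sqrt(e^2 + r1^2 + r2^2)`, phase `atan2(sqrt(r1^2 + r2^2), e)` and
#' orientation `atan2(r2, r1)` maps are each coded with the 8-bit
#' neighbour-comparison rule of [lbp()], histogrammed with 256 bins over a
#' 2x2 spatial block grid, and concatenated:
#' `3 components x 4 blocks x 256 bins = 3072` values. With several scales
#' the per-scale histograms are summed bin-wise, so the length is
#' scale-invariant.
#'
#' @param plane Numeric matrix, at least 8x8.
#' @param normalize L1-normalise each block histogram.
#' @param cfg A [descriptor_config()].
#' @return Numeric vector of length `3 * mbc_blocks^2 * mbc_bins` (3072 by
#'   default; any other total is rejected).
#' @export
mbc <- function(plane, normalize = TRUE, cfg = descriptor_config()) {
  check_plane(plane, min_side = 8L)
  nb <- cfg$mbc_blocks; nbin <- cfg$mbc_bins
  if (3L * nb * nb * nbin != 3072L) {
    stop_dermtex("MBC configuration must total 3 x blocks^2 x bins = 3072",
                 "dermtex_config_error")
  }
  total <- NULL
  for (s in seq_len(cfg$mbc_scales)) {
    mono <- monogenic_maps(plane, cfg$mbc_wavelength * 2^(s - 1), cfg$mbc_sigma_on_f)
    hists <- lapply(mono, function(map) {
      code <- neighbor_code_map(map)
      block_histograms(code, nb, nbin)
    })
    v <- unlist(hists, use.names = FALSE)
    total <- if (is.null(total)) v else total + v
  }
  if (normalize) {
    # renormalise per block so each segment sums to 1
    seg <- rep(seq_len(3L * nb * nb), each = nbin)
    sums <- tapply(total, seg, sum)[seg]
    out <- ifelse(sums > 0, total / sums, 0)
    as.numeric(out)
  } else {
    total
  }
}

monogenic_maps <- function(plane, wavelength, sigma_on_f) {
  storage.mode(plane) <- "double"
  h <- nrow(plane); w <- ncol(plane)
  fy <- fft_freqs(h); fx <- fft_freqs(w)
  uy <- matrix(fy, h, w)
  ux <- matrix(fx, h, w, byrow = TRUE)
  radius <- sqrt(ux^2 + uy^2)
  radius[1, 1] <- 1
  lg <- exp(-(log(radius * wavelength))^2 / (2 * log(sigma_on_f)^2))
  lg[1, 1] <- 0 # zero DC: band-pass
  H1 <- (1i * ux) / radius
  H2 <- (1i * uy) / radius
  H1[1, 1] <- 0; H2[1, 1] <- 0
  F <- stats::fft(plane)
  n <- h * w
  e  <- Re(stats::fft(F * lg, inverse = TRUE)) / n
  r1 <- Re(stats::fft(F * lg * H1, inverse = TRUE)) / n
  r2 <- Re(stats::fft(F * lg * H2, inverse = TRUE)) / n
  odd <- sqrt(r1^2 + r2^2)
  list(
    amplitude   = sqrt(e^2 + odd^2),
    phase       = atan2(odd, e),
    orientation = atan2(r2, r1)
  )
}

fft_freqs <- function(n) {
  c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
}

block_histograms <- function(code, nblocks, nbins) {
  h <- nrow(code); w <- ncol(code)
  rb <- pmin(ceiling(row(code) * nblocks / h), nblocks)
  cb <- pmin(ceiling(col(code) * nblocks / w), nblocks)
  out <- numeric(0)
  for (i in seq_len(nblocks)) for (j in seq_len(nblocks)) {
    out <- c(out, tabulate(code[rb == i & cb == j] + 1, nbins = nbins))
  }
  out
}

#' Extract one descriptor from a channel plane
#'
#' Dispatch wrapper over [lbp()], [ldn()], [phog()], [ldip()] and [mbc()];
#' the output length always equals `descriptor_length(d)`.
#'
#' @param plane Numeric matrix.
#' @param d Descriptor id (see [descriptor_ids()]).
#' @param cfg A [descriptor_config()].
#' @return Numeric vector of length `descriptor_length(d)`.
#' @export
extract_descriptor <- function(plane, d, cfg = descriptor_config()) {
  check_descriptor_id(d)
  nz <- cfg$normalize
  out <- switch(d,
    LBP  = lbp(plane, normalize = nz),
    LDN  = ldn(plane, normalize = nz),
    LDIP = ldip(plane, normalize = nz),
    PHOG = phog(plane, normalize = nz, levels = cfg$phog_levels, bins = cfg$phog_bins),
    MBC  = mbc(plane, normalize = nz, cfg = cfg)
  )
  if (length(out) != descriptor_length(d)) {
    stop_dermtex("configured descriptor length violates the length contract",
                 "dermtex_config_error")
  }
  out
}
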