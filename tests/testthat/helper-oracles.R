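# Independent brute-force oracles: per-pixel loops written directly from
# the descriptor definitions, sharing no code with the package internals.

random_plane <- function(h, w = h, max_val = 255) {
  matrix(sample(0:max_val, h * w, replace = TRUE), h, w)
}

oracle_kirsch_masks <- function() {
  # East mask written out, then ring rotated counterclockwise step by step
  east <- matrix(c(-3, -3, 5,
                   -3,  0, 5,
                   -3, -3, 5), 3, 3, byrow = TRUE)
  ring <- rbind(c(2, 3), c(1, 3), c(1, 2), c(1, 1), c(2, 1), c(3, 1), c(3, 2), c(3, 3))
  masks <- vector("list", 8)
  masks[[1]] <- east
  for (k in 2:8) {
    prev <- masks[[k - 1]]
    m <- prev
    for (i in 1:8) {
      src <- ring[i, ]
      dst <- ring[(i %% 8) + 1, ]
      m[dst[1], dst[2]] <- prev[src[1], src[2]]
    }
    masks[[k]] <- m
  }
  masks
}

oracle_kirsch <- function(plane) {
  masks <- oracle_kirsch_masks()
  h <- nrow(plane); w <- ncol(plane)
  out <- array(NA_real_, dim = c(h - 2, w - 2, 8))
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    patch <- plane[(i - 1):(i + 1), (j - 1):(j + 1)]
    for (k in 1:8) out[i - 1, j - 1, k] <- sum(patch * masks[[k]])
  }
  out
}

# clockwise neighbour order from top-left, bit i = neighbour i (weight 2^i)
oracle_lbp_code <- function(patch) {
  centre <- patch[2, 2]
  nb <- c(patch[1, 1], patch[1, 2], patch[1, 3], patch[2, 3],
          patch[3, 3], patch[3, 2], patch[3, 1], patch[2, 1])
  sum((nb >= centre) * 2^(0:7))
}

oracle_lbp_hist <- function(plane) {
  h <- nrow(plane); w <- ncol(plane)
  counts <- numeric(256)
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    code <- oracle_lbp_code(plane[(i - 1):(i + 1), (j - 1):(j + 1)])
    counts[code + 1] <- counts[code + 1] + 1
  }
  counts
}

oracle_ldn_hist <- function(plane) {
  resp <- oracle_kirsch(plane)
  counts <- numeric(56)
  for (i in seq_len(dim(resp)[1])) for (j in seq_len(dim(resp)[2])) {
    r <- resp[i, j, ]
    imax <- which(r == max(r))[1]
    imin <- which(r == min(r))[1]
    if (imin == imax) imin <- setdiff(1:8, imax)[1]
    low <- if (imin < imax) imin - 1 else imin - 2
    code <- (imax - 1) * 7 + low
    counts[code + 1] <- counts[code + 1] + 1
  }
  counts
}

oracle_ldip_hist <- function(plane) {
  resp <- oracle_kirsch(plane)
  valid <- sort(Filter(function(c) {
    sum(as.integer(intToBits(c))[1:8]) == 3
  }, 0:255))
  counts <- numeric(56)
  for (i in seq_len(dim(resp)[1])) for (j in seq_len(dim(resp)[2])) {
    a <- abs(resp[i, j, ])
    top <- order(-a, 1:8)[1:3]
    code <- sum(2^(top - 1))
    counts[which(valid == code)] <- counts[which(valid == code)] + 1
  }
  counts
}

oracle_phog <- function(plane, levels = 2, bins = 8) {
  h <- nrow(plane); w <- ncol(plane)
  hi <- h - 2; wi <- w - 2
  out <- numeric(0)
  for (l in 0:levels) {
    g <- 2^l
    acc <- array(0, dim = c(g, g, bins))
    for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
      gx <- (plane[i, j + 1] - plane[i, j - 1]) / 2
      gy <- (plane[i + 1, j] - plane[i - 1, j]) / 2
      mag <- sqrt(gx^2 + gy^2)
      theta <- (atan2(gy, gx) * 180 / pi) %% 360
      b <- min(floor(theta / (360 / bins)), bins - 1) + 1
      cr <- min(ceiling((i - 1) * g / hi), g)
      cc <- min(ceiling((j - 1) * g / wi), g)
      acc[cr, cc, b] <- acc[cr, cc, b] + mag
    }
    for (cr in seq_len(g)) for (cc in seq_len(g)) out <- c(out, acc[cr, cc, ])
  }
  if (sum(out) > 0) out / sum(out) else out * 0
}

# high-resolution quadrature for the two-tailed t-density tail probability
oracle_t_pvalue <- function(t, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(t), Inf, rel.tol = 1e-12)$value
}
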