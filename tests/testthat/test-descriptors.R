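# Per-plane descriptor contracts: fixed lengths, forced codes on degenerate
# inputs, brute-force equivalence, invariances and mass conservation.

test_that("every descriptor honours its fixed length on assorted plane sizes", {
  set.seed(31)
  for (dims in list(c(8, 8), c(9, 13), c(28, 28))) {
    p <- random_plane(dims[1], dims[2])
    for (d in descriptor_ids()) {
      expect_length(extract_descriptor(p, d), descriptor_length(d))
    }
  }
  expect_identical(unname(descriptor_length()), c(256L, 56L, 168L, 56L, 3072L))
  expect_error(extract_descriptor(random_plane(8), "SIFT"),
               class = "dermtex_config_error")
})

test_that("constant planes produce the tie-break-forced codes", {
  p <- matrix(42, 5, 5)
  h_lbp <- lbp(p)
  expect_equal(h_lbp[256], 1) # all neighbours >= centre: code 255
  expect_equal(sum(h_lbp), 1)
  h_ldn <- ldn(p)
  expect_equal(h_ldn[1], 1) # i_max = 0, i_min reassigned to 1: code 0
  h_ldip <- ldip(p)
  expect_equal(h_ldip[1], 1) # directions {0,1,2}: code 7, the smallest 3-bit code
  expect_equal(phog(p), rep(0, 168)) # no gradient mass anywhere
})

test_that("code histograms match the brute-force per-pixel oracles", {
  set.seed(32)
  for (i in 1:40) {
    p <- random_plane(sample(3:8, 1), sample(3:8, 1))
    expect_equal(lbp(p, normalize = FALSE), oracle_lbp_hist(p))
    expect_equal(ldn(p, normalize = FALSE), oracle_ldn_hist(p))
    expect_equal(ldip(p, normalize = FALSE), oracle_ldip_hist(p))
  }
})

test_that("PHOG matches its oracle and puts step-edge mass at 0/180 degrees", {
  set.seed(33)
  for (i in 1:10) {
    p <- random_plane(sample(4:8, 1), sample(4:8, 1))
    expect_equal(phog(p), oracle_phog(p))
  }
  # vertical step edge: gradients are horizontal, orientations 0 or 180 deg
  step <- cbind(matrix(0, 8, 4), matrix(200, 8, 4))
  v <- phog(step)
  expect_equal(sum(v), 1)
  bins_hit <- unique((which(v > 0) - 1) %% 8)
  expect_true(all(bins_hit %in% c(0, 4)))
})

test_that("unnormalized histogram mass equals the interior pixel count", {
  set.seed(34)
  for (i in 1:10) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    p <- random_plane(h, w)
    interior <- (h - 2) * (w - 2)
    expect_equal(sum(lbp(p, normalize = FALSE)), interior)
    expect_equal(sum(ldn(p, normalize = FALSE)), interior)
    expect_equal(sum(ldip(p, normalize = FALSE)), interior)
  }
})

test_that("LBP is invariant under strictly increasing intensity maps", {
  set.seed(35)
  for (i in 1:10) {
    p <- random_plane(8)
    expect_identical(lbp(p), lbp(p^1.7 + 3))
    expect_identical(lbp(p), lbp(5 * p - 40))
  }
})

test_that("LDN and LDiP are invariant under positive affine maps", {
  # exactly representable a, b so exact response ties survive the float
  # transform (the invariance is exact in exact arithmetic)
  set.seed(36)
  for (i in 1:10) {
    p <- random_plane(8)
    a <- sample(1:9, 1); b <- sample(-160:160, 1) / 2
    expect_equal(ldn(p), ldn(a * p + b))
    expect_equal(ldip(p), ldip(a * p + b))
  }
})

test_that("MBC geometry: 3 components x 4 blocks x 256 bins, mass = coded pixels", {
  set.seed(37)
  p <- random_plane(16)
  v <- mbc(p, normalize = FALSE)
  expect_length(v, 3072)
  # per block, the unnormalized histogram mass is the number of coded pixels
  # in that block; 14x14 interior split 2x2 -> 49 per block
  seg <- matrix(v, nrow = 256)
  expect_equal(colSums(seg), rep(49, 12))
  # normalized: every non-empty block histogram sums to 1
  vn <- mbc(p, normalize = TRUE)
  expect_equal(colSums(matrix(vn, nrow = 256)), rep(1, 12))
  # rejected geometry
  bad <- descriptor_config(mbc_blocks = 3)
  expect_error(mbc(p, cfg = bad), class = "dermtex_config_error")
  # multi-scale keeps the length contract
  expect_length(mbc(p, cfg = descriptor_config(mbc_scales = 2)), 3072)
})

test_that("descriptors are deterministic", {
  set.seed(38)
  p <- random_plane(12)
  for (d in descriptor_ids()) {
    expect_identical(extract_descriptor(p, d), extract_descriptor(p, d))
  }
})

test_that("size preconditions are enforced", {
  expect_error(lbp(matrix(0, 2, 2)), class = "dermtex_size_error")
  expect_error(phog(matrix(0, 3, 3)), class = "dermtex_size_error")
  expect_error(mbc(matrix(0, 7, 7)), class = "dermtex_size_error")
})
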