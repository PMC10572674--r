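# Closed-form checks of the fixed color conversions at the RGB cube corners
# and of the image IO contracts.

solid_image <- function(rgb, h = 4, w = 4) {
  img <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}

test_that("plane counts and value ranges hold for every space", {
  set.seed(11)
  img <- array(sample(0:255, 5 * 6 * 3, TRUE), dim = c(5, 6, 3))
  storage.mode(img) <- "integer"
  for (space in color_spaces()) {
    pl <- to_planes(img, space)
    expect_length(pl, if (space == "GRAY") 1L else 3L)
    for (p in pl) {
      expect_identical(dim(p), c(5L, 6L))
      expect_true(min(p) >= 0 && max(p) <= 255)
      expect_type(p, "integer")
    }
  }
  expect_error(to_planes(img, "XYZ"), class = "dermtex_config_error")
})

test_that("YCbCr on achromatic images gives Y = gray, Cb = Cr = 128", {
  for (c in c(0, 100, 255)) {
    pl <- to_planes(solid_image(c(c, c, c)), "YCBCR")
    expect_true(all(pl$Y == c))
    expect_true(all(pl$Cb == 128))
    expect_true(all(pl$Cr == 128))
    gr <- to_planes(solid_image(c(c, c, c)), "GRAY")[[1]]
    expect_identical(gr, pl$Y)
  }
})

test_that("GRAY equals the Y plane for arbitrary R=G=B images", {
  set.seed(3)
  v <- matrix(sample(0:255, 25, TRUE), 5, 5)
  img <- array(0L, dim = c(5, 5, 3))
  for (ch in 1:3) img[, , ch] <- v
  expect_identical(to_planes(img, "GRAY")[[1]], to_planes(img, "YCBCR")$Y)
})

test_that("cube corners match hand-computed BT.601 / HSV / LAB values", {
  # BT.601 luma of the corners, rounded half away from zero
  luma <- function(rgb) trunc(0.299 * rgb[1] + 0.587 * rgb[2] + 0.114 * rgb[3] + 0.5)
  corners <- list(c(0, 0, 0), c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
                  c(255, 255, 0), c(255, 0, 255), c(0, 255, 255), c(255, 255, 255))
  for (rgb in corners) {
    pl <- to_planes(solid_image(rgb), "GRAY")
    expect_equal(pl[[1]][1, 1], luma(rgb))
  }
  # hue of the primary corners, scaled to [0, 255]
  hsv_red <- to_planes(solid_image(c(255, 0, 0)), "HSV")
  expect_equal(hsv_red$H[1, 1], 0L)
  expect_equal(hsv_red$S[1, 1], 255L)
  expect_equal(hsv_red$V[1, 1], 255L)
  hsv_green <- to_planes(solid_image(c(0, 255, 0)), "HSV")
  expect_equal(hsv_green$H[1, 1], as.integer(round(120 * 255 / 360)))
  hsv_blue <- to_planes(solid_image(c(0, 0, 255)), "HSV")
  expect_equal(hsv_blue$H[1, 1], as.integer(round(240 * 255 / 360)))
  # white: L* = 100 -> 255; a* = b* = 0 -> ~128
  lab_white <- to_planes(solid_image(c(255, 255, 255)), "LAB")
  expect_equal(lab_white$L[1, 1], 255L)
  expect_equal(lab_white$A[1, 1], 128L)
  expect_true(abs(lab_white$B[1, 1] - 128L) <= 1)
  lab_black <- to_planes(solid_image(c(0, 0, 0)), "LAB")
  expect_equal(lab_black$L[1, 1], 0L)
})

test_that("LAB agrees with grDevices::convertColor on random colors", {
  set.seed(7)
  for (i in 1:20) {
    rgb <- sample(0:255, 3)
    pl <- to_planes(solid_image(rgb), "LAB")
    ref <- grDevices::convertColor(matrix(rgb / 255, 1), "sRGB", "Lab")
    # within ~1 code value: the reference uses a slightly different sRGB matrix
    expect_lte(abs(pl$L[1, 1] - ref[1] * 255 / 100), 1.5)
    expect_lte(abs(pl$A[1, 1] - (ref[2] + 128)), 1.5)
    expect_lte(abs(pl$B[1, 1] - (ref[3] + 128)), 1.5)
  }
})

test_that("image IO round-trips PNGs and enforces the error contracts", {
  img <- solid_image(c(255, 0, 0), h = 3, w = 3)
  f <- tempfile(fileext = ".png")
  write_image_png(img, f)
  expect_identical(load_image(f), img)

  # grayscale source replicated to three identical channels
  g <- tempfile(fileext = ".png")
  png::writePNG(matrix(100 / 255, 4, 4), g)
  got <- load_image(g)
  expect_true(all(got == 100L))
  expect_identical(dim(got), c(4L, 4L, 3L))

  # alpha dropped
  a <- tempfile(fileext = ".png")
  png::writePNG(array(runif(4 * 4 * 4), dim = c(4, 4, 4)), a)
  expect_identical(dim(load_image(a)), c(4L, 4L, 3L))

  expect_error(load_image(tempfile()), class = "dermtex_input_error")
  bad <- tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(load_image(bad), class = "dermtex_format_error")
  tiny <- tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 2, 2), tiny)
  expect_error(load_image(tiny), class = "dermtex_size_error")
})

test_that("JPEG files decode through the same loader", {
  img <- solid_image(c(120, 60, 30), h = 8, w = 8)
  f <- tempfile(fileext = ".jpg")
  jpeg::writeJPEG(img / 255, f, quality = 1)
  got <- load_image(f)
  expect_identical(dim(got), c(8L, 8L, 3L))
  expect_lt(max(abs(got - img)), 6) # lossy but near-exact at quality 1
})
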