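test_that("dot synthesis matches the Gaussian closed form", {
  quiet <- dot_model(noise_sd_nm = 0, tilt = c(0, 0))
  # all-zero matrix, no noise, no tilt: flat zero image
  img0 <- synthesize_image(bit_matrix(matrix(0L, 4, 4)), quiet)
  expect_true(all(img0$heights == 0))
  # single centred dot: peak = height, value at FWHM/2 offset = height/2
  img1 <- synthesize_image(bit_matrix(matrix(1L, 1, 1)), quiet, margin_px = 30L)
  pk <- which(img1$heights == max(img1$heights), arr.ind = TRUE)[1, ]
  expect_equal(max(img1$heights), 10)
  offset_px <- round(25 / quiet$pixel_size_nm)  # FWHM/2 = 25 nm
  expect_equal(img1$heights[pk[1], pk[2] + offset_px], 5, tolerance = 1e-6)
  # two adjacent dots at 100-nm pitch: midpoint = 2 h exp(-50^2 / (2 sigma^2))
  img2 <- synthesize_image(bit_matrix(matrix(1L, 1, 2)), quiet, margin_px = 30L)
  sigma <- 50 / (2 * sqrt(2 * log(2)))
  expected_mid <- 2 * 10 * exp(-50^2 / (2 * sigma^2))
  mid <- img2$heights[31, 31 + 10]  # 50 nm right of the first dot
  expect_equal(mid, expected_mid, tolerance = 1e-3)
  expect_error(synthesize_image(bit_matrix(matrix(1L, 500, 500)), quiet),
               "too large")
})

test_that("plane flattening removes exact planes and is idempotent", {
  z <- outer(1:40, 1:50, function(y, x) 3 + 0.2 * x - 0.1 * y)
  flat <- plane_flatten(height_image(z, 5))
  expect_lt(max(abs(flat$heights)), 1e-9)
  withr::with_seed(12, {
    img <- synthesize_image(bit_matrix(matrix(rbinom(64, 1, 0.5), 8, 8)),
                            dot_model(), seed = 3)
    f1 <- plane_flatten(img)
    f2 <- plane_flatten(f1)
    expect_equal(f1$heights, f2$heights, tolerance = 1e-9)
  })
})

test_that("tilt only shifts the plane: flattened images agree within noise", {
  b <- withr::with_seed(13, matrix(rbinom(64, 1, 0.5), 8, 8))
  no_tilt <- plane_flatten(synthesize_image(bit_matrix(b),
                                            dot_model(tilt = c(0, 0)), seed = 4))
  tilted <- plane_flatten(synthesize_image(bit_matrix(b),
                                           dot_model(tilt = c(0.05, -0.02)),
                                           seed = 4))
  expect_lt(max(abs(no_tilt$heights - tilted$heights)), 0.2)
})

test_that("grid detection recovers dimensions and pitch to half a pixel", {
  # 28x28 at 10 px pitch (50-nm pitch, 20-nm dots at 5 nm/px)
  small <- dot_model(fwhm_nm = 20, pitch_nm = 50, noise_sd_nm = 0.5)
  b <- withr::with_seed(14, matrix(rbinom(28 * 28, 1, 0.5), 28, 28))
  flat <- plane_flatten(synthesize_image(bit_matrix(b), small, seed = 5))
  g <- detect_grid(flat)
  expect_identical(c(g$rows, g$cols), c(28L, 28L))
  expect_lt(abs(g$pitch_px - 10), 0.5)
  # degenerate 1x4 lattice
  g2 <- detect_grid(plane_flatten(synthesize_image(bit_matrix(matrix(1L, 1, 4)),
                                                   dot_model(), seed = 6)))
  expect_identical(c(g2$rows, g2$cols), c(1L, 4L))
  # pure noise carries no lattice
  noise <- height_image(matrix(rnorm(200 * 200), 200, 200), 5)
  expect_error(detect_grid(plane_flatten(noise)), "periodic|regular")
})

test_that("noiseless and noisy read-out round-trips random matrices", {
  quiet <- dot_model(noise_sd_nm = 0, tilt = c(0, 0))
  noisy <- dot_model()  # 1-nm noise, tilted background
  withr::with_seed(15, {
    for (i in 1:5) {
      side <- sample(4:16, 1)
      b <- matrix(rbinom(side^2, 1, 0.5), side, side)
      b[1, 1] <- 1L; b[side, side] <- 1L  # anchor the lattice extent
      for (dm in list(quiet, noisy)) {
        flat <- plane_flatten(synthesize_image(bit_matrix(b), dm, seed = i))
        m <- read_matrix(flat, detect_grid(flat))
        expect_identical(m$bits, b)
      }
    }
  })
  # all-ones and all-zeros round trip with a known grid
  for (b in list(matrix(1L, 8, 8), matrix(0L, 8, 8))) {
    flat <- plane_flatten(synthesize_image(bit_matrix(b), noisy, seed = 9))
    grid <- list(origin_px = c(row = 13, col = 13), pitch_px = 20,
                 rows = 8L, cols = 8L)
    expect_identical(read_matrix(flat, grid)$bits, b)
  }
})

test_that("read-out is bit-exact over 100 random 28x28 arrays", {
  dm <- dot_model()  # 50-nm FWHM, 10-nm height, 100-nm pitch, 1-nm noise
  errors <- 0L
  withr::with_seed(100, {
    for (i in 1:100) {
      b <- matrix(rbinom(28 * 28, 1, 0.5), 28, 28)
      flat <- plane_flatten(synthesize_image(bit_matrix(b), dm,
                                             seed = 1000L + i))
      g <- detect_grid(flat)
      errors <- errors + sum(g$rows != 28L, g$cols != 28L)
      if (g$rows == 28L && g$cols == 28L)
        errors <- errors + sum(read_matrix(flat, g)$bits != b)
    }
  })
  expect_identical(errors, 0L)
})
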