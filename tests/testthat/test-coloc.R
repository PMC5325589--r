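# Pixel colocalization: smoothing kernel, thresholding, ICQ, overlap and
# triple conjunction, each against its definition.

test_that("gaussian_preprocess preserves constants and sigma=0 is identity", {
  x <- array(7, c(4, 5, 6))
  expect_equal(gaussian_preprocess(x, 1), x)
  y <- array(runif(120), c(4, 5, 6))
  expect_identical(gaussian_preprocess(y, 0), y)
})

test_that("unit impulse maps to the sampled normalized 3D Gaussian kernel", {
  x <- array(0, c(17, 17, 17))
  x[9, 9, 9] <- 1
  sm <- gaussian_preprocess(x, 1)
  r <- 4
  k <- dnorm(-r:r, sd = 1)
  k <- k / sum(k)
  expect_equal(sm[9 + (-r:r), 9, 9], k * k[r + 1] * k[r + 1],
               tolerance = 1e-12)
  expect_equal(sm[5:13, 5:13, 5:13], k %o% k %o% k, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-6) # conservation away from borders
})

test_that("2D smoothing matches the 2D separable kernel", {
  img <- matrix(0, 15, 15)
  img[8, 8] <- 1
  sm <- gaussian_preprocess(img, 1)
  k <- dnorm(-4:4, sd = 1)
  k <- k / sum(k)
  expect_equal(sm[4:12, 4:12], k %o% k, tolerance = 1e-12)
})

test_that("thresholding: manual cutoffs, two-level images, otsu vs oracle", {
  x <- c(10, 60, 40, 80)
  m <- threshold_channel(x, method = 50)
  expect_equal(as.logical(m), c(FALSE, TRUE, FALSE, TRUE))

  two <- array(sample(c(10, 200), 64, replace = TRUE), c(4, 4, 4))
  m2 <- threshold_channel(two, "otsu")
  expect_equal(as.logical(m2), as.logical(two == 200))

  expect_error(threshold_channel(array(5, c(3, 3, 3))), "no separable")

  set.seed(42)
  for (i in 1:20) {
    img <- array(sample(c(10, 60, 120, 200), 125, replace = TRUE,
                        prob = c(0.4, 0.2, 0.2, 0.2)), c(5, 5, 5))
    got <- threshold_channel(img, "otsu")
    want <- oracle_otsu_mask(img)
    expect_equal(as.logical(got), as.logical(want))
  }
})

test_that("ICQ attains its bounds on identical and inverted channels", {
  a <- array(runif(1000, 1, 10), c(10, 10, 10))
  expect_equal(icq(a, a)$icq, 0.5)
  expect_equal(icq(a, max(a) + 1 - a)$icq, -0.5)
  expect_equal(icq(a, a)$two_icq, 1)
})

test_that("ICQ matches the hand-enumerated 4-voxel example", {
  a <- c(1, 2, 3, 4)
  b <- c(1, 2, 3, 0)
  # deviations around means 2.5 / 1.5 give product signs +,-,+,-
  expect_equal(icq(a, b)$icq, 0)
  expect_equal(icq(a, b)$n_pixels_used, 4)
})

test_that("ICQ errors on constant channels and tiny domains", {
  a <- array(1:8, c(2, 2, 2))
  expect_error(icq(a, array(3, c(2, 2, 2))), "undefined covariation")
  expect_error(icq(1, 1), "fewer than 2")
})

test_that("ICQ equals the brute-force sign-count oracle on random images", {
  set.seed(7)
  for (i in 1:50) {
    a <- matrix(sample(0:20, 48, replace = TRUE), 6, 8)
    b <- matrix(sample(0:20, 48, replace = TRUE), 6, 8)
    expect_identical(icq(a, b)$icq, oracle_icq(a, b))
  }
})

test_that("ICQ is symmetric in its channels over a fixed domain", {
  set.seed(11)
  a <- array(rnorm(500, 100, 20), c(5, 10, 10))
  b <- array(rnorm(500, 80, 15), c(5, 10, 10))
  roi <- array(runif(500) > 0.3, c(5, 10, 10))
  expect_equal(icq(a, b, roi)$icq, icq(b, a, roi)$icq)
})

test_that("independent channels sit below the chance criterion", {
  set.seed(23)
  two_icqs <- replicate(100, {
    a <- matrix(rnorm(1e4, 100, 15), 100, 100)
    b <- matrix(rnorm(1e4, 100, 15), 100, 100)
    icq(a, b)$two_icq
  })
  expect_lt(abs(mean(two_icqs)), 0.02)
  expect_gte(mean(abs(two_icqs) < 0.1), 0.95)
})

test_that("overlap_pct counts reference-domain intersections", {
  ref <- array(FALSE, c(2, 5, 5))
  ref[1, 1:2, 1:5] <- TRUE # 10 voxels
  other <- array(FALSE, c(2, 5, 5))
  other[1, 1, 1:3] <- TRUE # 3 of them inside ref
  expect_equal(overlap_pct(ref, other), 30)
  expect_equal(overlap_pct(ref, ref), 100)
  expect_equal(overlap_pct(ref, !ref), 0)
  expect_error(overlap_pct(array(FALSE, c(2, 5, 5)), other), "empty")
})

test_that("overlap_pct is monotone in the other mask and scale-free", {
  set.seed(3)
  ref <- array(runif(250) > 0.5, c(5, 5, 10))
  small <- array(runif(250) > 0.7, c(5, 5, 10))
  bigger <- small | array(runif(250) > 0.8, c(5, 5, 10))
  expect_gte(overlap_pct(ref, bigger), overlap_pct(ref, small))
})

test_that("triple_mask is voxelwise conjunction", {
  a <- array(TRUE, c(2, 3, 3))
  expect_true(all(triple_mask(a, a, a)))
  expect_false(any(triple_mask(a, a, array(FALSE, c(2, 3, 3)))))
  set.seed(5)
  m1 <- array(runif(27) > 0.4, c(3, 3, 3))
  m2 <- array(runif(27) > 0.4, c(3, 3, 3))
  m3 <- array(runif(27) > 0.4, c(3, 3, 3))
  got <- triple_mask(m1, m2, m3)
  expect_identical(which(got), intersect(intersect(which(m1), which(m2)),
                                         which(m3)))
})

test_that("overlap on noiseless vesicle scenes tracks the designed fraction", {
  for (frac in c(0, 0.5, 1)) {
    sc <- make_vesicle_scene(vesicle_scene_spec(coloc_fraction = frac,
                                                noise_sd = 0, seed = 17))
    res <- coloc_pair(sc$stack_a, sc$stack_b)
    expect_lt(abs(res$overlap_pct_ref_a - 100 * frac), 5)
  }
})
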