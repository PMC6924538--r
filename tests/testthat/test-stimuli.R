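# Two-tone stimulus pipeline: resize, grayscale, opening, blur, Otsu.

test_that("bicubic resize handles identity, constants and matches the dense oracle", {
  set.seed(101)
  m <- matrix(runif(144, 0, 255), 12)
  expect_equal(resize_cubic(m, 12), m, tolerance = 1e-12)

  const <- matrix(77, 10, 10)
  up <- resize_cubic(const, 25)
  expect_true(all(abs(up - 77) < 1e-9))

  ramp <- matrix(seq(0, 255, length.out = 16), 4)
  got <- resize_cubic(ramp, 8)
  expect_lt(max(abs(got - oracle_bicubic(ramp, 8))), 1)

  expect_error(resize_cubic(matrix(numeric(0), 0, 0), 8), "empty")
  expect_error(resize_cubic(m, 1), ">= 2")
})

test_that("grayscale conversion uses BT.601 weights and validates channels", {
  gray <- matrix(10:13, 2)
  expect_identical(to_grayscale(gray), gray)

  white <- array(255, c(2, 2, 3))
  expect_true(all(to_grayscale(white) == 255))

  red <- array(0, c(2, 2, 3)); red[, , 1] <- 255
  expect_true(all(to_grayscale(red) == round(0.299 * 255)))  # 76

  expect_error(to_grayscale(array(1, c(2, 2, 2))), "channels")
})

test_that("morphological opening matches the sliding min/max oracle", {
  set.seed(102)
  img <- matrix(sample(0:255, 256, TRUE), 16)
  expect_identical(morphological_open(img, 1L), img)

  spot <- matrix(0, 9, 9); spot[5, 5] <- 200
  expect_true(all(morphological_open(spot, 3L) == 0))

  expect_equal(morphological_open(img, 3L), oracle_open(img, 3))
  expect_error(morphological_open(img, 2L), "odd")
})

test_that("separable Gaussian blur equals dense 2-D convolution", {
  const <- matrix(42, 12, 12)
  expect_true(all(abs(gaussian_blur(const, 9L) - 42) < 1e-9))

  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  sig <- 0.3 * ((9 - 1) / 2 - 1) + 0.8  # auto rule -> 1.7
  g <- exp(-((-4:4)^2) / (2 * sig^2)); g <- g / sum(g)
  expect_equal(gaussian_blur(imp, 9L), outer(g, g), tolerance = 1e-12)

  set.seed(103)
  img <- matrix(runif(1024, 0, 255), 32)
  got <- gaussian_blur(img, 9L, sigma = 2)
  ref <- oracle_blur(img, 9, 2)
  expect_lt(max(abs(got - ref) / pmax(abs(ref), 1)), 1e-6)

  expect_error(gaussian_blur(img, 9L, sigma = -1), "positive")
})

test_that("Otsu threshold maximizes between-class variance", {
  bimodal <- matrix(rep(c(0, 255), each = 32), 8)
  res <- otsu_threshold(bimodal)
  expect_identical(res$binary == 255, bimodal == 255)

  set.seed(104)
  for (rep in 1:20) {
    img <- matrix(sample(0:255, 64 * 64, TRUE,
                         prob = runif(256)^2), 64)
    expect_identical(otsu_threshold(img)$threshold, oracle_otsu(img))
  }

  expect_error(otsu_threshold(matrix(7, 4, 4)), "constant")
})

test_that("two-tone pipeline is deterministic, binary, and polarity-invariant", {
  sp <- synthetic_portrait(60, seed = 5)
  params <- stimulus_params(target_size = 64)
  a <- make_two_tone(sp$image, params, id = "a")
  b <- make_two_tone(sp$image, params, id = "a")
  expect_identical(a$pixels, b$pixels)
  expect_true(all(a$pixels %in% c(0, 255)))
  expect_identical(dim(a$pixels), c(64L, 64L))

  # inverting the template flips the tones but preserves the partition
  inv <- make_two_tone(255 - sp$image, params, id = "inv")
  same <- mean((a$pixels == 255) == (inv$pixels == 255))
  expect_true(same > 0.99 || same < 0.01)

  # known bright ellipse stays majority one tone after binarization
  full <- make_two_tone(sp$image, stimulus_params(target_size = 60), id = "f")
  ellipse_tones <- full$pixels[sp$mask]
  expect_gte(max(mean(ellipse_tones == 255), mean(ellipse_tones == 0)), 0.9)
})

test_that("pilot screening keeps exactly the stimuli inside the difficulty band", {
  scores <- data.frame(stimulus_id = c("a", "b", "c"),
                       before = c(0.95, 0.40, 0.60),
                       after = c(0.90, 0.30, 0.80))
  kept <- screen_stimuli(scores, max_before = 0.9, min_after = 0.5)
  expect_identical(kept, "c")  # a too easy before, b too hard after

  set.seed(105)
  rand <- data.frame(stimulus_id = sprintf("s%02d", 1:10),
                     before = runif(10), after = runif(10))
  kept <- screen_stimuli(rand, 0.8, 0.65)
  brute <- rand$stimulus_id[rand$before <= 0.8 & rand$after >= 0.65]
  expect_identical(kept, as.character(brute))

  rand$after[1] <- NA
  expect_error(screen_stimuli(rand), "missing")
})
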