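test_that("background estimation returns the histogram mode", {
  const <- matrix(7, 20, 20)
  expect_equal(estimate_background(const), 7)
  expect_true(all(subtract_background(const, 7) == 0))

  bimodal <- matrix(c(rep(10, 700), rep(100, 300)), 25, 40)
  expect_equal(estimate_background(bimodal), 10)

  # additive constant recovered within one bin on a noisy synthetic image
  img <- simulate_cell_image(image_design(background_level = 120,
                                          noise_sd = 4, seed = 6))
  expect_lte(abs(estimate_background(img$lysosome) - 120), 1)

  # restricted region
  reg <- matrix(FALSE, 25, 40); reg[1:10, 1:10] <- TRUE
  expect_equal(estimate_background(bimodal, region = reg), 10)
})

test_that("top-hat correction removes haze but keeps puncta", {
  expect_true(all(tophat_correct(matrix(5, 40, 40), 6) == 0))

  # a bright punctum on a smooth gradient survives; the gradient does not
  n <- 64
  gradient <- matrix(seq(0, 200, length.out = n), n, n)
  img <- gradient
  img[30:34, 30:34] <- img[30:34, 30:34] + 1000
  th <- tophat_correct(img, 8)
  expect_gt(th[32, 32], 0.95 * 1000)
  corner <- th[1:10, 50:60]
  expect_lt(max(corner), 0.05 * 1000)

  # anti-extensivity of the opening: repeated top-hat never adds intensity
  set.seed(2); noisy <- matrix(rpois(64 * 64, 20), 64, 64)
  t1 <- tophat_correct(noisy, 5)
  expect_lte(sum(tophat_correct(t1, 5)), sum(t1) + 1e-6)
})

test_that("nuclear segmentation recovers a disc and handles degenerate crops", {
  img <- simulate_cell_image(image_design(nucleus_radius = 40, noise_sd = 0,
                                          seed = 8))
  mask <- segment_nucleus(img$nuclear)
  expect_lt(abs(sum(mask) - pi * 40^2) / (pi * 40^2), 0.02)

  expect_error(segment_nucleus(matrix(100, 64, 64)), "no foreground")

  # two discs in one crop: the larger is selected
  n <- 200
  d <- matrix(0, n, n)
  xs <- matrix(seq_len(n), n, n); ys <- matrix(seq_len(n), n, n, byrow = TRUE)
  d[(xs - 60)^2 + (ys - 60)^2 <= 30^2] <- 1000
  d[(xs - 150)^2 + (ys - 150)^2 <= 12^2] <- 1000
  mask <- segment_nucleus(d)
  expect_true(mask[60, 60]); expect_false(mask[150, 150])
  expect_lt(abs(sum(mask) - pi * 30^2) / (pi * 30^2), 0.05)
})

test_that("ring fractions hit their geometric limits", {
  n <- 180
  nuc_mask <- analytic_ring(n, c(90.5, 90.5), -1, 31)   # disc radius 30
  ring <- analytic_ring(n, c(90.5, 90.5), 30, 30)
  in_ring <- matrix(0, n, n); in_ring[ring] <- 5
  m <- ring_fraction(nuc_mask, in_ring, 30)
  expect_equal(m$fraction, 1)
  expect_false(any(m$ring_mask & m$nuclear_mask))       # disjoint masks

  inside <- matrix(0, n, n); inside[nuc_mask] <- 5
  expect_equal(ring_fraction(nuc_mask, inside, 30)$fraction, 0)

  blank <- matrix(0, n, n)
  expect_equal(ring_fraction(nuc_mask, blank, 30)$fraction, 0)

  # ring cut by the frame edge raises the truncation flag
  big <- analytic_ring(100, c(50.5, 50.5), -1, 41)
  expect_warning(tr <- ring_fraction(big, matrix(1, 100, 100), 30),
                 "truncated")
  expect_true(tr$truncated)
})

test_that("measured ring fractions track the generator truth", {
  fracs <- seq(0.15, 0.85, length.out = 12)
  got <- truth <- numeric(length(fracs))
  for (i in seq_along(fracs)) {
    img <- simulate_cell_image(image_design(perinuclear_fraction = fracs[i],
                                            seed = 300 + i))
    m <- measure_cell(img$nuclear, img$lysosome, cell_id = paste0("c", i))
    got[i] <- m$fraction; truth[i] <- img$truth_fraction
    expect_false(m$truncated)
    expect_gte(m$fraction, 0); expect_lte(m$fraction, 1)
  }
  expect_lt(max(abs(got - truth)), 0.05)
})

test_that("PLA quantification is additive and scales linearly", {
  expect_equal(pla_quantify(matrix(0, 50, 50))$integrated_signal, 0)

  # k identical puncta integrate to k times one punctum's mass
  base <- image_design(n_puncta = 1, perinuclear_fraction = 1, noise_sd = 0,
                       background_level = 0, seed = 5)
  one <- simulate_cell_image(base)$lysosome
  many <- simulate_cell_image(image_design(n_puncta = 12,
                                           perinuclear_fraction = 1,
                                           noise_sd = 0, background_level = 0,
                                           seed = 5))$lysosome
  s1 <- pla_quantify(one, threshold = "none")$integrated_signal
  s12 <- pla_quantify(many, threshold = "none")$integrated_signal
  expect_lt(abs(s12 - 12 * s1) / (12 * s1), 0.05)
  s12 <- pla_quantify(many)$integrated_signal   # Otsu path for the rest

  # doubling exposure doubles the integrated signal (threshold rescales)
  expect_equal(pla_quantify(2 * many)$integrated_signal, 2 * s12,
               tolerance = 1e-6)

  # per-cell masks split the signal
  masks <- list(left = cbind(matrix(TRUE, 256, 128), matrix(FALSE, 256, 128)),
                right = cbind(matrix(FALSE, 256, 128), matrix(TRUE, 256, 128)))
  per <- pla_quantify(many, masks)
  expect_equal(sum(per$integrated_signal), s12, tolerance = 1e-6)
})

test_that("stack projection and TIFF round-trip preserve the channels", {
  img <- simulate_cell_image(image_design(seed = 44))
  st <- array(0, c(dim(img$lysosome), 3))
  st[, , 2] <- img$lysosome
  expect_equal(max_project(st), img$lysosome)
  path <- withr::local_tempfile(fileext = ".tif")
  write_channel_tiff(img$lysosome, path)
  back <- read_channel_tiff(path)
  expect_lt(max(abs(back - img$lysosome)), 1)   # 16-bit quantisation
})
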