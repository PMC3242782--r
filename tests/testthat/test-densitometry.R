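test_that("transmittance conversion follows Beer-Lambert with a saturation floor", {
  img <- absorbance_map(matrix(c(255, 25.5, 2.55), 1), white_reference = 255)
  expect_equal(img$values[1, ], c(0, 1, 2))
  expect_identical(attr(img, "saturated_px"), 0L)

  sat <- absorbance_map(matrix(c(0, 100), 1), white_reference = 100)
  expect_identical(attr(sat, "saturated_px"), 1L)
  expect_equal(sat$values[1, 1], log10(100))  # clipped to floor = 1 count

  expect_error(absorbance_map(matrix(1), white_reference = 0),
               "positive")
  expect_error(absorbance_map(matrix(-1), white_reference = 10),
               "intensities")
})

test_that("absorbance images reject invalid grids", {
  expect_error(absorbance_image(matrix(-0.1)), ">= 0")
  expect_error(absorbance_image(matrix(NaN)), "finite")
  expect_error(absorbance_image(matrix(1), pixel_pitch_um = 0), "positive")
})

test_that("background rule removes OD <= 0.020 and keeps strictly above", {
  v <- matrix(0, 10, 10)
  v[3:9, 3:9] <- 0.021          # 49 px nucleus, just above background
  v[1, 1] <- 0.020              # exactly at threshold: background
  masks <- segment_nuclei(tiny_img(v), min_area_px = 10)
  expect_length(masks, 1)
  expect_equal(masks[[1]]$area_px, 49)
  expect_false((1L) %in% masks[[1]]$idx)

  expect_identical(segment_nuclei(tiny_img(matrix(0, 5, 5))), list())
})

test_that("segmentation is 8-connected and filters small components", {
  # two blobs touching only diagonally must merge into one component
  v <- matrix(0, 8, 8)
  v[1:3, 1:3] <- 0.2
  v[4:6, 4:6] <- 0.2
  masks <- segment_nuclei(tiny_img(v), min_area_px = 1)
  expect_length(masks, 1)
  expect_equal(masks[[1]]$area_px, 18)

  # separated blobs stay separate; the small one is filtered out
  v2 <- matrix(0, 12, 12)
  v2[1:4, 1:4] <- 0.2    # 16 px
  v2[9:11, 9:11] <- 0.2  # 9 px
  masks2 <- segment_nuclei(tiny_img(v2), min_area_px = 10)
  expect_length(masks2, 1)
  expect_equal(masks2[[1]]$area_px, 16)
})

test_that("the four-pixel worked example reproduces every karyometric field", {
  img <- tiny_img(matrix(c(0.30, 0.30, 0.05, 0.05), 2))
  m <- measure_nucleus(img, nucleus_mask(1:4, c(2, 2)))
  expect_equal(m$A_T, 0.70)
  expect_equal(m$S_T_um2, 1.0)
  expect_equal(m$A_C, 0.60)
  expect_equal(m$S_C_um2, 0.5)
  expect_equal(m$Sc_pct, 50)
  expect_equal(m$Ac_pct, 100 * 0.6 / 0.7)
  expect_equal(m$AAR, (0.60 / 0.5) / (0.70 / 1.0))
})

test_that("homogeneous and sub-cutoff nuclei hit the degenerate corners", {
  uni <- tiny_img(matrix(0.15, 10, 10))
  m <- measure_nucleus(uni, nucleus_mask(1:100, c(10, 10)))
  expect_equal(m$S_T_um2, 25)
  expect_equal(m$Sc_pct, 100)
  expect_identical(m$AAR, 1)      # exact: x/x division
  expect_equal(m$A_T, 15.0)

  low <- tiny_img(matrix(0.05, 4, 4))
  m2 <- measure_nucleus(low, nucleus_mask(1:16, c(4, 4)))
  expect_equal(m2$S_C_um2, 0)
  expect_equal(m2$Sc_pct, 0)
  expect_true(is.na(m2$AAR))

  expect_error(measure_nucleus(uni, nucleus_mask(1:4, c(4, 4))),
               "dimensions")
  expect_error(nucleus_mask(integer(0), c(2, 2)), "empty")
})

test_that("measurements are histogram functionals: permutation invariant, additive, cutoff monotone", {
  set.seed(41)
  for (rep in 1:20) {
    img <- random_dyadic_image(16, 16)
    idx <- sort(sample.int(256, 150))
    mask <- nucleus_mask(idx, c(16, 16))
    m <- measure_nucleus(img, mask)

    # permutation invariance: shuffle values among the mask pixels
    v2 <- img$values
    v2[idx] <- sample(v2[idx])
    m2 <- measure_nucleus(tiny_img(v2), mask)
    for (f in c("A_T", "A_C", "S_T_um2", "S_C_um2", "Sc_pct"))
      expect_equal(m2[[f]], m[[f]], tolerance = 1e-12)

    # additivity of integrated absorbance
    noncond <- sum(img$values[idx][img$values[idx] <= m$cutoff])
    expect_equal(m$A_T, m$A_C + noncond, tolerance = 1e-12)

    # cutoff monotonicity over a rising grid
    grid <- seq(0.02, 0.3, length.out = 10)
    prev <- measure_nucleus(img, mask, cutoff = grid[1])
    for (ct in grid[-1]) {
      cur <- measure_nucleus(img, mask, cutoff = ct)
      expect_lte(cur$S_C_um2, prev$S_C_um2)
      expect_lte(cur$A_C, prev$A_C)
      if (!is.na(cur$AAR) && !is.na(prev$AAR))
        expect_gte(cur$AAR, prev$AAR - 1e-12)
      prev <- cur
    }
  }
})

test_that("measure_nuclei tabulates all masks of an image", {
  v <- matrix(0, 12, 12)
  v[2:5, 2:5] <- 0.2
  v[8:11, 8:11] <- 0.05
  img <- tiny_img(v)
  masks <- segment_nuclei(img, min_area_px = 10)
  df <- measure_nuclei(img, masks)
  expect_equal(nrow(df), 2)
  expect_setequal(df$Sc_pct, c(100, 0))
})

test_that("TIFF and PNG round-trips preserve absorbance", {
  nuc <- generate_nucleus(nucleus_sim_params(nucleus_radius_px = 18,
                                             seed = 5))
  tf <- tempfile(fileext = ".tif")
  write_absorbance_tiff(nuc$image, tf)
  back <- read_absorbance_tiff(tf)
  expect_equal(back$values, nuc$image$values, tolerance = 1e-6)

  pf <- tempfile(fileext = ".png")
  write_transmittance_png(nuc$image, pf)
  back2 <- read_transmittance_png(pf)
  # 8-bit transmittance quantization: coarse but unbiased
  expect_equal(back2$values, nuc$image$values, tolerance = 0.01)
  expect_equal(back2$pixel_pitch_um, 0.5)
})
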