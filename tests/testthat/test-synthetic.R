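test_that("generator parameters are validated", {
  expect_error(nucleus_sim_params(condensed_fraction = 1.2), "\\[0, 1\\]")
  expect_error(nucleus_sim_params(od_diffuse = 0.2, od_condensed = 0.1),
               "exceed")
  expect_error(nucleus_sim_params(target_iod = -5), "target_iod")
  expect_error(generate_nucleus(nucleus_sim_params(nucleus_radius_px = 1.5)),
               "degenerate")
  # tiny nucleus cannot realize a 1% condensed fraction
  expect_error(
    generate_nucleus(nucleus_sim_params(nucleus_radius_px = 3,
                                        condensed_fraction = 0.01)),
    "degenerate")
})

test_that("identical params and seed give bit-identical nuclei", {
  p <- nucleus_sim_params(seed = 123)
  a <- generate_nucleus(p)
  b <- generate_nucleus(p)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$mask$idx, b$mask$idx)
  expect_identical(a$truth, b$truth)
})

test_that("noise-free extremes are uniform with forced downstream Sc%", {
  flat <- generate_nucleus(nucleus_sim_params(
    nucleus_radius_px = 20, condensed_fraction = 0, od_diffuse = 0.05,
    od_condensed = 0.3, od_noise_sd = 0, seed = 1))
  expect_true(all(flat$image$values[flat$mask$idx] == 0.05))
  m <- measure_nucleus(flat$image, flat$mask)
  expect_equal(m$Sc_pct, 0)

  solid <- generate_nucleus(nucleus_sim_params(
    nucleus_radius_px = 20, condensed_fraction = 1, od_diffuse = 0.05,
    od_condensed = 0.30, od_noise_sd = 0, seed = 1))
  expect_true(all(solid$image$values[solid$mask$idx] == 0.30))
  m2 <- measure_nucleus(solid$image, solid$mask)
  expect_equal(m2$Sc_pct, 100)
  expect_identical(m2$AAR, 1)
})

test_that("realized condensed fraction tracks the request and IOD control is exact", {
  for (f in c(0.2, 0.4, 0.6, 0.8)) {
    nuc <- generate_nucleus(nucleus_sim_params(
      nucleus_radius_px = 30, condensed_fraction = f, seed = 99))
    expect_lt(abs(nuc$truth$true_condensed_fraction - f), 0.02)
  }
  tgt <- generate_nucleus(nucleus_sim_params(
    nucleus_radius_px = 30, target_iod = 250, seed = 4))
  expect_equal(sum(tgt$image$values), 250, tolerance = 1e-3 * 1e-3)
  expect_equal(tgt$truth$true_iod, 250)
})

test_that("pipeline-measured Sc% calibrates to generator truth within 5 points", {
  seeds <- 11:20
  for (s in seeds) {
    nuc <- generate_nucleus(nucleus_sim_params(
      nucleus_radius_px = 30, condensed_fraction = 0.5, seed = s))
    masks <- segment_nuclei(nuc$image)
    m <- measure_nucleus(nuc$image, masks[[1]])
    expect_lt(abs(m$Sc_pct - 100 * nuc$truth$true_condensed_fraction), 5)
  }
})

test_that("populations are reproducible and presets order as constructed", {
  a <- generate_population("control", 3, seed = 1)
  b <- generate_population("control", 3, seed = 1)
  expect_identical(a$truth, b$truth)
  expect_identical(a$nuclei[[2]]$image$values, b$nuclei[[2]]$image$values)

  ctl <- generate_population("control", 60, seed = 2)
  dec <- generate_population("decondensed", 60, seed = 2)
  expect_gt(mean(ctl$truth$true_condensed_fraction),
            mean(dec$truth$true_condensed_fraction))

  expect_error(generate_population("mystery", 3), "unknown preset")
  expect_error(generate_population("control", 0), ">= 1")
})

test_that("per-nucleus target_iod vectors drive ploidy mixtures", {
  pop <- generate_population(
    "control", 6, seed = 3,
    overrides = list(radius_mean = 20, radius_min = 16,
                     target_iod = c(100, 100, 100, 150, 200, 200)))
  expect_equal(pop$truth$true_iod, c(100, 100, 100, 150, 200, 200),
               tolerance = 1e-9)
})

test_that("population writer emits TIFFs plus a truth table", {
  dir <- file.path(tempdir(), "popwrite")
  pop <- generate_population("control", 2, seed = 1,
                             overrides = list(radius_mean = 18,
                                              radius_min = 16))
  write_population(pop, dir)
  expect_length(list.files(dir, pattern = "\\.tif$"), 2)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_identical(names(truth),
                   c("id", "seed", "true_condensed_fraction", "true_iod",
                     "true_nuclear_area_um2"))
})

test_that("synthetic TUNEL cells honor coverage, window and rank", {
  expect_error(generate_tunel_cell(1.5), "\\[0, 1\\]")

  neg <- generate_tunel_cell(0, seed = 1)
  expect_length(detect_spots(neg$image, neg$mask), 0)
  expect_identical(neg$truth$true_rank, "negative")

  for (cov in c(0.03, 0.2, 0.6)) {
    cell <- generate_tunel_cell(cov, seed = 42)
    expect_lt(abs(cell$truth$true_relative_area_pct - 100 * cov), 2)
    spots <- detect_spots(cell$image, cell$mask)
    # detected spots are exactly the painted ones at zero noise
    expect_equal(length(spots) / cell$mask$area_px, cov,
                 tolerance = 0.02)
    lum <- 0.299 * cell$image[, , 1][spots] +
           0.587 * cell$image[, , 2][spots] +
           0.114 * cell$image[, , 3][spots]
    expect_true(all(lum >= 60 & lum <= 100))
  }

  c1 <- generate_tunel_cell(0.25, seed = 9)
  c2 <- generate_tunel_cell(0.25, seed = 9)
  expect_identical(c1$image, c2$image)
})
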