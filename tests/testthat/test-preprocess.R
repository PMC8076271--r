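test_that("rubberband baseline removes offsets and is idempotent", {
  sp <- gaussian_spectrum(1630)
  shifted <- new_spectrum(sp$wavenumbers, sp$absorbance + 0.7,
                          mode = "synthetic")
  corrected <- baseline_correct(shifted)
  # a Gaussian's tails touch its hull, so correction recovers the band shape
  expect_equal(corrected$absorbance, baseline_correct(sp)$absorbance,
               tolerance = 1e-8)
  expect_true(min(corrected$absorbance) >= -1e-9)

  again <- baseline_correct(corrected)
  expect_equal(again$absorbance, corrected$absorbance, tolerance = 1e-9)
})

test_that("a planted linear baseline is removed to within 2% of amplitudes", {
  p <- sample_spectrum_params("oligomer", seed = 8, noise_sd = 0)
  p$baseline_coeffs <- c(0.3, 4e-3)  # steep relative to the defaults
  sp <- baseline_correct(simulate_spectrum(p))
  p$baseline_coeffs <- 0
  clean <- simulate_spectrum(p)
  for (j in seq_len(nrow(p$band_set))) {
    i <- which.min(abs(sp$wavenumbers - p$band_set$center[j]))
    expect_equal(sp$absorbance[i], clean$absorbance[i],
                 tolerance = 0.02 * p$band_set$amplitude[j])
  }
})

test_that("Amide I normalization pins the band maximum at one", {
  sp <- baseline_correct(gaussian_spectrum(1655, amplitude = 3.2))
  norm <- normalize_amide_one(sp)
  in_band <- norm$wavenumbers >= 1600 & norm$wavenumbers <= 1700
  expect_equal(max(norm$absorbance[in_band]), 1.0)
  expect_equal(normalize_amide_one(norm)$absorbance, norm$absorbance)
  flat <- new_spectrum(sp$wavenumbers, rep(0, length(sp$wavenumbers)),
                       mode = "synthetic")
  expect_error(normalize_amide_one(flat), "non-positive")
})

test_that("the Savitzky-Golay pass reproduces analytic second derivatives", {
  grid <- seq(1580, 1720, by = 1)
  a <- 3e-4
  quad <- new_spectrum(grid, a * (grid - 1650)^2 + 0.2, mode = "synthetic")
  d <- second_derivative(quad)
  interior <- 20:(length(grid) - 20)
  expect_equal(d$dii[interior], rep(2 * a, length(interior)),
               tolerance = 1e-10)

  d2 <- second_derivative(gaussian_spectrum(1630))
  expect_equal(d2$wavenumbers[which.min(d2$dii)], 1630)

  # the two-step mode (finite difference then smoothing) agrees closely
  d3 <- second_derivative(gaussian_spectrum(1630), method = "two_step")
  expect_equal(d3$wavenumbers[which.min(d3$dii)], 1630)

  expect_error(second_derivative(quad, window_pts = 30), "odd")
  expect_error(second_derivative(quad, window_pts = 301), "exceeds")
})

test_that("band positions survive noise to within 2 cm^-1 when separated", {
  hits <- 0
  for (s in 1:20) {
    p <- sample_spectrum_params("oligomer", seed = s)  # bands >= 49 apart
    sp <- normalize_amide_one(baseline_correct(simulate_spectrum(p)))
    bands <- pick_bands(second_derivative(sp))
    planted <- sort(p$band_set$center)
    found <- sort(bands$position)[seq_len(min(2, nrow(bands)))]
    hits <- hits + (nrow(bands) >= 2 && all(abs(found - planted) <= 2))
  }
  expect_gte(hits, 19)
})

test_that("aromatic exclusion removes weak ring bands, not the amide band", {
  grid <- seq(1580, 1720, by = 1)
  trace <- exp(-(grid - 1655)^2 / (2 * 81)) +
    0.12 * exp(-(grid - 1616)^2 / (2 * 16))
  sp <- new_spectrum(grid, trace, mode = "synthetic")
  dii <- second_derivative(normalize_amide_one(baseline_correct(sp)))
  with_y <- pick_bands(dii, sequence = "ALEEYT")
  expect_false(any(abs(with_y$position - 1616) <= 3))
  without_y <- pick_bands(dii, sequence = "ALEEGG")
  expect_true(any(abs(without_y$position - 1616) <= 3))

  # a dominant-depth band at an aromatic position is amide, and kept
  fib <- gaussian_spectrum(1620)
  call <- classify_spectrum(fib, sequence = "SWVIIE")
  expect_equal(call$dominant_position, 1620)
  expect_true(call$positive)
})

test_that("the pipeline is deterministic and scale-invariant", {
  p <- sample_spectrum_params("fibril", "YTVIIE", seed = 13)
  sp <- simulate_spectrum(p)
  ref <- classify_spectrum(sp, "YTVIIE")
  expect_identical(classify_spectrum(sp, "YTVIIE"), ref)
  for (k in c(0.1, 3, 100)) {
    scaled <- new_spectrum(sp$wavenumbers, k * sp$absorbance,
                           mode = "synthetic")
    expect_identical(attr(classify_spectrum(scaled, "YTVIIE"), "bands"),
                     attr(ref, "bands"))
  }
})

test_that("degenerate spectra are rejected along the pipeline", {
  grid <- seq(1580, 1720, by = 1)
  flat <- new_spectrum(grid, rep(1, length(grid)), mode = "synthetic")
  expect_error(classify_spectrum(flat))
  expect_error(new_spectrum(grid[1:30], rnorm(30)), "50 points")
  expect_error(new_spectrum(grid, rep(NaN, length(grid))), "non-finite")
})

test_that("two-column text spectra read back and average correctly", {
  sp <- gaussian_spectrum(1640)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# wavenumber absorbance",
               sprintf("%.1f, %.8f", sp$wavenumbers, sp$absorbance)), path)
  back <- read_spectrum(path)
  expect_equal(back$wavenumbers, sp$wavenumbers)
  expect_equal(back$absorbance, sp$absorbance, tolerance = 1e-7)

  avg <- average_spectra(list(sp, gaussian_spectrum(1640, amplitude = 3)))
  expect_equal(avg$absorbance, 2 * sp$absorbance)
})
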