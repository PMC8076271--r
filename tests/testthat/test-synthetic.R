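test_that("band parameters respect the class-conditional priors", {
  for (s in 1:25) {
    p <- sample_spectrum_params("fibril", seed = s)
    dom <- p$band_set[which.max(p$band_set$amplitude), ]
    expect_gte(dom$center, 1620)
    expect_lte(dom$center, 1632)

    q <- sample_spectrum_params("oligomer", seed = s)
    dom <- q$band_set[which.max(q$band_set$amplitude), ]
    minor <- q$band_set[q$band_set$center >= 1685 & q$band_set$center <= 1695, ]
    expect_equal(nrow(minor), 1L)
    expect_gte(minor$amplitude / dom$amplitude, 0.1)
    expect_lte(minor$amplitude / dom$amplitude, 0.35)

    r <- sample_spectrum_params("non_amyloid", seed = s)
    dom <- r$band_set[which.max(r$band_set$amplitude), ]
    expect_gte(dom$center, 1644)
    expect_lte(dom$center, 1682)
  }
  expect_error(sample_spectrum_params("helix"), "unknown spectrum class")
})

test_that("aromatic bands appear only for residues present in the sequence", {
  p <- sample_spectrum_params("fibril", "KPAESD", seed = 1)
  expect_equal(p$aromatic_residues, character(0))
  q <- sample_spectrum_params("fibril", "LVFYQQ", seed = 1)
  expect_setequal(q$aromatic_residues, c("F", "Y"))
  expect_true(any(abs(q$band_set$center - 1616) <= 1))
})

test_that("the forward model is analytic and reproducible", {
  grid <- seq(1580, 1720, by = 1)
  p <- sample_spectrum_params("fibril", seed = 3, noise_sd = 0)
  p$band_set <- data.frame(center = 1630, width = 5, amplitude = 1)
  p$baseline_coeffs <- 0
  sp <- simulate_spectrum(p, grid)
  expect_equal(grid[which.max(sp$absorbance)], 1630)
  expect_equal(max(sp$absorbance), 1.0, tolerance = 1e-12)

  p$band_set <- data.frame(center = c(1630, 1690), width = c(5, 4),
                           amplitude = c(1, 0.2))
  sp2 <- simulate_spectrum(p, grid)
  closed <- exp(-(grid - 1630)^2 / 50) + 0.2 * exp(-(grid - 1690)^2 / 32)
  expect_equal(sp2$absorbance, closed, tolerance = 1e-12)

  q <- sample_spectrum_params("oligomer", seed = 11)
  expect_identical(simulate_spectrum(q)$absorbance,
                   simulate_spectrum(q)$absorbance)

  expect_error(simulate_spectrum(q, seq(1600, 1700, 1)), "cover")
  expect_error(simulate_spectrum(q, rev(grid)), "increasing")
})

test_that("label noise is planted at the configured rate", {
  cfg <- label_noise_config(n_peptides = 200, flip_rate = 0, seed = 4)
  d <- simulate_peptide_dataset(cfg)
  expect_identical(d$observed_label, d$true_label)
  expect_false(any(d$flipped))

  cfg <- label_noise_config(n_peptides = 1000, flip_rate = 0.1, seed = 5)
  d <- simulate_peptide_dataset(cfg)
  ci <- stats::qbinom(c(0.005, 0.995), 1000, 0.1) / 1000
  expect_gte(mean(d$flipped), ci[1])
  expect_lte(mean(d$flipped), ci[2])
  # flips invert the observed label exactly where indicated
  expect_identical(d$observed_label != d$true_label, d$flipped)

  expect_error(label_noise_config(flip_rate = 0.5), "noise exceeds")
  expect_error(label_noise_config(n_peptides = 5), "n_peptides")
})

test_that("rule strength 0 decouples labels from composition", {
  d <- simulate_peptide_dataset(
    label_noise_config(n_peptides = 2000, flip_rate = 0, rule_strength = 0,
                       seed = 6))
  # class balance near a coin flip and no score separation between classes
  expect_lt(abs(mean(d$true_label == "amyloid") - 0.5), 0.05)
  gap <- mean(d$score[d$true_label == "amyloid"]) -
    mean(d$score[d$true_label == "non_amyloid"])
  expect_lt(abs(gap), 0.1)
  # under a strong rule the same gap is large
  d2 <- simulate_peptide_dataset(
    label_noise_config(n_peptides = 2000, flip_rate = 0, rule_strength = 8,
                       seed = 6))
  gap2 <- mean(d2$score[d2$true_label == "amyloid"]) -
    mean(d2$score[d2$true_label == "non_amyloid"])
  expect_gt(gap2, 1)
})

test_that("the planted rule and its Bayes decision are consistent", {
  seqs <- c("ILVVIF", "DEKNSQ", "FNPQGG")
  s <- planted_rule_score(seqs)
  expect_gt(s[1], 0)  # aliphatic, beta-prone
  expect_lt(s[2], 0)  # charged / polar
  expect_identical(planted_rule_bayes(seqs), ifelse(s > 0, "amyloid",
                                                    "non_amyloid"))
  expect_error(planted_rule_score("FNPXGG"), "non-standard")
})
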