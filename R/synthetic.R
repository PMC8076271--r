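# Per-residue scales behind the planted true-label rule.
# Kyte-Doolittle hydropathy and Chou-Fasman beta-sheet propensity.
.amylir_kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                Y = -1.3, V = 4.2)
.amylir_cf_beta <- c(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
                     Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
                     L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
                     S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70)

.planted_weights <- function() {
  w <- 0.5 * scale(.amylir_kd)[, 1] + 0.5 * scale(.amylir_cf_beta)[, 1]
  names(w) <- names(.amylir_kd)
  w
}

#' Planted aggregation-propensity score of a hexapeptide
#'
#' The synthetic-label generator plants amyloidogenicity as a per-residue
#' composition score: the average of z-scored Kyte-Doolittle hydropathy and
#' Chou-Fasman beta-sheet propensity, summed over residues and standardized so
#' the score of a uniformly random hexapeptide is approximately standard
#' normal. The score (and the Bayes decision `score > 0`, see
#' [planted_rule_bayes()]) is exported so tests can evaluate the filter against
#' the generator independently of any fitted model.
#'
#' @param sequences character vector of peptide sequences.
#' @return numeric score vector (positive = aggregation-prone).
#' @export
#' @examples
#' planted_rule_score(c("ILVVIF", "DEKNSQ"))
planted_rule_score <- function(sequences) {
  w <- .planted_weights()
  sd_w <- sd(w) * sqrt((length(w) - 1) / length(w))
  vapply(strsplit(toupper(sequences), ""), function(res) {
    if (!all(res %in% names(w))) {
      stop("non-standard residue in sequence")
    }
    sum(w[res]) / (sd_w * sqrt(length(res)))
  }, numeric(1))
}

#' Bayes decision of the planted label rule
#'
#' @param sequences character vector of peptide sequences.
#' @return character vector, "amyloid" where [planted_rule_score()] exceeds 0,
#'   else "non_amyloid".
#' @export
planted_rule_bayes <- function(sequences) {
  ifelse(planted_rule_score(sequences) > 0, "amyloid", "non_amyloid")
}

#' Draw uniformly random hexapeptide sequences
#'
#' @param n number of sequences (drawn from the current RNG stream).
#' @return character vector of length `n`.
#' @export
random_hexapeptides <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(.amylir_aa, 6, replace = TRUE), collapse = "")
  }, character(1))
}

#' Configuration of a label-noise peptide dataset
#'
#' @param n_peptides number of hexapeptides (>= 10). Default 400, a size at
#'   which the out-of-fold filter is comfortably learnable while the whole
#'   noise experiment stays desk-scale.
#' @param flip_rate probability epsilon in `[0, 0.5)` that an observed label is
#'   flipped relative to the true label.
#' @param rule_strength separability of the planted rule: the true label is
#'   amyloid with probability `plogis(rule_strength * score)`. 0 gives labels
#'   independent of sequence (coin flips); the default 8 is a strong rule with
#'   a small intrinsic Bayes error.
#' @param seed integer seed; the dataset is deterministic given the config.
#' @return a `label_noise_config` list.
#' @export
label_noise_config <- function(n_peptides = 400, flip_rate = 0.1,
                               rule_strength = 8, seed = 1) {
  stopifnot(n_peptides >= 10, rule_strength >= 0)
  if (flip_rate < 0 || flip_rate >= 0.5) {
    stop("flip_rate must lie in [0, 0.5): at 0.5 the noise exceeds the signal")
  }
  structure(list(n_peptides = as.integer(n_peptides), flip_rate = flip_rate,
                 rule_strength = rule_strength, seed = as.integer(seed)),
            class = "label_noise_config")
}

#' Simulate a weakly labeled hexapeptide dataset
#'
#' Sequences are drawn uniformly over hexapeptides; the hidden true label
#' follows the planted composition rule at the configured strength; the
#' observed label flips the true label independently with probability
#' `flip_rate`. The flip indicator is retained as ground truth for evaluating
#' label-noise filters.
#'
#' @param config a [label_noise_config()].
#' @return data frame with columns `id`, `sequence`, `score`, `true_label`,
#'   `observed_label`, `flipped`, `origin`, `subset`.
#' @export
#' @examples
#' head(simulate_peptide_dataset(label_noise_config(n_peptides = 20)))
simulate_peptide_dataset <- function(config) {
  stopifnot(inherits(config, "label_noise_config"))
  set.seed(config$seed)
  seqs <- random_hexapeptides(config$n_peptides)
  score <- planted_rule_score(seqs)
  p_amy <- plogis(config$rule_strength * score)
  true <- ifelse(runif(config$n_peptides) < p_amy, "amyloid", "non_amyloid")
  flipped <- runif(config$n_peptides) < config$flip_rate
  observed <- ifelse(flipped,
                     ifelse(true == "amyloid", "non_amyloid", "amyloid"),
                     true)
  data.frame(id = sprintf("pep%04d", seq_len(config$n_peptides)),
             sequence = seqs, score = score, true_label = true,
             observed_label = observed, flipped = flipped,
             origin = "synthetic", subset = "none", stringsAsFactors = FALSE)
}

#' Sample class-conditional Amide I band parameters
#'
#' Encodes the band-position priors of the three structural classes:
#' * fibril: dominant cross-beta band drawn in 1620-1632 cm^-1 (the amyloid
#'   window reaches down to 1611 but maxima sit close to 1630), with an
#'   optional weak high-frequency companion in 1685-1695;
#' * oligomer: dominant band in 1628-1636 plus a mandatory antiparallel
#'   beta-sheet band in 1685-1695 at roughly one fifth of the dominant
#'   amplitude (ratio drawn in 0.1-0.35);
#' * non_amyloid: one band from the alpha-helix (1650-1660, broad), disordered
#'   (1644-1649) or turn / high-frequency (1660-1682) families.
#'
#' Weak aromatic ring bands at 1600 (Phe), 1616 (Tyr) and 1620 (Trp) cm^-1 are
#' added only when the corresponding residue occurs in `sequence`.
#'
#' @param true_class "fibril", "oligomer" or "non_amyloid".
#' @param sequence peptide sequence used for the aromatic bands; "" for none.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param noise_sd Gaussian noise level in absorbance units; the default 0.01
#'   is 1% of the unit-normalized dominant amplitude.
#' @return a `spectrum_params` list: `true_class`, `band_set` (data frame with
#'   `center`, `width`, `amplitude`), `baseline_coeffs` (intercept and slope of
#'   a linear baseline in `nu - 1650`), `noise_sd`, `aromatic_residues`,
#'   `seed`.
#' @export
#' @examples
#' sample_spectrum_params("fibril", "YTVIIE", seed = 1)
sample_spectrum_params <- function(true_class, sequence = "", seed = NULL,
                                   noise_sd = 0.01) {
  if (!is.character(true_class) || length(true_class) != 1 ||
      !true_class %in% .amylir_classes) {
    stop("unknown spectrum class '", paste(true_class, collapse = ","), "'")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  bands <- switch(true_class,
    fibril = {
      b <- data.frame(center = runif(1, 1620, 1632), width = runif(1, 4, 7),
                      amplitude = 1)
      if (runif(1) < 0.7) {
        b <- rbind(b, data.frame(center = runif(1, 1685, 1695),
                                 width = runif(1, 4, 6),
                                 amplitude = runif(1, 0.1, 0.35)))
      }
      b
    },
    oligomer = rbind(
      data.frame(center = runif(1, 1628, 1636), width = runif(1, 4, 7),
                 amplitude = 1),
      data.frame(center = runif(1, 1685, 1695), width = runif(1, 4, 6),
                 amplitude = runif(1, 0.1, 0.35))),
    non_amyloid = switch(sample(c("alpha", "disordered", "turn"), 1),
      alpha = data.frame(center = runif(1, 1650, 1660),
                         width = runif(1, 8, 12), amplitude = 1),
      disordered = data.frame(center = runif(1, 1644, 1649),
                              width = runif(1, 6, 9), amplitude = 1),
      turn = data.frame(center = runif(1, 1660, 1682),
                        width = runif(1, 5, 9), amplitude = 1)))
  aromatics <- names(.amylir_aromatic)[
    vapply(names(.amylir_aromatic), grepl, logical(1), x = toupper(sequence),
           fixed = TRUE)]
  for (res in aromatics) {
    bands <- rbind(bands,
                   data.frame(center = .amylir_aromatic[[res]] + runif(1, -1, 1),
                              width = runif(1, 2.5, 3.5),
                              amplitude = runif(1, 0.03, 0.08)))
  }
  structure(list(true_class = true_class, band_set = bands,
                 baseline_coeffs = c(runif(1, 0, 0.05), runif(1, -2e-4, 2e-4)),
                 noise_sd = noise_sd, aromatic_residues = aromatics,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "spectrum_params")
}

#' Simulate an Amide I spectrum from band parameters
#'
#' Forward model: a sum of Gaussian component bands plus a polynomial baseline
#' (in `nu - 1650`) plus i.i.d. Gaussian noise. Gaussian band shapes preserve
#' the property the pipeline relies on — the second derivative attains its
#' minimum at the band center.
#'
#' @param params a `spectrum_params` object from [sample_spectrum_params()].
#' @param grid strictly increasing wavenumber grid covering 1580-1720 cm^-1;
#'   default 1 cm^-1 spacing.
#' @return an `amide_spectrum` (see [new_spectrum()]) with mode "synthetic".
#' @export
#' @examples
#' sp <- simulate_spectrum(sample_spectrum_params("fibril", seed = 1))
#' range(sp$wavenumbers)
simulate_spectrum <- function(params, grid = seq(1580, 1720, by = 1)) {
  stopifnot(inherits(params, "spectrum_params"))
  if (any(diff(grid) <= 0)) {
    stop("wavenumber grid must be strictly increasing")
  }
  if (min(grid) > 1580 || max(grid) < 1720) {
    stop("grid must cover the supported Amide I window [1580, 1720] cm^-1")
  }
  trace <- rowSums(vapply(seq_len(nrow(params$band_set)), function(j) {
    b <- params$band_set[j, ]
    b$amplitude * exp(-(grid - b$center)^2 / (2 * b$width^2))
  }, numeric(length(grid))))
  x <- grid - 1650
  baseline <- rowSums(vapply(seq_along(params$baseline_coeffs), function(k) {
    params$baseline_coeffs[k] * x^(k - 1)
  }, numeric(length(grid))))
  if (!is.na(params$seed)) {
    set.seed((params$seed + 1L) %% .Machine$integer.max)
  }
  noise <- if (params$noise_sd > 0) {
    stats::rnorm(length(grid), 0, params$noise_sd)
  } else {
    0
  }
  new_spectrum(grid, trace + baseline + noise, mode = "synthetic")
}

#' Generate a seeded panel of synthetic spectra with known classes
#'
#' Convenience wrapper used throughout the tests and the chemometrics
#' examples: draws random hexapeptides, assigns structural classes, samples
#' band parameters and simulates one spectrum per peptide.
#'
#' @param n panel size.
#' @param seed integer seed.
#' @param classes class pool sampled uniformly; recycle to force a fixed
#'   composition (e.g. `rep(c("fibril","non_amyloid"), 20)` for a balanced
#'   40-spectrum panel).
#' @param noise_sd noise level passed to [sample_spectrum_params()].
#' @return list with `records` (data frame: `id`, `sequence`, `true_class`,
#'   `positive`), `params` (list of `spectrum_params`, exposing the planted
#'   band centers) and `spectra` (list of `amide_spectrum`).
#' @export
spectrum_panel <- function(n, seed = 1,
                           classes = .amylir_classes, noise_sd = 0.01) {
  set.seed(as.integer(seed))
  cls <- if (length(classes) == n) classes else sample(classes, n, replace = TRUE)
  seqs <- random_hexapeptides(n)
  seeds <- sample.int(2^30, n)
  params <- lapply(seq_len(n), function(i) {
    sample_spectrum_params(cls[i], seqs[i], seed = seeds[i],
                           noise_sd = noise_sd)
  })
  spectra <- lapply(params, simulate_spectrum)
  list(records = data.frame(id = sprintf("syn%04d", seq_len(n)),
                            sequence = seqs, true_class = cls,
                            positive = cls != "non_amyloid",
                            stringsAsFactors = FALSE),
       params = params, spectra = spectra)
}
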