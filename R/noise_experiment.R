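#' Run one weak-label filtering experiment
#'
#' End-to-end simulation of label-noise filtering with spectroscopic
#' adjudication: a weakly labeled hexapeptide dataset is generated
#' ([simulate_peptide_dataset()]), out-of-fold amyloid probabilities are
#' fitted on the observed (noisy) labels ([oof_probabilities()]), and records
#' the model confidently contradicts are flagged as outliers
#' ([select_outliers()]). Each flagged peptide is then adjudicated the way a
#' wet-lab follow-up would be: a spectrum is simulated from its HIDDEN true
#' class (fibril or oligomer for true amyloids, a non-amyloid family
#' otherwise) and classified through the same band-rule path as real spectra.
#'
#' Filter precision is the fraction of flagged records whose observed label
#' was actually flipped; enrichment is precision divided by the flip rate, so
#' values above 1 mean the filter beats random flagging.
#'
#' @param config a [label_noise_config()].
#' @param tau outlier confidence threshold, see [select_outliers()].
#' @param k_folds folds for out-of-fold scoring.
#' @param seed seed for model fitting and adjudication; defaults to the
#'   config seed.
#' @param adjudication_noise_sd noise level of the adjudication spectra.
#' @return a `noise_experiment` list: `flip_rate`, `threshold`, `n`,
#'   `n_flagged`, `filter_precision` (NA when nothing is flagged),
#'   `filter_recall`, `enrichment`, `adjudication_agreement`, `seed`, and the
#'   flagged record table.
#' @export
#' @examples
#' run_noise_experiment(label_noise_config(n_peptides = 60, seed = 2),
#'                      tau = 0.8, k_folds = 3)
run_noise_experiment <- function(config, tau = 0.9, k_folds = 5,
                                 seed = config$seed,
                                 adjudication_noise_sd = 0.01) {
  stopifnot(inherits(config, "label_noise_config"))
  records <- simulate_peptide_dataset(config)
  probs <- oof_probabilities(records, k_folds = k_folds, seed = seed)
  flagged <- select_outliers(records, probs, tau = tau)
  n_flagged <- nrow(flagged)
  precision <- if (n_flagged > 0) mean(flagged$flipped) else NA_real_
  recall <- if (sum(records$flipped) > 0) {
    sum(flagged$flipped) / sum(records$flipped)
  } else {
    NA_real_
  }
  enrichment <- if (config$flip_rate > 0 && !is.na(precision)) {
    precision / config$flip_rate
  } else {
    NA_real_
  }
  agreement <- NA_real_
  if (n_flagged > 0) {
    set.seed((seed + 104729L) %% .Machine$integer.max)
    spec_seeds <- sample.int(2^30, n_flagged)
    subtype <- ifelse(flagged$true_label == "amyloid",
                      ifelse(runif(n_flagged) < 0.7, "fibril", "oligomer"),
                      "non_amyloid")
    adjudicated <- vapply(seq_len(n_flagged), function(i) {
      sp <- simulate_spectrum(sample_spectrum_params(
        subtype[i], flagged$sequence[i], seed = spec_seeds[i],
        noise_sd = adjudication_noise_sd))
      classify_spectrum(sp, sequence = flagged$sequence[i])$positive
    }, logical(1))
    agreement <- mean(adjudicated == (flagged$true_label == "amyloid"))
  }
  structure(list(flip_rate = config$flip_rate, threshold = tau,
                 n = config$n_peptides, n_flagged = n_flagged,
                 filter_precision = precision, filter_recall = recall,
                 enrichment = enrichment,
                 adjudication_agreement = agreement, seed = seed,
                 flagged = flagged),
            class = "noise_experiment")
}

#' @export
print.noise_experiment <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf(
    "<noise_experiment> eps=%.2f tau=%.2f n=%d: flagged %d, precision %s, recall %s, enrichment %s, adjudication %s\n",
    x$flip_rate, x$threshold, x$n, x$n_flagged, fmt(x$filter_precision),
    fmt(x$filter_recall), fmt(x$enrichment), fmt(x$adjudication_agreement)))
  invisible(x)
}

#' Sweep flip rates and thresholds over replicated noise experiments
#'
#' Cartesian sweep of `flip_rates` x `thresholds` x replicates, each cell
#' with its own derived seed stream.
#'
#' @param flip_rates numeric grid of label-flip rates.
#' @param thresholds numeric grid of outlier thresholds.
#' @param replicates experiments per cell.
#' @param n_peptides,rule_strength dataset settings, see
#'   [label_noise_config()].
#' @param k_folds folds for out-of-fold scoring.
#' @param seed master seed; one derived seed per (flip rate, replicate) pair,
#'   shared across the threshold grid so that, within a replicate, the same
#'   dataset and probabilities are thresholded at every tau (making
#'   `n_flagged` non-increasing in tau).
#' @return tidy long-format data frame, one row per experiment, with the
#'   scalar fields of [run_noise_experiment()] plus `replicate`.
#' @export
noise_sweep <- function(flip_rates = c(0.05, 0.1, 0.2, 0.3),
                        thresholds = c(0.7, 0.8, 0.9), replicates = 10,
                        n_peptides = 400, rule_strength = 8, k_folds = 5,
                        seed = 1) {
  datasets <- expand.grid(flip_rate = flip_rates,
                          replicate = seq_len(replicates))
  set.seed(as.integer(seed))
  datasets$seed <- sample.int(2^30, nrow(datasets))
  cells <- merge(datasets, data.frame(threshold = thresholds))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- label_noise_config(n_peptides = n_peptides,
                              flip_rate = cells$flip_rate[i],
                              rule_strength = rule_strength,
                              seed = cells$seed[i])
    res <- run_noise_experiment(cfg, tau = cells$threshold[i],
                                k_folds = k_folds, seed = cells$seed[i])
    data.frame(flip_rate = res$flip_rate, threshold = res$threshold,
               replicate = cells$replicate[i], n = res$n,
               n_flagged = res$n_flagged,
               filter_precision = res$filter_precision,
               filter_recall = res$filter_recall,
               enrichment = res$enrichment,
               adjudication_agreement = res$adjudication_agreement,
               seed = res$seed)
  })
  do.call(rbind, rows)
}
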