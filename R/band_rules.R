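#' Amide I decision-rule thresholds
#'
#' Position windows behind the fibril / oligomer / non-amyloid calls:
#'
#' * `fibril_window`: dominant-band window of amyloid cross-beta structure.
#'   The literature quotes 1611-1630 cm^-1 with maxima "usually close to
#'   1630"; the upper edge defaults to 1632 because adjudicated amyloid
#'   spectra in the packaged panel place dominant maxima at 1631 and 1632.
#' * `native_beta_upper`: upper edge (1643) of the native beta-sheet region
#'   that begins where the fibril window ends; a dominant band there is
#'   amyloid-positive only with oligomer evidence.
#' * `oligomer_minor_window`: the weak antiparallel beta-sheet companion band,
#'   nominally 1685-1695; the lower edge defaults to 1684, where the packaged
#'   panel still shows an amyloid-positive minor band, while 1679-1681 minors
#'   belong to negative spectra.
#' * `oligomer_ratio_max`: advisory bound on the minor/dominant amplitude
#'   ratio (the companion band is roughly five-fold weaker); used for evidence
#'   flags only, because band tables carry grades, not amplitudes.
#'
#' @param fibril_window numeric length-2, default `c(1611, 1632)`.
#' @param native_beta_upper scalar, default 1643.
#' @param oligomer_minor_window numeric length-2, default `c(1684, 1695)`.
#' @param oligomer_ratio_max scalar, default 0.35.
#' @return a `rule_config` list.
#' @export
rule_config <- function(fibril_window = c(1611, 1632),
                        native_beta_upper = 1643,
                        oligomer_minor_window = c(1684, 1695),
                        oligomer_ratio_max = 0.35) {
  stopifnot(length(fibril_window) == 2, diff(fibril_window) > 0,
            length(oligomer_minor_window) == 2,
            diff(oligomer_minor_window) > 0,
            native_beta_upper > fibril_window[2])
  structure(list(fibril_window = as.numeric(fibril_window),
                 native_beta_upper = as.numeric(native_beta_upper),
                 oligomer_minor_window = as.numeric(oligomer_minor_window),
                 oligomer_ratio_max = as.numeric(oligomer_ratio_max)),
            class = "rule_config")
}

#' Classify a band table into fibril / oligomer / non-amyloid
#'
#' Rule order, with `d` the dominant-band position:
#' 1. `d` inside the fibril window: fibril, amyloid-positive. A non-dominant
#'    band inside the oligomer minor window additionally fires an
#'    oligomer-consistent evidence flag.
#' 2. otherwise, `d` in the native beta-sheet region (fibril upper edge to
#'    `native_beta_upper`] AND some non-dominant band inside the oligomer
#'    minor window: oligomer, amyloid-positive.
#' 3. otherwise non-amyloid, negative.
#'
#' Aromatic bands are assumed already excluded (see [pick_bands()]).
#'
#' @param bands a `band_table` with exactly one dominant band.
#' @param config a [rule_config()].
#' @return a `spectral_call` list: `subtype`, `positive`, `dominant_position`,
#'   `evidence` (character vector of fired rules).
#' @export
#' @examples
#' classify_bands(parse_band_string("1685(m)/1633(s)*"))  # oligomer
#' classify_bands(parse_band_string("1629(s)*"))          # fibril
#' classify_bands(parse_band_string("1655(s,br)*"))       # non-amyloid
classify_bands <- function(bands, config = rule_config()) {
  stopifnot(inherits(config, "rule_config"))
  if (!is.data.frame(bands) || nrow(bands) == 0) {
    stop("empty band list")
  }
  n_dom <- sum(bands$dominant)
  if (n_dom != 1) {
    stop("band list must have exactly one dominant band, found ", n_dom)
  }
  d <- bands$position[bands$dominant]
  minors <- bands$position[!bands$dominant]
  minor_in_window <- any(minors >= config$oligomer_minor_window[1] &
                           minors <= config$oligomer_minor_window[2])
  evidence <- character(0)
  if (d >= config$fibril_window[1] && d <= config$fibril_window[2]) {
    subtype <- "fibril"
    evidence <- c(evidence, "dominant_in_fibril_window")
    if (minor_in_window) {
      evidence <- c(evidence, "oligomer_consistent_minor")
    }
  } else if (d > config$fibril_window[2] && d <= config$native_beta_upper &&
             minor_in_window) {
    subtype <- "oligomer"
    evidence <- c(evidence, "dominant_in_native_beta_region",
                  "minor_in_oligomer_window")
  } else {
    subtype <- "non_amyloid"
    evidence <- c(evidence, "dominant_outside_amyloid_windows")
  }
  structure(list(subtype = subtype, positive = subtype != "non_amyloid",
                 dominant_position = d, evidence = evidence),
            class = "spectral_call")
}

#' @export
print.spectral_call <- function(x, ...) {
  cat(sprintf("<spectral_call> %s (%s), dominant %g cm^-1 [%s]\n", x$subtype,
              if (x$positive) "amyloid-positive" else "negative",
              x$dominant_position, paste(x$evidence, collapse = ", ")))
  invisible(x)
}

#' Classify a raw spectrum end to end
#'
#' Full pipeline: baseline correction, Amide I normalization, Savitzky-Golay
#' second derivative, band picking with aromatic exclusion, band rules. Fully
#' deterministic: identical input yields identical bands and call.
#'
#' @param spectrum an `amide_spectrum`.
#' @param sequence peptide sequence (for aromatic exclusion); "" disables it.
#' @param config a [rule_config()].
#' @param baseline baseline method, see [baseline_correct()].
#' @param window_pts,polyorder Savitzky-Golay settings, see
#'   [second_derivative()].
#' @param prominence band-picking threshold, see [pick_bands()].
#' @return a `spectral_call`; the picked `band_table` is attached as attribute
#'   `"bands"`.
#' @export
#' @examples
#' sp <- simulate_spectrum(sample_spectrum_params("oligomer", seed = 7))
#' classify_spectrum(sp)
classify_spectrum <- function(spectrum, sequence = "", config = rule_config(),
                              baseline = "rubberband", window_pts = 31,
                              polyorder = 2, prominence = 0.1) {
  sp <- baseline_correct(spectrum, method = baseline)
  sp <- normalize_amide_one(sp)
  dii <- second_derivative(sp, window_pts = window_pts, polyorder = polyorder)
  bands <- pick_bands(dii, sequence = sequence, prominence = prominence)
  call <- classify_bands(bands, config = config)
  attr(call, "bands") <- bands
  call
}
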