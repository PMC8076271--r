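# Toy three-group alphabet used in encoding tests: hydrophobic -> H,
# polar/special -> P, charged -> C.
toy_alphabet <- function() {
  new_reduced_alphabet(c(
    A = "H", I = "H", L = "H", M = "H", V = "H", F = "H", W = "H", Y = "H",
    N = "P", Q = "P", S = "P", T = "P", C = "P", G = "P",
    P = "P", D = "C", E = "C", H = "C", K = "C", R = "C"), "toy3")
}

# Binary band-rule calls for one band-string column of a set fixture.
fixture_binary_calls <- function(fixture, mode) {
  vapply(fixture[[paste0(mode, "_bands")]], function(s) {
    classify_bands(parse_band_string(s))$positive
  }, logical(1), USE.NAMES = FALSE)
}

# Noise-free single-Gaussian spectrum on the default grid.
gaussian_spectrum <- function(center, width = 5, amplitude = 1,
                              grid = seq(1580, 1720, by = 1)) {
  new_spectrum(grid, amplitude * exp(-(grid - center)^2 / (2 * width^2)),
               mode = "synthetic")
}
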