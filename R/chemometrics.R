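#' PCA on second-derivative spectra
#'
#' Mean-centered (unscaled) principal component analysis over the 1580-1720
#' cm^-1 DII window, one observation per spectrum. Each component is oriented
#' so its largest-magnitude loading is positive, making score plots
#' reproducible; scores are otherwise defined up to per-component sign.
#'
#' @param spectra list of `dii_spectrum` objects on a common grid (>= 3).
#' @param n_components number of components to keep (<= rank).
#' @param labels optional per-spectrum class labels, carried for plotting and
#'   scoring.
#' @return a `dii_pca` list: `scores` (spectra x components),
#'   `explained_variance_fraction`, `loadings` (wavenumbers x components),
#'   `labels`, `wavenumbers`.
#' @export
#' @examples
#' panel <- spectrum_panel(12, seed = 3, classes = rep(c("fibril", "non_amyloid"), 6))
#' dii <- lapply(panel$spectra, second_derivative)
#' pca <- pca_on_dii(dii, 2, labels = panel$records$true_class)
#' pca$explained_variance_fraction
pca_on_dii <- function(spectra, n_components = 2, labels = NULL) {
  stopifnot(length(spectra) >= 3,
            all(vapply(spectra, inherits, logical(1), "dii_spectrum")))
  grid <- spectra[[1]]$wavenumbers
  for (sp in spectra) {
    if (!isTRUE(all.equal(sp$wavenumbers, grid))) {
      stop("mismatched wavenumber grids across spectra")
    }
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(spectra))
  }
  x <- t(vapply(spectra, `[[`, numeric(length(grid)), "dii"))
  total_var <- sum(apply(x, 2, stats::var))
  if (total_var <= .Machine$double.eps) {
    stop("zero variance across spectra; PCA undefined")
  }
  rank <- qr(scale(x, center = TRUE, scale = FALSE))$rank
  if (n_components > rank) {
    stop("n_components (", n_components, ") exceeds data rank (", rank, ")")
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  scores <- p$x[, k, drop = FALSE]
  loadings <- p$rotation[, k, drop = FALSE]
  for (j in k) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- format(grid)
  structure(list(scores = scores,
                 explained_variance_fraction = p$sdev[k]^2 / sum(p$sdev^2),
                 loadings = loadings, labels = labels, wavenumbers = grid),
            class = "dii_pca")
}

#' Class-separation score in PCA space
#'
#' Mean silhouette width of the class labels computed on the first
#' `k_components` score dimensions — a quantitative stand-in for the visual
#' cluster separation usually read off score plots. Values near 1 indicate
#' well-separated classes, near 0 no structure, negative values mixing.
#'
#' @param result a `dii_pca` with labels, or pass `labels` explicitly.
#' @param k_components number of leading score dimensions, default 2.
#' @param labels optional override of `result$labels`.
#' @return mean silhouette width in \[-1, 1\].
#' @export
separation_score <- function(result, k_components = 2, labels = NULL) {
  stopifnot(inherits(result, "dii_pca"))
  if (is.null(labels)) {
    labels <- result$labels
  }
  if (is.null(labels)) {
    stop("no class labels available")
  }
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2) {
    stop("need at least two classes for a separation score")
  }
  k <- min(k_components, ncol(result$scores))
  sil <- cluster::silhouette(cl, dist(result$scores[, seq_len(k),
                                                    drop = FALSE]))
  mean(sil[, "sil_width"])
}
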