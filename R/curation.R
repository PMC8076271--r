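#' Reduced amino-acid alphabets
#'
#' A reduced alphabet maps each of the 20 standard letters onto a group
#' symbol; sequences identical after reduction are treated as redundant and
#' n-gram features are counted over the group symbols. The default `"hydro6"`
#' alphabet is a six-group physicochemical surrogate (aliphatic hydrophobic,
#' aromatic, polar, positive, negative, special) — a stand-in for published
#' predictor-specific alphabets, which are not reprinted here.
#'
#' @param name `"hydro6"` or `"identity"`.
#' @return a `reduced_alphabet`: list with `mapping` (named character over the
#'   20 letters) and `name`.
#' @export
#' @examples
#' reduced_alphabet()$mapping[c("L", "F", "D")]
reduced_alphabet <- function(name = c("hydro6", "identity")) {
  name <- match.arg(name)
  mapping <- switch(name,
    hydro6 = c(A = "A", I = "A", L = "A", M = "A", V = "A",
               F = "B", W = "B", Y = "B",
               N = "C", Q = "C", S = "C", T = "C",
               H = "D", K = "D", R = "D",
               D = "E", E = "E",
               C = "F", G = "F", P = "F"),
    identity = stats::setNames(.amylir_aa, .amylir_aa))
  new_reduced_alphabet(mapping, name)
}

#' Construct a reduced alphabet from an explicit mapping
#'
#' @param mapping named character vector: every one of the 20 standard letters
#'   to a group symbol.
#' @param name label for the alphabet.
#' @return a `reduced_alphabet`.
#' @export
new_reduced_alphabet <- function(mapping, name = "custom") {
  if (!setequal(names(mapping), .amylir_aa)) {
    stop("mapping must cover exactly the 20 standard amino-acid letters")
  }
  structure(list(mapping = mapping[.amylir_aa], name = name),
            class = "reduced_alphabet")
}

#' Read a reduced alphabet from a two-column TSV (letter, group)
#'
#' @param path TSV file with columns `letter` and `group`.
#' @param name label for the alphabet; default the file name.
#' @return a `reduced_alphabet`.
#' @export
read_alphabet <- function(path, name = basename(path)) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("letter", "group") %in% names(tab)))
  new_reduced_alphabet(stats::setNames(as.character(tab$group),
                                       toupper(tab$letter)), name)
}

#' Encode a sequence in a reduced alphabet
#'
#' @param sequence peptide sequence.
#' @param alphabet a `reduced_alphabet`.
#' @return the position-wise encoded string, same length.
#' @export
#' @examples
#' encode_reduced("LVFYQQ", reduced_alphabet())
encode_reduced <- function(sequence, alphabet = reduced_alphabet()) {
  stopifnot(inherits(alphabet, "reduced_alphabet"))
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!all(res %in% names(alphabet$mapping))) {
    stop("letter outside the alphabet mapping in '", sequence, "'")
  }
  paste(alphabet$mapping[res], collapse = "")
}

#' Remove sequences redundant under a reduced alphabet
#'
#' Keeps one representative per (encoded form, label) pair. Encoded forms
#' shared by records of conflicting labels are ambiguous supervision: those
#' groups are dropped from both classes and reported.
#'
#' @param records peptide record data frame with `sequence` and a label column
#'   (`db_label` or `observed_label`).
#' @param alphabet a `reduced_alphabet`.
#' @return list with `records` (deduplicated, plus an `encoded` column) and
#'   `conflicts` (data frame: `encoded`, `n_records`, `labels`).
#' @export
deduplicate_encoded <- function(records, alphabet = reduced_alphabet()) {
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  label_col <- intersect(c("db_label", "observed_label"), names(records))[1]
  if (is.na(label_col)) {
    stop("records need a db_label or observed_label column")
  }
  if (nrow(records) == 0) {
    return(list(records = records,
                conflicts = data.frame(encoded = character(0),
                                       n_records = integer(0),
                                       labels = character(0))))
  }
  records$encoded <- vapply(records$sequence, encode_reduced, character(1),
                            alphabet = alphabet)
  groups <- split(seq_len(nrow(records)), records$encoded)
  conflict_rows <- lapply(names(groups), function(enc) {
    labs <- unique(records[[label_col]][groups[[enc]]])
    if (length(labs) > 1) {
      data.frame(encoded = enc, n_records = length(groups[[enc]]),
                 labels = paste(sort(labs), collapse = "+"),
                 stringsAsFactors = FALSE)
    }
  })
  conflicts <- do.call(rbind, conflict_rows)
  if (is.null(conflicts)) {
    conflicts <- data.frame(encoded = character(0), n_records = integer(0),
                            labels = character(0))
  }
  keep <- !duplicated(records[c("encoded", label_col)]) &
    !(records$encoded %in% conflicts$encoded)
  list(records = records[keep, , drop = FALSE], conflicts = conflicts)
}

#' N-gram count features of one sequence
#'
#' Counts all contiguous n-grams, n = 1..`max_n`, of the reduced encoding,
#' over the full gram space of the alphabet in a fixed ordering (by n, then
#' lexicographic), zeros included — so feature vectors of different sequences
#' align.
#'
#' @param sequence peptide sequence.
#' @param alphabet a `reduced_alphabet`.
#' @param max_n largest n-gram length; must not exceed the sequence length.
#' @return named integer vector of n-gram counts.
#' @export
#' @examples
#' ngram_features("LVFYQQ", max_n = 2)[c("A", "AA", "AB")]
ngram_features <- function(sequence, alphabet = reduced_alphabet(),
                           max_n = 2) {
  enc <- encode_reduced(sequence, alphabet)
  if (max_n < 1 || max_n > nchar(enc)) {
    stop("max_n must be between 1 and the sequence length")
  }
  symbols <- sort(unique(alphabet$mapping))
  space <- unlist(lapply(seq_len(max_n), function(n) {
    grid <- expand.grid(rep(list(symbols), n), stringsAsFactors = FALSE)
    sort(apply(grid, 1, paste, collapse = ""))
  }))
  counts <- stats::setNames(integer(length(space)), space)
  chars <- strsplit(enc, "")[[1]]
  for (n in seq_len(max_n)) {
    for (i in seq_len(length(chars) - n + 1)) {
      g <- paste(chars[i:(i + n - 1)], collapse = "")
      counts[g] <- counts[g] + 1L
    }
  }
  counts
}

#' N-gram feature matrix for a set of sequences
#'
#' @param sequences character vector.
#' @param alphabet a `reduced_alphabet`.
#' @param max_n largest n-gram length.
#' @return integer matrix, one row per sequence.
#' @export
ngram_feature_matrix <- function(sequences, alphabet = reduced_alphabet(),
                                 max_n = 2) {
  t(vapply(sequences, ngram_features,
           ngram_features(sequences[1], alphabet, max_n),
           alphabet = alphabet, max_n = max_n))
}

#' Out-of-fold amyloid probabilities from a tree-ensemble surrogate
#'
#' Scores every record with a probability of being amyloid under a random
#' forest fitted on n-gram features of the reduced encoding. The default
#' `"out_of_fold"` scoring fits k stratified folds and scores each record
#' with the model that never saw it, so memorization cannot mask outliers;
#' `"in_fit"` scores records with the model fitted on all of them (the
#' provenance field always records which was used).
#'
#' @param records data frame with `id`, `sequence` and an observed label
#'   column (`observed_label` or `db_label`) over
#'   \{"amyloid","non_amyloid"\}.
#' @param k_folds number of folds (records must number >= 2 * k_folds).
#' @param seed integer seed; probabilities are deterministic given it.
#' @param scoring "out_of_fold" (default) or "in_fit".
#' @param alphabet a `reduced_alphabet`.
#' @param max_n n-gram order of the feature space.
#' @param num_trees forest size.
#' @return data frame: `peptide_id`, `p_amyloid`, `provenance`.
#' @export
oof_probabilities <- function(records, k_folds = 5, seed = 1,
                              scoring = c("out_of_fold", "in_fit"),
                              alphabet = reduced_alphabet(), max_n = 2,
                              num_trees = 300) {
  scoring <- match.arg(scoring)
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  label_col <- intersect(c("observed_label", "db_label"), names(records))[1]
  if (is.na(label_col)) {
    stop("records need an observed_label or db_label column")
  }
  n <- nrow(records)
  if (n < 2 * k_folds) {
    stop("need at least 2 * k_folds records")
  }
  y <- factor(records[[label_col]], levels = c("non_amyloid", "amyloid"))
  x <- ngram_feature_matrix(records$sequence, alphabet, max_n)
  colnames(x) <- paste0("g_", colnames(x))
  dat <- data.frame(x, check.names = TRUE)
  p <- numeric(n)
  if (scoring == "in_fit") {
    fit <- ranger::ranger(x = dat, y = y, probability = TRUE,
                          num.trees = num_trees, seed = seed,
                          num.threads = 1)
    p <- predict(fit, dat, num.threads = 1)$predictions[, "amyloid"]
  } else {
    # stratified fold assignment: shuffle within class, deal round-robin
    set.seed(seed)
    fold <- integer(n)
    for (lev in levels(y)) {
      idx <- sample(which(y == lev))
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))
    }
    for (k in seq_len(k_folds)) {
      train <- fold != k
      if (length(unique(y[train])) < 2) {
        stop("single-class training fold; stratify labels or reduce k_folds")
      }
      fit <- ranger::ranger(x = dat[train, , drop = FALSE], y = y[train],
                            probability = TRUE, num.trees = num_trees,
                            seed = seed + k, num.threads = 1)
      p[!train] <- predict(fit, dat[!train, , drop = FALSE],
                           num.threads = 1)$predictions[, "amyloid"]
    }
  }
  data.frame(peptide_id = records$id, p_amyloid = p,
             provenance = if (scoring == "in_fit") "in_fit" else "out_of_fold",
             stringsAsFactors = FALSE)
}

.select_by_confidence <- function(records, probs, tau, agree, n_top) {
  stopifnot(is.data.frame(records), all(c("id") %in% names(records)))
  label_col <- intersect(c("observed_label", "db_label"), names(records))[1]
  if (is.na(label_col)) {
    stop("records need an observed_label or db_label column")
  }
  m <- match(records$id, probs$peptide_id)
  if (anyNA(m)) {
    stop("every record needs a probability")
  }
  p <- probs$p_amyloid[m]
  is_amy <- records[[label_col]] == "amyloid"
  conf <- ifelse(is_amy == agree, p, 1 - p)  # confidence in the selecting direction
  records$p_amyloid <- p
  if (!is.null(n_top)) {
    ord <- order(-conf)
    return(utils::head(records[ord, , drop = FALSE], n_top))
  }
  if (tau <= 0.5 || tau > 1) {
    stop("tau must lie in (0.5, 1]; at or below 0.5 everything qualifies")
  }
  sel <- conf >= tau
  out <- records[sel, , drop = FALSE]
  out[order(-conf[sel]), , drop = FALSE]
}

#' Select outlier peptides: confident disagreement with the observed label
#'
#' A record is an outlier when the predictor assigns, with confidence at
#' least `tau`, the class opposite to its observed label — i.e.
#' `p_amyloid >= tau` for a non-amyloid-labeled record, or
#' `p_amyloid <= 1 - tau` for an amyloid-labeled one. Outliers are candidate
#' misannotations. Alternatively pass `n_top` to take the `n_top` most
#' confident disagreements regardless of threshold.
#'
#' @param records data frame with `id`, label column.
#' @param probs output of [oof_probabilities()].
#' @param tau confidence threshold in (0.5, 1], default 0.9.
#' @param n_top optional top-k override of the threshold rule.
#' @return the selected records, most confident first, with `p_amyloid`
#'   attached.
#' @export
select_outliers <- function(records, probs, tau = 0.9, n_top = NULL) {
  .select_by_confidence(records, probs, tau, agree = FALSE, n_top = n_top)
}

#' Select reference peptides: confident agreement with the observed label
#'
#' Mirror image of [select_outliers()]: records the predictor confirms with
#' confidence at least `tau`.
#'
#' @inheritParams select_outliers
#' @return the selected records, most confident first.
#' @export
select_references <- function(records, probs, tau = 0.9, n_top = NULL) {
  .select_by_confidence(records, probs, tau, agree = TRUE, n_top = n_top)
}
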