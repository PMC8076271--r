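#' Confusion statistics of one method against a truth column
#'
#' Both inputs are binarized first (oligomer counts as amyloid-positive, which
#' the aggregate tables force: an oligomer truth row scored by a positive
#' predictor call is a true positive). If both vectors are named, they are
#' aligned on the intersection of names. Ratios are kept at full precision;
#' round only for display. Sensitivity (specificity) is reported as `NA` —
#' explicitly undefined, never silently 0 — when there are no actual
#' positives (negatives).
#'
#' @param predictions calls of the method under audit.
#' @param truth reference calls (e.g. IR microscopy).
#' @return a `concordance_stats` list: `n`, `tp`, `tn`, `fp`, `fn`, `acc`,
#'   `sn`, `sp`.
#' @export
#' @examples
#' tab <- load_fixture("predictor_calls_test")
#' confusion_stats(tab$amylogram, tab$ir_microscopy)
confusion_stats <- function(predictions, truth) {
  if (!is.null(names(predictions)) && !is.null(names(truth))) {
    common <- intersect(names(predictions), names(truth))
    if (length(common) == 0) {
      stop("empty peptide intersection between predictions and truth")
    }
    predictions <- predictions[common]
    truth <- truth[common]
  }
  if (length(predictions) == 0 || length(predictions) != length(truth)) {
    stop("predictions and truth must cover the same non-empty peptide set")
  }
  p <- binarize_call(predictions)
  t <- binarize_call(truth)
  tp <- sum(p & t)
  tn <- sum(!p & !t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  structure(list(n = length(p), tp = tp, tn = tn, fp = fp, fn = fn,
                 acc = (tp + tn) / length(p),
                 sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "concordance_stats")
}

#' @export
print.concordance_stats <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", v)
  cat(sprintf("<concordance_stats> n=%d  Acc=%s  Sn=%s  Sp=%s  (tp %d, tn %d, fp %d, fn %d)\n",
              x$n, fmt(x$acc), fmt(x$sn), fmt(x$sp), x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Per-peptide consensus of the five predictors with a truth call
#'
#' 100 times the fraction of the five predictors whose binarized call equals
#' the binarized truth call.
#'
#' @param method_calls named vector or list of the five predictor calls, names
#'   `amylogram`, `path_lr`, `path_rf`, `foldamyloid`, `pasta2`.
#' @param truth_call the reference call for the peptide.
#' @return consensus percentage in 0-100.
#' @export
#' @examples
#' consensus_percent(c(amylogram = "Yes", path_lr = "No", path_rf = "Yes",
#'                     foldamyloid = "No", pasta2 = "Yes"), "Yes*")
consensus_percent <- function(method_calls, truth_call) {
  calls <- unlist(method_calls)
  missing <- setdiff(.amylir_methods, names(calls))
  if (length(missing)) {
    stop("missing predictor call(s): ", paste(missing, collapse = ", "))
  }
  calls <- calls[.amylir_methods]
  100 * mean(binarize_call(calls) == binarize_call(truth_call))
}

#' Audit database labels against an experimental truth column
#'
#' A peptide is misannotated when its binarized database label differs from
#' the binarized truth call. False-positive labels are database-amyloid
#' records whose truth is negative; false-negative labels the reverse.
#' Per-class fractions are taken over the truth classes.
#'
#' @param db_calls database labels ("amyloid"/"non_amyloid" or Yes/No
#'   dialect), optionally named by peptide.
#' @param truth_calls experimental truth calls, same peptides.
#' @return a `misannotation_report` list: `n_total`, `n_misannotated`,
#'   `n_false_positive_labels`, `n_false_negative_labels`,
#'   `frac_misannotated_truth_negative`, `frac_misannotated_truth_positive`,
#'   and the per-peptide logical vector `misannotated`.
#' @export
misannotation_audit <- function(db_calls, truth_calls) {
  if (length(db_calls) == 0) {
    stop("empty peptide set")
  }
  stopifnot(length(db_calls) == length(truth_calls))
  db <- if (all(db_calls %in% c("amyloid", "non_amyloid"))) {
    db_calls == "amyloid"
  } else {
    binarize_call(db_calls)
  }
  truth <- binarize_call(truth_calls)
  mis <- db != truth
  structure(list(
    n_total = length(mis),
    n_misannotated = sum(mis),
    n_false_positive_labels = sum(mis & db),
    n_false_negative_labels = sum(mis & !db),
    frac_misannotated_truth_negative =
      if (any(!truth)) mean(mis[!truth]) else NA_real_,
    frac_misannotated_truth_positive =
      if (any(truth)) mean(mis[truth]) else NA_real_,
    misannotated = stats::setNames(mis, names(db_calls))),
    class = "misannotation_report")
}

#' @export
print.misannotation_report <- function(x, ...) {
  cat(sprintf("<misannotation_report> %d/%d misannotated (%d db-false-positive, %d db-false-negative)\n",
              x$n_misannotated, x$n_total, x$n_false_positive_labels,
              x$n_false_negative_labels))
  invisible(x)
}

#' Recompute the per-method concordance table from packaged fixtures
#'
#' Scores each of the five predictors against the IR-microscopy truth column
#' of the chosen fixture set, optionally restricted to the peptides whose
#' database label the IR truth overturns (the misannotated subset).
#'
#' @param set `"test"` or `"reference"`.
#' @param restrict_to_misannotated if `TRUE`, keep only peptides flagged by
#'   [misannotation_audit()] of database vs IR microscopy. Errors on the
#'   reference set, which contains no misannotations.
#' @return data frame with one row per method: `method`, `n`, `tp`, `tn`,
#'   `fp`, `fn`, `acc`, `sn`, `sp`.
#' @export
#' @examples
#' reproduce_audit_tables("test")
reproduce_audit_tables <- function(set = c("test", "reference"),
                                   restrict_to_misannotated = FALSE) {
  set <- match.arg(set)
  calls <- load_fixture(paste0("predictor_calls_", set))
  if (restrict_to_misannotated) {
    db <- if (set == "test") {
      calls$database
    } else {
      fix <- load_fixture("reference_set")
      fix$db_label[match(calls$id, fix$id)]
    }
    audit <- misannotation_audit(db, calls$ir_microscopy)
    if (audit$n_misannotated == 0) {
      stop("no misannotated peptides in the ", set, " set")
    }
    calls <- calls[audit$misannotated, , drop = FALSE]
  }
  rows <- lapply(.amylir_methods, function(m) {
    s <- confusion_stats(calls[[m]], calls$ir_microscopy)
    data.frame(method = m, n = s$n, tp = s$tp, tn = s$tn, fp = s$fp,
               fn = s$fn, acc = s$acc, sn = s$sn, sp = s$sp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Recompute per-peptide consensus columns from a predictor fixture
#'
#' @param set `"test"` or `"reference"`.
#' @return data frame: `id`, `computed` (consensus recomputed from the five
#'   calls), `printed` (the fixture's transcribed consensus cell), `match`.
#' @export
consensus_table <- function(set = c("test", "reference")) {
  set <- match.arg(set)
  calls <- load_fixture(paste0("predictor_calls_", set))
  computed <- vapply(seq_len(nrow(calls)), function(i) {
    consensus_percent(stats::setNames(
      unlist(calls[i, .amylir_methods]), .amylir_methods),
      calls$ir_microscopy[i])
  }, numeric(1))
  data.frame(id = calls$id, computed = computed,
             printed = calls$consensus_ir_pct,
             match = computed == calls$consensus_ir_pct,
             stringsAsFactors = FALSE)
}
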