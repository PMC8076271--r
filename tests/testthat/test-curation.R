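test_that("hexapeptide filtering and origin splitting follow the curation rules", {
  expect_identical(filter_hexapeptides(c("FNPQGG", "FNPQG", "FNPXGG")),
                   "FNPQGG")
  expect_identical(filter_hexapeptides(character(0)), character(0))
  panel <- rbind(load_fixture("reference_set")[c("id", "sequence")],
                 load_fixture("test_set")[c("id", "sequence")])
  expect_equal(nrow(filter_hexapeptides(panel)), 34L)

  rec <- peptide_records(c("FNPQGG", "YTVIIE", "AAAAAA"),
                         c("amyloid", "amyloid", "non_amyloid"),
                         origin = c("amylhex", "other", "synthetic"))
  parts <- split_by_origin(rec)
  expect_equal(parts$amylhex$id, "FNPQGG")
  expect_equal(nrow(parts$amylhex) + nrow(parts$other), 3L)
})

test_that("reduced-alphabet encoding is position-wise and total", {
  expect_identical(encode_reduced("LVFYQQ", toy_alphabet()), "HHHHPP")
  expect_identical(encode_reduced("LVFYQQ", reduced_alphabet("identity")),
                   "LVFYQQ")
  expect_identical(encode_reduced("LVFYQQ"), "AABBCC")
  expect_error(encode_reduced("LVFYQ?"), "outside the alphabet")
  expect_error(new_reduced_alphabet(c(A = "X")), "20 standard")
})

test_that("alphabet TSV round trip preserves the mapping", {
  path <- withr::local_tempfile(fileext = ".tsv")
  alpha <- reduced_alphabet()
  writeLines(c("letter\tgroup",
               paste(names(alpha$mapping), alpha$mapping, sep = "\t")), path)
  expect_identical(read_alphabet(path)$mapping, alpha$mapping)
})

test_that("encoded deduplication keeps one representative and drops conflicts", {
  rec <- peptide_records(c("ILVVIA", "LIVVIA", "DEKNSQ"),
                         c("amyloid", "amyloid", "non_amyloid"),
                         id = c("a", "b", "c"))
  out <- deduplicate_encoded(rec)
  expect_equal(nrow(out$records), 2L)  # a/b collapse, c kept
  expect_equal(nrow(out$conflicts), 0L)

  rec2 <- peptide_records(c("ILVVIA", "LIVVIA"), c("amyloid", "non_amyloid"),
                          id = c("a", "b"))
  out2 <- deduplicate_encoded(rec2)
  expect_equal(nrow(out2$records), 0L)
  expect_equal(out2$conflicts$n_records, 2L)
})

test_that("deduplication matches a brute-force pairwise scan", {
  set.seed(41)
  seqs <- random_hexapeptides(200)
  labels <- sample(c("amyloid", "non_amyloid"), 200, replace = TRUE)
  rec <- peptide_records(seqs, labels, id = sprintf("p%03d", 1:200))
  out <- deduplicate_encoded(rec)

  enc <- vapply(seqs, encode_reduced, character(1))
  conflicted <- vapply(seq_along(enc), function(i) {
    any(enc == enc[i] & labels != labels[i])
  }, logical(1))
  expect_equal(sort(out$conflicts$encoded), sort(unique(enc[conflicted])))
  n_expected <- nrow(unique(data.frame(enc, labels)[!conflicted, ]))
  expect_equal(nrow(out$records), n_expected)
})

test_that("n-gram features count contiguous grams over the full space", {
  f <- ngram_features("LLL", toy_alphabet(), max_n = 2)  # encodes to HHH
  expect_equal(unname(f["H"]), 3L)
  expect_equal(unname(f["HH"]), 2L)
  expect_equal(sum(f[c("C", "P")]), 0L)
  expect_equal(length(f), 3 + 9)
  # 1-gram counts conserve sequence length
  g <- ngram_features("LVFYQQ", max_n = 2)
  expect_equal(sum(g[nchar(names(g)) == 1]), 6L)
  expect_error(ngram_features("LVF", max_n = 4), "sequence length")
})

test_that("out-of-fold scoring learns a feature-separable rule deterministically", {
  set.seed(42)
  seqs <- random_hexapeptides(200)
  alpha <- reduced_alphabet()
  n_hydro <- vapply(strsplit(seqs, ""), function(r) {
    sum(alpha$mapping[r] %in% c("A", "B"))
  }, numeric(1))
  rec <- data.frame(id = sprintf("p%03d", 1:200), sequence = seqs,
                    observed_label = ifelse(n_hydro >= 3, "amyloid",
                                            "non_amyloid"))
  probs <- oof_probabilities(rec, k_folds = 5, seed = 43)
  acc <- mean((probs$p_amyloid > 0.5) == (rec$observed_label == "amyloid"))
  expect_gt(acc, 0.9)
  expect_identical(probs$p_amyloid,
                   oof_probabilities(rec, k_folds = 5, seed = 43)$p_amyloid)
  expect_true(all(probs$provenance == "out_of_fold"))
  in_fit <- oof_probabilities(rec, seed = 43, scoring = "in_fit")
  expect_true(all(in_fit$provenance == "in_fit"))

  rare <- rec
  rare$observed_label <- c("amyloid", rep("non_amyloid", 199))
  expect_error(oof_probabilities(rare, k_folds = 5, seed = 1),
               "single-class")
  expect_error(oof_probabilities(rec[1:8, ], k_folds = 5), "2 \\* k_folds")
})

test_that("shuffled labels leave out-of-fold probabilities uninformative", {
  set.seed(44)
  seqs <- random_hexapeptides(1000)
  truth <- planted_rule_bayes(seqs)
  rec <- data.frame(id = sprintf("p%04d", 1:1000), sequence = seqs,
                    observed_label = sample(truth))
  probs <- oof_probabilities(rec, k_folds = 5, seed = 45)
  gap <- mean(probs$p_amyloid[truth == "amyloid"]) -
    mean(probs$p_amyloid[truth == "non_amyloid"])
  expect_lt(abs(gap), 0.1)
})

test_that("outlier and reference selection partition confident calls", {
  rec <- data.frame(id = c("a", "b", "c"),
                    sequence = c("ILVVIF", "DEKNSQ", "FNPQGG"),
                    observed_label = c("non_amyloid", "amyloid", "amyloid"))
  probs <- data.frame(peptide_id = c("a", "b", "c"),
                      p_amyloid = c(0.95, 0.95, 0.60),
                      provenance = "external_fixture")
  expect_equal(select_outliers(rec, probs, tau = 0.9)$id, "a")
  expect_equal(select_references(rec, probs, tau = 0.9)$id, "b")
  expect_equal(nrow(select_outliers(rec[3, ], probs, tau = 0.9)), 0L)
  expect_error(select_outliers(rec, probs, tau = 0.5), "0.5")
  expect_equal(select_outliers(rec, probs, n_top = 2)$id, c("a", "c"))

  # disjoint, and both shrink monotonically in tau
  set.seed(46)
  big <- data.frame(id = sprintf("p%03d", 1:100),
                    sequence = random_hexapeptides(100),
                    observed_label = sample(c("amyloid", "non_amyloid"), 100,
                                            replace = TRUE))
  bp <- data.frame(peptide_id = big$id, p_amyloid = runif(100),
                   provenance = "external_fixture")
  sizes <- vapply(c(0.6, 0.7, 0.8, 0.9, 1), function(tau) {
    out <- select_outliers(big, bp, tau = tau)
    ref <- select_references(big, bp, tau = tau)
    expect_length(intersect(out$id, ref$id), 0)
    c(nrow(out), nrow(ref))
  }, numeric(2))
  expect_true(all(diff(sizes[1, ]) <= 0) && all(diff(sizes[2, ]) <= 0))
})
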