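#' Build a validated peptide record table
#'
#' @param sequence character vector of peptide sequences (uppercase, 20
#'   standard amino-acid letters).
#' @param db_label database annotation, "amyloid" or "non_amyloid".
#' @param id record identifiers; default the sequences themselves.
#' @param origin provenance of each record: "amylhex", "other" or "synthetic".
#' @param subset experimental subset tag: "reference", "test" or "none".
#' @return data frame with columns id, sequence, db_label, origin, subset.
#' @export
#' @examples
#' peptide_records(c("FNPQGG", "YTVIIE"), c("non_amyloid", "amyloid"))
peptide_records <- function(sequence, db_label, id = sequence,
                            origin = "other", subset = "none") {
  sequence <- toupper(as.character(sequence))
  stopifnot(length(sequence) >= 0, length(db_label) %in% c(1, length(sequence)))
  if (any(!nzchar(sequence))) {
    stop("peptide sequences must be non-empty")
  }
  bad <- !grepl(sprintf("^[%s]+$", paste(.amylir_aa, collapse = "")), sequence)
  if (any(bad)) {
    stop("non-standard amino-acid letters in: ",
         paste(sequence[bad], collapse = ", "))
  }
  db_label <- match.arg(as.character(db_label), c("amyloid", "non_amyloid"),
                        several.ok = TRUE)
  origin <- match.arg(as.character(origin), c("amylhex", "other", "synthetic"),
                      several.ok = TRUE)
  subset <- match.arg(as.character(subset), c("reference", "test", "none"),
                      several.ok = TRUE)
  if (anyDuplicated(id)) {
    stop("peptide ids must be unique")
  }
  data.frame(id = as.character(id), sequence = sequence, db_label = db_label,
             origin = origin, subset = subset, stringsAsFactors = FALSE)
}

#' Keep only standard hexapeptides
#'
#' Retains records whose sequence has exactly six residues, all from the 20
#' standard amino-acid letters. This is a filter, not a validator: offending
#' records are silently dropped.
#'
#' @param records a peptide record data frame (column `sequence`) or a
#'   character vector of sequences.
#' @return the filtered object, same type as the input.
#' @export
#' @examples
#' filter_hexapeptides(c("FNPQGG", "FNPQG", "FNPXGG"))
filter_hexapeptides <- function(records) {
  seqs <- if (is.data.frame(records)) records$sequence else records
  keep <- nchar(seqs) == 6 &
    grepl(sprintf("^[%s]+$", paste(.amylir_aa, collapse = "")), seqs)
  if (is.data.frame(records)) records[keep, , drop = FALSE] else records[keep]
}

#' Partition peptide records by dataset origin
#'
#' Splits a record table into the AmylHex-derived subset and everything else
#' (including synthetic records), preserving order. The split guards against
#' overrepresentation of the historically biased AmylHex panel.
#'
#' @param records peptide record data frame with an `origin` column.
#' @return list with elements `amylhex` and `other`.
#' @export
split_by_origin <- function(records) {
  stopifnot(is.data.frame(records), "origin" %in% names(records))
  list(amylhex = records[records$origin == "amylhex", , drop = FALSE],
       other = records[records$origin != "amylhex", , drop = FALSE])
}

#' Write peptide records to a FASTA file
#'
#' @param peptides peptide record data frame (columns `id`, `sequence`).
#' @param destination output path.
#' @return the number of records written, invisibly.
#' @export
write_fasta <- function(peptides, destination) {
  stopifnot(is.data.frame(peptides),
            all(c("id", "sequence") %in% names(peptides)))
  if (anyDuplicated(peptides$id)) {
    stop("duplicate peptide ids; FASTA headers must be unique")
  }
  if (nrow(peptides) == 0) {
    file.create(destination)
    return(invisible(0L))
  }
  seqinr::write.fasta(as.list(peptides$sequence), names = peptides$id,
                      file.out = destination)
  invisible(nrow(peptides))
}

#' Read a peptide set from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return data frame with columns `id` and `sequence` (uppercase).
#' @export
read_peptides_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  data.frame(id = names(fa),
             sequence = toupper(vapply(fa, as.character, character(1))),
             stringsAsFactors = FALSE)
}
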