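#' Parse a band-annotation string into a band table
#'
#' Band lists are written as slash-separated tokens `POS(grade,flags)`, where
#' `POS` is the band position in cm^-1, the grade is one of `s`/`m`/`w`
#' (strong/medium/weak) and the optional shape flags are `br` (broad) and `sh`
#' (shoulder). Exactly one token must be marked as the dominant maximum, either
#' with a trailing `*` (the fixture dialect, replacing typographic bold) or by
#' `**...**` wrapping. A few printed tokens carry only a shape flag
#' (e.g. `1676(sh)`); their grade is stored as `NA`.
#'
#' @param text band notation string, e.g. `"1689(m,sh)/1628(s)*"`.
#' @return a `band_table` data frame with columns `position` (integer cm^-1),
#'   `grade` (`"s"`, `"m"`, `"w"` or `NA`), `broad`, `shoulder` and `dominant`
#'   (logical).
#' @seealso [serialize_band_string()] for the inverse, [classify_bands()].
#' @export
#' @examples
#' parse_band_string("1689(m,sh)/1628(s)*")
#' parse_band_string("**1655(s,br)**")
parse_band_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) {
    stop("empty band string")
  }
  # accept the printed bold dialect by rewriting **TOKEN** -> TOKEN*
  text <- gsub("\\*\\*([^*]+)\\*\\*", "\\1*", text)
  tokens <- strsplit(text, "/", fixed = TRUE)[[1]]
  rows <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([0-9]+)\\(([a-z,]*)\\)(\\*?)$", tok))[[1]]
    if (length(m) == 0) {
      stop("malformed band token: '", tok, "'")
    }
    flags <- strsplit(m[3], ",", fixed = TRUE)[[1]]
    grade <- NA_character_
    if (length(flags) && flags[1] %in% c("s", "m", "w")) {
      grade <- flags[1]
      flags <- flags[-1]
    }
    if (!all(flags %in% c("br", "sh"))) {
      stop("unknown band flag(s) in token: '", tok, "'")
    }
    data.frame(position = as.integer(m[2]), grade = grade,
               broad = "br" %in% flags, shoulder = "sh" %in% flags,
               dominant = m[4] == "*", stringsAsFactors = FALSE)
  })
  bands <- do.call(rbind, rows)
  n_dom <- sum(bands$dominant)
  if (n_dom != 1) {
    stop("band string must mark exactly one dominant maximum, found ", n_dom,
         ": '", text, "'")
  }
  if (any(bands$position < 1580 | bands$position > 1720)) {
    stop("band position outside the Amide I analysis window [1580, 1720]")
  }
  class(bands) <- c("band_table", class(bands))
  bands
}

#' Serialize a band table back to its string notation
#'
#' Exact inverse of [parse_band_string()] under the `*` dominance dialect.
#'
#' @param bands a band table as returned by [parse_band_string()].
#' @return a single band-notation string.
#' @export
#' @examples
#' serialize_band_string(parse_band_string("1689(m,sh)/1628(s)*"))
serialize_band_string <- function(bands) {
  stopifnot(is.data.frame(bands), nrow(bands) >= 1)
  tok <- vapply(seq_len(nrow(bands)), function(i) {
    b <- bands[i, ]
    flags <- c(if (!is.na(b$grade)) b$grade, if (b$broad) "br",
               if (b$shoulder) "sh")
    sprintf("%d(%s)%s", b$position, paste(flags, collapse = ","),
            if (b$dominant) "*" else "")
  }, character(1))
  paste(tok, collapse = "/")
}
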