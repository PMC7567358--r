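#' ATC code utilities
#'
#' The Anatomical Therapeutic Chemical (ATC) classification is a 7-character
#' hierarchical drug code: one letter (anatomical main group), two digits
#' (therapeutic subgroup), two letters (pharmacological / chemical subgroup)
#' and two digits (chemical substance), e.g. `"N05CD08"` (midazolam). Valid
#' truncation levels have 1, 3, 4, 5 or 7 characters.
#'
#' @param code character vector of ATC codes (any hierarchy level).
#' @return `atc_valid()` returns a logical vector: does each code match the
#'   ATC structural pattern at its level?
#' @examples
#' atc_valid(c("N05CD08", "A02BC", "ZZZ"))
#' @export
atc_valid <- function(code) {
  code <- toupper(as.character(code))
  patterns <- c(
    "1" = "^[A-Z]$",
    "3" = "^[A-Z][0-9]{2}$",
    "4" = "^[A-Z][0-9]{2}[A-Z]$",
    "5" = "^[A-Z][0-9]{2}[A-Z]{2}$",
    "7" = "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
  )
  len <- as.character(nchar(code))
  ok <- !is.na(code) & len %in% names(patterns)
  idx <- which(ok)
  ok[idx] <- vapply(
    idx,
    function(i) grepl(patterns[[len[i]]], code[i]),
    logical(1)
  )
  ok
}

#' Match an ATC code against a pattern prefix
#'
#' A rule pattern is a (possibly partial) ATC code; a dispensed code matches
#' when it starts with the pattern. Codes shorter than the pattern never
#' match. Matching is performed on uppercase codes.
#'
#' @param code character vector of dispensed ATC codes.
#' @param pattern a single ATC prefix (1-7 characters).
#' @return logical vector.
#' @examples
#' match_atc(c("A02BC01", "A02BA02"), "A02BC")
#' @export
match_atc <- function(code, pattern) {
  stopifnot(length(pattern) == 1L)
  startsWith(toupper(as.character(code)), toupper(pattern))
}

# Deterministically extend an ATC prefix to a full structurally valid
# 7-character code (used by the claims simulator, which draws codes from the
# rule table's own patterns). Letter positions are padded with "A", digit
# positions with "01"/"0".
atc_complete <- function(prefix) {
  template <- c("A", "0", "1", "A", "A", "0", "1")
  vapply(toupper(prefix), function(p) {
    if (nchar(p) >= 7L) return(substr(p, 1L, 7L))
    paste0(p, paste(template[seq.int(nchar(p) + 1L, 7L)], collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
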