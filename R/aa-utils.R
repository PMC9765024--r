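# Shared amino-acid alphabet helpers.

# The 20 standard residues; X stands for an unknown residue.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET_X <- c(AA_STANDARD, "X")
GAP_CHARS <- c("-", ".")

#' Clean a raw amino-acid string for storage
#'
#' Uppercases, strips whitespace, and maps the nonstandard letters B, Z, U
#' and O (ambiguity and rare-residue codes) to X, with a warning naming the
#' substitutions.  Characters outside the amino-acid alphabet raise an error.
#'
#' @param x character scalar, a raw protein sequence (no gaps).
#' @param id optional identifier used in messages.
#' @return the cleaned sequence over `ACDEFGHIKLMNPQRSTVWY` plus `X`.
#' @export
clean_sequence <- function(x, id = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- toupper(gsub("[[:space:]]", "", x))
  who <- if (is.null(id)) "sequence" else paste0("sequence '", id, "'")
  if (nzchar(s) && grepl("[BZUO]", s)) {
    bad <- sort(unique(strsplit(gsub("[^BZUO]", "", s), "")[[1]]))
    warning(who, ": nonstandard letters ", paste(bad, collapse = ","),
            " mapped to X", call. = FALSE)
    s <- chartr("BZUO", "XXXX", s)
  }
  residues <- unique(strsplit(s, "")[[1]])
  unknown <- setdiff(residues, AA_ALPHABET_X)
  if (length(unknown) > 0L) {
    stop(who, ": invalid characters: ", paste(unknown, collapse = ","),
         call. = FALSE)
  }
  if (!nzchar(s)) stop(who, " is empty", call. = FALSE)
  s
}

#' Remove gap characters and uppercase a (possibly aligned) sequence
#'
#' @param x character vector of sequences possibly containing `-` or `.` gaps
#'   and lowercase letters.
#' @return ungapped uppercase sequences.
#' @export
degap <- function(x) {
  toupper(gsub("[-.]", "", x))
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# For an aligned row, the alignment column of each ungapped position
# (1-based): pos2col(row)[p] is the column holding the p-th residue.
pos2col <- function(row) {
  which(!chars(row) %in% GAP_CHARS)
}

# Inverse map: for each alignment column, the ungapped residue number, or
# NA at gap columns.
col2pos <- function(row) {
  cc <- chars(row)
  isres <- !cc %in% GAP_CHARS
  out <- rep(NA_integer_, length(cc))
  out[isres] <- seq_len(sum(isres))
  out
}
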