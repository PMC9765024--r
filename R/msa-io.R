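# Multiple-alignment container and format I/O (FASTA, Clustal, Stockholm).
# Case is preserved throughout: lowercase letters mark non-homologous
# (insert-state) positions, as written by HMM aligners; '-' and '.' are both
# gap characters and are preserved as given.

#' Construct a multiple sequence alignment object
#'
#' @param ids unique sequence identifiers.
#' @param rows aligned strings (equal length; residues, `-`, `.`; case
#'   preserved).
#' @param descriptions optional free-text descriptions (same length as ids).
#' @return an `msa` object with fields `ids`, `rows`, `descriptions` and
#'   `n_cols`.
#' @export
msa <- function(ids, rows, descriptions = NULL) {
  stopifnot(length(ids) == length(rows), length(ids) > 0L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ","))
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    ragged <- ids[widths != stats::median(widths)]
    stop("ragged alignment rows: ", paste(ragged, collapse = ","))
  }
  for (i in seq_along(rows)) {
    # validates the residue alphabet of the ungapped sequence
    clean_sequence(degap(rows[i]), id = ids[i])
  }
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 descriptions = as.character(descriptions),
                 n_cols = widths[1]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$ids), " sequences x ", x$n_cols, " columns\n",
      sep = "")
  invisible(x)
}

msa_row <- function(m, id) {
  i <- match(id, m$ids)
  if (is.na(i)) stop("no row named '", id, "' in the alignment")
  m$rows[i]
}

#' Read a multiple alignment
#'
#' @param text alignment text (string or lines) or a file path.
#' @param format `"fasta"`, `"clustal"`, or `"stockholm"`.
#' @return an [msa()] object; case and gap characters (`-`, `.`) preserved.
#' @export
read_alignment <- function(text, format = c("fasta", "clustal",
                                            "stockholm")) {
  format <- match.arg(format)
  lines <- as_lines(text)
  switch(format,
         fasta = read_fasta_msa(lines),
         clustal = read_clustal_msa(lines),
         stockholm = read_stockholm_msa(lines))
}

#' Write a multiple alignment
#'
#' @param m an [msa()] object.
#' @param format output format.
#' @param path optional file path; when omitted the text is returned.
#' @param width residues per line for wrapped formats.
#' @return the alignment text, invisibly when `path` is given.
#' @export
write_alignment <- function(m, format = c("fasta", "clustal", "stockholm"),
                            path = NULL, width = 60L) {
  format <- match.arg(format)
  txt <- switch(format,
                fasta = write_fasta_msa(m, width),
                clustal = write_clustal_msa(m, width),
                stockholm = write_stockholm_msa(m))
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

read_fasta_msa <- function(lines) {
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no FASTA headers found")
  ends <- c(utils::tail(heads, -1L) - 1L, length(lines))
  ids <- character(); descs <- character(); rows <- character()
  for (k in seq_along(heads)) {
    header <- sub("^>", "", lines[heads[k]])
    ids <- c(ids, sub("\\s.*$", "", header))
    descs <- c(descs, ifelse(grepl("\\s", header),
                             sub("^\\S+\\s+", "", header), ""))
    body <- lines[seq(heads[k] + 1L, ends[k])]
    body <- body[!grepl("^>", body)]
    rows <- c(rows, paste(gsub("[[:space:]]", "", body), collapse = ""))
  }
  msa(ids, rows, descs)
}

write_fasta_msa <- function(m, width) {
  out <- character()
  for (i in seq_along(m$ids)) {
    header <- if (nzchar(m$descriptions[i])) {
      paste0(">", m$ids[i], " ", m$descriptions[i])
    } else paste0(">", m$ids[i])
    row <- m$rows[i]
    starts <- seq(1L, nchar(row), by = width)
    out <- c(out, header, substring(row, starts,
                                    pmin(starts + width - 1L, nchar(row))))
  }
  out
}

read_clustal_msa <- function(lines) {
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1])) {
    stop("missing CLUSTAL header line")
  }
  acc <- list()
  order <- character()
  for (line in lines[-1]) {
    if (!nzchar(trimws(line))) next
    if (grepl("^\\s", line)) next   # conservation line
    parts <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(parts) < 2L) next
    id <- parts[1]
    seg <- parts[2]
    if (!grepl("^[A-Za-z.-]+$", seg)) next
    if (!(id %in% order)) order <- c(order, id)
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], seg)
  }
  if (length(order) == 0L) stop("no sequence lines in Clustal input")
  msa(order, unlist(acc[order], use.names = FALSE))
}

write_clustal_msa <- function(m, width) {
  out <- c("CLUSTAL W multiple sequence alignment", "")
  namew <- max(nchar(m$ids)) + 3L
  for (start in seq(1L, m$n_cols, by = width)) {
    for (i in seq_along(m$ids)) {
      seg <- substr(m$rows[i], start, min(start + width - 1L, m$n_cols))
      out <- c(out, paste0(formatC(m$ids[i], width = -namew), seg))
    }
    out <- c(out, "")
  }
  out
}

read_stockholm_msa <- function(lines) {
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1])) {
    stop("missing '# STOCKHOLM' header line")
  }
  acc <- list()
  order <- character()
  for (line in lines[-1]) {
    if (grepl("^//", line)) break
    if (!nzchar(trimws(line)) || startsWith(line, "#")) next
    parts <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(parts) != 2L) next
    id <- parts[1]
    if (!(id %in% order)) order <- c(order, id)
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], parts[2])
  }
  if (length(order) == 0L) stop("no sequence lines in Stockholm input")
  msa(order, unlist(acc[order], use.names = FALSE))
}

write_stockholm_msa <- function(m) {
  namew <- max(nchar(m$ids)) + 3L
  c("# STOCKHOLM 1.0",
    paste0(formatC(m$ids, width = -namew), m$rows),
    "//")
}
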