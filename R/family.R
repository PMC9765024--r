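# Family-level operations: homolog selection, alignment trimming,
# evolutionary distances, site transfer onto alignment columns, pattern
# search, anchor numbering, and label search.

#' Select homologs of a query for family analysis
#'
#' Pools candidate proteins from sites databases and/or user-supplied
#' sequence tables, keeps those passing the E-value, identity and coverage
#' thresholds against the query, deduplicates by exact sequence, and
#' truncates to `max_seqs` by ascending E-value.  The query itself is always
#' first.
#'
#' @param query a [protein_record()] (or list with `id`, `description`,
#'   `sequence`).
#' @param pools list whose elements are `sites_db` objects or data frames
#'   with `id`, `description`, `sequence` columns.
#' @param min_identity minimum percent identity (default 30).
#' @param min_coverage minimum query-coverage fraction (default 0.70).
#' @param max_evalue E-value cutoff (default 0.001).
#' @param max_seqs cap on the number of sequences returned (default 100).
#' @return data frame `id`, `description`, `sequence` (query first).
#' @export
select_homologs <- function(query, pools, min_identity = 30,
                            min_coverage = 0.70, max_evalue = 0.001,
                            max_seqs = 100) {
  cands <- do.call(rbind, lapply(pools, function(p) {
    if (inherits(p, "sites_db")) p$proteins
    else p[, c("id", "description", "sequence")]
  }))
  qlen <- nchar(query$sequence)
  out <- data.frame(id = query$id,
                    description = if (is.null(query$description)) "" else
                      query$description,
                    sequence = toupper(query$sequence),
                    stringsAsFactors = FALSE)
  if (is.null(cands) || nrow(cands) == 0L) return(out)
  db_len <- sum(nchar(cands$sequence))
  keep <- list()
  for (i in seq_len(nrow(cands))) {
    hit <- local_align(query$sequence, cands$sequence[i],
                       query_id = query$id, subject_id = cands$id[i])
    if (is_empty_hit(hit)) next
    hit <- score_hit(hit, qlen, db_len)
    if (hit$evalue > max_evalue) next
    if (percent_identity(hit) < min_identity) next
    if (query_coverage(hit, qlen) < min_coverage) next
    keep[[length(keep) + 1L]] <- list(row = cands[i, ], ev = hit$evalue)
  }
  if (length(keep) > 0L) {
    ev <- vapply(keep, `[[`, numeric(1), "ev")
    rows <- do.call(rbind, lapply(keep[order(ev)], `[[`, "row"))
    out <- rbind(out, rows)
  }
  out <- out[!duplicated(toupper(out$sequence)), , drop = FALSE]
  out <- out[!duplicated(out$id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_seqs)
}

#' Trim alignment columns for tree inference
#'
#' A column is removed when its gap fraction is >= 0.5 (`trim_gaps`) or when
#' it holds more lowercase than uppercase letters (`trim_case`; lowercase
#' marks non-homologous positions).  A tie between lowercase and uppercase
#' keeps the column.  The trimmed alignment is intended only for tree
#' inference; site display always uses the untrimmed alignment.
#'
#' @param m an [msa()].
#' @param trim_gaps,trim_case enable each rule independently.
#' @return list with `msa` (trimmed) and `column_map` (strictly increasing
#'   original column indices of the kept columns).
#' @export
trim_alignment <- function(m, trim_gaps = TRUE, trim_case = TRUE) {
  grid <- do.call(rbind, strsplit(m$rows, ""))
  n <- nrow(grid)
  keep <- rep(TRUE, m$n_cols)
  for (j in seq_len(m$n_cols)) {
    col <- grid[, j]
    isgap <- col %in% GAP_CHARS
    if (trim_gaps && sum(isgap) / n >= 0.5) keep[j] <- FALSE
    if (trim_case) {
      low <- sum(col %in% letters)
      up <- sum(!isgap) - low
      if (low > up) keep[j] <- FALSE
    }
  }
  if (!any(keep)) {
    stop("trimming removed every column; disable a trimming rule ",
         "(trim_gaps/trim_case)")
  }
  rows <- apply(grid[, keep, drop = FALSE], 1, paste, collapse = "")
  list(msa = msa(m$ids, rows, m$descriptions),
       column_map = which(keep))
}

#' Poisson-corrected distance matrix from an alignment
#'
#' For each pair of rows, the mismatch fraction `p` is computed over columns
#' where neither row is gapped (case-insensitive), and the distance is
#' `-ln(1 - p)`; saturated pairs (`p >= 0.95`) are clamped to distance 3.0.
#'
#' @param m an [msa()] with at least 2 rows.
#' @return symmetric matrix with zero diagonal, dimnames = ids.
#' @export
compute_distance_matrix <- function(m) {
  n <- length(m$ids)
  stopifnot(n >= 2L)
  grid <- toupper(do.call(rbind, strsplit(m$rows, "")))
  isres <- !(grid == "-" | grid == ".")
  D <- matrix(0, n, n, dimnames = list(m$ids, m$ids))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      shared <- isres[i, ] & isres[j, ]
      if (!any(shared)) {
        stop("rows '", m$ids[j], "' and '", m$ids[i],
             "' share no aligned columns")
      }
      p <- mean(grid[i, shared] != grid[j, shared])
      D[i, j] <- D[j, i] <- if (p >= 0.95) 3.0 else -log(1 - p)
    }
  }
  D
}

#' Transfer known sites from a database onto alignment columns
#'
#' Each alignment row whose degapped, uppercased sequence exactly matches a
#' database record inherits that record's annotations; every annotated
#' position is converted to the alignment column holding that residue.
#'
#' @param m an [msa()].
#' @param db a `sites_db`.
#' @return named list (by row id) of data frames with columns
#'   `annotation_row`, `category`, `comment`, `ligand`, `position`,
#'   `column`; rows without a database match are absent.
#' @export
transfer_known_sites <- function(m, db) {
  out <- list()
  for (i in seq_along(m$ids)) {
    ann <- lookup_by_sequence(db, m$rows[i])
    if (nrow(ann) == 0L) next
    p2c <- pos2col(m$rows[i])
    rows <- do.call(rbind, lapply(seq_len(nrow(ann)), function(a) {
      pos <- ann$positions[[a]]
      data.frame(annotation_row = a, category = ann$category[a],
                 comment = ann$comment[a], ligand = ann$ligand[a],
                 position = pos, column = p2c[pos],
                 stringsAsFactors = FALSE)
    }))
    out[[m$ids[i]]] <- rows
  }
  out
}

#' Find a residue pattern across all alignment rows
#'
#' Pattern grammar: uppercase letters are literal residues, lowercase `x`
#' matches any residue, and `[...]` is a residue class (e.g. `DEA[DH]`).
#' Matches are found in the degapped rows (possibly overlapping) and mapped
#' back to alignment columns through each row's gap structure.
#'
#' @param m an [msa()].
#' @param pattern pattern string.
#' @return data frame `protein_id`, `start_pos` (1-based ungapped),
#'   `matched` (substring), and `columns` (list column of alignment column
#'   vectors).
#' @export
find_pattern <- function(m, pattern) {
  compiled <- compile_pattern(pattern)
  out <- list()
  for (i in seq_along(m$ids)) {
    seq <- degap(m$rows[i])
    p2c <- pos2col(m$rows[i])
    starts <- overlapping_match_starts(seq, compiled$regex)
    for (s in starts) {
      span <- s:(s + compiled$length - 1L)
      out[[length(out) + 1L]] <- data.frame(
        protein_id = m$ids[i], start_pos = s,
        matched = substr(seq, s, s + compiled$length - 1L),
        columns = I(list(p2c[span])), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(protein_id = character(), start_pos = integer(),
                      matched = character(), columns = I(list()),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Pattern -> fixed-length regular expression; errors carry the offending
# position.  'x' (lowercase only) is the wildcard; uppercase X is a literal
# unknown-residue code.
compile_pattern <- function(pattern) {
  if (!nzchar(pattern)) stop("empty pattern")
  cc <- chars(pattern)
  i <- 1L
  parts <- character()
  len <- 0L
  while (i <= length(cc)) {
    ch <- cc[i]
    if (ch == "[") {
      close <- NA_integer_
      j <- i + 1L
      while (j <= length(cc)) {
        if (cc[j] == "]") { close <- j; break }
        j <- j + 1L
      }
      if (is.na(close)) {
        stop("unclosed '[' at pattern position ", i)
      }
      members <- cc[(i + 1L):(close - 1L)]
      if (length(members) == 0L || !all(members %in% LETTERS)) {
        stop("invalid residue class at pattern position ", i,
             ": classes hold uppercase letters only")
      }
      parts <- c(parts, paste0("[", paste(members, collapse = ""), "]"))
      i <- close + 1L
    } else if (ch == "x") {
      parts <- c(parts, "[A-Z]")
      i <- i + 1L
    } else if (ch %in% LETTERS) {
      parts <- c(parts, ch)
      i <- i + 1L
    } else {
      stop("invalid pattern character '", ch, "' at position ", i)
    }
    len <- len + 1L
  }
  list(regex = paste(parts, collapse = ""), length = len)
}

# All (overlapping) match start positions via a lookahead scan.
overlapping_match_starts <- function(seq, regex) {
  hits <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer())
  as.integer(hits)
}

#' Map anchor-sequence positions to alignment columns
#'
#' @param m an [msa()].
#' @param anchor_id the anchor row's id (by default a family view uses the
#'   original query as anchor).
#' @param positions 1-based residue indices in the anchor's ungapped
#'   sequence.
#' @return integer alignment columns.
#' @export
map_anchor_positions <- function(m, anchor_id, positions) {
  row <- msa_row(m, anchor_id)
  p2c <- pos2col(row)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > length(p2c))) {
    stop("position(s) beyond the anchor length (",
         length(p2c), "): ",
         paste(positions[positions < 1L | positions > length(p2c)],
               collapse = ","))
  }
  p2c[positions]
}

#' Anchor residue numbers of alignment columns (inverse mapping)
#'
#' @param m an [msa()].
#' @param anchor_id the anchor row's id.
#' @param columns alignment column indices.
#' @return integer anchor residue numbers, `NA` where the anchor has a gap.
#' @export
anchor_position_of_column <- function(m, anchor_id, columns) {
  row <- msa_row(m, anchor_id)
  columns <- as.integer(columns)
  if (any(columns < 1L | columns > nchar(row))) {
    stop("column(s) out of range")
  }
  col2pos(row)[columns]
}

#' Search protein identifiers and descriptions
#'
#' Case-insensitive substring search over ids and descriptions.
#'
#' @param meta data frame with `id` and `description` columns.
#' @param query search string.
#' @return matching ids.
#' @export
search_labels <- function(meta, query) {
  q <- tolower(query)
  hit <- grepl(q, tolower(meta$id), fixed = TRUE) |
    grepl(q, tolower(meta$description), fixed = TRUE)
  meta$id[hit]
}

#' Read a per-protein metadata table
#'
#' Tab-separated columns `id`, and optionally `color` (hex), `description`
#' and `url`; missing columns are filled with empty strings.
#'
#' @param text TSV text or file path.
#' @return data frame with `id`, `color`, `description`, `url`.
#' @export
read_metadata_tsv <- function(text) {
  lines <- as_lines(text)
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                           quote = "", colClasses = "character")
  if (!"id" %in% names(tab)) stop("metadata table needs an 'id' column")
  for (col in c("color", "description", "url")) {
    if (!col %in% names(tab)) tab[[col]] <- ""
  }
  tab[, c("id", "color", "description", "url")]
}
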