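# The pairwise engine: local alignment of a query against database subjects,
# hit ranking/filtering, transfer of annotated subject residues through the
# alignment, and conservation-labeled reports.

# Default scoring: BLOSUM62 with affine gaps, open 11 / extend 1 (a gap of
# length L costs 11 + L).
default_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Karlin-Altschul constants for gapped BLOSUM62 11/1 scoring.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gap penalties.  Returns a
#' `pairwise_hit` carrying both aligned rows and 1-based inclusive endpoint
#' coordinates in each ungapped sequence.  When no positive-scoring local
#' match exists the hit is empty (score 0, zero-length rows).
#'
#' @param query,subject amino-acid strings (uppercased internally).
#' @param matrix substitution matrix; default BLOSUM62.
#' @param gap_open,gap_extend affine gap costs (positive; a gap of length L
#'   costs `gap_open + L * gap_extend`).
#' @param query_id,subject_id identifiers stored on the hit.
#' @return a `pairwise_hit` list: `query_id`, `subject_id`, `raw_score`,
#'   `bit_score`, `evalue` (NA until [score_to_evalue()] is applied),
#'   `q_aligned`, `s_aligned`, `q_start`, `q_end`, `s_start`, `s_end`.
#' @export
local_align <- function(query, subject, matrix = default_matrix(),
                        gap_open = 11, gap_extend = 1,
                        query_id = "query", subject_id = "subject") {
  stopifnot(nzchar(query), nzchar(subject), gap_open >= gap_extend,
            gap_extend > 0)
  q <- toupper(query)
  s <- toupper(subject)
  ok <- rownames(matrix)
  for (nm in c(query = q, subject = s)) {
    bad <- setdiff(unique(chars(nm)), ok)
    if (length(bad) > 0L) {
      stop("character(s) outside the substitution alphabet: ",
           paste(bad, collapse = ","))
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = q, subject = s, type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend)
  hit_from_pa(pa, query_id, subject_id)
}

hit_from_pa <- function(pa, query_id, subject_id) {
  sc <- Biostrings::score(pa)
  if (sc <= 0) return(empty_hit(query_id, subject_id))
  structure(list(
    query_id = query_id, subject_id = subject_id,
    raw_score = as.integer(round(sc)), bit_score = NA_real_,
    evalue = NA_real_,
    q_aligned = as.character(Biostrings::alignedPattern(pa)),
    s_aligned = as.character(Biostrings::alignedSubject(pa)),
    q_start = Biostrings::start(Biostrings::pattern(pa)),
    q_end = Biostrings::end(Biostrings::pattern(pa)),
    s_start = Biostrings::start(Biostrings::subject(pa)),
    s_end = Biostrings::end(Biostrings::subject(pa))),
    class = "pairwise_hit")
}

empty_hit <- function(query_id, subject_id) {
  structure(list(query_id = query_id, subject_id = subject_id,
                 raw_score = 0L, bit_score = NA_real_, evalue = NA_real_,
                 q_aligned = "", s_aligned = "",
                 q_start = 0L, q_end = -1L, s_start = 0L, s_end = -1L),
            class = "pairwise_hit")
}

is_empty_hit <- function(hit) nchar(hit$q_aligned) == 0L

# Check the structural invariants of a hit against its source sequences.
validate_hit <- function(hit, query, subject) {
  stopifnot(nchar(hit$q_aligned) == nchar(hit$s_aligned))
  if (is_empty_hit(hit)) return(invisible(TRUE))
  qc <- chars(hit$q_aligned); sc <- chars(hit$s_aligned)
  stopifnot(!any(qc == "-" & sc == "-"))
  stopifnot(identical(degap(hit$q_aligned),
                      toupper(substr(query, hit$q_start, hit$q_end))))
  stopifnot(identical(degap(hit$s_aligned),
                      toupper(substr(subject, hit$s_start, hit$s_end))))
  stopifnot(hit$q_end - hit$q_start + 1L == sum(qc != "-"))
  invisible(TRUE)
}

#' Convert a raw alignment score to bit score and E-value
#'
#' Karlin-Altschul statistics: `bits = (lambda * S - ln K) / ln 2` and
#' `E = m * n * 2^(-bits)` for query length `m` and database length `n`.
#' Defaults are the standard gapped BLOSUM62 11/1 constants.
#'
#' @param raw_score integer alignment score.
#' @param query_len,db_len lengths (residues) of query and search space.
#' @param lambda,K Karlin-Altschul parameters.
#' @return list with `bit_score` and `evalue`.
#' @export
score_to_evalue <- function(raw_score, query_len, db_len,
                            lambda = KA_LAMBDA, K = KA_K) {
  stopifnot(lambda > 0, K > 0, query_len >= 1, db_len >= 1)
  bits <- (lambda * raw_score - log(K)) / log(2)
  list(bit_score = bits,
       evalue = as.numeric(query_len) * as.numeric(db_len) * 2^(-bits))
}

# Fill bit_score/evalue on a hit in place.
score_hit <- function(hit, query_len, db_len) {
  if (is_empty_hit(hit)) {
    hit$evalue <- Inf
    return(hit)
  }
  se <- score_to_evalue(hit$raw_score, query_len, db_len)
  hit$bit_score <- se$bit_score
  hit$evalue <- se$evalue
  hit
}

#' Percent identity of a local alignment
#'
#' 100 x (columns where the two rows carry the same letter, neither a gap) /
#' alignment length including gap columns.
#'
#' @param hit a `pairwise_hit`.
#' @return percentage in `[0, 100]`.
#' @export
percent_identity <- function(hit) {
  n <- nchar(hit$q_aligned)
  if (n == 0L) stop("zero-length alignment has no percent identity")
  qc <- chars(hit$q_aligned); sc <- chars(hit$s_aligned)
  100 * sum(qc == sc & qc != "-") / n
}

#' Fraction of the query covered by a local alignment
#'
#' @param hit a `pairwise_hit`.
#' @param query_len ungapped query length.
#' @return `(q_end - q_start + 1) / query_len` (0 for an empty hit).
#' @export
query_coverage <- function(hit, query_len) {
  if (is_empty_hit(hit)) return(0)
  stopifnot(hit$q_end <= query_len)
  (hit$q_end - hit$q_start + 1) / query_len
}

#' Rank and filter pairwise hits
#'
#' Keeps at most one hit per subject (best E-value), applies the supplied
#' thresholds, sorts by ascending E-value (ties: descending bit score, then
#' subject id), and truncates to `max_hits`.
#'
#' @param hits list of scored `pairwise_hit` objects (E-values present).
#' @param max_evalue E-value cutoff (default 0.001).
#' @param max_hits maximum number of hits returned (default 20).
#' @param min_identity optional minimum percent identity.
#' @param min_coverage optional minimum query-coverage fraction; requires
#'   `query_len`.
#' @param query_len ungapped query length (needed for `min_coverage`).
#' @return filtered, ordered list of hits.
#' @export
rank_and_filter_hits <- function(hits, max_evalue = 0.001, max_hits = 20,
                                 min_identity = NULL, min_coverage = NULL,
                                 query_len = NULL) {
  hits <- Filter(Negate(is_empty_hit), hits)
  if (length(hits) == 0L) return(list())
  stopifnot(!any(is.na(vapply(hits, `[[`, numeric(1), "evalue"))))
  keep <- vapply(hits, function(h) {
    if (h$evalue > max_evalue) return(FALSE)
    if (!is.null(min_identity) && percent_identity(h) < min_identity) {
      return(FALSE)
    }
    if (!is.null(min_coverage)) {
      stopifnot(!is.null(query_len))
      if (query_coverage(h, query_len) < min_coverage) return(FALSE)
    }
    TRUE
  }, logical(1))
  hits <- hits[keep]
  if (length(hits) == 0L) return(list())
  ev <- vapply(hits, `[[`, numeric(1), "evalue")
  bs <- vapply(hits, `[[`, numeric(1), "bit_score")
  id <- vapply(hits, `[[`, character(1), "subject_id")
  ord <- order(ev, -bs, id)
  hits <- hits[ord]
  id <- id[ord]
  hits <- hits[!duplicated(id)]
  utils::head(hits, max_hits)
}

#' Map annotated subject residues through a local alignment
#'
#' For each annotated subject position, finds the alignment column holding
#' that residue and reports the corresponding query residue and a
#' conservation status: `match` when the letters agree (case-insensitive; X
#' never matches, including against X), `mismatch` when they differ, and
#' `unaligned` when the position lies outside the local alignment or meets a
#' gap in the query row.
#'
#' @param hit a `pairwise_hit`.
#' @param annotations annotation rows for the hit's subject.
#' @param subject_seq the subject's full ungapped sequence.
#' @param query_seq optional query sequence (validated when given).
#' @return data frame of mapped sites: `annotation_row`, `category`,
#'   `comment`, `subject_pos`, `subject_res`, `query_pos`, `query_res`,
#'   `status`.
#' @export
map_sites_through_alignment <- function(hit, annotations, subject_seq,
                                        query_seq = NULL) {
  subject_seq <- toupper(subject_seq)
  cols_s <- if (is_empty_hit(hit)) integer() else col2pos(hit$s_aligned)
  cols_q <- if (is_empty_hit(hit)) integer() else col2pos(hit$q_aligned)
  qc <- if (is_empty_hit(hit)) character() else chars(hit$q_aligned)
  sc <- if (is_empty_hit(hit)) character() else chars(hit$s_aligned)
  out <- list()
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    for (p in ann$positions[[1]]) {
      if (p > nchar(subject_seq)) {
        stop("annotation position ", p, " exceeds subject length ",
             nchar(subject_seq))
      }
      s_res <- substr(subject_seq, p, p)
      q_pos <- NA_integer_
      q_res <- NA_character_
      status <- "unaligned"
      if (!is_empty_hit(hit) && p >= hit$s_start && p <= hit$s_end) {
        column <- which(cols_s == (p - hit$s_start + 1L))
        stopifnot(length(column) == 1L)
        if (qc[column] != "-") {
          q_pos <- hit$q_start + cols_q[column] - 1L
          q_res <- toupper(qc[column])
          status <- if (q_res == toupper(sc[column]) && q_res != "X") {
            "match"
          } else "mismatch"
          if (!is.null(query_seq)) {
            stopifnot(identical(toupper(substr(query_seq, q_pos, q_pos)),
                                q_res))
          }
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        annotation_row = i, category = ann$category, comment = ann$comment,
        ligand = ann$ligand, subject_pos = p, subject_res = s_res,
        query_pos = q_pos, query_res = q_res, status = status,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(annotation_row = integer(), category = character(),
                      comment = character(), ligand = character(),
                      subject_pos = integer(), subject_res = character(),
                      query_pos = integer(), query_res = character(),
                      status = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Format the conservation label for one mapped site
#'
#' Produces the report grammar `"D12 (= D9)"` for a conserved site,
#' `"E41 (≠ R38)"` for a substituted one, and `"K7 (unaligned)"` when
#' the site falls outside the alignment.
#'
#' @param m one row of the [map_sites_through_alignment()] output.
#' @return character label.
#' @export
format_site_label <- function(m) {
  lhs <- paste0(m$subject_res, m$subject_pos)
  if (m$status == "unaligned") return(paste0(lhs, " (unaligned)"))
  op <- if (m$status == "match") "=" else "≠"
  paste0(lhs, " (", op, " ", m$query_res, m$query_pos, ")")
}

#' Compare a query against a sites database
#'
#' Aligns the query locally against every database record, keeps up to
#' `max_hits` hits at the E-value cutoff, and maps each hit's annotated
#' residues through its alignment with conservation calls.  The search-space
#' size for E-values is the total residue count of the database.
#'
#' @param query a [protein_record()] (or list with `id`, `sequence`).
#' @param db a `sites_db`.
#' @param max_evalue,max_hits,min_identity,min_coverage filtering
#'   parameters; identity/coverage filters are off by default (they are used
#'   in family mode).
#' @param hits optional precomputed hit list (e.g. from
#'   [import_blast_tab()]); when given, the built-in aligner is skipped.
#' @return a `sites_report`: `query`, `entries` (list of
#'   `list(hit, sites)`), `params`.
#' @export
sitesblast_report <- function(query, db, max_evalue = 0.001, max_hits = 20,
                              min_identity = NULL, min_coverage = NULL,
                              hits = NULL) {
  stopifnot(inherits(db, "sites_db"))
  qlen <- nchar(query$sequence)
  db_len <- sum(nchar(db$proteins$sequence))
  if (is.null(hits)) {
    hits <- align_against_db(query, db)
  }
  hits <- lapply(hits, score_hit, query_len = qlen,
                 db_len = max(db_len, 1L))
  hits <- rank_and_filter_hits(hits, max_evalue = max_evalue,
                               max_hits = max_hits,
                               min_identity = min_identity,
                               min_coverage = min_coverage,
                               query_len = qlen)
  entries <- lapply(hits, function(h) {
    subj <- db$proteins[db$proteins$id == h$subject_id, ]
    ann <- db$annotations[db$annotations$protein_id == h$subject_id, ,
                          drop = FALSE]
    rownames(ann) <- NULL
    sites <- map_sites_through_alignment(h, ann, subj$sequence,
                                         query_seq = query$sequence)
    list(hit = h, subject_description = subj$description, sites = sites)
  })
  structure(list(query = query, entries = entries,
                 params = list(max_evalue = max_evalue, max_hits = max_hits,
                               min_identity = min_identity,
                               min_coverage = min_coverage,
                               db_len = db_len)),
            class = "sites_report")
}

# Align one query against every database record.
align_against_db <- function(query, db) {
  if (nrow(db$proteins) == 0L) return(list())
  matrix <- default_matrix()
  lapply(seq_len(nrow(db$proteins)), function(i) {
    local_align(query$sequence, db$proteins$sequence[i], matrix = matrix,
                query_id = query$id, subject_id = db$proteins$id[i])
  })
}

#' @export
print.sites_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

#' Import hits from BLAST tabular output
#'
#' Reads `outfmt 6`-style tab-separated output with the columns
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore qseq sseq` (the two trailing aligned-row columns are
#' required to reconstruct alignments).
#'
#' @param text tabular text or file path.
#' @return list of `pairwise_hit` objects with E-values populated.
#' @export
import_blast_tab <- function(text) {
  lines <- as_lines(text)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qseq", "sseq")
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                           header = FALSE, quote = "",
                           colClasses = "character")
  if (ncol(tab) != length(cols)) {
    stop("expected ", length(cols), " tab-separated columns, got ",
         ncol(tab))
  }
  names(tab) <- cols
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    structure(list(
      query_id = r$qseqid, subject_id = r$sseqid,
      raw_score = NA_integer_, bit_score = as.numeric(r$bitscore),
      evalue = as.numeric(r$evalue),
      q_aligned = toupper(r$qseq), s_aligned = toupper(r$sseq),
      q_start = as.integer(r$qstart), q_end = as.integer(r$qend),
      s_start = as.integer(r$sstart), s_end = as.integer(r$send)),
      class = "pairwise_hit")
  })
}
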