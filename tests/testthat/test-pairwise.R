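# Local alignment, E-values, identity/coverage, hit ranking, site mapping
# through alignments, and label formatting.

test_that("self-alignment of identical sequences scores the matrix diagonal", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  hit <- local_align(s, s)
  expect_identical(hit$q_aligned, s)
  expect_identical(hit$s_aligned, s)
  expect_identical(hit$q_start, 1L)
  expect_identical(hit$q_end, 20L)
  expect_identical(hit$raw_score,
                   as.integer(sum(diag(blosum62)[strsplit(s, "")[[1]]])))
  expect_equal(percent_identity(hit), 100)
})

test_that("all-negative pairs give an empty zero-score alignment", {
  hit <- local_align("AAAA", "CCCC")
  expect_identical(hit$raw_score, 0L)
  expect_identical(hit$q_aligned, "")
  expect_equal(query_coverage(hit, 4L), 0)
})

test_that("local alignment score is symmetric in its arguments", {
  set.seed(41)
  for (i in 1:15) {
    q <- random_seq(sample(8:25, 1))
    s <- random_seq(sample(8:25, 1))
    expect_identical(local_align(q, s)$raw_score,
                     local_align(s, q)$raw_score)
  }
})

test_that("aligner matches the textbook Smith-Waterman oracle on random pairs", {
  set.seed(42)
  for (i in 1:60) {
    q <- random_seq(sample(5:30, 1))
    s <- random_seq(sample(5:30, 1))
    hit <- local_align(q, s)
    expect_identical(hit$raw_score, as.integer(sw_oracle_score(q, s)))
    validate_hit(hit, q, s)
    if (!is_empty_hit(hit)) {
      # the returned alignment itself scores the optimum
      expect_equal(score_alignment(hit$q_aligned, hit$s_aligned),
                   hit$raw_score)
    }
  }
})

test_that("invalid characters are rejected by name", {
  expect_error(local_align("AC1DE", "ACDE"), "1")
  expect_error(local_align("ACDE", "AC?DE"), "\\?")
})

test_that("score_to_evalue follows the Karlin-Altschul closed form", {
  se <- score_to_evalue(100, 250, 1e6)
  expect_equal(se$evalue, 250 * 1e6 * 2^(-se$bit_score))
  # +1 bit halves E
  s2 <- score_to_evalue(100 + log(2) / 0.267, 250, 1e6)
  expect_equal(s2$bit_score, se$bit_score + 1)
  expect_equal(s2$evalue, se$evalue / 2)
  # bit = 0 <=> S = ln(K)/lambda; then E = m*n
  s0 <- log(0.041) / 0.267
  expect_equal(score_to_evalue(s0, 100, 1000)$evalue, 100000)
  # strictly decreasing in raw score
  ev <- vapply(1:50, function(s) score_to_evalue(s, 100, 1e5)$evalue,
               numeric(1))
  expect_true(all(diff(ev) < 0))
})

test_that("percent identity and coverage follow the stated conventions", {
  mk <- function(qa, sa) {
    structure(list(q_aligned = qa, s_aligned = sa, q_start = 1L,
                   q_end = sum(strsplit(qa, "")[[1]] != "-"),
                   s_start = 1L,
                   s_end = sum(strsplit(sa, "")[[1]] != "-")),
              class = "pairwise_hit")
  }
  expect_equal(percent_identity(mk("AC-D", "ACED")), 75)
  expect_equal(percent_identity(mk("ACDE", "ACDF")), 75)
  expect_error(percent_identity(mk("", "")), "zero-length")
  h <- mk("ACDEF", "ACDEF")
  h$q_start <- 11L; h$q_end <- 80L
  expect_equal(query_coverage(h, 100L), 0.70)
  h$q_start <- 5L; h$q_end <- 5L
  expect_equal(query_coverage(h, 100L), 0.01)
})

test_that("rank_and_filter enforces cutoffs, ordering and per-subject dedup", {
  mk <- function(subject, ev, bits, qa = "ACDE", sa = "ACDE") {
    structure(list(query_id = "q", subject_id = subject, raw_score = 10L,
                   bit_score = bits, evalue = ev, q_aligned = qa,
                   s_aligned = sa, q_start = 1L, q_end = 4L, s_start = 1L,
                   s_end = 4L), class = "pairwise_hit")
  }
  hits <- lapply(1:25, function(i) mk(sprintf("S%02d", i), 1e-6 * i, 50 - i))
  out <- rank_and_filter_hits(hits, max_evalue = 0.001, max_hits = 20)
  expect_length(out, 20)
  ev <- vapply(out, `[[`, numeric(1), "evalue")
  expect_true(all(diff(ev) >= 0))

  # E above the cutoff excluded
  expect_length(rank_and_filter_hits(list(mk("S1", 0.01, 30))), 0)
  expect_length(rank_and_filter_hits(list()), 0)

  # best hit per subject kept
  two <- list(mk("S1", 1e-8, 40), mk("S1", 1e-4, 20), mk("S2", 1e-5, 30))
  out2 <- rank_and_filter_hits(two)
  expect_length(out2, 2)
  expect_identical(out2[[1]]$subject_id, "S1")
  expect_equal(out2[[1]]$evalue, 1e-8)

  # ties on E broken by descending bit score
  tie <- list(mk("S1", 1e-6, 20), mk("S2", 1e-6, 45))
  expect_identical(rank_and_filter_hits(tie)[[1]]$subject_id, "S2")

  # identity and coverage thresholds
  weak <- mk("S3", 1e-9, 50, qa = "AAAA", sa = "CCCC")
  expect_length(rank_and_filter_hits(list(weak), min_identity = 30), 0)
  short <- mk("S4", 1e-9, 50)
  expect_length(rank_and_filter_hits(list(short), min_coverage = 0.7,
                                     query_len = 100L), 0)
})

test_that("site mapping handles identity, gaps, substitutions and offsets", {
  mk <- function(qa, sa, qs = 1L, ss = 1L) {
    structure(list(query_id = "q", subject_id = "s", raw_score = 1L,
                   bit_score = 10, evalue = 1e-9, q_aligned = qa,
                   s_aligned = sa, q_start = qs,
                   q_end = qs + sum(strsplit(qa, "")[[1]] != "-") - 1L,
                   s_start = ss,
                   s_end = ss + sum(strsplit(sa, "")[[1]] != "-") - 1L),
              class = "pairwise_hit")
  }
  ann <- site_annotation("s", "swissprot", "active", 3L)

  m1 <- map_sites_through_alignment(mk("ACDEF", "ACDEF"), ann, "ACDEF",
                                    "ACDEF")
  expect_identical(m1$status, "match")
  expect_identical(m1$query_pos, 3L)
  expect_identical(m1$subject_res, "D")

  m2 <- map_sites_through_alignment(mk("AC-EF", "ACDEF"), ann, "ACDEF",
                                    "ACEF")
  expect_identical(m2$status, "unaligned")
  expect_true(is.na(m2$query_pos))

  m3 <- map_sites_through_alignment(mk("ACREF", "ACDEF"), ann, "ACDEF",
                                    "ACREF")
  expect_identical(m3$status, "mismatch")
  expect_identical(m3$query_res, "R")

  # coordinate offsets: identity rows starting at q 9 / s 12
  ann12 <- site_annotation("s", "swissprot", "active", 12L)
  full_s <- paste0(strrep("G", 11), "ACDEF")
  full_q <- paste0(strrep("G", 8), "ACDEF")
  m4 <- map_sites_through_alignment(mk("ACDEF", "ACDEF", 9L, 12L), ann12,
                                    full_s, full_q)
  expect_identical(m4$query_pos, 9L)
  expect_identical(m4$status, "match")

  # X never matches, even against X
  mx <- map_sites_through_alignment(mk("AXD", "AXD"),
                                    site_annotation("s", "swissprot",
                                                    "active", 2L),
                                    "AXD", "AXD")
  expect_identical(mx$status, "mismatch")

  # corrupt annotation position -> error
  expect_error(
    map_sites_through_alignment(mk("ACD", "ACD"),
                                site_annotation("s", "swissprot", "active",
                                                9L), "ACD"),
    "exceeds subject length")
})

test_that("site mapping agrees with the column-walk oracle on random triples", {
  set.seed(99)
  n_checked <- 0
  while (n_checked < 120) {
    q <- random_seq(sample(20:60, 1))
    s <- random_seq(sample(20:60, 1))
    hit <- local_align(q, s)
    if (is_empty_hit(hit)) next
    slen <- nchar(s)
    positions <- sort(sample(slen, min(5, slen)))
    ann <- site_annotation("subject", "swissprot", "active", positions)
    got <- map_sites_through_alignment(hit, ann, s, q)
    for (i in seq_len(nrow(got))) {
      want <- map_site_oracle(hit, got$subject_pos[i], s, q)
      expect_identical(got$status[i], want$status)
      expect_identical(got$subject_res[i], want$subject_res)
      if (!is.na(want$query_pos)) {
        expect_identical(got$query_pos[i], as.integer(want$query_pos))
        expect_identical(got$query_res[i], want$query_res)
      }
      n_checked <- n_checked + 1
    }
    # invariant: subject->query map strictly increasing over aligned sites
    aligned <- got[got$status != "unaligned", ]
    if (nrow(aligned) > 1) {
      expect_true(all(diff(aligned$query_pos) > 0))
    }
    # reported residues equal the source sequences at reported positions
    if (nrow(aligned) > 0) {
      expect_identical(aligned$query_res,
                       toupper(substring(q, aligned$query_pos,
                                         aligned$query_pos)))
    }
    expect_identical(got$subject_res,
                     toupper(substring(s, got$subject_pos,
                                       got$subject_pos)))
  }
})

test_that("site labels follow the report grammar", {
  mism <- data.frame(subject_res = "E", subject_pos = 41L, query_res = "R",
                     query_pos = 38L, status = "mismatch",
                     stringsAsFactors = FALSE)
  expect_identical(format_site_label(mism), "E41 (≠ R38)")
  match <- data.frame(subject_res = "D", subject_pos = 12L, query_res = "D",
                      query_pos = 9L, status = "match",
                      stringsAsFactors = FALSE)
  expect_identical(format_site_label(match), "D12 (= D9)")
  unal <- data.frame(subject_res = "K", subject_pos = 7L,
                     query_res = NA_character_, query_pos = NA_integer_,
                     status = "unaligned", stringsAsFactors = FALSE)
  expect_identical(format_site_label(unal), "K7 (unaligned)")
})

test_that("sitesblast_report ranks the exact self-hit first with all matches", {
  fx <- generate_fixture_database(seed = 3L, n_proteins = 5L)
  db <- fx$expected
  # pick an annotated record as the query
  qid <- db$annotations$protein_id[1]
  qrec <- db$proteins[db$proteins$id == qid, ]
  query <- list(id = "QUERY", description = "self", sequence = qrec$sequence)
  rep <- sitesblast_report(query, db)
  expect_gt(length(rep$entries), 0)
  top <- rep$entries[[1]]
  expect_identical(top$hit$subject_id, qid)
  expect_equal(percent_identity(top$hit), 100)
  expect_true(all(top$sites$status == "match"))
  # hits sorted by ascending evalue
  ev <- vapply(rep$entries, function(e) e$hit$evalue, numeric(1))
  expect_true(all(diff(ev) >= 0))
})

test_that("a query with no positive-scoring hit yields an empty report", {
  prot <- data.frame(id = "P1", description = "", sequence = "MKVLAADTGH",
                     stringsAsFactors = FALSE)
  db <- build_database(prot, site_annotation("P1", "swissprot", "active", 2L))
  rep <- sitesblast_report(list(id = "q", description = "",
                                sequence = "WWWWWWWW"), db)
  expect_length(rep$entries, 0)
  # empty database is not an error either
  rep0 <- sitesblast_report(list(id = "q", description = "",
                                 sequence = "ACDEF"),
                            build_database(empty_proteins()))
  expect_length(rep0$entries, 0)
})

test_that("report serializations are well-formed and carry the labels", {
  fx <- generate_fixture_database(seed = 3L, n_proteins = 4L)
  db <- fx$expected
  qid <- db$annotations$protein_id[1]
  query <- list(id = "Q1", description = "d",
                sequence = db$proteins$sequence[db$proteins$id == qid])
  rep <- sitesblast_report(query, db)
  txt <- format_report_text(rep)
  expect_true(any(grepl("^Query: Q1", txt)))
  js <- jsonlite::fromJSON(format_report_json(rep), simplifyVector = FALSE)
  expect_identical(js$query$id, "Q1")
  expect_identical(js$hits[[1]]$subject_id, qid)
  expect_true(length(js$hits[[1]]$sites) > 0)
  html <- format_report_html(rep)
  expect_true(startsWith(html, "<!DOCTYPE html>"))
  doc <- xml2::read_html(html)
  expect_gt(length(xml2::xml_find_all(doc, "//span[@class='site match']")),
            0)
})

test_that("BLAST tabular import reconstructs scored hits", {
  tabline <- paste("Q1", "S1", "100.000", "4", "0", "0", "1", "4", "3", "6",
                   "1e-05", "22.3", "ACDE", "ACDE", sep = "\t")
  hits <- import_blast_tab(tabline)
  expect_length(hits, 1)
  h <- hits[[1]]
  expect_identical(h$subject_id, "S1")
  expect_equal(h$evalue, 1e-5)
  expect_identical(h$s_start, 3L)
  expect_identical(h$q_aligned, "ACDE")
  expect_error(import_blast_tab("a\tb\tc"), "columns")
})
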