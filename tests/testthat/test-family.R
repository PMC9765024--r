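# Trimming, distances, homolog selection, site transfer, pattern search,
# anchor numbering and label search.

test_that("trimming removes >=50%-gap columns and lowercase-majority columns", {
  m <- msa(c("a", "b", "c", "d"),
           c("A-aAC",
             "A-aAC",
             "AAA-C",
             "AA--C"))
  # col1: 0 gaps keep; col2: 3/4 gaps remove; col3: 3 lower 1 upper remove;
  # col4: 2/4 gaps = exactly 50% -> removed; col5 keep.
  tr <- trim_alignment(m)
  expect_identical(tr$column_map, c(1L, 5L))
  expect_identical(tr$msa$rows, c("AC", "AC", "AC", "AC"))

  # lowercase tie (2 vs 2) keeps the column
  m2 <- msa(c("a", "b", "c", "d"), c("aA", "aA", "AA", "AA"))
  tr2 <- trim_alignment(m2)
  expect_identical(tr2$column_map, c(1L, 2L))

  # toggles disable each rule independently
  no_gap_rule <- trim_alignment(m, trim_gaps = FALSE)
  expect_identical(no_gap_rule$column_map, c(1L, 2L, 4L, 5L))
  no_case_rule <- trim_alignment(m, trim_case = FALSE)
  expect_identical(no_case_rule$column_map, c(1L, 3L, 5L))
  neither <- trim_alignment(m, trim_gaps = FALSE, trim_case = FALSE)
  expect_identical(neither$column_map, seq_len(5L))
  expect_identical(neither$msa$rows, m$rows)

  # gapless all-uppercase alignment is unchanged
  m3 <- msa(c("a", "b"), c("ACDE", "ACDE"))
  expect_identical(trim_alignment(m3)$column_map, 1:4)

  # all columns removed -> actionable error
  m4 <- msa(c("a", "b"), c("a-", "-a"))
  expect_error(trim_alignment(m4), "disable")
})

test_that("trim invariants hold on random alignments", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    rows <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "d", "-", "."), 40, replace = TRUE,
                   prob = c(4, 4, 2, 3, 1)), collapse = "")
    }, character(1))
    rows[1] <- paste0("K", substr(rows[1], 2, 40))  # keep >=1 column
    m <- tryCatch(msa(sprintf("s%d", 1:n), rows), error = function(e) NULL)
    if (is.null(m)) next
    tr <- tryCatch(trim_alignment(m), error = function(e) NULL)
    if (is.null(tr)) next
    expect_true(all(diff(tr$column_map) > 0))
    grid <- do.call(rbind, strsplit(m$rows, ""))
    for (j in tr$column_map) {
      col <- grid[, j]
      expect_lt(mean(col %in% c("-", ".")), 0.5)
      low <- sum(col %in% letters)
      up <- sum(!(col %in% c("-", "."))) - low
      expect_lte(low, up)
    }
  }
})

test_that("distances follow the Poisson correction with saturation clamp", {
  m <- msa(c("a", "b"), c("ACDEFGHIKL", "ACDEFGHIKL"))
  expect_equal(compute_distance_matrix(m)["a", "b"], 0)

  # 10 mismatches over 100 shared columns
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("C", 10), strrep("A", 90))
  m2 <- msa(c("a", "b"), c(s1, s2))
  expect_equal(compute_distance_matrix(m2)["a", "b"], -log(0.9))

  # saturation: all-different rows clamp to 3.0
  m3 <- msa(c("a", "b"), c(strrep("A", 20), strrep("C", 20)))
  expect_equal(compute_distance_matrix(m3)["a", "b"], 3.0)

  # no shared columns errors naming the pair
  m4 <- msa(c("a", "b"), c("AC--", "--DE"))
  expect_error(compute_distance_matrix(m4), "'a' and 'b'")

  # brute-force recomputation on random alignments
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    rows <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "k", "-"), 30, replace = TRUE),
            collapse = "")
    }, character(1))
    m5 <- tryCatch(msa(sprintf("s%d", 1:n), rows), error = function(e) NULL)
    if (is.null(m5)) next
    D <- tryCatch(compute_distance_matrix(m5), error = function(e) NULL)
    if (is.null(D)) next
    expect_true(isSymmetric(unname(D)))
    expect_true(all(diag(D) == 0))
    # independent per-pair walk
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        a <- toupper(strsplit(rows[i], "")[[1]])
        b <- toupper(strsplit(rows[j], "")[[1]])
        ok <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
        p <- sum(a[ok] != b[ok]) / sum(ok)
        want <- if (p >= 0.95) 3.0 else -log(1 - p)
        expect_equal(D[i, j], want)
      }
    }
  }
})

test_that("homolog selection enforces identity, coverage and dedup", {
  set.seed(23)
  base <- random_seq(80)
  mutate_pct <- function(s, pct) {
    cc <- strsplit(s, "")[[1]]
    k <- round(length(cc) * pct)
    at <- sample(length(cc), k)
    cc[at] <- vapply(cc[at], function(x) sample(setdiff(AA_STANDARD, x), 1),
                     character(1))
    paste(cc, collapse = "")
  }
  pool <- data.frame(
    id = c("close", "mid", "far", "short", "same"),
    description = c("90% id", "60% id", "25% id", "half-cover", "query"),
    sequence = c(mutate_pct(base, 0.10), mutate_pct(base, 0.40),
                 mutate_pct(base, 0.75), substr(base, 1, 40), base),
    stringsAsFactors = FALSE)
  query <- list(id = "Q", description = "query", sequence = base)
  out <- select_homologs(query, list(pool))
  expect_identical(out$id[1], "Q")
  # the query's own sequence under another id is deduplicated away
  expect_false("same" %in% out$id)
  expect_true("close" %in% out$id)
  expect_false("far" %in% out$id)    # 25% identity < 30
  expect_false("short" %in% out$id)  # 50% coverage < 70
  # max_seqs truncation
  out2 <- select_homologs(query, list(pool), max_seqs = 1)
  expect_identical(out2$id, "Q")
})

test_that("known sites transfer to the columns holding their residues", {
  prot <- data.frame(id = c("P1", "P2"),
                     description = "",
                     sequence = c("ACDEF", "ACDE"),
                     stringsAsFactors = FALSE)
  ann <- rbind(site_annotation("P1", "swissprot", "active", 3L),
               site_annotation("P1", "swissprot", "binding", 5L,
                               ligand = "ZN"))
  db <- build_database(prot, ann)
  m <- msa(c("P1", "P2", "other"),
           c("AC--DEF", "AC--DE-", "ACKKDEF"))
  ts <- transfer_known_sites(m, db)
  # only P1 carries annotations; P2 matches the db but has none to transfer
  expect_identical(names(ts), "P1")
  p1 <- ts[["P1"]]
  # ungapped position 3 (D) sits in column 5
  expect_identical(p1$column[p1$position == 3L], 5L)
  expect_identical(p1$column[p1$position == 5L], 7L)
  # gapless row: column equals position
  m2 <- msa(c("P1"), c("ACDEF"))
  expect_identical(transfer_known_sites(m2, db)[["P1"]]$column[1], 3L)
  # unmatched rows carry no entry
  expect_false("other" %in% names(ts))
})

test_that("anchor mapping and its inverse are consistent", {
  m <- msa(c("anchor", "b"), c("A-CD", "AACD"))
  expect_identical(map_anchor_positions(m, "anchor", 2L), 3L)
  expect_identical(map_anchor_positions(m, "anchor", c(1L, 3L)), c(1L, 4L))
  expect_error(map_anchor_positions(m, "anchor", 9L), "beyond the anchor")
  expect_identical(anchor_position_of_column(m, "anchor", 3L), 2L)
  expect_true(is.na(anchor_position_of_column(m, "anchor", 2L)))
  # gapless anchor: identity both ways
  m2 <- msa(c("anchor"), c("ACDEF"))
  expect_identical(map_anchor_positions(m2, "anchor", 1:5), 1:5)
  expect_identical(anchor_position_of_column(m2, "anchor", 1:5), 1:5)
})

test_that("transfer and anchor mapping agree for the anchor itself", {
  set.seed(47)
  for (rep in 1:10) {
    seqn <- random_seq(40)
    cc <- strsplit(seqn, "")[[1]]
    at <- sort(sample(40, 6))
    row <- character(46)
    row[] <- "-"
    row[setdiff(1:46, at)] <- cc
    row <- paste(row[1:46], collapse = "")
    prot <- data.frame(id = "P", description = "", sequence = seqn,
                       stringsAsFactors = FALSE)
    pos <- sort(sample(40, 4))
    db <- build_database(prot,
                         site_annotation("P", "swissprot", "active", pos))
    m <- msa("P", row)
    via_transfer <- transfer_known_sites(m, db)[["P"]]$column
    via_anchor <- map_anchor_positions(m, "P", pos)
    expect_identical(via_transfer, via_anchor)
  }
})

test_that("pattern search matches the named example patterns", {
  m <- msa(c("r1", "r2", "r3"),
           c("MCAACG---DEADKL",
             "M--CAACGDEAHKLX",
             "NSGDEAKCAAC----"))
  # CxxC: overlapping matches allowed
  cx <- find_pattern(m, "CxxC")
  expect_true(all(c("r1", "r2", "r3") %in% cx$protein_id))
  r1 <- cx[cx$protein_id == "r1", ]
  expect_identical(r1$start_pos, 2L)
  expect_identical(r1$matched, "CAAC")
  # DEA[DH] matches DEAD and DEAH but not DEAK
  dea <- find_pattern(m, "DEA[DH]")
  expect_setequal(dea$protein_id, c("r1", "r2"))
  expect_setequal(dea$matched, c("DEAD", "DEAH"))
  # NSG present only in r3
  nsg <- find_pattern(m, "NSG")
  expect_identical(nsg$protein_id, "r3")
  expect_identical(nsg$start_pos, 1L)
  # no match -> empty frame
  expect_identical(nrow(find_pattern(m, "WWW")), 0L)
  # column mapping respects gaps: r1 DEAD starts after a 3-column gap
  expect_identical(dea$columns[[which(dea$protein_id == "r1")]],
                   c(10L, 11L, 12L, 13L))
  # malformed patterns error with position
  expect_error(find_pattern(m, "DEA[DH"), "position 4")
  expect_error(find_pattern(m, "a"), "position 1")
})

test_that("pattern search equals a reference regex scan on random cases", {
  set.seed(61)
  n_cases <- 0
  while (n_cases < 300) {
    row <- paste(sample(c(AA_STANDARD, "-", "."), 50, replace = TRUE,
                        prob = c(rep(2, 20), 5, 2)), collapse = "")
    if (!grepl("[A-Z]", row)) next
    m <- msa("r", row)
    k <- sample(2:4, 1)
    toks <- replicate(k, {
      r <- runif(1)
      if (r < 0.5) sample(c("A", "C", "D", "G", "K"), 1)
      else if (r < 0.8) "x"
      else paste0("[", paste(sample(LETTERS[1:11], 2), collapse = ""), "]")
    })
    pattern <- paste(toks, collapse = "")
    got <- find_pattern(m, pattern)
    # reference: plain regex with lookahead on the degapped row
    seqn <- toupper(gsub("[-.]", "", row))
    ref_rx <- paste(vapply(toks, function(t) {
      if (t == "x") "[A-Z]" else t
    }, character(1)), collapse = "")
    ref <- gregexpr(paste0("(?=", ref_rx, ")"), seqn, perl = TRUE)[[1]]
    ref <- if (ref[1] == -1) integer() else as.integer(ref)
    expect_identical(got$start_pos, ref)
    # every reported match substring matches the reference regex
    if (nrow(got) > 0) {
      expect_true(all(grepl(paste0("^", ref_rx, "$"), got$matched)))
      # columns map back to the row's residues
      for (i in seq_len(nrow(got))) {
        cols <- got$columns[[i]]
        expect_identical(
          toupper(paste(strsplit(row, "")[[1]][cols], collapse = "")),
          got$matched[i])
      }
    }
    n_cases <- n_cases + max(1, nrow(got))
  }
})

test_that("label search is case-insensitive substring over id/description", {
  meta <- data.frame(
    id = c("BT2402", "KIN1", "ABC9"),
    description = c("alternative homoserine kinase", "protein kinase",
                    "transporter"),
    stringsAsFactors = FALSE)
  expect_identical(search_labels(meta, "BT2402"), "BT2402")
  expect_setequal(search_labels(meta, "kinase"), c("BT2402", "KIN1"))
  expect_identical(search_labels(meta, "zzz"), character(0))
})
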