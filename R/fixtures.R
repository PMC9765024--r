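# Synthetic fixture generator: emits Swiss-Prot DAT text and a BioLiP-style
# TSV, together with the ground-truth parsed database from its own
# bookkeeping.  Deterministic for a fixed seed, with deliberate edge cases:
# non-experimental evidence, excluded and retained VARIANTs, an unlisted
# feature type, ranged features, duplicate sequences within and across
# sources, and an out-of-range BioLiP row.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_fixed_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_protein_seq <- function(len) {
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic sites-database fixture
#'
#' Emits a small Swiss-Prot flat file and a BioLiP-style TSV plus the
#' expected parsed database, assembled by the generator's own bookkeeping
#' (not by the parsers), so the parse → build pipeline can be checked
#' against an independent ground truth.
#'
#' @param seed integer seed; outputs are byte-identical for equal seeds.
#' @param n_proteins number of Swiss-Prot entries to generate (>= 1).
#' @return a list with `swissprot_dat` and `biolip_tsv` (single strings),
#'   `expected` (a `sites_db`), and `expected_counts` (rejection totals the
#'   parse reports must reproduce).
#' @export
generate_fixture_database <- function(seed = 1L, n_proteins = 6L) {
  stopifnot(n_proteins >= 1L)
  with_fixed_seed(seed, {
    proteins <- empty_proteins()
    annotations <- empty_annotations()
    dat_entries <- character()
    n_reject <- c("unlisted type" = 0L, "no experimental evidence" = 0L,
                  "excluded VARIANT" = 0L)

    add_protein <- function(id, seqn, desc) {
      proteins <<- rbind(proteins, data.frame(
        id = id, description = desc, sequence = seqn,
        stringsAsFactors = FALSE))
    }
    book <- function(...) annotations <<- rbind(annotations,
                                                site_annotation(...))

    for (k in seq_len(n_proteins)) {
      id <- sprintf("SYN%04d", k)
      desc <- sprintf("Synthetic fixture protein %d", k)
      dup_of <- NULL
      if (k == n_proteins && n_proteins >= 2L) {
        # duplicate sequence under a different accession
        seqn <- proteins$sequence[1]
        dup_of <- proteins$id[1]
      } else {
        seqn <- random_protein_seq(sample(60:120, 1L))
      }
      L <- nchar(seqn)
      add_protein(id, seqn, desc)
      canon <- if (is.null(dup_of)) id else dup_of

      fts <- list()
      ev_ok <- sprintf("ECO:0000269|PubMed:%d", 100000L + k)

      p_act <- sample(5:(L - 5L), 1L)
      fts <- c(fts, list(list(key = "ACT_SITE", loc = as.character(p_act),
                              quals = c(sprintf('/note="Nucleophile"'),
                                        sprintf('/evidence="%s"', ev_ok)))))
      book(canon, "swissprot", "active", p_act,
           comment = "Nucleophile", evidence = ev_ok)

      p_met <- sort(sample(setdiff(1:L, p_act), 2L))
      for (p in p_met) {
        fts <- c(fts, list(list(key = "METAL", loc = as.character(p),
                                quals = c('/note="Zinc"',
                                          sprintf('/evidence="%s"', ev_ok)))))
        book(canon, "swissprot", "binding", p,
             comment = "Zinc", evidence = ev_ok)
      }

      if (k == 1L) {
        # rejected: predicted evidence only
        fts <- c(fts, list(list(key = "ACT_SITE", loc = "3",
                                quals = c('/note="Proton acceptor"',
                                          '/evidence="ECO:0000255"'))))
        n_reject["no experimental evidence"] <-
          n_reject["no experimental evidence"] + 1L
        # rejected: VARIANT naming only a dbSNP entry
        fts <- c(fts, list(list(key = "VARIANT", loc = "4",
                                quals = c('/note="in dbSNP:rs12345"',
                                          sprintf('/evidence="%s"', ev_ok)))))
        n_reject["excluded VARIANT"] <- n_reject["excluded VARIANT"] + 1L
        # accepted ranged DISULFID: endpoints only
        ends <- c(6L, L - 2L)
        fts <- c(fts, list(list(
          key = "DISULFID", loc = sprintf("%d..%d", ends[1], ends[2]),
          quals = sprintf('/evidence="%s"', ev_ok))))
        book(canon, "swissprot", "modified", ends,
             comment = "", evidence = ev_ok)
      }
      if (k == 2L && n_proteins >= 2L) {
        # accepted span REGION, expanded residue-by-residue
        a <- sample(2:(L - 8L), 1L)
        fts <- c(fts, list(list(
          key = "REGION", loc = sprintf("%d..%d", a, a + 5L),
          quals = c('/note="Substrate binding"',
                    sprintf('/evidence="%s"', ev_ok)))))
        book(canon, "swissprot", "functional_other", a:(a + 5L),
             comment = "Substrate binding", evidence = ev_ok)
        # rejected: unlisted feature type
        fts <- c(fts, list(list(key = "HELIX", loc = "1..9",
                                quals = sprintf('/evidence="%s"', ev_ok))))
        n_reject["unlisted type"] <- n_reject["unlisted type"] + 1L
      }
      if (k == 3L && n_proteins >= 3L) {
        # VARIANT with an informative comment is retained
        pv <- sample(seq_len(L), 1L)
        fts <- c(fts, list(list(
          key = "VARIANT", loc = as.character(pv),
          quals = c('/note="L -> P: loss of kinase activity"',
                    sprintf('/evidence="%s"', ev_ok)))))
        book(canon, "swissprot", "modified", pv,
             comment = "L -> P: loss of kinase activity", evidence = ev_ok)
      }
      if (!is.null(dup_of)) {
        pm <- sample(seq_len(L), 1L)
        fts <- c(fts, list(list(
          key = "MUTAGENESIS", loc = as.character(pm),
          quals = c('/note="Loss of activity"',
                    sprintf('/evidence="%s"', ev_ok)))))
        book(canon, "swissprot", "mutagenesis", pm,
             comment = "Loss of activity", evidence = ev_ok)
      }
      dat_entries <- c(dat_entries,
                       format_dat_entry(id, desc, seqn, fts))
    }

    # BioLiP rows: fresh chains, plus one chain duplicating a Swiss-Prot
    # sequence (cross-source dedup) and one out-of-range row (rejected).
    biolip_rows <- character()
    header <- paste("pdb", "chain", "ligand", "binding_residues",
                    "active_residues", "sequence", sep = "\t")
    n_chains <- max(1L, ceiling(n_proteins / 2))
    for (k in seq_len(n_chains)) {
      pdb <- sprintf("1ab%d", k)
      seqn <- random_protein_seq(sample(60:100, 1L))
      id <- paste0(pdb, "_A")
      add_protein(id, seqn, paste0("PDB ", pdb, " chain A"))
      pb <- sort(sample(seq_len(nchar(seqn)), 3L))
      btok <- paste0(substring(seqn, pb, pb), pb, collapse = " ")
      atok <- ""
      if (k == 1L) {
        pa <- sample(setdiff(seq_len(nchar(seqn)), pb), 1L)
        atok <- paste0(substring(seqn, pa, pa), pa)
        book(id, "biolip", "active", pa, comment = "active site",
             pdb_chain = "A", evidence = pdb)
      }
      book(id, "biolip", "binding", pb, ligand = "ZN",
           comment = "binding to ZN", pdb_chain = "A", evidence = pdb)
      biolip_rows <- c(biolip_rows,
                       paste(pdb, "A", "ZN", btok, atok, seqn, sep = "\t"))
    }
    if (n_proteins >= 2L) {
      seqn <- proteins$sequence[2]
      id <- "2dup_B"
      add_protein(id, seqn, "PDB 2dup chain B")
      pb <- sort(sample(seq_len(nchar(seqn)), 2L))
      book("SYN0002", "biolip", "binding", pb, ligand = "MG",
           comment = "binding to MG", pdb_chain = "B", evidence = "2dup")
      biolip_rows <- c(biolip_rows, paste(
        "2dup", "B", "MG",
        paste0(substring(seqn, pb, pb), pb, collapse = " "), "",
        seqn, sep = "\t"))
    }
    # rejected row: residue index beyond the chain
    bad_seq <- random_protein_seq(50L)
    biolip_rows <- c(biolip_rows,
                     paste("9bad", "C", "CA", "D999", "", bad_seq,
                           sep = "\t"))

    expected <- expected_database(proteins, annotations)
    list(
      swissprot_dat = paste(dat_entries, collapse = ""),
      biolip_tsv = paste(c(header, biolip_rows, ""), collapse = "\n"),
      expected = expected,
      expected_counts = list(
        swissprot_rejected = as.list(n_reject),
        biolip_rejected_rows = 1L,
        n_annotations = nrow(annotations)))
  })
}

#' Generate a synthetic homologous family around a base sequence
#'
#' Emits point-substitution mutants of `base` at increasing divergence,
#' including one remote outlier below the usual 30%-identity inclusion
#' threshold.  Deterministic for a fixed seed.
#'
#' @param base base amino-acid sequence.
#' @param seed integer seed.
#' @param n number of family members to emit (>= 2).
#' @return data frame `id`, `description`, `sequence`.
#' @export
generate_fixture_family <- function(base, seed = 1L, n = 6L) {
  stopifnot(n >= 2L)
  with_fixed_seed(seed + 7919L, {
    L <- nchar(base)
    rates <- c(seq(0.05, 0.45, length.out = n - 1L), 0.85)
    seqs <- vapply(rates, function(r) {
      cc <- chars(base)
      at <- sample(L, max(1L, round(L * r)))
      cc[at] <- vapply(cc[at],
                       function(x) sample(setdiff(AA_STANDARD, x), 1L),
                       character(1))
      paste(cc, collapse = "")
    }, character(1))
    data.frame(
      id = sprintf("FAM%03d", seq_len(n)),
      description = sprintf("synthetic family member (%.0f%% mutated)",
                            100 * rates),
      sequence = seqs, stringsAsFactors = FALSE)
  })
}

# Ground-truth database assembled directly (dedup bookkeeping is explicit in
# the generator: annotations are already booked under canonical ids).
expected_database <- function(proteins, annotations) {
  keep <- !duplicated(proteins$sequence)
  survivors <- proteins[keep, , drop = FALSE]
  rownames(survivors) <- NULL
  ann <- annotations[order(match(annotations$protein_id, survivors$id)), ,
                     drop = FALSE]
  rownames(ann) <- NULL
  structure(list(proteins = survivors, annotations = ann,
                 seq_index = stats::setNames(survivors$id,
                                             survivors$sequence)),
            class = "sites_db")
}

# Render one Swiss-Prot DAT entry.
format_dat_entry <- function(id, desc, seqn, features) {
  L <- nchar(seqn)
  lines <- c(
    sprintf("ID   %s_SYN%s Reviewed; %9d AA.", id,
            strrep(" ", max(0L, 15L - nchar(id) - 4L)), L),
    sprintf("AC   %s;", id),
    sprintf("DE   RecName: Full=%s;", desc))
  for (ft in features) {
    lines <- c(lines, sprintf("FT   %-15s%s", ft$key, ft$loc),
               paste0("FT                   ", ft$quals))
  }
  lines <- c(lines, sprintf(
    "SQ   SEQUENCE   %d AA;  %d MW;  0000000000000000 CRC64;", L, L * 110L))
  for (start in seq(1L, L, by = 60L)) {
    block <- substr(seqn, start, min(start + 59L, L))
    tens <- substring(block, seq(1L, nchar(block), 10L),
                      pmin(seq(10L, nchar(block) + 9L, 10L), nchar(block)))
    lines <- c(lines, paste0("     ", paste(tens, collapse = " ")))
  }
  paste0(paste(lines, collapse = "\n"), "\n//\n")
}
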