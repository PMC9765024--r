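# BioLiP-style records: one row per (PDB chain, ligand), with binding
# residues (and optional active-site residues) given as residue-letter +
# 1-based sequence position tokens, plus the chain's sequence.

#' Parse BioLiP-style binding/active-site records
#'
#' Expects a tab-separated table with columns `pdb`, `chain`, `ligand`,
#' `binding_residues`, `active_residues`, `sequence`.  Residue lists are
#' space-separated tokens like `"D12 H14"` (residue letter, then the 1-based
#' position in the chain sequence).  Each row yields a binding annotation
#' when `binding_residues` is nonempty (with the ligand code attached) and an
#' active-site annotation when `active_residues` is nonempty.  Rows whose
#' residue indices exceed the chain length are rejected with a warning; a
#' residue letter disagreeing with the sequence is warned about but the
#' position is kept.
#'
#' @param text TSV text (string or lines) or a file path.
#' @return list with `proteins`, `annotations`, and `report`
#'   (`n_accepted`, `n_rejected_rows`, `warnings`).
#' @export
parse_biolip_annotations <- function(text) {
  lines <- as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                           quote = "", colClasses = "character")
  need <- c("pdb", "chain", "ligand", "binding_residues", "active_residues",
            "sequence")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("BioLiP table lacks columns: ", paste(missing, collapse = ","))
  }
  proteins <- list()
  annotations <- list()
  warnings <- character()
  n_rejected <- 0L
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    id <- paste0(row$pdb, "_", row$chain)
    seq <- clean_sequence(row$sequence, id = id)
    res_bind <- parse_residue_tokens(row$binding_residues)
    res_act <- parse_residue_tokens(row$active_residues)
    all_pos <- c(res_bind$pos, res_act$pos)
    if (length(all_pos) == 0L) {
      n_rejected <- n_rejected + 1L
      warnings <- c(warnings, paste0(id, ": no residues listed; row skipped"))
      next
    }
    if (any(all_pos > nchar(seq))) {
      n_rejected <- n_rejected + 1L
      warnings <- c(warnings,
                    paste0(id, ": residue index ", max(all_pos),
                           " exceeds chain length ", nchar(seq),
                           "; row rejected"))
      next
    }
    check_letters <- function(tok) {
      got <- substring(seq, tok$pos, tok$pos)
      bad <- which(got != tok$letter)
      if (length(bad) > 0L) {
        warnings <<- c(warnings,
                       paste0(id, ": listed residue ", tok$letter[bad[1]],
                              tok$pos[bad[1]], " is ", got[bad[1]],
                              " in the chain sequence"))
      }
    }
    if (!(id %in% names(proteins))) {
      proteins[[id]] <- data.frame(
        id = id, description = paste0("PDB ", row$pdb, " chain ", row$chain),
        sequence = seq, stringsAsFactors = FALSE)
    }
    if (length(res_bind$pos) > 0L) {
      check_letters(res_bind)
      annotations[[length(annotations) + 1L]] <- site_annotation(
        protein_id = id, source = "biolip", category = "binding",
        positions = sort(unique(res_bind$pos)), ligand = row$ligand,
        comment = if (nzchar(row$ligand)) paste0("binding to ", row$ligand)
                  else "ligand binding",
        pdb_chain = row$chain, evidence = row$pdb)
    }
    if (length(res_act$pos) > 0L) {
      check_letters(res_act)
      annotations[[length(annotations) + 1L]] <- site_annotation(
        protein_id = id, source = "biolip", category = "active",
        positions = sort(unique(res_act$pos)), ligand = "",
        comment = "active site", pdb_chain = row$chain, evidence = row$pdb)
    }
  }
  list(
    proteins = if (length(proteins) > 0L) {
      out <- do.call(rbind, unname(proteins)); rownames(out) <- NULL; out
    } else empty_proteins(),
    annotations = if (length(annotations) > 0L) {
      do.call(rbind, annotations)
    } else empty_annotations(),
    report = list(n_accepted = length(annotations),
                  n_rejected_rows = n_rejected, warnings = warnings))
}

# "D12 H14" -> list(letter=c("D","H"), pos=c(12L,14L)); empty/NA -> empty.
parse_residue_tokens <- function(x) {
  x <- trimws(if (is.na(x)) "" else x)
  if (!nzchar(x)) return(list(letter = character(), pos = integer()))
  toks <- strsplit(x, "[[:space:]]+")[[1]]
  ok <- grepl("^[A-Za-z][0-9]+$", toks)
  if (!all(ok)) {
    stop("malformed residue token(s): ", paste(toks[!ok], collapse = ","))
  }
  list(letter = toupper(substr(toks, 1L, 1L)),
       pos = as.integer(sub("^[A-Za-z]", "", toks)))
}

# Merge parser outputs (same list(proteins, annotations) shape) prior to
# build_database().
merge_parsed <- function(...) {
  parts <- list(...)
  list(proteins = do.call(rbind, lapply(parts, `[[`, "proteins")),
       annotations = do.call(rbind, lapply(parts, `[[`, "annotations")))
}
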