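# The functional-site database: typed annotations on protein sequences with
# experimental support, deduplicated by exact sequence.

# Swiss-Prot feature keys admitted to each category.
FT_MODIFIED <- c("CARBOHYD", "CHAIN", "CONFLICT", "CROSSLNK", "DISULFID",
                 "INIT_MET", "LIPID", "MOD_RES", "NON_CONS", "NON_STD",
                 "PEPTIDE", "PROPEP", "SIGNAL", "TRANSIT", "UNSURE",
                 "VAR_SEQ", "VARIANT")
FT_BINDING <- c("BINDING", "CA_BIND", "DNA_BIND", "METAL", "NP_BIND")
FT_FUNCTIONAL <- c("ACT_SITE", "MOTIF", "REGION", "SITE")
FT_MUTAGENESIS <- "MUTAGENESIS"

# Endpoint-only ranged features (the two residues are covalently joined).
FT_ENDPOINTS <- c("DISULFID", "CROSSLNK")

# Span features longer than this keep only their endpoints.
SPAN_CAP <- 50L

SITE_CATEGORIES <- c("binding", "active", "modified", "mutagenesis",
                     "functional_other")

#' Construct a protein record
#'
#' @param id accession string, unique within a database.
#' @param sequence amino-acid string; cleaned via [clean_sequence()].
#' @param description free-text description.
#' @return a `protein_record` list with fields `id`, `description`, `sequence`.
#' @export
protein_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, description = description,
                 sequence = clean_sequence(sequence, id = id)),
            class = "protein_record")
}

#' Construct a functional-site annotation
#'
#' One experimentally supported feature on a protein: its source database,
#' category, 1-based residue positions in the protein's own numbering, and
#' supporting metadata.
#'
#' @param protein_id accession of the annotated protein.
#' @param source `"swissprot"` or `"biolip"`.
#' @param category one of `binding`, `active`, `modified`, `mutagenesis`,
#'   `functional_other`.
#' @param positions strictly increasing 1-based residue indices.
#' @param ligand ligand code (nonempty only for `binding`).
#' @param comment free text describing the site.
#' @param pdb_chain PDB chain identifier or empty.
#' @param evidence evidence string (e.g. an `ECO:0000269` reference or PDB id).
#' @return a one-row data frame with a `positions` list column.
#' @export
site_annotation <- function(protein_id, source, category, positions,
                            ligand = "", comment = "", pdb_chain = "",
                            evidence = "") {
  source <- match.arg(source, c("swissprot", "biolip"))
  category <- match.arg(category, SITE_CATEGORIES)
  positions <- as.integer(positions)
  if (length(positions) == 0L || any(diff(positions) <= 0L) ||
      any(positions < 1L)) {
    stop("positions must be a nonempty strictly increasing 1-based vector")
  }
  if (nzchar(ligand) && category != "binding") {
    stop("only binding annotations may carry a ligand code")
  }
  data.frame(protein_id = protein_id, source = source, category = category,
             ligand = ligand, comment = comment, pdb_chain = pdb_chain,
             evidence = evidence,
             positions = I(list(positions)),
             stringsAsFactors = FALSE)
}

# Empty annotation table with the canonical column layout.
empty_annotations <- function() {
  data.frame(protein_id = character(), source = character(),
             category = character(), ligand = character(),
             comment = character(), pdb_chain = character(),
             evidence = character(), positions = I(list()),
             stringsAsFactors = FALSE)
}

empty_proteins <- function() {
  data.frame(id = character(), description = character(),
             sequence = character(), stringsAsFactors = FALSE)
}

#' Classify a Swiss-Prot feature into a site category, or reject it
#'
#' Implements the admission rules for Swiss-Prot sequence features: only
#' feature types on the curated inclusion lists are kept, only features with
#' experimental evidence (an `ECO:0000269` evidence code) are kept, and
#' VARIANT features whose comment carries no functional information (only a
#' gene name, a strain name or a dbSNP reference) are dropped.
#'
#' A total function: every input yields either a category or a structured
#' rejection.
#'
#' @param feature_type Swiss-Prot feature key (e.g. `"ACT_SITE"`, `"METAL"`).
#' @param comment the feature's note/description text.
#' @param evidence_codes character vector of evidence strings.
#' @return a list with `accepted` (logical) and either `category` or
#'   `reason` (one of `"unlisted type"`, `"no experimental evidence"`,
#'   `"excluded VARIANT"`).
#' @export
classify_feature <- function(feature_type, comment = "",
                             evidence_codes = character()) {
  ft <- toupper(trimws(feature_type))
  reject <- function(reason) list(accepted = FALSE, reason = reason)
  category <-
    if (ft %in% FT_BINDING) "binding"
    else if (ft == "ACT_SITE") "active"
    else if (ft %in% FT_FUNCTIONAL) "functional_other"
    else if (ft %in% FT_MUTAGENESIS) "mutagenesis"
    else if (ft %in% FT_MODIFIED) "modified"
    else return(reject("unlisted type"))
  if (!any(grepl("ECO:0000269", evidence_codes, fixed = TRUE))) {
    return(reject("no experimental evidence"))
  }
  if (ft == "VARIANT" && variant_uninformative(comment)) {
    return(reject("excluded VARIANT"))
  }
  list(accepted = TRUE, category = category)
}

# A VARIANT comment is uninformative when it names only a gene, a strain or
# a dbSNP entry: empty text, any dbSNP reference, a single bare token, or a
# pure "in strain ..." phrase.
variant_uninformative <- function(comment) {
  txt <- trimws(comment)
  !nzchar(txt) ||
    grepl("dbSNP", txt, fixed = TRUE) ||
    grepl("^[A-Za-z0-9_.-]+$", txt) ||
    grepl("^in strain[^;,]*$", txt, ignore.case = TRUE)
}

# Expand a feature's FROM..TO range into stored positions:
#  * point features keep the single position;
#  * DISULFID/CROSSLNK keep both endpoints (the bonded pair);
#  * span features are expanded residue-by-residue up to SPAN_CAP residues,
#    beyond which only the endpoints are kept.
expand_feature_positions <- function(feature_type, from, to) {
  if (from == to) return(as.integer(from))
  if (toupper(feature_type) %in% FT_ENDPOINTS) return(as.integer(c(from, to)))
  if (to - from + 1L > SPAN_CAP) return(as.integer(c(from, to)))
  seq.int(from, to)
}

#' Build a deduplicated sites database
#'
#' Records are deduplicated by exact sequence: when several accessions share
#' a sequence, the first becomes the surviving record and all annotations are
#' merged onto it with positions unchanged (identical sequences share
#' numbering).  Annotations whose positions exceed their protein's length are
#' dropped with a warning.
#'
#' @param proteins data frame with columns `id`, `description`, `sequence`.
#' @param annotations annotation table as built by [site_annotation()].
#' @return a `sites_db` object: `proteins`, `annotations`, and `seq_index`
#'   mapping each exact sequence to its surviving record id.
#' @export
build_database <- function(proteins, annotations = empty_annotations()) {
  if (nrow(proteins) == 0L) {
    return(structure(list(proteins = empty_proteins(),
                          annotations = empty_annotations(),
                          seq_index = character()),
                     class = "sites_db"))
  }
  stopifnot(all(c("id", "description", "sequence") %in% names(proteins)))
  if (anyDuplicated(proteins$id)) {
    stop("duplicate protein ids: ",
         paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ","))
  }
  keep <- !duplicated(proteins$sequence)
  survivors <- proteins[keep, , drop = FALSE]
  rownames(survivors) <- NULL
  # id -> surviving id through the shared sequence
  canon <- stats::setNames(
    survivors$id[match(proteins$sequence, survivors$sequence)], proteins$id)
  ann <- annotations
  if (nrow(ann) > 0L) {
    orphans <- setdiff(ann$protein_id, proteins$id)
    if (length(orphans) > 0L) {
      stop("annotations reference unknown proteins: ",
           paste(unique(orphans), collapse = ","))
    }
    ann$protein_id <- unname(canon[ann$protein_id])
    lens <- nchar(survivors$sequence)[match(ann$protein_id, survivors$id)]
    bad <- vapply(seq_len(nrow(ann)),
                  function(i) max(ann$positions[[i]]) > lens[i], logical(1))
    if (any(bad)) {
      warning(sum(bad), " annotation(s) with out-of-range positions dropped",
              call. = FALSE)
      ann <- ann[!bad, , drop = FALSE]
    }
    ord <- order(match(ann$protein_id, survivors$id))
    ann <- ann[ord, , drop = FALSE]
    rownames(ann) <- NULL
  }
  structure(list(proteins = survivors, annotations = ann,
                 seq_index = stats::setNames(survivors$id,
                                             survivors$sequence)),
            class = "sites_db")
}

#' @export
print.sites_db <- function(x, ...) {
  cat("<sites_db> ", nrow(x$proteins), " distinct sequences, ",
      nrow(x$annotations), " annotations\n", sep = "")
  if (nrow(x$annotations) > 0L) {
    print(table(category = x$annotations$category,
                source = x$annotations$source))
  }
  invisible(x)
}

#' Look up annotations by exact sequence
#'
#' Gap characters (`-`, `.`) are removed and letters uppercased before the
#' exact-match lookup, so an aligned row matches its stored ungapped
#' sequence.
#'
#' @param db a `sites_db`.
#' @param seq possibly gapped and/or lowercase amino-acid string.
#' @return the matching record's annotation rows (zero rows when absent).
#' @export
lookup_by_sequence <- function(db, seq) {
  stopifnot(inherits(db, "sites_db"))
  key <- degap(seq)
  id <- unname(db$seq_index[key])
  if (length(id) == 0L || is.na(id)) return(empty_annotations())
  out <- db$annotations[db$annotations$protein_id == id, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- single-file relational store -------------------------------------------
# Two TSV tables (proteins, annotations) in one plain-text file, delimited by
# "#TABLE <name>" section headers; positions serialized as comma-joined ints.

#' Write a sites database to its single-file store
#'
#' @param db a `sites_db`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sites_store <- function(db, path) {
  stopifnot(inherits(db, "sites_db"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("#TABLE proteins", con)
  writeLines(paste("id", "description", "sequence", sep = "\t"), con)
  if (nrow(db$proteins) > 0L) {
    writeLines(paste(db$proteins$id, db$proteins$description,
                     db$proteins$sequence, sep = "\t"), con)
  }
  writeLines("#TABLE annotations", con)
  writeLines(paste("protein_id", "source", "category", "ligand", "comment",
                   "pdb_chain", "evidence", "positions", sep = "\t"), con)
  if (nrow(db$annotations) > 0L) {
    pos <- vapply(db$annotations$positions,
                  function(p) paste(p, collapse = ","), character(1))
    writeLines(paste(db$annotations$protein_id, db$annotations$source,
                     db$annotations$category, db$annotations$ligand,
                     db$annotations$comment, db$annotations$pdb_chain,
                     db$annotations$evidence, pos, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a sites database from its single-file store
#'
#' @param path file written by [write_sites_store()].
#' @return a `sites_db`.
#' @export
read_sites_store <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  marks <- grep("^#TABLE ", lines)
  if (length(marks) != 2L || lines[marks[1]] != "#TABLE proteins" ||
      lines[marks[2]] != "#TABLE annotations") {
    stop("not a sites store: ", path)
  }
  read_block <- function(body) {
    if (length(body) <= 1L) return(NULL)
    utils::read.delim(text = body, sep = "\t", quote = "",
                      colClasses = "character")
  }
  prot <- read_block(lines[(marks[1] + 1L):(marks[2] - 1L)])
  annb <- if (marks[2] < length(lines)) {
    read_block(lines[(marks[2] + 1L):length(lines)])
  } else NULL
  proteins <- if (is.null(prot)) empty_proteins() else prot
  ann <- empty_annotations()
  if (!is.null(annb)) {
    ann <- annb
    ann$positions <- I(lapply(strsplit(annb$positions, ",", fixed = TRUE),
                              as.integer))
  }
  build_database(proteins, ann)
}

#' Export a database's annotations as a flat TSV
#'
#' One annotation per row, positions comma-joined; a denormalized view for
#' spreadsheets and downstream scripts.
#'
#' @param db a `sites_db`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_annotations_tsv <- function(db, path) {
  stopifnot(inherits(db, "sites_db"))
  ann <- db$annotations
  flat <- data.frame(
    protein_id = ann$protein_id, source = ann$source,
    category = ann$category, ligand = ann$ligand, comment = ann$comment,
    pdb_chain = ann$pdb_chain, evidence = ann$evidence,
    positions = vapply(ann$positions, function(p) paste(p, collapse = ","),
                       character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
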