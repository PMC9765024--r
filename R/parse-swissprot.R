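# Swiss-Prot flat-file (DAT) parsing: entries delimited by "//", with ID/AC/DE
# header lines, an FT feature table (feature key + position(s), then indented
# /note= and /evidence= qualifier lines), and an SQ sequence block.

#' Parse Swiss-Prot flat-file feature records
#'
#' Reads DAT text, applies the feature admission rules of
#' [classify_feature()], and expands FROM..TO ranges into stored positions
#' (point features keep one position, disulfide/crosslink features keep both
#' endpoints, spans are expanded up to a cap).  Rejected and malformed
#' features are counted in the parse report, never silently dropped.
#'
#' @param text Swiss-Prot DAT text (single string or character vector of
#'   lines), or a file path.
#' @return a list with `proteins` (data frame `id`, `description`,
#'   `sequence`), `annotations` (see [site_annotation()]), and `report`: a
#'   list with `n_accepted`, `n_rejected`, rejection counts by reason, and
#'   `warnings`.
#' @export
parse_swissprot_features <- function(text) {
  lines <- as_lines(text)
  entry_ends <- grep("^//\\s*$", lines)
  entry_starts <- c(1L, utils::head(entry_ends, -1L) + 1L)
  if (length(entry_ends) == 0L && length(lines) > 0L) {
    stop("no '//' entry terminator found; not Swiss-Prot DAT text")
  }
  proteins <- list()
  annotations <- list()
  rejected <- c("unlisted type" = 0L, "no experimental evidence" = 0L,
                "excluded VARIANT" = 0L)
  warnings <- character()
  for (k in seq_along(entry_ends)) {
    entry <- lines[entry_starts[k]:(entry_ends[k] - 1L)]
    if (all(!nzchar(trimws(entry)))) next
    parsed <- parse_swissprot_entry(entry)
    warnings <- c(warnings, parsed$warnings)
    proteins[[length(proteins) + 1L]] <- parsed$protein
    for (ft in parsed$features) {
      cls <- classify_feature(ft$type, ft$comment, ft$evidence)
      if (!cls$accepted) {
        rejected[cls$reason] <- rejected[cls$reason] + 1L
        next
      }
      if (ft$to > nchar(parsed$protein$sequence)) {
        warnings <- c(warnings, paste0(parsed$protein$id, ": ", ft$type,
                                       " position ", ft$to,
                                       " beyond sequence end; skipped"))
        next
      }
      annotations[[length(annotations) + 1L]] <- site_annotation(
        protein_id = parsed$protein$id, source = "swissprot",
        category = cls$category,
        positions = expand_feature_positions(ft$type, ft$from, ft$to),
        ligand = if (cls$category == "binding") ft$ligand else "",
        comment = ft$comment,
        evidence = paste(ft$evidence, collapse = "; "))
    }
  }
  list(
    proteins = if (length(proteins) > 0L) {
      do.call(rbind, lapply(proteins, function(p) {
        data.frame(id = p$id, description = p$description,
                   sequence = p$sequence, stringsAsFactors = FALSE)
      }))
    } else empty_proteins(),
    annotations = if (length(annotations) > 0L) {
      do.call(rbind, annotations)
    } else empty_annotations(),
    report = list(n_accepted = length(annotations),
                  n_rejected = sum(rejected),
                  rejected_by_reason = as.list(rejected),
                  warnings = warnings))
}

as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, encoding = "UTF-8"))
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

# One entry's lines (without the trailing //) -> protein + raw features.
parse_swissprot_entry <- function(entry) {
  warnings <- character()
  tag <- substr(entry, 1L, 2L)
  body <- trimws(substr(entry, 6L, nchar(entry)))

  ac_line <- body[tag == "AC"][1]
  if (is.na(ac_line)) stop("entry without AC accession line")
  id <- sub(";.*$", "", ac_line)

  de <- body[tag == "DE"]
  description <- ""
  full <- grep("RecName: Full=", de, value = TRUE)
  if (length(full) > 0L) {
    description <- sub(";.*$", "", sub(".*Full=", "", full[1]))
    description <- sub("\\s*\\{[^}]*\\}", "", description)
  } else if (length(de) > 0L) {
    description <- sub(";.*$", "", de[1])
  }

  sq_at <- which(tag == "SQ")
  if (length(sq_at) == 0L) stop("entry ", id, " has no SQ sequence block")
  seq_lines <- entry[(sq_at[1] + 1L):length(entry)]
  sequence <- clean_sequence(paste(gsub("[[:space:]]", "", seq_lines),
                                   collapse = ""), id = id)

  # FT lines: a feature starts with a key in column 6; qualifier/continuation
  # lines are blank through column 21.
  ft_idx <- which(tag == "FT")
  features <- list()
  cur <- NULL
  flush <- function(cur, features) {
    if (!is.null(cur)) features[[length(features) + 1L]] <- cur
    features
  }
  for (i in ft_idx) {
    line <- entry[i]
    key_field <- trimws(substr(line, 6L, 20L))
    rest <- trimws(substr(line, 21L, nchar(line)))
    if (nzchar(key_field)) {
      features <- flush(cur, features)
      cur <- NULL
      loc <- parse_ft_location(rest)
      if (is.null(loc)) {
        warnings <- c(warnings, paste0(id, ": malformed FT location '",
                                       rest, "' for ", key_field,
                                       "; feature skipped"))
        next
      }
      cur <- list(type = key_field, from = loc[1], to = loc[2],
                  comment = "", ligand = "", evidence = character())
    } else if (!is.null(cur)) {
      if (grepl("^/note=", rest)) {
        cur$comment <- unquote_qualifier(sub("^/note=", "", rest))
      } else if (grepl("^/ligand=", rest)) {
        cur$ligand <- unquote_qualifier(sub("^/ligand=", "", rest))
      } else if (grepl("^/evidence=", rest)) {
        ev <- unquote_qualifier(sub("^/evidence=", "", rest))
        cur$evidence <- trimws(strsplit(ev, ",", fixed = TRUE)[[1]])
      }
      # other qualifiers ignored
    }
  }
  features <- flush(cur, features)
  list(protein = protein_record(id, sequence, description),
       features = features, warnings = warnings)
}

# "57" -> c(57,57); "5..20" -> c(5,20); anything else (unknown '?', '<', '>')
# is malformed here.
parse_ft_location <- function(x) {
  if (grepl("^[0-9]+$", x)) {
    p <- as.integer(x)
    return(c(p, p))
  }
  if (grepl("^[0-9]+\\.\\.[0-9]+$", x)) {
    p <- as.integer(strsplit(x, "..", fixed = TRUE)[[1]])
    if (p[1] <= p[2]) return(p)
  }
  NULL
}

unquote_qualifier <- function(x) {
  x <- trimws(x)
  x <- sub('^"', "", sub('";?$', "", x))
  x
}
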