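# Serialization of sites reports: plain text, JSON, and a static HTML view
# (green bar for conserved sites, red x for substitutions, labels as hover
# title text).

#' Render a sites report as plain text
#'
#' @param report a `sites_report`.
#' @return character vector of lines.
#' @export
format_report_text <- function(report) {
  out <- c(sprintf("Query: %s (%d aa)", report$query$id,
                   nchar(report$query$sequence)),
           sprintf("Hits: %d (E <= %g, max %d)", length(report$entries),
                   report$params$max_evalue, report$params$max_hits))
  for (e in report$entries) {
    h <- e$hit
    out <- c(out, "",
             sprintf("%s  %s", h$subject_id,
                     if (nzchar(e$subject_description)) {
                       e$subject_description
                     } else ""),
             sprintf(
               "  bits=%.1f E=%.3g identity=%.1f%% q:%d-%d s:%d-%d",
               h$bit_score, h$evalue, percent_identity(h), h$q_start,
               h$q_end, h$s_start, h$s_end),
             paste0("  Q ", h$q_aligned),
             paste0("    ", alignment_marks(h)),
             paste0("  S ", h$s_aligned))
    if (nrow(e$sites) > 0L) {
      labels <- vapply(seq_len(nrow(e$sites)),
                       function(i) format_site_label(e$sites[i, ]),
                       character(1))
      out <- c(out, paste0("  Sites: ", paste(labels, collapse = ", ")))
    }
  }
  out
}

# Per-column marker row: '|' where the letters agree, 'x' otherwise.
alignment_marks <- function(hit) {
  qc <- chars(hit$q_aligned); sc <- chars(hit$s_aligned)
  paste(ifelse(qc == sc & qc != "-" & qc != "X", "|",
               ifelse(qc == "-" | sc == "-", " ", "x")), collapse = "")
}

report_to_list <- function(report) {
  list(
    query = list(id = report$query$id,
                 description = report$query$description,
                 length = nchar(report$query$sequence)),
    params = report$params[!vapply(report$params, is.null, logical(1))],
    hits = lapply(report$entries, function(e) {
      h <- e$hit
      list(subject_id = h$subject_id,
           subject_description = e$subject_description,
           raw_score = h$raw_score,
           bit_score = round(h$bit_score, 4),
           evalue = signif(h$evalue, 6),
           percent_identity = round(percent_identity(h), 4),
           q_start = h$q_start, q_end = h$q_end,
           s_start = h$s_start, s_end = h$s_end,
           q_aligned = h$q_aligned, s_aligned = h$s_aligned,
           sites = if (nrow(e$sites) == 0L) list() else {
             lapply(seq_len(nrow(e$sites)), function(i) {
               m <- e$sites[i, ]
               list(category = m$category, comment = m$comment,
                    ligand = m$ligand, subject_pos = m$subject_pos,
                    subject_res = m$subject_res,
                    query_pos = if (is.na(m$query_pos)) NULL else m$query_pos,
                    query_res = if (is.na(m$query_res)) NULL else m$query_res,
                    status = m$status, label = format_site_label(m))
             })
           })
    }))
}

#' Render a sites report as JSON
#'
#' @param report a `sites_report`.
#' @return a JSON string (pretty-printed, stable ordering).
#' @export
format_report_json <- function(report) {
  as.character(jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                                pretty = TRUE, digits = NA, null = "null"))
}

#' Render a sites report as a static HTML page
#'
#' Aligned rows are shown in a monospace grid with a marker row (green bar
#' for conserved functional residues, red x for substituted ones); site
#' labels appear as hover titles on the markers.
#'
#' @param report a `sites_report`.
#' @return a single HTML string.
#' @export
format_report_html <- function(report) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  body <- c(sprintf("<h1>Functional sites for %s</h1>",
                    esc(report$query$id)))
  for (e in report$entries) {
    h <- e$hit
    site_cols <- integer()
    site_lab <- character()
    if (nrow(e$sites) > 0L) {
      aligned <- e$sites[e$sites$status != "unaligned", , drop = FALSE]
      if (nrow(aligned) > 0L) {
        cols_s <- col2pos(h$s_aligned)
        site_cols <- match(aligned$subject_pos - h$s_start + 1L, cols_s)
        site_lab <- vapply(seq_len(nrow(aligned)),
                           function(i) format_site_label(aligned[i, ]),
                           character(1))
      }
    }
    marks <- chars(alignment_marks(h))
    spans <- vapply(seq_along(marks), function(i) {
      j <- match(i, site_cols)
      if (is.na(j)) return(esc(marks[i]))
      m <- e$sites[e$sites$status != "unaligned", , drop = FALSE][j, ]
      if (m$status == "match") {
        sprintf("<span class=\"site match\" title=\"%s\">|</span>",
                esc(site_lab[j]))
      } else {
        sprintf("<span class=\"site mismatch\" title=\"%s\">x</span>",
                esc(site_lab[j]))
      }
    }, character(1))
    body <- c(body,
              sprintf("<h2>%s %s</h2>", esc(h$subject_id),
                      esc(e$subject_description)),
              sprintf("<p>bits=%.1f E=%.3g identity=%.1f%%</p>",
                      h$bit_score, h$evalue, percent_identity(h)),
              "<pre>",
              paste0("Q ", esc(h$q_aligned)),
              paste0("  ", paste(spans, collapse = "")),
              paste0("S ", esc(h$s_aligned)),
              "</pre>")
    if (length(site_lab) > 0L) {
      body <- c(body, "<p>",
                paste(sprintf("<span class=\"label\">%s</span>",
                              esc(site_lab)), collapse = " "),
                "</p>")
    }
  }
  paste(c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
          "<style>",
          ".site.match { color: darkgreen; font-weight: bold; }",
          ".site.mismatch { color: red; font-weight: bold; }",
          "pre { font-family: monospace; }",
          "</style></head><body>", body, "</body></html>"),
        collapse = "\n")
}
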