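# Tree + sites SVG rendering: the residue color scheme, tree layout,
# conserved-block computation for the compact view, and the full/compact
# SVG writers with hover titles.

# Six physicochemical groups, each assigned a (light, dark) color pair from
# the standard 12-color paired palette; colors within a group are evenly
# spaced interpolations between the pair endpoints.  For the two 5-member
# groups the light endpoint is darkened before interpolation so neighboring
# colors stay distinguishable.
AA_GROUPS <- list(
  DE    = c("D", "E"),            # negatively charged
  ST    = c("S", "T"),            # small polar
  NQKRH = c("N", "Q", "K", "R", "H"),  # positively charged / amide
  FWY   = c("F", "W", "Y"),       # aromatic
  GAVLI = c("G", "A", "V", "L", "I"),  # small hydrophobic
  PMC   = c("P", "M", "C"))       # other

GROUP_COLOR_PAIRS <- list(
  DE    = c("#FB9A99", "#E31A1C"),  # reds
  ST    = c("#B2DF8A", "#33A02C"),  # greens
  NQKRH = c("#7EB6D9", "#1F78B4"),  # blues, light end darkened
  FWY   = c("#CAB2D6", "#6A3D9A"),  # purples
  GAVLI = c("#E8A95B", "#FF7F00"),  # oranges, light end darkened
  PMC   = c("#FFFF99", "#B15928"))  # yellow-browns

GAP_COLOR <- "#BBBBBB"
UNKNOWN_COLOR <- "#888888"  # X, the unknown-residue code

#' Build the per-residue color scheme
#'
#' Every amino acid gets its own color: six (light, dark) pairs, one per
#' physicochemical group, interpolated within each pair to cover the group's
#' members; gaps are gray.  Deterministic.
#'
#' @return a `color_scheme`: `color_of` (named vector over the 20 residues,
#'   `-` and `X`) and `group_of` (residue to group id).
#' @export
build_color_scheme <- function() {
  color_of <- character()
  group_of <- character()
  for (g in names(AA_GROUPS)) {
    members <- AA_GROUPS[[g]]
    pal <- grDevices::colorRampPalette(GROUP_COLOR_PAIRS[[g]])(
      length(members))
    color_of[members] <- toupper(pal)
    group_of[members] <- g
  }
  color_of["-"] <- GAP_COLOR
  color_of["X"] <- UNKNOWN_COLOR
  group_of["-"] <- "gap"
  group_of["X"] <- "unknown"
  structure(list(color_of = color_of, group_of = group_of),
            class = "color_scheme")
}

residue_color <- function(scheme, res) {
  res <- toupper(res)
  res[res == "."] <- "-"
  out <- unname(scheme$color_of[res])
  out[is.na(out)] <- UNKNOWN_COLOR
  out
}

#' Geometric layout of a rooted tree
#'
#' x is the cumulative branch length from the root scaled to `width` (with a
#' minimum per-branch advance so very short branches stay visible); leaves
#' sit at uniform vertical spacing `row_height` in traversal order; each
#' internal node is centered on its children.
#'
#' @param tree a rooted `phylo` object.
#' @param width horizontal extent of the tree in drawing units.
#' @param row_height vertical distance between adjacent leaves.
#' @param min_branch minimum drawn branch length in drawing units.
#' @return a `tree_layout`: `x`, `y` (per node, ape numbering), `leaves`
#'   (leaf labels in display order), `row_height`.
#' @export
layout_tree <- function(tree, width = 150, row_height = 12,
                        min_branch = 1) {
  ntip <- length(tree$tip.label)
  if (ntip == 0L) stop("tree has no leaves")
  nnode <- ntip + tree$Nnode
  children <- tree_children(tree)
  root <- ntip + 1L
  depth <- rep(0, nnode)
  order <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(order))) {
    depth[order[e, 2]] <- depth[order[e, 1]] + elen[e]
  }
  scale <- if (max(depth) > 0) width / max(depth) else 0
  x <- rep(0, nnode)
  for (e in seq_len(nrow(order))) {
    x[order[e, 2]] <- x[order[e, 1]] + max(elen[e] * scale, min_branch)
  }
  leaves <- leaf_order(tree)
  y <- rep(NA_real_, nnode)
  y[match(leaves, tree$tip.label)] <-
    (seq_along(leaves) - 0.5) * row_height
  # internal y = mean of children, bottom-up
  post <- rev(unique(order[, 1]))
  for (nd in post) {
    y[nd] <- mean(y[children[[as.character(nd)]]])
  }
  structure(list(x = x, y = y, leaves = leaves, row_height = row_height,
                 n_tip = ntip, width = width),
            class = "tree_layout")
}

#' Maximal uniform-residue clades of one alignment column
#'
#' Top-down partition of the leaves: a clade whose leaves all carry the same
#' residue (gap included) at the column emits one block; otherwise the
#' recursion descends into the children.  The blocks partition the leaf
#' set, and each block's clade is maximal for its residue.
#'
#' @param tree a rooted `phylo` object.
#' @param column_residues named character vector, one single-character
#'   residue (or `-`) per leaf label.
#' @return data frame `node` (ape node number), `residue`, `leaves` (list
#'   column of leaf labels), `n_leaves`.
#' @export
conserved_blocks <- function(tree, column_residues) {
  missing <- setdiff(tree$tip.label, names(column_residues))
  if (length(missing) > 0L) {
    stop("no residue supplied for leaf/leaves: ",
         paste(missing, collapse = ","))
  }
  res <- toupper(column_residues)
  res[res == "."] <- "-"
  ntip <- length(tree$tip.label)
  children <- tree_children(tree)
  out <- list()
  emit <- function(node) {
    lv <- leaves_under(tree, node, children)
    labels <- tree$tip.label[lv]
    vals <- unique(res[labels])
    if (length(vals) == 1L) {
      out[[length(out) + 1L]] <<- data.frame(
        node = node, residue = vals, leaves = I(list(labels)),
        n_leaves = length(labels), stringsAsFactors = FALSE)
    } else {
      for (ch in children[[as.character(node)]]) emit(ch)
    }
  }
  emit(ntip + 1L)
  do.call(rbind, out)
}

leaves_under <- function(tree, node, children = tree_children(tree)) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  unlist(lapply(children[[as.character(node)]], leaves_under, tree = tree,
                children = children))
}

# --- SVG primitives ---------------------------------------------------------

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

num <- function(x) formatC(x, format = "f", digits = 2)

svg_rect <- function(x, y, w, h, fill, extra = "", title = NULL) {
  open <- sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s',
                  num(x), num(y), num(w), num(h), fill,
                  if (nzchar(extra)) paste0(" ", extra) else "")
  if (is.null(title)) return(paste0(open, "/>"))
  paste0(open, "><title>", svg_escape(title), "</title></rect>")
}

svg_text <- function(x, y, text, size = 9, anchor = "middle", extra = "",
                     title = NULL) {
  open <- sprintf(
    '<text x="%s" y="%s" font-size="%s" text-anchor="%s" font-family="monospace"%s',
    num(x), num(y), num(size), anchor,
    if (nzchar(extra)) paste0(" ", extra) else "")
  body <- svg_escape(text)
  if (!is.null(title)) {
    body <- paste0("<title>", svg_escape(title), "</title>", body)
  }
  paste0(open, ">", body, "</text>")
}

svg_line <- function(x1, y1, x2, y2, stroke = "#000000", sw = 1) {
  sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
          num(x1), num(y1), num(x2), num(y2), stroke, num(sw))
}

svg_circle <- function(cx, cy, r, fill, title = NULL) {
  open <- sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"',
                  num(cx), num(cy), num(r), fill)
  if (is.null(title)) return(paste0(open, "/>"))
  paste0(open, "><title>", svg_escape(title), "</title></circle>")
}

svg_document <- function(width, height, body) {
  paste(c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                         'width="%s" height="%s" viewBox="0 0 %s %s">'),
                  num(width), num(height), num(width), num(height)),
          body, "</svg>"), collapse = "\n")
}

# Rectangular (elbow) tree edges from a layout.
tree_edge_svg <- function(tree, lay) {
  order <- ape::reorder.phylo(tree, "cladewise")$edge
  parts <- character()
  for (e in seq_len(nrow(order))) {
    a <- order[e, 1]; b <- order[e, 2]
    parts <- c(parts,
               svg_line(lay$x[a], lay$y[a], lay$x[a], lay$y[b]),
               svg_line(lay$x[a], lay$y[b], lay$x[b], lay$y[b]))
  }
  parts
}

#' Render the legend of a color scheme
#'
#' One swatch plus residue letter per amino acid, grouped contiguously by
#' physicochemical group, with the gap swatch last.
#'
#' @param scheme a [build_color_scheme()] scheme.
#' @param x,y top-left position of the legend within the enclosing SVG.
#' @return character vector of SVG fragment lines (a `<g>` element).
#' @export
render_legend <- function(scheme, x = 0, y = 0) {
  parts <- sprintf('<g class="legend" transform="translate(%s,%s)">',
                   num(x), num(y))
  cx <- 0
  sw <- 14
  entries <- c(unlist(AA_GROUPS, use.names = FALSE), "X", "-")
  for (res in entries) {
    parts <- c(parts,
               svg_rect(cx, 0, sw, sw, residue_color(scheme, res),
                        extra = 'class="swatch" stroke="#666666" stroke-width="0.5"'),
               svg_text(cx + sw / 2, sw - 3.5,
                        ifelse(res == "-", "gap", res), size = 8))
    cx <- cx + sw + (if (res == "-") 0 else 4)
  }
  c(parts, "</g>")
}

legend_width <- function() 22 * 18 + 10

# Hover text for a cell carrying known sites.
site_titles <- function(site_rows) {
  paste(vapply(seq_len(nrow(site_rows)), function(i) {
    r <- site_rows[i, ]
    lig <- if (nzchar(r$ligand)) paste0(" [", r$ligand, "]") else ""
    paste0(r$category, lig, ": ", r$comment)
  }, character(1)), collapse = "; ")
}

#' Render the full tree + sites view as SVG
#'
#' The left side draws the midpoint-rooted tree with leaf labels (and
#' optional per-protein colored markers and hyperlinks from the metadata
#' table); the right side shows one residue glyph per (row, selected
#' column) on its scheme color, with known functional sites boxed and given
#' hover text.
#'
#' @param tree rooted `phylo`; leaves must equal the alignment ids.
#' @param m an [msa()].
#' @param columns alignment column indices to display.
#' @param known_sites output of [transfer_known_sites()] (possibly empty
#'   list).
#' @param scheme a [build_color_scheme()] scheme.
#' @param metadata optional data frame `id`, `color`, `description`, `url`.
#' @param anchor_id optional anchor row id used for column header numbering
#'   (defaults to alignment column numbers).
#' @return SVG text (single string).
#' @export
render_full_svg <- function(tree, m, columns, known_sites = list(),
                            scheme = build_color_scheme(), metadata = NULL,
                            anchor_id = NULL) {
  columns <- as.integer(columns)
  if (any(columns < 1L | columns > m$n_cols)) {
    stop("selected column(s) out of range 1..", m$n_cols)
  }
  stopifnot(setequal(tree$tip.label, m$ids))
  row_height <- 14
  cell <- 14
  tree_w <- 150
  label_w <- max(nchar(m$ids)) * 7 + 24
  lay <- layout_tree(tree, width = tree_w, row_height = row_height)
  grid_x0 <- tree_w + label_w
  n_leaf <- length(lay$leaves)
  header_h <- 30
  body <- c(sprintf('<g transform="translate(0,%s)">', num(header_h)),
            tree_edge_svg(tree, lay))
  meta_of <- function(id) {
    if (is.null(metadata)) return(NULL)
    r <- metadata[metadata$id == id, , drop = FALSE]
    if (nrow(r) == 0L) NULL else r[1, ]
  }
  # leaf markers and labels
  for (i in seq_along(lay$leaves)) {
    id <- lay$leaves[i]
    node <- match(id, tree$tip.label)
    md <- meta_of(id)
    fill <- if (!is.null(md) && nzchar(md$color)) md$color else "#333333"
    title <- if (!is.null(md) && nzchar(md$description)) md$description
             else NULL
    body <- c(body,
              svg_circle(lay$x[node] + 3, lay$y[node], 3, fill,
                         title = title))
    label <- svg_text(tree_w + 8, lay$y[node] + 3.5, id, size = 9,
                      anchor = "start", extra = 'class="leaf-label"',
                      title = title)
    if (!is.null(md) && nzchar(md$url)) {
      label <- paste0('<a href="', svg_escape(md$url), '">', label, "</a>")
    }
    body <- c(body, label)
  }
  # column headers (anchor numbering when available)
  headers <- column_headers(m, columns, anchor_id)
  for (k in seq_along(columns)) {
    body <- c(body, svg_text(grid_x0 + (k - 0.5) * cell, -6, headers[k],
                             size = 8,
                             extra = sprintf('transform="rotate(0)"')))
  }
  # residue cells
  for (i in seq_along(lay$leaves)) {
    id <- lay$leaves[i]
    node <- match(id, tree$tip.label)
    row <- msa_row(m, id)
    cy <- lay$y[node]
    sites <- known_sites[[id]]
    for (k in seq_along(columns)) {
      col <- columns[k]
      res <- substr(row, col, col)
      cx <- grid_x0 + (k - 1) * cell
      site_rows <- NULL
      if (!is.null(sites)) {
        site_rows <- sites[sites$column == col, , drop = FALSE]
        if (nrow(site_rows) == 0L) site_rows <- NULL
      }
      body <- c(body,
                svg_rect(cx, cy - cell / 2, cell, cell,
                         residue_color(scheme, res),
                         extra = 'class="cell"',
                         title = if (!is.null(site_rows))
                           site_titles(site_rows) else NULL),
                svg_text(cx + cell / 2, cy + 3.5,
                         ifelse(res %in% c("-", "."), "", toupper(res)),
                         size = 9, extra = 'class="res"'))
      if (!is.null(site_rows)) {
        body <- c(body,
                  svg_rect(cx + 0.75, cy - cell / 2 + 0.75, cell - 1.5,
                           cell - 1.5, "none",
                           extra = paste0('class="site-box" stroke="#000000"',
                                          ' stroke-width="1.5"')))
      }
    }
  }
  body <- c(body, "</g>")
  legend_y <- header_h + n_leaf * row_height + 16
  body <- c(body, render_legend(scheme, x = 10, y = legend_y))
  width <- max(grid_x0 + length(columns) * cell + 20, legend_width())
  svg_document(width, legend_y + 30, body)
}

# Header labels: anchor residue+number where the anchor aligns, else the
# alignment column number.
column_headers <- function(m, columns, anchor_id) {
  if (is.null(anchor_id)) return(as.character(columns))
  row <- msa_row(m, anchor_id)
  pos <- col2pos(row)[columns]
  ifelse(is.na(pos), as.character(columns),
         paste0(toupper(substring(row, columns, columns)), pos))
}

#' Render the compact tree + sites view as SVG
#'
#' For each selected column the leaves are partitioned into maximal
#' residue-uniform clades ([conserved_blocks()]); each block is drawn as a
#' single colored band, with the amino-acid letter drawn once when the band
#' is tall enough.  Leaf identifier text is omitted when the family exceeds
#' 30 sequences; column headers use anchor numbering; the legend sits at
#' the bottom.
#'
#' @param tree rooted `phylo`; leaves must equal the alignment ids.
#' @param m an [msa()].
#' @param columns alignment column indices to display.
#' @param scheme a [build_color_scheme()] scheme.
#' @param anchor_id anchor row id for column headers.
#' @param row_height vertical drawing units per leaf (compact default 4).
#' @param label_threshold minimum band height (drawing units) that still
#'   receives a residue letter.
#' @return SVG text (single string).
#' @export
render_compact_svg <- function(tree, m, columns,
                               scheme = build_color_scheme(),
                               anchor_id = NULL, row_height = 4,
                               label_threshold = 10) {
  columns <- as.integer(columns)
  if (any(columns < 1L | columns > m$n_cols)) {
    stop("selected column(s) out of range 1..", m$n_cols)
  }
  stopifnot(setequal(tree$tip.label, m$ids))
  n_leaf <- length(m$ids)
  show_ids <- n_leaf <= 30
  cell_w <- 16
  tree_w <- 120
  label_w <- if (show_ids) max(nchar(m$ids)) * 6 + 18 else 12
  lay <- layout_tree(tree, width = tree_w, row_height = row_height)
  grid_x0 <- tree_w + label_w
  header_h <- 26
  body <- c(sprintf('<g transform="translate(0,%s)">', num(header_h)),
            tree_edge_svg(tree, lay))
  if (show_ids) {
    for (id in lay$leaves) {
      node <- match(id, tree$tip.label)
      body <- c(body, svg_text(tree_w + 6, lay$y[node] + 2.5, id, size = 7,
                               anchor = "start",
                               extra = 'class="leaf-label"'))
    }
  }
  headers <- column_headers(m, columns, anchor_id)
  for (k in seq_along(columns)) {
    body <- c(body, svg_text(grid_x0 + (k - 0.5) * cell_w, -6, headers[k],
                             size = 8, extra = 'class="col-header"'))
  }
  # leaf rank in display order -> vertical band extents
  rank <- stats::setNames(seq_along(lay$leaves), lay$leaves)
  grid <- do.call(rbind, strsplit(m$rows, ""))
  rownames(grid) <- m$ids
  for (k in seq_along(columns)) {
    col <- columns[k]
    residues <- stats::setNames(grid[m$ids, col], m$ids)
    blocks <- conserved_blocks(tree, residues)
    cx <- grid_x0 + (k - 1) * cell_w
    for (b in seq_len(nrow(blocks))) {
      members <- blocks$leaves[[b]]
      rr <- range(rank[members])
      y0 <- (rr[1] - 1) * row_height
      y1 <- rr[2] * row_height
      res <- blocks$residue[b]
      body <- c(body,
                svg_rect(cx, y0, cell_w - 1, y1 - y0,
                         residue_color(scheme, res),
                         extra = 'class="band"',
                         title = sprintf("%s (%d seq%s)",
                                         ifelse(res == "-", "gap", res),
                                         blocks$n_leaves[b],
                                         ifelse(blocks$n_leaves[b] == 1L,
                                                "", "s"))))
      if (res != "-" && (y1 - y0) >= label_threshold) {
        body <- c(body,
                  svg_text(cx + (cell_w - 1) / 2, (y0 + y1) / 2 + 3, res,
                           size = 9, extra = 'class="block-label"'))
      }
    }
  }
  body <- c(body, "</g>")
  legend_y <- header_h + n_leaf * row_height + 14
  body <- c(body, render_legend(scheme, x = 10, y = legend_y))
  width <- max(grid_x0 + length(columns) * cell_w + 20, legend_width())
  svg_document(width, legend_y + 30, body)
}
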