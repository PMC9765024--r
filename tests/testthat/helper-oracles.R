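# Independent oracles used across the suite.  These are deliberately written
# as direct textbook procedures (loops, explicit walks, brute-force
# enumeration), separate from the package's code paths.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Textbook Smith-Waterman with affine gaps (Gotoh three-matrix recurrence).
# A gap of length L costs open + L * extend.  Returns the optimal score.
sw_oracle_score <- function(q, s, matrix = blosum62, open = 11, extend = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - (open + extend),
                             E[i + 1, j] - extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - (open + extend),
                             F[i, j + 1] - extend)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + matrix[qc[i], sc[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# Re-score an explicit alignment (pair scores plus affine gap run costs).
score_alignment <- function(qa, sa, matrix = blosum62, open = 11,
                            extend = 1) {
  qc <- strsplit(qa, "")[[1]]
  sc <- strsplit(sa, "")[[1]]
  total <- 0
  in_gap <- FALSE
  for (k in seq_along(qc)) {
    if (qc[k] == "-" || sc[k] == "-") {
      total <- total - extend - (if (!in_gap) open else 0)
      in_gap <- TRUE
    } else {
      total <- total + matrix[qc[k], sc[k]]
      in_gap <- FALSE
    }
  }
  total
}

random_seq <- function(len, letters = c("A", "C", "D", "E", "F", "G", "H",
                                        "I", "K", "L", "M", "N", "P", "Q",
                                        "R", "S", "T", "V", "W", "Y")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Independent site-mapping oracle: walk the alignment columns with explicit
# residue counters.
map_site_oracle <- function(hit, p, subject_seq, query_seq) {
  s_res <- toupper(substr(subject_seq, p, p))
  if (nchar(hit$q_aligned) == 0L || p < hit$s_start || p > hit$s_end) {
    return(list(subject_pos = p, subject_res = s_res, query_pos = NA,
                query_res = NA, status = "unaligned"))
  }
  qc <- strsplit(hit$q_aligned, "")[[1]]
  sc <- strsplit(hit$s_aligned, "")[[1]]
  qi <- hit$q_start - 1L
  si <- hit$s_start - 1L
  for (k in seq_along(qc)) {
    if (qc[k] != "-") qi <- qi + 1L
    if (sc[k] != "-") si <- si + 1L
    if (sc[k] != "-" && si == p) {
      if (qc[k] == "-") {
        return(list(subject_pos = p, subject_res = s_res, query_pos = NA,
                    query_res = NA, status = "unaligned"))
      }
      qr <- toupper(substr(query_seq, qi, qi))
      st <- if (qr == s_res && qr != "X") "match" else "mismatch"
      return(list(subject_pos = p, subject_res = s_res, query_pos = qi,
                  query_res = qr, status = st))
    }
  }
  stop("oracle walk failed")
}

# Brute-force minimax root placement: discretize every edge and measure the
# maximum leaf distance from each candidate point.
brute_force_midpoint_height <- function(tree, steps = 200) {
  n <- length(tree$tip.label)
  dn <- ape::dist.nodes(tree)
  best <- Inf
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    for (f in seq(0, 1, length.out = steps)) {
      dmax <- max(pmin(dn[a, 1:n] + f * len, dn[b, 1:n] + (1 - f) * len))
      if (dmax < best) best <- dmax
    }
  }
  best
}

# Brute-force conserved blocks: enumerate every clade, keep residue-uniform
# ones, and take maximal ones largest-first.
brute_blocks <- function(tree, residues) {
  ntip <- length(tree$tip.label)
  nodes <- seq_len(ntip + tree$Nnode)
  clades <- lapply(nodes, function(nd) {
    tree$tip.label[siteseer:::leaves_under(tree, nd)]
  })
  uniform <- vapply(clades, function(lv) {
    length(unique(toupper(residues[lv]))) == 1L
  }, logical(1))
  taken <- character()
  out <- list()
  ord <- order(-vapply(clades, length, integer(1)))
  for (idx in ord) {
    if (!uniform[idx]) next
    lv <- clades[[idx]]
    if (any(lv %in% taken)) next
    taken <- c(taken, lv)
    out[[length(out) + 1L]] <- sort(lv)
  }
  out
}

# Random rooted tree (ape phylo) with the given leaf labels; multifurcating
# with some probability.
random_tree <- function(labels, multifurcate = TRUE) {
  n <- length(labels)
  t <- ape::rtree(n, tip.label = sample(labels))
  t$edge.length <- round(stats::runif(nrow(t$edge), 0.05, 2), 3)
  if (multifurcate && n >= 4 && stats::runif(1) < 0.5) {
    t <- ape::di2multi(t, tol = stats::quantile(t$edge.length, 0.2))
    t$edge.length <- pmax(t$edge.length, 0.05)
  }
  t
}
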