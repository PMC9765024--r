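# Built-in progressive multiple aligner for desk-scale families: 3-mer
# distances, a UPGMA guide tree, and profile-profile global alignment with
# affine gaps under BLOSUM62.  An external-import backend reads a
# user-provided alignment instead.

#' Build a multiple sequence alignment
#'
#' @param proteins data frame with `id`, `sequence` (and optionally
#'   `description`) columns, at least 2 rows.
#' @param backend `"builtin"` for the progressive aligner, or
#'   `"external-import"` to read `aln_file` instead (every input id must be
#'   present there).
#' @param aln_file path to a user-provided alignment
#'   (`external-import` backend).
#' @param aln_format its format (`fasta`, `clustal`, `stockholm`).
#' @param gap_open,gap_extend affine gap costs for the builtin backend.
#' @return an [msa()] whose rows degap to the input sequences, in input
#'   order.
#' @export
build_msa <- function(proteins, backend = c("builtin", "external-import"),
                      aln_file = NULL, aln_format = "fasta",
                      gap_open = 11, gap_extend = 1) {
  backend <- match.arg(backend)
  stopifnot(nrow(proteins) >= 2L)
  if (anyDuplicated(proteins$id)) {
    stop("duplicate sequence ids: ",
         paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ","))
  }
  descs <- if ("description" %in% names(proteins)) proteins$description
           else rep("", nrow(proteins))
  if (backend == "external-import") {
    stopifnot(!is.null(aln_file))
    m <- read_alignment(aln_file, aln_format)
    missing <- setdiff(proteins$id, m$ids)
    if (length(missing) > 0L) {
      stop("sequences absent from the imported alignment: ",
           paste(missing, collapse = ","))
    }
    keep <- match(proteins$id, m$ids)
    for (i in seq_along(keep)) {
      if (!identical(degap(m$rows[keep[i]]),
                     toupper(proteins$sequence[i]))) {
        stop("imported row for '", proteins$id[i],
             "' does not degap to its sequence")
      }
    }
    return(msa(proteins$id, m$rows[keep], descs))
  }
  seqs <- toupper(proteins$sequence)
  D <- kmer_distance_matrix(seqs)
  merge_order <- stats::hclust(stats::as.dist(D), method = "average")$merge
  # each working alignment: character matrix, rows = member index
  align_sets <- lapply(seq_along(seqs), function(i) {
    m <- matrix(chars(seqs[i]), nrow = 1)
    attr(m, "members") <- i
    m
  })
  merged <- vector("list", nrow(merge_order))
  pick <- function(x) if (x < 0) align_sets[[-x]] else merged[[x]]
  for (k in seq_len(nrow(merge_order))) {
    merged[[k]] <- merge_profiles(pick(merge_order[k, 1]),
                                  pick(merge_order[k, 2]),
                                  gap_open, gap_extend)
  }
  final <- if (nrow(merge_order) > 0L) merged[[nrow(merge_order)]] else
    align_sets[[1]]
  members <- attr(final, "members")
  rows <- apply(final, 1, paste, collapse = "")
  rows <- rows[order(members)]
  out <- msa(proteins$id, rows, descs)
  for (i in seq_along(seqs)) {
    stopifnot(identical(degap(out$rows[i]), seqs[i]))
  }
  out
}

# Fractional shared 3-mer distance between all sequence pairs.
kmer_distance_matrix <- function(seqs, k = 3L) {
  n <- length(seqs)
  counts <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(table(s))
    table(substring(s, seq_len(nchar(s) - k + 1L),
                    seq_len(nchar(s) - k + 1L) + k - 1L))
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      shared <- sum(pmin(
        counts[[i]][intersect(names(counts[[i]]), names(counts[[j]]))],
        counts[[j]][intersect(names(counts[[i]]), names(counts[[j]]))]))
      denom <- max(1L, min(nchar(seqs[i]), nchar(seqs[j])) - k + 1L)
      D[i, j] <- D[j, i] <- 1 - shared / denom
    }
  }
  D
}

# Column frequency profile over the 24-letter BLOSUM alphabet (gap rows
# contribute nothing, so sparse columns score near zero).
profile_of <- function(aln, letters) {
  L <- ncol(aln)
  P <- matrix(0, length(letters), L, dimnames = list(letters, NULL))
  nr <- nrow(aln)
  for (j in seq_len(L)) {
    col <- aln[, j]
    col <- col[col != "-" & col != "."]
    if (length(col) > 0L) {
      tab <- table(col)
      P[names(tab), j] <- as.numeric(tab) / nr
    }
  }
  P
}

# Global (Needleman-Wunsch) affine-gap alignment of two profile alignments;
# returns the merged character matrix.
merge_profiles <- function(a, b, gap_open, gap_extend) {
  mat <- default_matrix()
  letters <- rownames(mat)
  Pa <- profile_of(a, letters)
  Pb <- profile_of(b, letters)
  S <- t(Pa) %*% mat %*% Pb
  path <- nw_affine_path(S, gap_open, gap_extend)
  n <- nrow(path)
  out <- matrix("-", nrow(a) + nrow(b), n)
  ai <- path[, 1]; bi <- path[, 2]
  out[seq_len(nrow(a)), ai != 0] <- a[, ai[ai != 0], drop = FALSE]
  out[nrow(a) + seq_len(nrow(b)), bi != 0] <- b[, bi[bi != 0],
                                                drop = FALSE]
  attr(out, "members") <- c(attr(a, "members"), attr(b, "members"))
  out
}

# Gotoh global alignment over a column-score matrix with affine gaps;
# returns a two-column matrix of (i, j) column indices along the merged
# alignment, 0 marking a gap in that side.  A gap of length L costs
# gap_open + L * gap_extend.
nw_affine_path <- function(S, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  go <- gap_open + gap_extend   # cost of the first gap column
  ge <- gap_extend
  NEG <- -1e12
  # states: 1 = M (diagonal), 2 = X (consume row side), 3 = Y (consume col)
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  PM <- matrix(1L, n + 1, m + 1)
  PX <- matrix(2L, n + 1, m + 1)
  PY <- matrix(3L, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    X[i + 1, 1] <- -(gap_open + ge * i)
    PX[i + 1, 1] <- if (i == 1L) 1L else 2L
  }
  for (j in seq_len(m)) {
    Y[1, j + 1] <- -(gap_open + ge * j)
    PY[1, j + 1] <- if (j == 1L) 1L else 3L
  }
  amax <- function(v) which.max(v)  # first maximum: deterministic ties
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      dm <- c(M[i, j], X[i, j], Y[i, j])
      sm <- amax(dm)
      M[i + 1, j + 1] <- dm[sm] + S[i, j]
      PM[i + 1, j + 1] <- sm
      dx <- c(M[i, j + 1] - go, X[i, j + 1] - ge, Y[i, j + 1] - go)
      sx <- amax(dx)
      X[i + 1, j + 1] <- dx[sx]
      PX[i + 1, j + 1] <- sx
      dy <- c(M[i + 1, j] - go, X[i + 1, j] - go, Y[i + 1, j] - ge)
      sy <- amax(dy)
      Y[i + 1, j + 1] <- dy[sy]
      PY[i + 1, j + 1] <- sy
    }
  }
  i <- n; j <- m
  state <- amax(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  steps <- list()
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      steps[[length(steps) + 1L]] <- c(i, j)
      state <- PM[i + 1, j + 1]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      steps[[length(steps) + 1L]] <- c(i, 0L)
      state <- PX[i + 1, j + 1]
      i <- i - 1L
    } else {
      steps[[length(steps) + 1L]] <- c(0L, j)
      state <- PY[i + 1, j + 1]
      j <- j - 1L
    }
  }
  do.call(rbind, rev(steps))
}
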