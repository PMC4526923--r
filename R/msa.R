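# Per-cluster multiple alignment and conserved-column pruning. A
# deterministic progressive aligner (UPGMA guide tree + profile-profile
# Needleman-Wunsch with sum-of-pairs BLOSUM62 scoring) aligns the small
# C-terminal segment clusters; columns that are gappy or score poorly
# under BLOSUM62 are masked out before HMM building.

GAP_IDX <- 22L  # internal profile code: 1..20 residues, 21 X, 22 gap

#' UPGMA guide tree over segments
#'
#' Distances are `1 - S(a,b) / min(S(a,a), S(b,b))` with S the
#' Smith-Waterman raw score (clamped to `[0, 1]`). Ties are broken by
#' joining the pair whose (smallest-member-id, smallest-member-id) label
#' pair sorts first, so the tree is fully deterministic.
#'
#' @param segments An `ssp_segments` data frame (>= 2 rows).
#' @param matrix,gap_open,gap_extend Aligner parameters (BLOSUM62, 11, 1 —
#'   the same scoring the progressive aligner uses).
#' @return Nested-list rooted binary tree: leaves are
#'   `list(leaf = <id>)`, internal nodes
#'   `list(left =, right =, height =)`.
#' @export
upgma_guide_tree <- function(segments, matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1) {
  n <- nrow(segments)
  stopifnot(n >= 2)
  D <- segment_distances(segments, matrix = matrix, gap_open = gap_open,
                         gap_extend = gap_extend)
  ids <- segments$parent_id
  trees <- lapply(ids, function(id) list(leaf = id))
  labels <- ids                   # smallest member id per active cluster
  sizes <- rep(1L, n)
  active <- seq_len(n)
  heights <- rep(0, n)
  while (length(active) > 1) {
    best <- NULL
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (bi <= ai) next
      i <- active[ai]; j <- active[bi]
      la <- min(labels[i], labels[j]); lb <- max(labels[i], labels[j])
      cand <- list(d = D[i, j], la = la, lb = lb, i = i, j = j)
      if (is.null(best) || cand$d < best$d ||
          (cand$d == best$d && (cand$la < best$la ||
           (cand$la == best$la && cand$lb < best$lb))))
        best <- cand
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    node <- list(left = trees[[i]], right = trees[[j]], height = h)
    # UPGMA average-linkage update into slot i
    for (k in setdiff(active, c(i, j))) {
      D[i, k] <- D[k, i] <-
        (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j])
    }
    trees[[i]] <- node
    sizes[i] <- sizes[i] + sizes[j]
    labels[i] <- min(labels[i], labels[j])
    active <- setdiff(active, j)
  }
  trees[[active]]
}

#' Normalised alignment-score distances between segments
#'
#' `d(a, b) = 1 - S(a, b) / min(S(a, a), S(b, b))` with S the
#' Smith-Waterman raw score, clamped to `[0, 1]`; `d(a, a) = 0`.
#'
#' @inheritParams upgma_guide_tree
#' @return Symmetric distance matrix with segment ids as dimnames.
#' @export
segment_distances <- function(segments, matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1) {
  m <- if (is.character(matrix)) ssp_matrix(matrix) else matrix
  enc <- lapply(segments$sequence, aa_encode)
  S <- .sw_all_pairs(enc, m, gap_open, gap_extend)
  self <- diag(S)
  n <- nrow(segments)
  D <- matrix(0, n, n,
              dimnames = list(segments$parent_id, segments$parent_id))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    denom <- min(self[i], self[j])
    D[i, j] <- if (denom > 0) min(1, max(0, 1 - S[i, j] / denom)) else 1
  }
  D
}

tree_leaves <- function(tree) {
  if (!is.null(tree$leaf)) return(tree$leaf)
  c(tree_leaves(tree$left), tree_leaves(tree$right))
}

#' Progressive multiple alignment along a guide tree
#'
#' Profiles are merged bottom-up with global (Needleman-Wunsch) affine-gap
#' alignment; the column score is the sum-of-pairs BLOSUM62 score over the
#' two profile columns, with gap-vs-residue pairs scoring 0, and gap
#' penalties scaled by the product of the profile depths so they stay
#' commensurate with the sum-of-pairs emission term. Traceback is
#' deterministic (diagonal > up > left).
#'
#' @param segments An `ssp_segments` data frame.
#' @param guide_tree Tree from [upgma_guide_tree()]; computed when `NULL`.
#' @param matrix,gap_open,gap_extend Scoring parameters (BLOSUM62, 11, 1).
#' @return List of class `ssp_alignment`: `member_ids`, `rows` (named
#'   character vector of equal-length gapped sequences, input order), and
#'   `column_mask` (all `TRUE`; see [prune_columns()]).
#' @export
progressive_align <- function(segments, guide_tree = NULL,
                              matrix = "BLOSUM62", gap_open = 11,
                              gap_extend = 1) {
  m <- if (is.character(matrix)) ssp_matrix(matrix) else matrix
  ids <- segments$parent_id
  if (nrow(segments) == 1) {
    rows <- stats::setNames(segments$sequence, ids)
    return(new_alignment(ids, rows))
  }
  if (is.null(guide_tree))
    guide_tree <- upgma_guide_tree(segments, matrix = m,
                                   gap_open = gap_open,
                                   gap_extend = gap_extend)
  if (!setequal(tree_leaves(guide_tree), ids))
    stop("guide tree leaves do not match segment ids", call. = FALSE)
  seqs <- stats::setNames(segments$sequence, ids)

  # substitution with gap row/col 0 (X already 0)
  mg <- matrix(0, 22, 22)
  mg[1:21, 1:21] <- m

  align_node <- function(node) {
    if (!is.null(node$leaf)) {
      prof <- matrix(aa_encode(seqs[[node$leaf]]), nrow = 1)
      rownames(prof) <- node$leaf
      return(prof)
    }
    A <- align_node(node$left)
    B <- align_node(node$right)
    # per-column symbol counts -> sum-of-pairs column score matrix
    countA <- vapply(seq_len(ncol(A)),
                     function(j) tabulate(A[, j], 22L), numeric(22))
    countB <- vapply(seq_len(ncol(B)),
                     function(j) tabulate(B[, j], 22L), numeric(22))
    S <- t(countA) %*% mg %*% countB
    scale <- nrow(A) * nrow(B)
    res <- .align_global_dp(S, gap_open * scale, gap_extend * scale)
    la <- res$a_idx; lb <- res$b_idx
    newA <- matrix(GAP_IDX, nrow(A), length(la),
                   dimnames = list(rownames(A), NULL))
    newB <- matrix(GAP_IDX, nrow(B), length(lb),
                   dimnames = list(rownames(B), NULL))
    newA[, la != 0L] <- A[, la[la != 0L], drop = FALSE]
    newB[, lb != 0L] <- B[, lb[lb != 0L], drop = FALSE]
    rbind(newA, newB)
  }
  prof <- align_node(guide_tree)
  prof <- prof[ids, , drop = FALSE]   # input order
  rows <- apply(prof, 1, function(r)
    paste(c(AAX, "-")[r], collapse = ""))
  new_alignment(ids, stats::setNames(rows, ids))
}

new_alignment <- function(member_ids, rows, column_mask = NULL) {
  w <- unique(nchar(rows))
  stopifnot(length(w) == 1)
  structure(list(member_ids = member_ids, rows = rows,
                 column_mask = column_mask %||% rep(TRUE, w)),
            class = "ssp_alignment")
}

#' @export
print.ssp_alignment <- function(x, ...) {
  cat("alignment:", length(x$rows), "sequences x", nchar(x$rows[1]),
      "columns (", sum(x$column_mask), "retained )\n")
  invisible(x)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
}

#' Mask gapped and non-conserved alignment columns
#'
#' A column is retained iff its gap fraction is at most `max_gap_frac`,
#' it has at least 2 non-gap residues, and the mean pairwise BLOSUM62
#' score over its non-gap residue pairs exceeds `min_col_score`. Only the
#' `column_mask` changes; rows are untouched.
#'
#' @param aln An `ssp_alignment`.
#' @param max_gap_frac Maximum tolerated gap fraction (default 0.5).
#' @param min_col_score Strict lower bound on the mean pairwise BLOSUM62
#'   column score (default 0).
#' @param matrix Substitution matrix name or matrix (default BLOSUM62).
#' @return The alignment with an updated `column_mask`. Errors with
#'   "no conserved region" when no column survives.
#' @export
prune_columns <- function(aln, max_gap_frac = 0.5, min_col_score = 0,
                          matrix = "BLOSUM62") {
  m <- if (is.character(matrix)) ssp_matrix(matrix) else matrix
  chars <- alignment_matrix(aln)
  nseq <- nrow(chars)
  mask <- vapply(seq_len(ncol(chars)), function(j) {
    col <- chars[, j]
    res <- col[col != "-"]
    if (length(res) < 2) return(FALSE)
    if ((nseq - length(res)) / nseq > max_gap_frac) return(FALSE)
    pairs <- utils::combn(length(res), 2)
    sc <- mean(m[cbind(res[pairs[1, ]], res[pairs[2, ]])])
    sc > min_col_score
  }, NA)
  if (!any(mask))
    stop("no conserved region", call. = FALSE)
  aln$column_mask <- mask
  aln
}

#' Write / read an alignment in Stockholm format
#'
#' The column mask is carried on the `#=GC RF` line (`x` retained, `.`
#' removed).
#'
#' @param aln An `ssp_alignment`.
#' @param path File path.
#' @return `path` (write) or an `ssp_alignment` (read).
#' @export
write_stockholm <- function(aln, path) {
  ids <- aln$member_ids
  w <- max(nchar(ids), nchar("#=GC RF"))
  lines <- c("# STOCKHOLM 1.0", "",
             sprintf("%-*s %s", w, ids, aln$rows[ids]),
             sprintf("%-*s %s", w, "#=GC RF",
                     paste(ifelse(aln$column_mask, "x", "."),
                           collapse = "")),
             "//")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_stockholm
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file: ", path, call. = FALSE)
  rf <- NULL
  ids <- character(); rows <- character()
  for (ln in lines[-1]) {
    if (ln == "//") break
    if (grepl("^#=GC RF", ln)) {
      rf <- sub("^#=GC RF\\s+", "", ln)
    } else if (!startsWith(ln, "#")) {
      parts <- strsplit(ln, "\\s+")[[1]]
      ids <- c(ids, parts[1]); rows <- c(rows, parts[2])
    }
  }
  mask <- if (!is.null(rf)) strsplit(rf, "")[[1]] == "x" else NULL
  new_alignment(ids, stats::setNames(rows, ids), mask)
}

#' Remove gaps from an alignment row
#'
#' @param x Gapped sequence string(s).
#' @return Ungapped sequence(s).
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)
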