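# All-against-all local alignment of C-terminal segments and conversion of
# the hits into a weighted similarity graph. The exact Smith-Waterman
# dynamic program replaces heuristic database-search seeding: at the scale
# of short-protein C-termini exactness is affordable and removes a source
# of irreproducibility.

#' Smith-Waterman local alignment
#'
#' Exact affine-gap local alignment (Gotoh). A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. The score is floored at 0; traceback
#' ties are broken diagonal > up > left.
#'
#' @param a,b Amino-acid sequences (strings over the 20-letter alphabet
#'   plus `X`; `X` scores 0 against everything).
#' @param matrix Substitution matrix name or 21 x 21 matrix (default
#'   BLOSUM50, tuned for distant similarities).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 and 2).
#' @return List with `score` (raw substitution-matrix units, >= 0) and
#'   `alignment`, a 2-row character matrix of the aligned local region
#'   (zero columns when the best score is 0).
#' @export
#' @examples
#' smith_waterman("WW", "WW")$score   # 30 under BLOSUM50
smith_waterman <- function(a, b, matrix = "BLOSUM50",
                           gap_open = 10, gap_extend = 2) {
  if (!nzchar(a) || !nzchar(b))
    stop("sequences must be non-empty", call. = FALSE)
  m <- if (is.character(matrix)) ssp_matrix(matrix) else matrix
  ea <- aa_encode(a)
  eb <- aa_encode(b)
  S <- m[ea, eb, drop = FALSE]
  res <- .align_local_dp(S, gap_open, gap_extend, TRUE)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  arow <- ifelse(res$a_idx == 0L, "-", ca[pmax(res$a_idx, 1L)])
  brow <- ifelse(res$b_idx == 0L, "-", cb[pmax(res$b_idx, 1L)])
  aln <- rbind(a = arow, b = brow)
  list(score = res$score, alignment = aln,
       end_a = res$end_a, end_b = res$end_b)
}

#' Calibrate the null score distribution on shuffled decoys
#'
#' Draws `n_decoys` pairs of residue-shuffled segments, scores them with
#' Smith-Waterman, and fits a Gumbel (type-I EVD) by maximum likelihood.
#' Segments share the same C-terminal window, so a single pooled length
#' class is fitted.
#'
#' @param segments An `ssp_segments` data frame (>= 2 rows).
#' @param n_decoys Number of decoy pairs (>= 100; default 500).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param matrix,gap_open,gap_extend Passed to the aligner.
#' @return List with `mu`, `beta`, `lambda`, `n_decoys`, `seed`.
#' @export
fit_score_background <- function(segments, n_decoys = 500L, seed = 1L,
                                 matrix = "BLOSUM50", gap_open = 10,
                                 gap_extend = 2) {
  stopifnot(n_decoys >= 100)
  if (nrow(segments) < 2)
    stop("need at least 2 segments", call. = FALSE)
  m <- if (is.character(matrix)) ssp_matrix(matrix) else matrix
  enc <- lapply(segments$sequence, aa_encode)
  scores <- withr_seed(seed, {
    vapply(seq_len(n_decoys), function(k) {
      ij <- sample.int(length(enc), 2, replace = FALSE)
      x <- sample(enc[[ij[1]]])
      y <- sample(enc[[ij[2]]])
      .sw_all_pairs(list(x, y), m, gap_open, gap_extend)[1, 2]
    }, 0)
  })
  if (stats::sd(scores) < 1e-12)
    stop("degenerate score distribution (all decoy scores equal); ",
         "increase n_decoys or check the segments", call. = FALSE)
  fit <- fit_gumbel(scores)
  c(fit, list(n_decoys = n_decoys, seed = seed))
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' All-against-all comparison of C-terminal segments
#'
#' Scores every unordered pair of segments with Smith-Waterman and converts
#' scores to E-values against the fitted decoy null, with the number of
#' comparisons equal to the number of pairs.
#'
#' @param segments An `ssp_segments` data frame (>= 2 rows). `parent_id`
#'   must be unique.
#' @param evd Optional pre-fitted null (from [fit_score_background()]);
#'   fitted on the fly when `NULL`.
#' @param matrix,gap_open,gap_extend Aligner parameters.
#' @param n_decoys,seed Passed to [fit_score_background()] when `evd` is
#'   `NULL`.
#' @return Data frame of class `ssp_hits`: `query_id`, `target_id`
#'   (`query_id < target_id`), `raw_score`, `bit_score`, `evalue`.
#' @export
all_vs_all <- function(segments, evd = NULL, matrix = "BLOSUM50",
                       gap_open = 10, gap_extend = 2,
                       n_decoys = 500L, seed = 1L) {
  n <- nrow(segments)
  if (n < 2) stop("need at least 2 segments", call. = FALSE)
  if (anyDuplicated(segments$parent_id))
    stop("segment ids must be unique", call. = FALSE)
  m <- if (is.character(matrix)) ssp_matrix(matrix) else matrix
  if (is.null(evd))
    evd <- fit_score_background(segments, n_decoys = n_decoys, seed = seed,
                                matrix = m, gap_open = gap_open,
                                gap_extend = gap_extend)
  enc <- lapply(segments$sequence, aa_encode)
  sc <- .sw_all_pairs(enc, m, gap_open, gap_extend)
  ids <- segments$parent_id
  pair <- which(upper.tri(sc), arr.ind = TRUE)
  # enforce query_id < target_id lexicographically
  qi <- ids[pair[, 1]]
  ti <- ids[pair[, 2]]
  swap <- qi > ti
  tmp <- qi[swap]; qi[swap] <- ti[swap]; ti[swap] <- tmp
  raw <- sc[pair]
  n_comp <- nrow(pair)
  ev <- evalue_from_score(raw, evd, n_comp)
  bits <- evd$lambda * (raw - evd$mu) / log(2)
  out <- data.frame(query_id = qi, target_id = ti, raw_score = raw,
                    bit_score = bits, evalue = ev,
                    stringsAsFactors = FALSE)
  out <- out[order(out$query_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "evd") <- evd
  attr(out, "node_ids") <- sort(ids)
  class(out) <- c("ssp_hits", "data.frame")
  out
}

#' Build a similarity graph from alignment hits
#'
#' Edges keep pairs with `evalue <= evalue_cutoff`; the weight is
#' `min(200, -log10(evalue))` (E-values are floored at 1e-200, the usual
#' convention that keeps weights finite for Markov clustering). Nodes whose
#' every hit fails the cutoff remain as isolated nodes, the future
#' singletons.
#'
#' @param hits An `ssp_hits` data frame from [all_vs_all()].
#' @param evalue_cutoff Inclusion threshold (default 1e-3).
#' @param node_ids Optional full node set; defaults to the ids recorded by
#'   [all_vs_all()].
#' @return List of class `ssp_graph` with `nodes` (character) and `edges`
#'   (data frame `from`, `to`, `weight`).
#' @export
build_graph <- function(hits, evalue_cutoff = 1e-3, node_ids = NULL) {
  nodes <- node_ids %||% attr(hits, "node_ids") %||%
    sort(unique(c(hits$query_id, hits$target_id)))
  keep <- hits$evalue <= evalue_cutoff
  edges <- data.frame(from = hits$query_id[keep],
                      to = hits$target_id[keep],
                      weight = pmin(200, -log10(hits$evalue[keep])),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ssp_graph")
}

#' @export
print.ssp_graph <- function(x, ...) {
  cat("similarity graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write / read a similarity graph as a TSV edge list
#'
#' Isolated nodes are written with an empty `to` field and weight 0 so the
#' full node set round-trips.
#'
#' @param graph An `ssp_graph`.
#' @param path TSV path.
#' @return `path` (write) or an `ssp_graph` (read).
#' @export
write_graph_tsv <- function(graph, path) {
  iso <- setdiff(graph$nodes, c(graph$edges$from, graph$edges$to))
  df <- graph$edges
  if (length(iso))
    df <- rbind(df, data.frame(from = iso, to = "", weight = 0,
                               stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric"))
  iso <- !nzchar(df$to)
  edges <- df[!iso, , drop = FALSE]
  nodes <- sort(unique(c(edges$from, edges$to, df$from[iso])))
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ssp_graph")
}
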