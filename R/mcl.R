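# Markov Cluster Algorithm over a weighted similarity graph. Used twice:
# on the sequence-level e-value graph, and on the profile-profile e-value
# graph when clusters are aggregated into families.

#' Markov clustering of a similarity graph
#'
#' Dense-matrix MCL: self-loops are added (weight = maximum incident edge
#' weight; 1 for isolated nodes), columns are normalised to stochastic,
#' then expansion (matrix power `expansion`) alternates with inflation
#' (entrywise power `inflation`, renormalise) and pruning (entries below
#' `prune_below` zeroed, renormalise) until the maximum entry change drops
#' below `tol` or `max_iter` is reached. Clusters are read off as connected
#' components of the attractor structure (rows with positive diagonal mass
#' together with the nodes they attract); a node attracted by several
#' attractor systems joins the cluster containing the smallest member id.
#' Single-member groups are reported as singletons. Cluster labels `c1`,
#' `c2`, ... are assigned by decreasing size, ties broken by smallest
#' member id.
#'
#' @param graph An `ssp_graph` (weights must be positive; edges undirected).
#' @param inflation Inflation exponent (> 1; default 1.5, the granularity
#'   used for delineating weakly similar peptide groups).
#' @param expansion Expansion power (default 2).
#' @param prune_below Entries below this value are zeroed each iteration
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 200).
#' @param tol Convergence threshold on the maximum entry change (default
#'   1e-8).
#' @return List of class `ssp_clustering`: `clusters` (named list of
#'   character vectors, labels `c1`, ...), `singletons` (character),
#'   `n_iter`, and `max_colsum_dev`, the largest deviation of any column
#'   sum from 1 observed after any normalisation step.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, expansion = 2L,
                        prune_below = 1e-5, max_iter = 200L, tol = 1e-8) {
  stopifnot(inflation > 1, expansion >= 2)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0)
    return(structure(list(clusters = list(), singletons = character(),
                          n_iter = 0L, max_colsum_dev = 0),
                     class = "ssp_clustering"))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e)) {
    if (any(e$weight <= 0))
      stop("graph weights must be positive", call. = FALSE)
    if (any(e$from == e$to))
      stop("self-edges are not allowed", call. = FALSE)
    ii <- match(e$from, nodes)
    jj <- match(e$to, nodes)
    if (anyNA(ii) || anyNA(jj))
      stop("edge endpoints missing from the node set", call. = FALSE)
    A[cbind(ii, jj)] <- e$weight
    A[cbind(jj, ii)] <- e$weight
  }
  if (!isSymmetric(unname(A)))
    stop("similarity matrix must be symmetric", call. = FALSE)

  # self-loops: max incident weight, 1 for isolated nodes
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop

  colnorm <- function(M) sweep(M, 2, colSums(M), "/")
  M <- colnorm(A)
  max_dev <- max(abs(colSums(M) - 1))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Mold <- M
    Mx <- M
    for (k in seq_len(expansion - 1L)) Mx <- Mx %*% M
    Mx <- colnorm(Mx^inflation)
    max_dev <- max(max_dev, abs(colSums(Mx) - 1))
    Mx[Mx < prune_below] <- 0
    Mx <- colnorm(Mx)
    max_dev <- max(max_dev, abs(colSums(Mx) - 1))
    M <- Mx
    if (max(abs(M - Mold)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter,
            " iterations; interpreting the current matrix")

  # attractors: rows with positive diagonal mass
  attr_idx <- which(diag(M) > 0)
  member_sets <- lapply(attr_idx, function(a) sort(unique(c(a, which(M[a, ] > 0)))))
  # merge overlapping attractor systems (union-find over shared members)
  comp <- seq_along(member_sets)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  if (length(member_sets) > 1) {
    owner <- integer(n)
    for (s in seq_along(member_sets)) {
      for (v in member_sets[[s]]) {
        if (owner[v] == 0) owner[v] <- s
        else {
          a <- find(owner[v]); b <- find(s)
          if (a != b) comp[max(a, b)] <- min(a, b)
        }
      }
    }
  }
  groups <- split(seq_along(member_sets),
                  vapply(seq_along(member_sets), find, 0L))
  raw_clusters <- lapply(groups, function(g)
    sort(unique(unlist(member_sets[g]))))

  # assign leftover nodes (column mass entirely on non-attractor rows)
  assigned <- unlist(raw_clusters)
  leftover <- setdiff(seq_len(n), assigned)
  for (v in leftover) {
    pull <- vapply(raw_clusters, function(cl) sum(M[cl, v]), 0)
    if (length(pull) && max(pull) > 0) {
      best <- which(pull == max(pull))
      # tie: the cluster with the smallest member id
      if (length(best) > 1) {
        first_ids <- vapply(raw_clusters[best],
                            function(cl) min(nodes[cl]), "")
        best <- best[order(first_ids)][1]
      } else best <- best[1]
      raw_clusters[[best]] <- sort(c(raw_clusters[[best]], v))
    } else {
      raw_clusters <- c(raw_clusters, list(v))
    }
  }

  sizes <- vapply(raw_clusters, length, 0L)
  singles <- nodes[unlist(raw_clusters[sizes < 2])]
  multi <- raw_clusters[sizes >= 2]
  if (length(multi)) {
    first_id <- vapply(multi, function(cl) min(nodes[cl]), "")
    ord <- order(-vapply(multi, length, 0L), first_id)
    multi <- multi[ord]
    clusters <- lapply(multi, function(cl) sort(nodes[cl]))
    names(clusters) <- paste0("c", seq_along(clusters))
  } else clusters <- stats::setNames(list(), character())

  structure(list(clusters = clusters, singletons = sort(singles),
                 n_iter = iter, max_colsum_dev = max_dev),
            class = "ssp_clustering")
}

#' @export
print.ssp_clustering <- function(x, ...) {
  cat("MCL clustering:", length(x$clusters), "clusters,",
      length(x$singletons), "singletons (", x$n_iter, "iterations )\n")
  invisible(x)
}

#' Write a clustering as a TSV of (node_id, cluster_id)
#'
#' Singletons get cluster_id `"singleton"`.
#'
#' @param clustering An `ssp_clustering`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clustering_tsv <- function(clustering, path) {
  rows <- c(
    lapply(names(clustering$clusters), function(cid)
      data.frame(node_id = clustering$clusters[[cid]], cluster_id = cid,
                 stringsAsFactors = FALSE)),
    if (length(clustering$singletons))
      list(data.frame(node_id = clustering$singletons,
                      cluster_id = "singleton", stringsAsFactors = FALSE)))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
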