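# Orchestration of the discovery pipeline: sequence-level clustering,
# per-cluster modelling, iterative singleton recruitment to a fixpoint,
# profile-level family assembly, consensus motifs, and cross-proteome
# screening against the family library.

cluster_num <- function(id) as.integer(sub("^[cf]", "", id))

# align, prune and model one cluster; returns the cluster record with
# `flagged = TRUE` (and no HMM) when pruning finds no conserved region
model_cluster <- function(id, member_ids, segments, config, seed) {
  seg <- segments[match(member_ids, segments$parent_id), , drop = FALSE]
  aln <- progressive_align(seg, matrix = config$msa$matrix,
                           gap_open = config$msa$gap_open,
                           gap_extend = config$msa$gap_extend)
  pruned <- tryCatch(
    prune_columns(aln, max_gap_frac = config$msa$max_gap_frac,
                  min_col_score = config$msa$min_col_score,
                  matrix = config$msa$matrix),
    error = function(e) NULL)
  if (is.null(pruned))
    return(list(id = id, member_ids = member_ids, alignment = aln,
                hmm = NULL, flagged = TRUE, history = list()))
  hmm <- build_profile_hmm(pruned,
                           pseudocount_weight = config$phmm$pseudocount_weight,
                           cluster_id = id,
                           exit_prob = config$phmm$exit_prob)
  hmm <- calibrate_hmm(hmm, n_samples = config$phmm$calib_n,
                       sample_length = config$phmm$calib_len, seed = seed)
  list(id = id, member_ids = member_ids, alignment = pruned, hmm = hmm,
       flagged = FALSE, history = list())
}

#' Build aligned, pruned, calibrated models for every cluster
#'
#' @param clustering An `ssp_clustering` over segment ids.
#' @param segments The `ssp_segments` the clustering was computed on.
#' @param config Configuration list ([ssp_config()]).
#' @param seed Integer seed (calibration sub-seeds are derived from it).
#' @return Named list of cluster records (`id`, `member_ids`, `alignment`,
#'   `hmm`, `flagged`, `history`).
#' @export
build_cluster_models <- function(clustering, segments,
                                 config = ssp_config(), seed = 1L) {
  out <- list()
  for (id in names(clustering$clusters)) {
    out[[id]] <- model_cluster(id, clustering$clusters[[id]], segments,
                               config, derive_seed(seed, cluster_num(id)))
  }
  out
}

#' Iteratively recruit singletons into clusters
#'
#' Each round, all remaining singletons are searched against every active
#' cluster model; a singleton with a hit at `E <= evalue_cutoff` joins its
#' best-E cluster (ties to the lower cluster id). Affected clusters are
#' realigned, re-pruned, rebuilt and recalibrated, and rounds repeat until
#' a round recruits nobody (the fixpoint) or `max_rounds` is reached (with
#' a warning). Cluster membership grows monotonically.
#'
#' @param clusters Named list of cluster records
#'   ([build_cluster_models()]).
#' @param segments The full `ssp_segments` table (members + singletons).
#' @param singleton_ids Character vector of unclustered segment ids.
#' @param evalue_cutoff Recruitment threshold (default 0.01).
#' @param max_rounds Round cap (default 20).
#' @param config Configuration list.
#' @param seed Integer seed.
#' @return List with updated `clusters`, remaining `singletons`, and
#'   `rounds` (number of recruiting rounds run).
#' @export
recruit_singletons <- function(clusters, segments, singleton_ids,
                               evalue_cutoff = 0.01, max_rounds = 20L,
                               config = ssp_config(), seed = 1L) {
  singles <- singleton_ids
  round <- 0L
  repeat {
    if (!length(singles) || round >= max_rounds) break
    active <- Filter(function(cl) !cl$flagged, clusters)
    if (!length(active)) break
    hmms <- lapply(active, `[[`, "hmm")
    seg <- segments[match(singles, segments$parent_id), , drop = FALSE]
    hits <- hmm_search(hmms, seg, evalue_cutoff)
    if (!nrow(hits)) break
    round <- round + 1L
    # best hit per singleton; ties to the lower cluster id
    hits <- hits[order(hits$sequence_id, hits$evalue,
                       cluster_num(hits$cluster_id)), , drop = FALSE]
    best <- hits[!duplicated(hits$sequence_id), , drop = FALSE]
    affected <- unique(best$cluster_id)
    for (cid in affected) {
      newcomers <- best$sequence_id[best$cluster_id == cid]
      cl <- clusters[[cid]]
      members <- c(cl$member_ids, newcomers)
      rebuilt <- model_cluster(cid, members, segments, config,
                               derive_seed(seed, 10000L * round +
                                             cluster_num(cid)))
      rebuilt$history <- c(cl$history,
                           list(list(iteration = round, ids = newcomers)))
      clusters[[cid]] <- rebuilt
    }
    singles <- setdiff(singles, best$sequence_id)
  }
  if (round >= max_rounds && length(singles)) {
    # check whether recruits were still arriving when the cap hit
    warning("recruitment stopped at the round cap (", max_rounds,
            " rounds) with singletons remaining")
  }
  list(clusters = clusters, singletons = singles, rounds = round)
}

#' Aggregate clusters into families by profile-profile comparison
#'
#' All cluster-model pairs are scored with the co-emission profile DP,
#' converted to E-values against shuffled-profile nulls (comparison count
#' = number of models), and pairs at `E <= prc_evalue_cutoff` become edges
#' of weight `min(200, -log10 E)`. Markov clustering of that graph at
#' `inflation` defines the families; unlinked clusters become
#' single-cluster families. Family ids `f1`, `f2`, ... are ordered by
#' total protein count (ties by smallest cluster id).
#'
#' @param clusters Named list of cluster records (flagged clusters are
#'   excluded from comparison and become single-cluster families without a
#'   model).
#' @param inflation MCL inflation for the profile-level graph (default
#'   1.5).
#' @param prc_evalue_cutoff Edge inclusion threshold (default 0.05).
#' @param config Configuration list.
#' @param seed Integer seed (decoy shuffles).
#' @return List of class `ssp_families`: each element has `id`,
#'   `cluster_ids`, `member_ids`, `representative` (cluster id whose HMM
#'   represents the family), `hmm`, `consensus`, `info_content`.
#' @export
assemble_families <- function(clusters, inflation = 1.5,
                              prc_evalue_cutoff = 0.05,
                              config = ssp_config(), seed = 1L) {
  if (!length(clusters)) stop("no clusters to assemble", call. = FALSE)
  active <- Filter(function(cl) !cl$flagged, clusters)
  ids <- names(active)
  edges <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(ids) >= 2) {
    pairs <- utils::combn(ids, 2)
    n_comp <- length(ids)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      pe <- profile_profile_evalue(
        active[[a]]$hmm, active[[b]]$hmm,
        n_decoys = config$phmm$pp_n_decoys, n_comparisons = n_comp,
        seed = derive_seed(seed, 20000L + k),
        gap_open = config$phmm$pp_gap_open,
        gap_extend = config$phmm$pp_gap_extend)
      if (pe$evalue <= prc_evalue_cutoff)
        edges <- rbind(edges,
                       data.frame(from = a, to = b,
                                  weight = pmin(200, -log10(pe$evalue)),
                                  stringsAsFactors = FALSE))
    }
  }
  graph <- structure(list(nodes = ids, edges = edges), class = "ssp_graph")
  cl2 <- mcl_cluster(graph, inflation = inflation,
                     expansion = config$mcl$expansion,
                     prune_below = config$mcl$prune_below,
                     max_iter = config$mcl$max_iter, tol = config$mcl$tol)
  groups <- c(unname(cl2$clusters), as.list(cl2$singletons),
              as.list(names(clusters)[vapply(clusters, `[[`, TRUE,
                                             "flagged")]))
  fams <- lapply(groups, function(g) {
    g <- sort(g)
    members <- unlist(lapply(clusters[g], `[[`, "member_ids"),
                      use.names = FALSE)
    sizes <- vapply(clusters[g], function(cl) length(cl$member_ids), 0L)
    has_hmm <- !vapply(clusters[g], `[[`, TRUE, "flagged")
    rep_id <- NA_character_
    if (any(has_hmm)) {
      cand <- g[has_hmm]
      cand <- cand[order(-sizes[has_hmm], cluster_num(cand))]
      rep_id <- cand[1]
    }
    list(cluster_ids = g, member_ids = members,
         representative = rep_id,
         hmm = if (!is.na(rep_id)) clusters[[rep_id]]$hmm else NULL)
  })
  total <- vapply(fams, function(f) length(f$member_ids), 0L)
  first <- vapply(fams, function(f) cluster_num(f$cluster_ids[1]), 0L)
  fams <- fams[order(-total, first)]
  for (i in seq_along(fams)) {
    fams[[i]]$id <- paste0("f", i)
    if (!is.null(fams[[i]]$hmm)) {
      cm <- consensus_motif(fams[[i]]$hmm)
      fams[[i]]$consensus <- cm$consensus
      fams[[i]]$info_content <- cm$info_content
    } else {
      fams[[i]]$consensus <- NA_character_
      fams[[i]]$info_content <- numeric()
    }
  }
  names(fams) <- vapply(fams, `[[`, "", "id")
  class(fams) <- "ssp_families"
  fams
}

#' Consensus motif and per-position information content
#'
#' Per match state: the residue of maximal emission probability and the
#' information content `log2(20) - H(emissions)` in bits. Positions with
#' at least 1 bit are uppercase, the rest lowercase.
#'
#' @param x An `ssp_hmm`, or a family record carrying one in `$hmm`.
#' @return List with `consensus` (string) and `info_content` (bits,
#'   one value per match state, each in `[0, log2 20]`).
#' @export
consensus_motif <- function(x) {
  hmm <- if (inherits(x, "ssp_hmm")) x else x$hmm
  if (is.null(hmm)) stop("no representative HMM", call. = FALSE)
  em <- hmm$match_emissions
  info <- apply(em, 1, function(p) log2(20) + sum(p * log2(p)))
  info <- pmin(pmax(info, 0), log2(20))
  res <- AA20[apply(em, 1, which.max)]
  cons <- ifelse(info >= 1, res, tolower(res))
  list(consensus = paste(cons, collapse = ""), info_content = info)
}

#' Screen proteomes against a family library
#'
#' Each protein is Viterbi-scored against every family's representative
#' model; it is assigned to the best family when that E-value is at most
#' `evalue_cutoff`. The E-value comparison count is the total number of
#' comparisons in the screen (proteins x profiles), so the cutoff bounds
#' the expected number of false assignments across the whole screen.
#' Proteomes are expected to be pre-filtered with the
#' same criteria as the reference set (length, signal peptide); use
#' `prefilter = TRUE` to apply them here.
#'
#' @param families An `ssp_families` library.
#' @param proteins An `ssp_proteins` data frame (the `species` column
#'   defines the rows of the family matrix).
#' @param evalue_cutoff Assignment threshold (default 0.05).
#' @param prefilter Apply the length + signal-peptide filters first
#'   (default `FALSE`).
#' @param config Configuration list (used by the prefilter).
#' @return List with `assignments` (data frame `id`, `species`, `family`,
#'   `bits`, `evalue`; unassigned proteins have `family = NA`),
#'   `family_matrix` (species x family count matrix), and `n_unassigned`.
#' @export
screen_proteomes <- function(families, proteins, evalue_cutoff = 0.05,
                             prefilter = FALSE, config = ssp_config()) {
  hmms <- Filter(Negate(is.null), lapply(families, `[[`, "hmm"))
  if (!length(hmms)) stop("empty family library", call. = FALSE)
  if (prefilter) {
    proteins <- filter_by_length(proteins, config$seqio$max_len)
    sig <- predict_signal(proteins, window = config$sigpep$window,
                          min_hydropathy = config$sigpep$min_hydropathy,
                          cleavage_range = config$sigpep$cleavage_range)
    proteins <- proteins[sig$has_signal, , drop = FALSE]
  }
  fam_ids <- names(hmms)
  n_lib <- length(hmms)
  species <- unique(proteins$species)
  mat <- matrix(0L, length(species), n_lib,
                dimnames = list(species, fam_ids))
  n <- nrow(proteins)
  n_comp <- max(1L, n * n_lib)
  assign_fam <- rep(NA_character_, n)
  assign_bits <- rep(NA_real_, n)
  assign_ev <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    best <- NULL
    for (fid in fam_ids) {
      h <- hmms[[fid]]
      bits <- viterbi_score(h, proteins$sequence[i])
      ev <- evalue_from_score(bits, h$calibration, n_comp)
      if (is.null(best) || ev < best$ev ||
          (ev == best$ev && fid < best$fid))
        best <- list(fid = fid, bits = bits, ev = ev)
    }
    if (best$ev <= evalue_cutoff) {
      assign_fam[i] <- best$fid
      assign_bits[i] <- best$bits
      assign_ev[i] <- best$ev
      mat[proteins$species[i], best$fid] <-
        mat[proteins$species[i], best$fid] + 1L
    }
  }
  assignments <- data.frame(id = proteins$id, species = proteins$species,
                            family = assign_fam, bits = assign_bits,
                            evalue = assign_ev, stringsAsFactors = FALSE)
  list(assignments = assignments, family_matrix = mat,
       n_unassigned = sum(is.na(assign_fam)))
}

#' Compare a predicted grouping with ground-truth labels
#'
#' Adjusted Rand Index (chance-corrected partition agreement) plus
#' pairwise precision and recall over co-membership pairs.
#'
#' @param predicted Named character vector: id -> predicted label
#'   (singletons should carry unique labels).
#' @param truth Named character vector over the same ids.
#' @return List `ari`, `pair_precision`, `pair_recall`.
#' @export
evaluate_clustering <- function(predicted, truth) {
  ids <- names(truth)
  if (!length(intersect(names(predicted), ids)))
    stop("predicted and truth share no ids", call. = FALSE)
  if (!setequal(names(predicted), ids))
    stop("predicted and truth must cover the same ids", call. = FALSE)
  p <- predicted[ids]
  ari <- mclust::adjustedRandIndex(p, truth)
  tab <- table(p, truth)
  ch2 <- function(x) x * (x - 1) / 2
  tp <- sum(ch2(tab))
  pred_pairs <- sum(ch2(rowSums(tab)))
  true_pairs <- sum(ch2(colSums(tab)))
  list(ari = ari,
       pair_precision = if (pred_pairs > 0) tp / pred_pairs else 0,
       pair_recall = if (true_pairs > 0) tp / true_pairs else 0)
}

#' Run the discovery pipeline end to end
#'
#' Length filter, signal-peptide filter, C-terminal window extraction,
#' all-against-all local alignment, sequence-level Markov clustering,
#' cluster modelling, singleton recruitment to a fixpoint, and
#' profile-level family assembly. Deterministic given `config` and `seed`.
#'
#' @param proteins An `ssp_proteins` data frame.
#' @param config Configuration list ([ssp_config()]).
#' @param seed Integer master seed.
#' @param signal External `ssp_signal` predictions to merge over the
#'   heuristic (optional).
#' @return Object of class `ssp_result`: `proteins` (the filtered set),
#'   `segments`, `clustering` (initial), `clusters` (after recruitment),
#'   `singletons`, `recruit_rounds`, `families`, `config`, `seed`.
#' @export
ssp_pipeline <- function(proteins, config = ssp_config(), seed = 1L,
                         signal = NULL) {
  short <- filter_by_length(proteins, config$seqio$max_len)
  sig <- predict_signal(short, window = config$sigpep$window,
                        min_hydropathy = config$sigpep$min_hydropathy,
                        cleavage_range = config$sigpep$cleavage_range)
  if (!is.null(signal)) sig <- combine_signal_predictions(sig, signal)
  keep <- sig$has_signal[match(short$id, sig$protein_id)]
  secreted <- short[keep, , drop = FALSE]
  if (nrow(secreted) < 2)
    stop("fewer than 2 candidate secreted proteins after filtering",
         call. = FALSE)
  segments <- extract_cterm(secreted, config$seqio$window)
  hits <- all_vs_all(segments, matrix = config$pairwise$matrix,
                     gap_open = config$pairwise$gap_open,
                     gap_extend = config$pairwise$gap_extend,
                     n_decoys = config$pairwise$n_decoys,
                     seed = derive_seed(seed, 1L))
  graph <- build_graph(hits, config$pairwise$evalue_cutoff)
  clustering <- mcl_cluster(graph, inflation = config$mcl$inflation,
                            expansion = config$mcl$expansion,
                            prune_below = config$mcl$prune_below,
                            max_iter = config$mcl$max_iter,
                            tol = config$mcl$tol)
  clusters <- build_cluster_models(clustering, segments, config,
                                   derive_seed(seed, 2L))
  rec <- recruit_singletons(clusters, segments, clustering$singletons,
                            evalue_cutoff = config$pipeline$recruit_evalue,
                            max_rounds = config$pipeline$recruit_max_rounds,
                            config = config, seed = derive_seed(seed, 3L))
  families <- assemble_families(rec$clusters,
                                inflation = config$pipeline$family_inflation,
                                prc_evalue_cutoff = config$pipeline$prc_evalue,
                                config = config,
                                seed = derive_seed(seed, 4L))
  structure(list(proteins = secreted, segments = segments,
                 clustering = clustering, clusters = rec$clusters,
                 singletons = rec$singletons,
                 recruit_rounds = rec$rounds, families = families,
                 config = config, seed = seed),
            class = "ssp_result")
}

#' @export
print.ssp_result <- function(x, ...) {
  cat("SSP pipeline result:", nrow(x$proteins), "proteins ->",
      length(x$clusters), "clusters (", length(x$singletons),
      "singletons ) ->", length(x$families), "families\n")
  invisible(x)
}

#' Family label per protein from a pipeline result
#'
#' Proteins left unclustered get unique `singleton:<id>` labels so that
#' partition metrics treat them as size-one groups.
#'
#' @param result An `ssp_result`.
#' @return Named character vector id -> family label.
#' @export
family_assignment <- function(result) {
  lab <- stats::setNames(paste0("singleton:", result$proteins$id),
                         result$proteins$id)
  for (f in result$families) lab[f$member_ids] <- f$id
  lab
}

#' Families as a JSON-ready list / file
#'
#' @param families An `ssp_families` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_families_json <- function(families, path) {
  obj <- lapply(families, function(f)
    list(clusters = f$cluster_ids, members = f$member_ids,
         representative = f$representative, consensus = f$consensus,
         info_content = f$info_content))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
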