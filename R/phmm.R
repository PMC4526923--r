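# Per-cluster profile hidden Markov models: build from a pruned alignment,
# calibrate the null score distribution, search sequences, and compare
# profiles against each other (the step that links related clusters into
# families).
#
# Architecture: single-hit local alignment. Match states are the retained
# alignment columns; begin-entry is uniform over match states; every match
# state carries a small exit probability to E (plus certain exit from the
# last state); N- and C-terminal flanking states self-loop emitting
# background, so scores are insensitive to where the motif sits in the
# precursor. There is no multi-hit (J) state: a bioactive motif occurs once
# per preproprotein.

#' Build a profile HMM from a pruned alignment
#'
#' Match emissions are Henikoff position-based sequence-weighted residue
#' counts mixed with `pseudocount_weight` x background and normalised.
#' Transition probabilities come from the observed match/insert/delete
#' structure of the alignment (residues in masked-out columns between two
#' retained columns count as insertions) with Laplace add-one pseudocounts.
#' Insert states emit background.
#'
#' @param aln An `ssp_alignment` whose `column_mask` marks the conserved
#'   columns (>= 1 retained).
#' @param pseudocount_weight Total background pseudocount mass added to
#'   each match-emission vector (default 1).
#' @param cluster_id Identifier stored on the model.
#' @param exit_prob Local exit mass from each internal match state to E
#'   (default 0.05).
#' @return Object of class `ssp_hmm`.
#' @export
build_profile_hmm <- function(aln, pseudocount_weight = 1,
                              cluster_id = "c0", exit_prob = 0.05) {
  mask <- aln$column_mask
  L <- sum(mask)
  if (L < 1) stop("zero retained columns", call. = FALSE)
  chars <- alignment_matrix(aln)
  nseq <- nrow(chars)
  core <- chars[, mask, drop = FALSE]

  # Henikoff position-based weights on the retained columns
  w <- rep(0, nseq)
  for (j in seq_len(L)) {
    col <- core[, j]
    res <- col[col != "-"]
    if (!length(res)) next
    tab <- table(res)
    r <- length(tab)
    contrib <- ifelse(col == "-", 0, 1 / (r * as.numeric(tab[col])))
    w <- w + ifelse(is.na(contrib), 0, contrib)
  }
  if (sum(w) == 0) w <- rep(1, nseq)
  w <- w / sum(w) * nseq            # effective counts total nseq

  bg <- AA_BACKGROUND
  match_emissions <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    counts <- stats::setNames(rep(0, 20), AA20)
    for (i in seq_len(nseq)) {
      a <- core[i, j]
      if (a %in% AA20) counts[a] <- counts[a] + w[i]
    }
    p <- counts + pseudocount_weight * bg
    match_emissions[j, ] <- p / sum(p)
  }

  # transition counts from the match/delete core plus inserts between
  # retained columns
  mpos <- which(mask)
  tc <- list(MM = rep(1, L), MI = rep(1, L), MD = rep(1, L),
             IM = rep(1, L), II = rep(1, L),
             DM = rep(1, L), DD = rep(1, L))   # Laplace pseudocounts
  for (i in seq_len(nseq)) {
    prev_state <- NULL                 # "M" or "D" at node k-1
    for (k in seq_len(L)) {
      st <- if (core[i, k] == "-") "D" else "M"
      nins <- 0L
      if (k > 1 && mpos[k] - mpos[k - 1] > 1) {
        between <- chars[i, (mpos[k - 1] + 1):(mpos[k] - 1)]
        nins <- sum(between != "-")
      }
      if (!is.null(prev_state)) {
        if (nins > 0 && prev_state == "M") {
          # insert run between nodes k-1 and k: M->I, (n-1) I->I, I->M
          tc$MI[k - 1] <- tc$MI[k - 1] + 1
          if (nins > 1) tc$II[k - 1] <- tc$II[k - 1] + (nins - 1)
          tc$IM[k - 1] <- tc$IM[k - 1] + 1
        } else {
          # the plan has no D->I move: inserts after a delete column are
          # dropped from the transition tally
          tc[[paste0(prev_state, st)]][k - 1] <-
            tc[[paste0(prev_state, st)]][k - 1] + 1
        }
      }
      prev_state <- st
    }
  }

  transitions <- list(
    MM = rep(0, L), MI = rep(0, L), MD = rep(0, L), ME = rep(0, L),
    IM = rep(0, L), II = rep(0, L), DM = rep(0, L), DD = rep(0, L))
  for (k in seq_len(L)) {
    if (k < L) {
      tot <- tc$MM[k] + tc$MI[k] + tc$MD[k]
      transitions$MM[k] <- (1 - exit_prob) * tc$MM[k] / tot
      transitions$MI[k] <- (1 - exit_prob) * tc$MI[k] / tot
      transitions$MD[k] <- (1 - exit_prob) * tc$MD[k] / tot
      transitions$ME[k] <- exit_prob
      toti <- tc$IM[k] + tc$II[k]
      transitions$IM[k] <- tc$IM[k] / toti
      transitions$II[k] <- tc$II[k] / toti
      totd <- tc$DM[k] + tc$DD[k]
      transitions$DM[k] <- tc$DM[k] / totd
      transitions$DD[k] <- tc$DD[k] / totd
    } else {
      transitions$ME[k] <- 1
    }
  }

  structure(list(cluster_id = cluster_id, length = L,
                 match_emissions = match_emissions,
                 insert_emissions = bg,
                 transitions = transitions,
                 entry = rep(1 / L, L),
                 background = bg,
                 flank_loop = 350 / 351,
                 calibration = NULL),
            class = "ssp_hmm")
}

#' @export
print.ssp_hmm <- function(x, ...) {
  cat("profile HMM", x$cluster_id, ":", x$length, "match states,",
      if (is.null(x$calibration)) "uncalibrated" else "calibrated", "\n")
  invisible(x)
}

hmm_log_params <- function(hmm) {
  L <- hmm$length
  tr <- hmm$transitions
  lme <- cbind(log(hmm$match_emissions), 0)   # X column emits "1"
  lie <- c(log(hmm$insert_emissions), 0)
  lg <- function(v) ifelse(v > 0, log(v), -Inf)
  r <- hmm$flank_loop
  list(lme = lme, lie = lie,
       tMM = lg(tr$MM), tMI = lg(tr$MI), tMD = lg(tr$MD), tME = lg(tr$ME),
       tIM = lg(tr$IM), tII = lg(tr$II), tDM = lg(tr$DM), tDD = lg(tr$DD),
       tBM = lg(hmm$entry),
       tNN = log(r), tNB = log(1 - r), tCC = log(r), tCT = log(1 - r),
       tDLE = 0)
}

hmm_null_logprob <- function(hmm, enc) {
  r <- hmm$flank_loop
  lie <- c(log(hmm$background), 0)
  length(enc) * log(r) + sum(lie[enc]) + log(1 - r)
}

hmm_score_one <- function(hmm, seq, forward) {
  if (!nzchar(seq)) stop("sequence must be non-empty", call. = FALSE)
  enc <- aa_encode(seq)
  p <- hmm_log_params(hmm)
  lp <- .hmm_score_dp(enc, p$lme, p$lie, p$tMM, p$tMI, p$tMD, p$tME,
                      p$tIM, p$tII, p$tDM, p$tDD, p$tBM,
                      p$tNN, p$tNB, p$tCC, p$tCT, p$tDLE, forward)
  (lp - hmm_null_logprob(hmm, enc)) / log(2)
}

#' Log-odds scores of a sequence against a profile HMM
#'
#' `forward_score()` sums over all paths; `viterbi_score()` takes the best
#' path. Both are reported in bits:
#' \eqn{\log_2 P(seq \mid hmm) / P(seq \mid background)}, with the null a
#' geometric-length background composition model. `X` residues emit
#' background in both numerator and denominator and so contribute 0 bits.
#'
#' @param hmm An `ssp_hmm`.
#' @param seq Non-empty amino-acid sequence.
#' @return Log-odds score in bits.
#' @export
forward_score <- function(hmm, seq) hmm_score_one(hmm, seq, TRUE)

#' @rdname forward_score
#' @export
viterbi_score <- function(hmm, seq) hmm_score_one(hmm, seq, FALSE)

# raw natural-log sequence probability under the model (used by the
# exhaustive-enumeration correctness checks)
hmm_log_prob <- function(hmm, seq, forward = TRUE) {
  enc <- aa_encode(seq)
  p <- hmm_log_params(hmm)
  .hmm_score_dp(enc, p$lme, p$lie, p$tMM, p$tMI, p$tMD, p$tME,
                p$tIM, p$tII, p$tDM, p$tDD, p$tBM,
                p$tNN, p$tNB, p$tCC, p$tCT, p$tDLE, forward)
}

#' Calibrate a profile HMM against random background sequences
#'
#' Scores `n_samples` i.i.d. background sequences of length
#' `sample_length` with Viterbi (the same scorer used in search) and fits
#' a Gumbel by maximum likelihood. Deterministic given `seed`.
#'
#' @param hmm An `ssp_hmm`.
#' @param n_samples Number of null samples (>= 100; default 1000).
#' @param sample_length Length of each null sequence (default 350).
#' @param seed Integer seed.
#' @return The HMM with a `calibration` field: `mu`, `lambda`, `beta`,
#'   `n_samples`, `sample_length`, `seed`.
#' @export
calibrate_hmm <- function(hmm, n_samples = 1000L, sample_length = 350L,
                          seed = 1L) {
  stopifnot(n_samples >= 100)
  scores <- withr_seed(seed, {
    vapply(seq_len(n_samples), function(i)
      viterbi_score(hmm, aa_sample(sample_length, hmm$background)), 0)
  })
  if (stats::sd(scores) < 1e-12)
    stop("degenerate null score distribution; calibration failed",
         call. = FALSE)
  fit <- fit_gumbel(scores)
  hmm$calibration <- list(mu = fit$mu, lambda = fit$lambda,
                          beta = fit$beta, n_samples = n_samples,
                          sample_length = sample_length, seed = seed)
  hmm
}

#' Search sequences against calibrated profile HMMs
#'
#' Every sequence is Viterbi-scored against every model; E-values use each
#' model's Gumbel calibration with the number of target sequences as the
#' comparison count. Hits with `E <= evalue_cutoff` are returned sorted by
#' E (ties by sequence then cluster id).
#'
#' @param hmms List of calibrated `ssp_hmm` objects.
#' @param seqs An `ssp_proteins` or `ssp_segments` data frame (columns
#'   `id`/`parent_id` and `sequence`).
#' @param evalue_cutoff Maximum reported E-value.
#' @return Data frame `sequence_id`, `cluster_id`, `bits`, `evalue`.
#' @export
hmm_search <- function(hmms, seqs, evalue_cutoff = 0.01) {
  ids <- seqs$id %||% seqs$parent_id
  n <- length(ids)
  if (n == 0)
    return(data.frame(sequence_id = character(), cluster_id = character(),
                      bits = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  rows <- list()
  for (h in hmms) {
    if (is.null(h$calibration))
      stop("HMM ", h$cluster_id, " is not calibrated", call. = FALSE)
    bits <- vapply(seqs$sequence, function(s) viterbi_score(h, s), 0,
                   USE.NAMES = FALSE)
    ev <- evalue_from_score(bits, h$calibration, n)
    rows[[length(rows) + 1L]] <-
      data.frame(sequence_id = ids, cluster_id = h$cluster_id,
                 bits = bits, evalue = ev, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[out$evalue <= evalue_cutoff, , drop = FALSE]
  out <- out[order(out$evalue, out$sequence_id, out$cluster_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Profile-profile comparison score
#'
#' Local dynamic program over match-state pairs with the co-emission
#' column score
#' \eqn{s(i, j) = \log_2 \sum_a p_i(a) q_j(a) / f(a)}
#' and affine gaps on either profile; the score is floored at 0 and is
#' exactly symmetric in its arguments.
#'
#' @param h1,h2 `ssp_hmm` objects.
#' @param gap_open,gap_extend Profile-level affine gap penalties in bits
#'   (defaults 5 and 1).
#' @return List with `score` (bits) and `pairs`, a 2-column matrix of
#'   aligned match-state indices (gaps as 0).
#' @export
profile_profile_score <- function(h1, h2, gap_open = 5, gap_extend = 1) {
  S <- coemission_matrix(h1, h2)
  res <- .align_local_dp(S, gap_open, gap_extend, TRUE)
  list(score = res$score,
       pairs = cbind(state1 = res$a_idx, state2 = res$b_idx))
}

coemission_matrix <- function(h1, h2) {
  f <- h1$background
  log2(h1$match_emissions %*% (t(h2$match_emissions) / f))
}

#' Profile-profile E-value by shuffled-profile calibration
#'
#' The null is built by permuting the order of `h2`'s match states
#' (column shuffling) `n_decoys` times, rescoring, and fitting a Gumbel;
#' when the decoy score distribution is degenerate (typical for unrelated
#' profiles, whose local scores floor at 0) an empirical rank p-value
#' `(1 + #(decoy >= S)) / (n_decoys + 1)` is used instead. Deterministic
#' given `seed`.
#'
#' @param h1,h2 `ssp_hmm` objects.
#' @param n_decoys Number of shuffled decoy profiles (default 200).
#' @param n_comparisons Comparison count scaling the E-value (default 1).
#' @param seed Integer seed.
#' @param gap_open,gap_extend Passed to [profile_profile_score()].
#' @return List with `score`, `evalue`, `pvalue`.
#' @export
profile_profile_evalue <- function(h1, h2, n_decoys = 200L,
                                   n_comparisons = 1L, seed = 1L,
                                   gap_open = 5, gap_extend = 1) {
  obs <- profile_profile_score(h1, h2, gap_open, gap_extend)$score
  decoy <- withr_seed(seed, {
    vapply(seq_len(n_decoys), function(i) {
      perm <- sample.int(h2$length)
      hs <- h2
      hs$match_emissions <- h2$match_emissions[perm, , drop = FALSE]
      profile_profile_score(h1, hs, gap_open, gap_extend)$score
    }, 0)
  })
  if (stats::sd(decoy) > 1e-8) {
    fit <- fit_gumbel(decoy)
    p <- evalue_from_score(obs, fit, 1L)
  } else {
    p <- (1 + sum(decoy >= obs)) / (n_decoys + 1)
  }
  p <- min(1, max(p, 1e-200))
  list(score = obs, pvalue = p,
       evalue = max(n_comparisons * p, 1e-200))
}

#' Serialise / load a profile HMM as JSON
#'
#' @param hmm An `ssp_hmm`.
#' @param path JSON file path.
#' @return `path` (write) or an `ssp_hmm` (read).
#' @export
write_hmm_json <- function(hmm, path) {
  obj <- list(cluster_id = hmm$cluster_id, length = hmm$length,
              alphabet = AA20,
              match_emissions = unname(apply(hmm$match_emissions, 1,
                                             as.numeric, simplify = FALSE)),
              insert_emissions = as.numeric(hmm$insert_emissions),
              transitions = lapply(hmm$transitions, as.numeric),
              entry = as.numeric(hmm$entry),
              background = as.numeric(hmm$background),
              flank_loop = hmm$flank_loop,
              calibration = hmm$calibration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  me <- obj$match_emissions
  if (!is.matrix(me)) me <- do.call(rbind, me)
  colnames(me) <- AA20
  structure(list(cluster_id = obj$cluster_id, length = obj$length,
                 match_emissions = me,
                 insert_emissions = stats::setNames(obj$insert_emissions,
                                                    AA20),
                 transitions = lapply(obj$transitions, as.numeric),
                 entry = obj$entry,
                 background = stats::setNames(obj$background, AA20),
                 flank_loop = obj$flank_loop,
                 calibration = obj$calibration),
            class = "ssp_hmm")
}
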