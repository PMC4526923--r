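test_that("profile construction yields normalised, data-driven emissions", {
  single <- sspfam:::new_alignment("a", c(a = "WKY"))
  h <- build_profile_hmm(single, cluster_id = "c1")
  expect_equal(h$length, 3L)
  expect_equal(colnames(h$match_emissions)[apply(h$match_emissions, 1,
                                                 which.max)],
               c("W", "K", "Y"))
  expect_equal(unname(rowSums(h$match_emissions)), rep(1, 3),
               tolerance = 1e-9)

  rows <- stats::setNames(rep("MKWVL", 4), c("a", "b", "c", "d"))
  ident <- sspfam:::new_alignment(c("a", "b", "c", "d"), rows)
  hi <- build_profile_hmm(ident)
  expect_equal(colnames(hi$match_emissions)[apply(hi$match_emissions, 1,
                                                  which.max)],
               c("M", "K", "W", "V", "L"))
  # transition vectors are proper distributions wherever defined
  tr <- hi$transitions
  L <- hi$length
  for (k in seq_len(L - 1)) {
    expect_equal(tr$MM[k] + tr$MI[k] + tr$MD[k] + tr$ME[k], 1,
                 tolerance = 1e-9)
    expect_equal(tr$IM[k] + tr$II[k], 1, tolerance = 1e-9)
    expect_equal(tr$DM[k] + tr$DD[k], 1, tolerance = 1e-9)
  }
  expect_equal(tr$ME[L], 1)
  expect_equal(sum(hi$entry), 1, tolerance = 1e-9)

  h0 <- build_profile_hmm(ident, pseudocount_weight = 0)
  expect_false(isTRUE(all.equal(h0$match_emissions, hi$match_emissions)))
  expect_equal(unname(rowSums(h0$match_emissions)), rep(1, 5),
               tolerance = 1e-9)

  empty <- sspfam:::new_alignment("a", c(a = "WKY"),
                                  column_mask = rep(FALSE, 3))
  expect_error(build_profile_hmm(empty), "zero retained columns")
})

test_that("forward probability sums to one over all emittable sequences", {
  h <- tiny_enumerable_hmm()
  seqs <- c("A", "C", "AA", "AC", "CA", "CC")
  p <- vapply(seqs, function(s)
    exp(sspfam:::hmm_log_prob(h, s, forward = TRUE)), 0)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # hand-computed path sums for the length-1 sequences:
  # P(A) = .5*.7*.3 (M1->E) + .5*.2 (M2->E) + .5*.7*.2 (M1->D2->E)
  expect_equal(unname(p["A"]), 0.275, tolerance = 1e-12)
  expect_equal(unname(p["C"]), 0.475, tolerance = 1e-12)
})

test_that("viterbi never exceeds forward", {
  h <- tiny_enumerable_hmm()
  for (s in c("A", "AC", "CC", "CA"))
    expect_lte(sspfam:::hmm_log_prob(h, s, FALSE),
               sspfam:::hmm_log_prob(h, s, TRUE) + 1e-12)

  aln <- prune_columns(progressive_align(
    make_segments(c("WKYGDECF", "WKYGDECF", "WKYADECF"))))
  hm <- build_profile_hmm(aln)
  set.seed(51)
  for (k in 1:20) {
    s <- rand_seq(sample(10:60, 1))
    expect_lte(viterbi_score(hm, s), forward_score(hm, s) + 1e-9)
  }
})

test_that("a model prefers its own sequence to shuffles of it", {
  seqn <- "WKYGDECFMWKYPQ"
  aln <- sspfam:::new_alignment("a", stats::setNames(seqn, "a"))
  h <- build_profile_hmm(aln)
  own <- viterbi_score(h, seqn)
  set.seed(52)
  shuf <- vapply(1:100, function(i)
    viterbi_score(h, paste(sample(strsplit(seqn, "")[[1]]),
                           collapse = "")), 0)
  expect_gt(own, stats::median(shuf))
})

test_that("calibration recovers a known Gumbel and is reproducible", {
  set.seed(53)
  x <- sspfam:::rgumbel(5000, mu = -5, beta = 1.5)
  fit <- fit_gumbel(x)
  expect_lt(abs(fit$mu - (-5)), 0.2)
  expect_lt(abs(fit$beta - 1.5) / 1.5, 0.10)
  # E-value of a score at the fitted location with database size 1
  expect_equal(evalue_from_score(fit$mu, fit, 1), 1 - exp(-1),
               tolerance = 1e-9)

  aln <- prune_columns(progressive_align(
    make_segments(c("WKYGDECF", "WKYGDECF", "WKYADECF"))))
  h <- build_profile_hmm(aln)
  c1 <- calibrate_hmm(h, n_samples = 150, sample_length = 80, seed = 7)
  c2 <- calibrate_hmm(h, n_samples = 150, sample_length = 80, seed = 7)
  expect_identical(c1$calibration, c2$calibration)
  expect_gt(c1$calibration$lambda, 0)
})

test_that("hmm_search returns calibrated hits below the cutoff", {
  memb <- c("GGWKYGDECFAA", "TTWKYGDECFLL", "PPWKYADECFSS")
  aln <- prune_columns(progressive_align(make_segments(memb)))
  h <- calibrate_hmm(build_profile_hmm(aln, cluster_id = "c1"),
                     n_samples = 200, sample_length = 60, seed = 8)

  empty <- hmm_search(list(h), make_segments(character(0)), 0.05)
  expect_equal(nrow(empty), 0L)

  set.seed(54)
  seqs <- make_segments(c(memb[1], rand_seq(40)), ids = c("self", "bg"))
  hits <- hmm_search(list(h), seqs, evalue_cutoff = 10)
  expect_true(all(hits$evalue <= 10))
  expect_equal(hits$sequence_id[1], "self")   # best hit is the member

  un <- build_profile_hmm(aln, cluster_id = "u")
  expect_error(hmm_search(list(un), seqs, 1), "not calibrated")
})

test_that("profile comparison is symmetric and self-favouring", {
  memb1 <- c("AAWKYGDECFGG", "CCWKYGDECFTT", "IIWKYADECFNN")
  memb2 <- c("PPMNQRSTVLHH", "KKMNQRSTVLDD", "EEMNQRSTVLSS")
  h1 <- build_profile_hmm(prune_columns(progressive_align(
    make_segments(memb1))), cluster_id = "c1")
  h2 <- build_profile_hmm(prune_columns(progressive_align(
    make_segments(memb2))), cluster_id = "c2")
  s12 <- profile_profile_score(h1, h2)$score
  s21 <- profile_profile_score(h2, h1)$score
  expect_identical(s12, s21)
  expect_gte(profile_profile_score(h1, h1)$score, s12)
  expect_gte(profile_profile_score(h2, h2)$score, s12)
})

test_that("disjoint near-delta profiles score zero", {
  # single-residue columns on disjoint residues; pseudocounts leave only
  # a small off-mass, so every co-emission column score is negative
  a1 <- sspfam:::new_alignment(c("a", "b"), c(a = "WWWW", b = "WWWW"))
  a2 <- sspfam:::new_alignment(c("a", "b"), c(a = "PPPP", b = "PPPP"))
  h1 <- build_profile_hmm(a1, pseudocount_weight = 0.1)
  h2 <- build_profile_hmm(a2, pseudocount_weight = 0.1)
  S <- sspfam:::coemission_matrix(h1, h2)
  expect_true(all(S <= 0))
  expect_equal(profile_profile_score(h1, h2)$score, 0)
})

test_that("profile E-values separate related from unrelated profiles", {
  base <- c("AAWKYGDECFGG", "CCWKYGDECFTT", "IIWKYADECFNN")
  related <- c("TTWKYGDECFPP", "GGWKYGDTCFAA", "LLWKYGDECFEE")
  other <- c("PPMNQRSTVLHH", "KKMNQRSTVLDD", "EEMNQRSTVLSS")
  mk <- function(x, id) build_profile_hmm(
    prune_columns(progressive_align(make_segments(x))), cluster_id = id)
  h0 <- mk(base, "c0"); hr <- mk(related, "cr"); hu <- mk(other, "cu")
  er <- profile_profile_evalue(h0, hr, seed = 3)
  eu <- profile_profile_evalue(h0, hu, seed = 3)
  expect_lt(er$evalue, 0.05)
  expect_gt(eu$evalue, 0.05)
  # determinism under the seed
  expect_identical(er, profile_profile_evalue(h0, hr, seed = 3))
})

test_that("profile HMMs round-trip through JSON", {
  aln <- prune_columns(progressive_align(
    make_segments(c("WKYGDECF", "WKYGDECF", "WKYADECF"))))
  h <- calibrate_hmm(build_profile_hmm(aln, cluster_id = "c9"),
                     n_samples = 120, sample_length = 60, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(h, f)
  h2 <- read_hmm_json(f)
  expect_equal(h2$cluster_id, "c9")
  expect_equal(h2$match_emissions, h$match_emissions, tolerance = 1e-12)
  expect_equal(h2$transitions$MM, h$transitions$MM, tolerance = 1e-12)
  expect_equal(h2$calibration$mu, h$calibration$mu, tolerance = 1e-12)
  s <- "GGWKYGDECFAA"
  expect_equal(viterbi_score(h2, s), viterbi_score(h, s),
               tolerance = 1e-9)
})
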