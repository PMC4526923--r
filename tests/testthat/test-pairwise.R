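test_that("Smith-Waterman handles the elementary cases", {
  expect_equal(smith_waterman("WW", "WW")$score, 30)   # 2 x BLOSUM50 W/W
  neg <- smith_waterman("WWWW", "PPPP")
  expect_equal(neg$score, 0)
  expect_equal(ncol(neg$alignment), 0L)                # empty alignment
  expect_error(smith_waterman("WWB", "WW"), "unknown residue 'B'")
  expect_error(smith_waterman("", "WW"), "non-empty")
  # X is neutral: scores 0 against everything
  expect_equal(smith_waterman("XXXX", "WWWW")$score, 0)
})

test_that("scores match the memoised-recursion oracle on random pairs", {
  set.seed(11)
  mat <- ssp_matrix("BLOSUM50")
  for (k in 1:200) {
    a <- rand_seq(sample(3:12, 1))
    b <- rand_seq(sample(3:12, 1))
    expect_equal(smith_waterman(a, b)$score,
                 sw_oracle_memo(a, b, mat),
                 label = paste(a, "vs", b))
  }
})

test_that("scores match brute-force enumeration over all local alignments", {
  set.seed(12)
  mat <- ssp_matrix("BLOSUM50")
  for (k in 1:60) {
    a <- rand_seq(sample(3:6, 1))
    b <- rand_seq(sample(3:6, 1))
    expect_equal(smith_waterman(a, b)$score,
                 sw_oracle_enum(a, b, mat),
                 label = paste(a, "vs", b))
  }
})

test_that("scores agree with an independent aligner implementation", {
  # Biostrings charges a gap of length L as opening + L*extension, so its
  # opening penalty is ours minus one extension
  suppressPackageStartupMessages(requireNamespace("Biostrings"))
  env <- new.env()
  utils::data("BLOSUM50", package = "Biostrings", envir = env)
  set.seed(13)
  for (k in 1:60) {
    a <- rand_seq(sample(4:30, 1))
    b <- rand_seq(sample(4:30, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = env$BLOSUM50, gapOpening = 8, gapExtension = 2)
    expect_equal(smith_waterman(a, b)$score, Biostrings::score(ref))
  }
})

test_that("SW is symmetric, non-negative, and flank-monotone", {
  set.seed(14)
  for (k in 1:30) {
    a <- rand_seq(sample(3:15, 1))
    b <- rand_seq(sample(3:15, 1))
    sa <- smith_waterman(a, b)$score
    expect_identical(sa, smith_waterman(b, a)$score)
    expect_gte(sa, 0)
    flank <- rand_seq(sample(1:6, 1))
    expect_gte(smith_waterman(paste0(a, flank), paste0(b, flank))$score, sa)
  }
})

test_that("Gumbel calibration recovers known parameters and is seeded", {
  set.seed(20)
  x <- sspfam:::rgumbel(5000, mu = 10, beta = 2)
  fit <- fit_gumbel(x)
  expect_lt(abs(fit$mu - 10), 0.2)
  expect_lt(abs(fit$beta - 2) / 2, 0.10)

  expect_error(fit_gumbel(rep(5, 1000)), "degenerate")

  seg <- make_segments(replicate(12, rand_seq(50)))
  f1 <- fit_score_background(seg, n_decoys = 150, seed = 5)
  f2 <- fit_score_background(seg, n_decoys = 150, seed = 5)
  expect_identical(f1, f2)
  expect_gt(f1$lambda, 0)
})

test_that("E-values follow the Gumbel identity and are monotone", {
  evd <- list(mu = 10, lambda = 0.5)
  expect_equal(evalue_from_score(10, evd, 1), 1 - exp(-1),
               tolerance = 1e-12)
  # strict within double precision: away from the p ~ 1 saturation zone
  # and above the 1e-200 floor
  s <- seq(8, 100, by = 4)
  e <- evalue_from_score(s, evd, 100)
  expect_true(all(diff(e) < 0))
  expect_true(all(diff(evalue_from_score(c(-20, 0, 8), evd, 100)) <= 0))
  expect_equal(evalue_from_score(1e6, evd, 1), 1e-200)  # floor
})

test_that("all_vs_all produces one canonical hit per pair", {
  set.seed(21)
  base <- rand_seq(40)
  seg <- make_segments(c(paste0(rand_seq(10), base),   # related pair
                         paste0(rand_seq(10), base),
                         rand_seq(50), rand_seq(50)),
                       ids = c("dup1", "dup2", "bg1", "bg2"))
  hits <- all_vs_all(seg, n_decoys = 150, seed = 9)
  expect_equal(nrow(hits), 6L)                        # 4 choose 2
  expect_true(all(hits$query_id < hits$target_id))
  # the near-identical pair attains the smallest E-value involving either
  dup <- hits$evalue[hits$query_id == "dup1" & hits$target_id == "dup2"]
  other <- hits$evalue[hits$query_id %in% c("dup1", "dup2") |
                         hits$target_id %in% c("dup1", "dup2")]
  expect_equal(dup, min(other))
})

test_that("graph construction applies cutoff, weight transform and cap", {
  hits <- structure(
    data.frame(query_id = c("a", "a", "b"),
               target_id = c("b", "c", "c"),
               raw_score = c(50, 20, 80),
               bit_score = c(5, 2, 8),
               evalue = c(1e-4, 0.01, 1e-250),
               stringsAsFactors = FALSE),
    class = c("ssp_hits", "data.frame"))
  attr(hits, "node_ids") <- c("a", "b", "c", "d")
  g <- build_graph(hits, evalue_cutoff = 1e-3)
  expect_setequal(g$nodes, c("a", "b", "c", "d"))     # isolated d kept
  expect_equal(nrow(g$edges), 2L)                     # 0.01 dropped
  expect_equal(g$edges$weight[g$edges$from == "a"], 4)        # -log10(1e-4)
  expect_equal(g$edges$weight[g$edges$from == "b"], 200)      # cap
  # edge set shrinks monotonically as the cutoff tightens
  expect_lte(nrow(build_graph(hits, 1e-6)$edges), nrow(g$edges))
  # round-trip through the TSV edge list
  f <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, f)
  g2 <- read_graph_tsv(f)
  expect_setequal(g2$nodes, g$nodes)
  expect_equal(nrow(g2$edges), nrow(g$edges))
})
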