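test_that("the three signal rules behave on designed sequences", {
  # n-region MKT (charge +1), strong h-region, A-S-A before the mature Qs
  pass <- paste0("MKT", "LLLLLLLL", "ASA", strrep("Q", 60))
  p <- ssp_proteins("pass", "", pass)
  sig <- predict_signal(p)
  expect_true(sig$has_signal)
  expect_equal(sig$cleavage_pos, 14L)
  expect_gt(sig$score, 0)
  expect_lte(sig$score, 1)

  # acidic, no hydrophobic core: rule (i) cannot hold
  neg <- predict_signal(ssp_proteins("neg", "", strrep("E", 80)))
  expect_false(neg$has_signal)
  expect_equal(neg$score, 0)

  # too short for any call
  tiny <- predict_signal(ssp_proteins("tiny", "", "MKTLLLLASA"))
  expect_false(tiny$has_signal)
})

test_that("predictions are deterministic and the invariant holds", {
  set.seed(3)
  p <- ssp_proteins(sprintf("r%02d", 1:30), "",
                    vapply(sample(20:150, 30), rand_seq, ""))
  s1 <- predict_signal(p)
  s2 <- predict_signal(p)
  expect_identical(s1, s2)
  pos <- s1[s1$has_signal, ]
  if (nrow(pos)) {
    expect_true(all(pos$cleavage_pos >= 10 & pos$cleavage_pos <= 45))
  }
  expect_true(all(s1$score >= 0 & s1$score <= 1))
})

test_that("adding leucines to a passing h-region never loses the signal", {
  base <- paste0("MKT", "LLLLLLLL", "ASA", strrep("Q", 50))
  p0 <- predict_signal(ssp_proteins("x", "", base))
  expect_true(p0$has_signal)
  for (extra in 1:6) {
    seq <- paste0("MKT", strrep("L", 8 + extra), "ASA", strrep("Q", 50))
    expect_true(predict_signal(ssp_proteins("x", "", seq))$has_signal,
                label = paste("extra L =", extra))
  }
})

test_that("generator signal peptides are detected with high sensitivity", {
  # generate 1000 signal-bearing records in total across repeated draws
  specs <- lapply(1:10, function(k)
    synthetic_spec(n_families = 10L, members_per_family = 10L,
                   n_decoys = 0L, seed = 100L + k))
  prots <- do.call(rbind, lapply(specs, function(s) {
    d <- generate_dataset(s)$proteins
    d$id <- paste0("s", s$seed, "_", d$id)
    d
  }))
  class(prots) <- c("ssp_proteins", "data.frame")
  expect_gte(nrow(prots), 1000L)
  sens <- mean(predict_signal(prots)$has_signal)
  expect_gte(sens, 0.95)
})

test_that("signal-free records are rejected with high specificity", {
  spec <- synthetic_spec(n_families = 10L, members_per_family = 10L,
                         n_decoys = 100L, include_signal = FALSE,
                         seed = 202L)
  prots <- generate_dataset(spec)$proteins
  spec_rate <- mean(!predict_signal(prots)$has_signal)
  expect_gte(spec_rate, 0.9)
})

test_that("external prediction tables import, validate and override", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\thas_signal\tcleavage_pos\tscore",
               "a\tY\t22\t0.91",
               "b\tN\t0\t0.03",
               "zz\tY\t30\t0.5"), f)
  ext <- import_signal_predictions(f)
  expect_equal(nrow(ext), 3L)
  expect_equal(ext$source, rep("external", 3))
  expect_true(ext$has_signal[1])
  expect_equal(ext$cleavage_pos[1], 22L)
  expect_false(ext$has_signal[2])

  writeLines(c("id\thas_signal\tcleavage_pos\tscore",
               "a\tmaybe\t22\t0.91"), f)
  expect_error(import_signal_predictions(f), "line 2")

  heur <- predict_signal(ssp_proteins("a", "", strrep("E", 80)))
  merged <- combine_signal_predictions(heur, ext)
  expect_true(merged$has_signal[merged$protein_id == "a"])
  expect_equal(sort(unique(merged$protein_id)), c("a", "b", "zz"))
})
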