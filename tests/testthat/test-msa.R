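test_that("normalised distances are zero on the diagonal and bounded", {
  set.seed(41)
  seg <- make_segments(replicate(5, rand_seq(30)))
  D <- segment_distances(seg)
  expect_equal(unname(diag(D)), rep(0, 5))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
})

test_that("the guide tree joins the closest pair first", {
  seg <- make_segments(c("ACDEFGHIKL", "ACDEFGHIKL", "WWPPWWPPWW"),
                       ids = c("a", "b", "c"))
  tree <- upgma_guide_tree(seg)
  # identical a and b form the first cherry; c joins at the root
  inner <- if (!is.null(tree$left$leaf)) tree$right else tree$left
  expect_setequal(sspfam:::tree_leaves(inner), c("a", "b"))
  expect_equal(inner$height, 0)

  two <- upgma_guide_tree(make_segments(c("ACD", "ACE"),
                                        ids = c("p", "q")))
  expect_setequal(sspfam:::tree_leaves(two), c("p", "q"))
})

test_that("progressive alignment reproduces inputs after ungapping", {
  seg <- make_segments(c("ACDE", "ACE"), ids = c("a", "b"))
  aln <- progressive_align(seg)
  expect_equal(unname(nchar(aln$rows)), c(4L, 4L))
  expect_equal(ungap(aln$rows[["a"]]), "ACDE")
  expect_equal(ungap(aln$rows[["b"]]), "ACE")
  expect_equal(sum(strsplit(aln$rows[["b"]], "")[[1]] == "-"), 1L)

  ident <- make_segments(rep("MKWVLS", 4))
  ai <- progressive_align(ident)
  expect_true(all(ai$rows == "MKWVLS"))     # zero gaps

  set.seed(42)
  seqs <- replicate(6, rand_seq(sample(20:40, 1)))
  rseg <- make_segments(seqs)
  raln <- progressive_align(rseg)
  expect_length(raln$rows, 6L)
  expect_length(unique(nchar(raln$rows)), 1L)
  expect_equal(unname(ungap(raln$rows[rseg$parent_id])), seqs)
})

test_that("column pruning enforces the gap and conservation rules", {
  rows <- c(a = "WA-C", b = "WC-C", c = "W--C")
  aln <- sspfam:::new_alignment(c("a", "b", "c"), rows)
  pr <- prune_columns(aln)
  # col1 all-W retained; col2 60%-ish gaps? (1/3 gaps, A vs C scores 0) ->
  # mean pairwise B62(A,C) = 0, not > 0 -> removed; col3 all-gap removed;
  # col4 all-C retained
  expect_equal(pr$column_mask, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(pr$rows, aln$rows)       # rows untouched
  # idempotent
  expect_equal(prune_columns(pr)$column_mask, pr$column_mask)

  gappy <- sspfam:::new_alignment(
    c("a", "b", "c", "d", "e"),
    c(a = "W-", b = "W-", c = "W-", d = "WW", e = "WW"))
  pg <- prune_columns(gappy)
  expect_equal(pg$column_mask, c(TRUE, FALSE))   # 60% gaps removed

  allgap <- sspfam:::new_alignment(c("a", "b"), c(a = "-P", b = "-P"))
  pa <- prune_columns(allgap)
  expect_equal(pa$column_mask, c(FALSE, TRUE))

  bad <- sspfam:::new_alignment(c("a", "b"), c(a = "AW", b = "WA"))
  expect_error(prune_columns(bad), "no conserved region")
})

test_that("identical-sequence clusters keep every column", {
  aln <- progressive_align(make_segments(rep("WKYGDE", 3)))
  pr <- prune_columns(aln)
  expect_true(all(pr$column_mask))
})

test_that("alignments round-trip through Stockholm with the mask", {
  seg <- make_segments(c("ACDEFW", "ACDFW", "ACEFW"))
  aln <- prune_columns(progressive_align(seg))
  f <- withr::local_tempfile(fileext = ".sto")
  write_stockholm(aln, f)
  back <- read_stockholm(f)
  expect_equal(back$rows, aln$rows)
  expect_equal(back$column_mask, aln$column_mask)
  expect_equal(back$member_ids, aln$member_ids)
})
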