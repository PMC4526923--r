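# Shared fixtures and independent oracles for the test suite.

AA20 <- sspfam:::AA20

rand_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

make_segments <- function(seqs, ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_along(seqs))
  structure(data.frame(parent_id = ids, sequence = as.character(seqs),
                       offset = rep(0L, length(seqs)),
                       stringsAsFactors = FALSE),
            class = c("ssp_segments", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_graph <- function(nodes, from, to, weight) {
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, weight = weight,
                                    stringsAsFactors = FALSE)),
            class = "ssp_graph")
}

# two 4-cliques joined by a single weak bridge: the canonical fixture for
# inflation-controlled splitting
bridged_cliques_graph <- function(bridge_weight = 0.1) {
  a <- paste0("A", 1:4)
  b <- paste0("B", 1:4)
  ea <- utils::combn(a, 2)
  eb <- utils::combn(b, 2)
  make_graph(c(a, b),
             c(ea[1, ], eb[1, ], "A1"),
             c(ea[2, ], eb[2, ], "B1"),
             c(rep(1, 12), bridge_weight))
}

# ---- independent Smith-Waterman oracles -------------------------------

# top-down memoised recursion over (i, j, state), written independently of
# the package's iterative kernel; gap of length L costs open + (L-1)*ext
sw_oracle_memo <- function(a, b, mat, open = 10, ext = 2) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  H <- array(NA_real_, c(n + 1, m + 1))
  X <- array(NA_real_, c(n + 1, m + 1))   # gap in b (consumes a)
  Y <- array(NA_real_, c(n + 1, m + 1))   # gap in a (consumes b)
  hf <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (!is.na(H[i + 1, j + 1])) return(H[i + 1, j + 1])
    v <- max(0,
             hf(i - 1, j - 1) + mat[ca[i], cb[j]],
             xf(i, j), yf(i, j))
    H[i + 1, j + 1] <<- v
    v
  }
  xf <- function(i, j) {
    if (i == 0) return(-Inf)
    if (!is.na(X[i + 1, j + 1])) return(X[i + 1, j + 1])
    v <- max(hf(i - 1, j) - open, xf(i - 1, j) - ext)
    X[i + 1, j + 1] <<- v
    v
  }
  yf <- function(i, j) {
    if (j == 0) return(-Inf)
    if (!is.na(Y[i + 1, j + 1])) return(Y[i + 1, j + 1])
    v <- max(hf(i, j - 1) - open, yf(i, j - 1) - ext)
    Y[i + 1, j + 1] <<- v
    v
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    best <- max(best, hf(i, j))
  best
}

# brute-force enumeration of every gapped local alignment: every increasing
# sequence of aligned residue pairs, with affine costs for the unaligned
# stretches between consecutive pairs; feasible for short sequences
sw_oracle_enum <- function(a, b, mat, open = 10, ext = 2) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  gapcost <- function(g) if (g == 0) 0 else open + (g - 1) * ext
  best <- 0
  for (k in seq_len(min(n, m))) {
    ia <- utils::combn(n, k)
    ib <- utils::combn(m, k)
    for (p in seq_len(ncol(ia))) for (q in seq_len(ncol(ib))) {
      ii <- ia[, p]; jj <- ib[, q]
      sc <- sum(mat[cbind(ca[ii], cb[jj])])
      if (k > 1) {
        sc <- sc - sum(vapply(diff(ii) - 1L, gapcost, 0)) -
          sum(vapply(diff(jj) - 1L, gapcost, 0))
      }
      best <- max(best, sc)
    }
  }
  best
}

# ---- enumerable HMM fixture -------------------------------------------

# two match states over an effective {A, C} alphabet, no inserts, no
# flanking self-loops; every probability mass is hand-assigned so the
# model's total sequence probability can be enumerated exactly
tiny_enumerable_hmm <- function() {
  em <- matrix(0, 2, 20, dimnames = list(NULL, AA20))
  em[1, c("A", "C")] <- c(0.7, 0.3)
  em[2, c("A", "C")] <- c(0.2, 0.8)
  structure(list(cluster_id = "fixture", length = 2L,
                 match_emissions = em,
                 insert_emissions = sspfam:::AA_BACKGROUND,
                 transitions = list(MM = c(0.5, 0), MI = c(0, 0),
                                    MD = c(0.2, 0), ME = c(0.3, 1),
                                    IM = c(1, 1), II = c(0, 0),
                                    DM = c(1, 0), DD = c(0, 0)),
                 entry = c(0.5, 0.5),
                 background = sspfam:::AA_BACKGROUND,
                 flank_loop = 0, calibration = NULL),
            class = "ssp_hmm")
}

# cluster models straight from grouped segment sets (scaled-down
# calibration for test speed)
models_from_groups <- function(groups, segments, seed = 1L) {
  cfg <- ssp_config()
  cfg$phmm$calib_n <- 150L
  cfg$phmm$calib_len <- 80L
  cl <- structure(list(clusters = groups, singletons = character(),
                       n_iter = 0L, max_colsum_dev = 0),
                  class = "ssp_clustering")
  build_cluster_models(cl, segments, cfg, seed)
}

# ---- cached heavy computations ----------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, expr, envir = .fixture_cache)
  .fixture_cache[[key]]
}

seed42_dataset <- function() {
  cached("seed42_ds", generate_dataset(synthetic_spec(seed = 42L)))
}

seed42_result <- function() {
  cached("seed42_res", ssp_pipeline(seed42_dataset()$proteins, seed = 42L))
}
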