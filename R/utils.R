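# Shared constants and small helpers.

# 20 canonical residues; X (unknown) is carried as a 21st symbol that scores
# 0 against everything in substitution matrices and emits background in HMMs.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AAX <- c(AA20, "X")

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2, X = 0
)

# Robinson-Robinson amino-acid background frequencies (HMMER2 default null).
AA_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

aa_encode <- function(seq) {
  # returns 1-based indices into AAX; errors on anything else
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, AAX)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("unknown residue '%s' at position %d", chars[bad], bad),
         call. = FALSE)
  }
  idx
}

aa_sample <- function(n, freqs = AA_BACKGROUND) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# Deterministic derivation of stream-specific sub-seeds from a master seed,
# kept within the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revstring <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), "")
}
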