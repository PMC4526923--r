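# Signal-peptide detection. A transparent von-Heijne-style heuristic stands
# in for neural-network predictors: a hydrophobic h-region, a non-acidic
# n-region, and a (-3,-1) small-residue cleavage site. Externally computed
# prediction tables (e.g. from a dedicated predictor) can be imported and
# override the heuristic.

SMALL_CLEAVAGE <- c("A", "G", "S", "C", "T")

#' Heuristic signal-peptide prediction
#'
#' A protein is called signal-positive when all three hold:
#' \enumerate{
#'   \item an h-region exists: some window of `window` residues within the
#'     first 40 has mean Kyte-Doolittle hydropathy >= `min_hydropathy`;
#'   \item the n-region (residues before the h-region) has net charge >= 0
#'     (K/R = +1, D/E = -1);
#'   \item a cleavage site exists after the h-region: some mature-start
#'     position within `cleavage_range` has small residues (A, G, S, C, T)
#'     at the -1 and -3 positions of the signal.
#' }
#' `cleavage_pos` is the 1-based index of the last signal residue at the
#' first qualifying site; `score` is `min(1, h-window mean hydropathy / 4)`.
#' Proteins shorter than 15 residues are signal-negative with score 0.
#'
#' @param proteins An `ssp_proteins` data frame.
#' @param window h-region window length (residues; default 8).
#' @param min_hydropathy Mean Kyte-Doolittle threshold for the h-window.
#'   The default 2.2 keeps the false-positive rate on background-composition
#'   proteins below 10% while retaining every designed h-region (the
#'   threshold is a tunable, not a literature constant).
#' @param cleavage_range Two integers: the range of mature-start positions
#'   searched for the cleavage site (default `c(15, 45)`).
#' @return Data frame of class `ssp_signal` with columns `protein_id`,
#'   `has_signal`, `cleavage_pos` (0 when negative), `score`, `source`.
#' @export
predict_signal <- function(proteins, window = 8L, min_hydropathy = 2.2,
                           cleavage_range = c(15L, 45L)) {
  res <- lapply(seq_len(nrow(proteins)), function(i) {
    p <- predict_signal_one(proteins$sequence[i], window, min_hydropathy,
                            cleavage_range)
    data.frame(protein_id = proteins$id[i], has_signal = p$has_signal,
               cleavage_pos = p$cleavage_pos, score = p$score,
               source = "heuristic", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("ssp_signal", "data.frame")
  out
}

predict_signal_one <- function(seq, window, min_hydropathy, cleavage_range) {
  neg <- list(has_signal = FALSE, cleavage_pos = 0L, score = 0)
  n <- nchar(seq)
  if (n < 15L) return(neg)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  kd <- unname(KD_SCALE[chars])
  kd[is.na(kd)] <- 0

  # (i) h-region: first qualifying window starting within the first 40 aa
  lastStart <- min(40L, n) - window + 1L
  if (lastStart < 1L) return(neg)
  csum <- cumsum(c(0, kd))
  means <- (csum[(window + 1L):(lastStart + window)] -
              csum[1:lastStart]) / window
  h_start <- which(means >= min_hydropathy)[1L]
  if (is.na(h_start)) return(neg)
  h_end <- h_start + window - 1L

  # (ii) n-region net charge
  pre <- if (h_start > 1L) chars[1:(h_start - 1L)] else character()
  charge <- sum(pre %in% c("K", "R")) - sum(pre %in% c("D", "E"))
  if (charge < 0) return(neg)

  # (iii) (-3,-1) rule at the first qualifying mature-start q after the
  # h-region; the signal then spans 1..(q-1)
  q_lo <- max(cleavage_range[1L], h_end + 2L)
  q_hi <- min(cleavage_range[2L], n)
  cleave <- 0L
  if (q_lo <= q_hi) {
    for (q in q_lo:q_hi) {
      if (chars[q - 1L] %in% SMALL_CLEAVAGE &&
          chars[q - 3L] %in% SMALL_CLEAVAGE) { cleave <- q - 1L; break }
    }
  }
  if (cleave == 0L) return(neg)
  list(has_signal = TRUE, cleavage_pos = cleave,
       score = min(1, means[h_start] / 4))
}

#' Import external signal-peptide predictions
#'
#' Reads a TSV with columns `id`, `has_signal` (Y/N), `cleavage_pos`,
#' `score`. Imported rows are marked `source = "external"` and override
#' heuristic calls for the same protein when combined with
#' [combine_signal_predictions()]. IDs absent from a proteome are kept
#' (screened proteomes may be supersets).
#'
#' @param path Path to the TSV file (with header).
#' @return An `ssp_signal` data frame with `source = "external"`.
#' @export
import_signal_predictions <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "has_signal", "cleavage_pos", "score")
  if (!all(need %in% names(raw)))
    stop("prediction table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  ok_flag <- raw$has_signal %in% c("Y", "N")
  if (!all(ok_flag))
    stop("malformed row at line ", which(!ok_flag)[1L] + 1L,
         ": has_signal must be Y or N", call. = FALSE)
  pos <- suppressWarnings(as.integer(raw$cleavage_pos))
  sc <- suppressWarnings(as.numeric(raw$score))
  bad <- is.na(pos) | is.na(sc) | sc < 0 | sc > 1
  if (any(bad))
    stop("malformed row at line ", which(bad)[1L] + 1L,
         ": cleavage_pos must be integer and score in [0,1]", call. = FALSE)
  out <- data.frame(protein_id = as.character(raw$id),
                    has_signal = raw$has_signal == "Y",
                    cleavage_pos = pos, score = sc,
                    source = "external", stringsAsFactors = FALSE)
  class(out) <- c("ssp_signal", "data.frame")
  out
}

#' Merge heuristic and external predictions
#'
#' External rows override heuristic rows with the same `protein_id`.
#'
#' @param heuristic,external `ssp_signal` data frames.
#' @return Combined `ssp_signal` data frame.
#' @export
combine_signal_predictions <- function(heuristic, external) {
  keep <- !(heuristic$protein_id %in% external$protein_id)
  out <- rbind(heuristic[keep, , drop = FALSE], external)
  rownames(out) <- NULL
  class(out) <- c("ssp_signal", "data.frame")
  out
}
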