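# Seeded generator of synthetic preproprotein datasets with planted motif
# families, so every pipeline stage can be exercised with known ground
# truth. Records mimic the canonical small-secretory-peptide architecture:
# an N-terminal signal peptide (charged n-region, hydrophobic h-region,
# small residues at the -1/-3 cleavage positions), a variable middle
# region of background composition, and a conserved C-terminal motif that
# ends at or within a few residues of the C-terminus.

#' Specification of a synthetic planted-family dataset
#'
#' @param n_families Number of planted families.
#' @param members_per_family Members per family.
#' @param motif_length Planted motif length (8-20 residues).
#' @param motif_divergence Per-residue substitution probability applied to
#'   each member's motif copy (substitutions resample uniformly over the
#'   20 residues, so they silently preserve the ancestor with probability
#'   1/20).
#' @param n_decoys Decoy records: same precursor architecture, no planted
#'   motif.
#' @param mature_length_mean,mature_length_sd Normal distribution of the
#'   mature-region length (linker + motif + tail), truncated so the motif
#'   fits.
#' @param include_signal Prepend a signal peptide built to satisfy the
#'   detection heuristic (default `TRUE`).
#' @param species Species tag written on every record.
#' @param seed Integer seed; generation is fully reproducible.
#' @return List of class `ssp_synth_spec`.
#' @export
synthetic_spec <- function(n_families = 5L, members_per_family = 8L,
                           motif_length = 14L, motif_divergence = 0.10,
                           n_decoys = 40L, mature_length_mean = 70,
                           mature_length_sd = 15, include_signal = TRUE,
                           species = "synthetica", seed = 42L) {
  stopifnot(motif_length >= 8, motif_length <= 20,
            motif_divergence >= 0, motif_divergence <= 1,
            n_families >= 0, members_per_family >= 1, n_decoys >= 0,
            mature_length_mean > 0, mature_length_sd >= 0)
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 motif_length = as.integer(motif_length),
                 motif_divergence = motif_divergence,
                 n_decoys = as.integer(n_decoys),
                 mature_length_mean = mature_length_mean,
                 mature_length_sd = mature_length_sd,
                 include_signal = isTRUE(include_signal),
                 species = species, seed = as.integer(seed)),
            class = "ssp_synth_spec")
}

# a signal peptide that satisfies the detection heuristic: M + basic
# n-region, 9-11 strongly hydrophobic residues, then small residues ending
# at the cleavage site (the -1/-3 rule holds because the whole c-region is
# drawn from the small-residue set)
random_signal_peptide <- function() {
  n_extra <- sample(1:3, 1)
  nreg <- paste0("M", paste(sample(c("K", "R", "S", "N"), n_extra,
                                   replace = TRUE), collapse = ""))
  h_len <- sample(9:11, 1)
  hreg <- paste(sample(c("L", "I", "V", "F"), h_len, replace = TRUE),
                collapse = "")
  c_len <- max(3L, 14L - nchar(nreg) - h_len)   # signal >= 14 residues
  creg <- paste(sample(c("A", "G", "S", "T"), c_len, replace = TRUE),
                collapse = "")
  paste0(nreg, hreg, creg)
}

# maximum fraction of identical positions between two motifs over all
# ungapped alignment registers with an overlap of at least 7 residues
motif_max_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(ca); nb <- length(cb)
  best <- 0
  for (off in (-(nb - 7)):(na - 7)) {
    ia <- max(1, 1 + off):min(na, nb + off)
    ib <- ia - off
    best <- max(best, mean(ca[ia] == cb[ib]))
  }
  best
}

# draw ancestor motifs uniformly, rejecting draws that resemble an earlier
# ancestor (> 25% identity in any register): planted families are distinct
# by definition, so the ground-truth labels must not hide chance relatives
draw_ancestors <- function(n, len, max_identity = 0.25) {
  motifs <- character(0)
  for (i in seq_len(n)) {
    repeat {
      cand <- paste(sample(AA20, len, replace = TRUE), collapse = "")
      if (!length(motifs) ||
          max(vapply(motifs, motif_max_identity, 0, b = cand)) <=
            max_identity) break
    }
    motifs <- c(motifs, cand)
  }
  motifs
}

mutate_motif <- function(motif, divergence) {
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < divergence
  chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

# replace the given positions with residues guaranteed to differ
branch_motif <- function(motif, positions) {
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  for (p in positions)
    chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  paste(chars, collapse = "")
}

synth_record <- function(motif, divergence, spec) {
  mlen <- if (is.null(motif)) 0L else nchar(motif)
  mature_len <- max(mlen + 6L,
                    round(rnorm(1, spec$mature_length_mean,
                                spec$mature_length_sd)))
  tail_len <- sample(0:5, 1)
  linker_len <- max(0L, mature_len - mlen - tail_len)
  motif_copy <- if (is.null(motif)) "" else mutate_motif(motif, divergence)
  mature <- paste0(aa_sample(linker_len), motif_copy, aa_sample(tail_len))
  sig <- if (spec$include_signal) random_signal_peptide() else ""
  paste0(sig, mature)
}

#' Generate a synthetic proteome with planted families
#'
#' Per family, an ancestor motif is drawn uniformly over the 20 residues;
#' each member carries an independently mutated copy placed so it ends at
#' or within 5 residues of the C-terminus. Decoys share the precursor
#' architecture but have no planted motif. Fully reproducible from the
#' spec's seed.
#'
#' @param spec An [synthetic_spec()].
#' @return List with `proteins` (`ssp_proteins`), `truth` (data frame
#'   `id`, `family` — `"decoy"` for decoys — and `species`), and `motifs`
#'   (the ancestor motif per family).
#' @export
generate_dataset <- function(spec) {
  withr_seed(spec$seed, {
    motifs <- draw_ancestors(spec$n_families, spec$motif_length)
    ids <- character(); seqs <- character(); fams <- character()
    for (f in seq_len(spec$n_families)) {
      for (m in seq_len(spec$members_per_family)) {
        ids <- c(ids, sprintf("F%d_m%02d", f, m))
        seqs <- c(seqs, synth_record(motifs[f], spec$motif_divergence,
                                     spec))
        fams <- c(fams, paste0("family", f))
      }
    }
    for (d in seq_len(spec$n_decoys)) {
      ids <- c(ids, sprintf("D_%03d", d))
      seqs <- c(seqs, synth_record(NULL, 0, spec))
      fams <- c(fams, "decoy")
    }
    if (any(nchar(seqs) >= 200))
      stop("spec produced sequences of 200 aa or more; reduce ",
           "mature_length_mean/sd", call. = FALSE)
    proteins <- ssp_proteins(ids, spec$species, seqs)
    truth <- data.frame(id = ids, family = fams, species = spec$species,
                        stringsAsFactors = FALSE)
    list(proteins = proteins, truth = truth,
         motifs = stats::setNames(motifs,
                                  paste0("family",
                                         seq_len(spec$n_families))))
  })
}

#' Truth labels as a named vector for partition metrics
#'
#' Decoys get unique labels (they are unrelated to one another), so a
#' perfect prediction leaves every decoy in its own group.
#'
#' @param truth Truth table from [generate_dataset()].
#' @return Named character vector id -> label.
#' @export
truth_labels <- function(truth) {
  lab <- truth$family
  dec <- lab == "decoy"
  lab[dec] <- paste0("decoy:", truth$id[dec])
  stats::setNames(lab, truth$id)
}

#' Two-subfamily scenario (split families)
#'
#' Two planted families with independent, unrelated ancestor motifs at low
#' within-family divergence. The pipeline should report two families —
#' related peptides with genuinely distinct consensus motifs stay apart.
#'
#' @param seed Integer seed.
#' @param members_per_family,motif_length,n_decoys Dataset shape.
#' @return As [generate_dataset()].
#' @export
generate_split_scenario <- function(seed = 7L, members_per_family = 8L,
                                    motif_length = 14L, n_decoys = 10L) {
  spec <- synthetic_spec(n_families = 2L,
                         members_per_family = members_per_family,
                         motif_length = motif_length,
                         motif_divergence = 0.05, n_decoys = n_decoys,
                         seed = seed)
  generate_dataset(spec)
}

#' Single-motif two-cluster scenario (unified family)
#'
#' One ancestor motif diverges into two sub-lineages: each branch replaces
#' an exact, disjoint 20% of the motif positions with new residues, so the
#' two sub-ancestors differ at exactly 40% of positions by construction
#' (the divergence is part of the scenario's definition, not a random
#' realisation). Members are tight within each lineage (divergence 0.04).
#' Sequence-level clustering tends to split the lineages, but their
#' profiles remain similar, so profile-level aggregation should reunite
#' them into one family.
#'
#' @param seed Integer seed.
#' @param members_per_group,motif_length,n_decoys Dataset shape.
#' @return As [generate_dataset()] with truth labelling both groups as the
#'   same family.
#' @export
generate_unified_scenario <- function(seed = 11L, members_per_group = 8L,
                                      motif_length = 16L, n_decoys = 10L) {
  base <- synthetic_spec(n_families = 0L, members_per_family = 1L,
                         motif_length = motif_length,
                         motif_divergence = 0.04, n_decoys = n_decoys,
                         seed = seed)
  withr_seed(seed, {
    ancestor <- paste(sample(AA20, motif_length, replace = TRUE),
                      collapse = "")
    n_branch <- max(1L, round(0.2 * motif_length))
    pos <- sample.int(motif_length, 2L * n_branch)
    sub1 <- branch_motif(ancestor, pos[seq_len(n_branch)])
    sub2 <- branch_motif(ancestor, pos[n_branch + seq_len(n_branch)])
    ids <- character(); seqs <- character(); fams <- character()
    for (g in 1:2) {
      anc <- if (g == 1) sub1 else sub2
      for (m in seq_len(members_per_group)) {
        ids <- c(ids, sprintf("G%d_m%02d", g, m))
        seqs <- c(seqs, synth_record(anc, 0.04, base))
        fams <- c(fams, "family1")
      }
    }
    for (d in seq_len(n_decoys)) {
      ids <- c(ids, sprintf("D_%03d", d))
      seqs <- c(seqs, synth_record(NULL, 0, base))
      fams <- c(fams, "decoy")
    }
    proteins <- ssp_proteins(ids, "synthetica", seqs)
    truth <- data.frame(id = ids, family = fams, species = "synthetica",
                        stringsAsFactors = FALSE)
    list(proteins = proteins, truth = truth,
         motifs = c(ancestor = ancestor, sub1 = sub1, sub2 = sub2))
  })
}
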