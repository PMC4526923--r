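# Pipeline configuration: a nested list of every exposed threshold, with a
# YAML reader that deep-merges user overrides onto the defaults.

#' Default pipeline configuration
#'
#' All thresholds of the discovery pipeline in one nested list. Values with
#' a literature anchor: `seqio$max_len` 200 (strict), `seqio$window` 50,
#' `pairwise$matrix` BLOSUM50, `pairwise$evalue_cutoff` 1e-3,
#' `mcl$inflation` and `pipeline$family_inflation` 1.5,
#' `pipeline$screen_evalue` 0.05. The remaining values are documented
#' package choices.
#'
#' @return Nested configuration list.
#' @export
ssp_config <- function() {
  list(
    seqio = list(max_len = 200L, window = 50L),
    sigpep = list(window = 8L, min_hydropathy = 2.2,
                  cleavage_range = c(15L, 45L)),
    pairwise = list(matrix = "BLOSUM50", gap_open = 10, gap_extend = 2,
                    evalue_cutoff = 1e-3, n_decoys = 500L),
    mcl = list(inflation = 1.5, expansion = 2L, prune_below = 1e-5,
               max_iter = 200L, tol = 1e-8),
    msa = list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
               max_gap_frac = 0.5, min_col_score = 0),
    phmm = list(pseudocount_weight = 1, exit_prob = 0.05,
                calib_n = 1000L, calib_len = 350L,
                pp_gap_open = 5, pp_gap_extend = 1, pp_n_decoys = 200L),
    pipeline = list(recruit_evalue = 0.01, recruit_max_rounds = 20L,
                    family_inflation = 1.5, prc_evalue = 0.05,
                    screen_evalue = 0.05)
  )
}

#' Read a YAML configuration file
#'
#' Keys present in the file override the defaults from [ssp_config()];
#' everything else keeps its default.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return Nested configuration list.
#' @export
read_ssp_config <- function(path = NULL) {
  cfg <- ssp_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_lists(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}
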