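#' Representation similarity of the sensory basis network
#'
#' Relaxes the network on each of the 32 stimuli and correlates the
#' equilibrium rate vectors of the second basis layer pairwise.  In a trained
#' network the basis representation is expected to differentiate the
#' task-relevant dimensions (duration, modulation direction) and to collapse
#' the irrelevant ones: correlations are high for stimulus pairs differing
#' only along task-irrelevant dimensions and low for pairs requiring
#' different responses.
#'
#' @param conn A (typically trained) [connection_set()].
#' @param layout The matching [network_layout()].
#' @param up A [unit_params()].
#' @param suppress `"none"` (default) relaxes with all motor units free;
#'   `"all"` clamps suppression of strength `inhib_weight` on every motor
#'   unit, probing the basis network with the experts gated off.
#' @param inhib_weight Suppression strength used when `suppress = "all"`.
#' @param ... Passed to [relax_network()] (`dt`, `tol`, `max_steps`).
#' @return A list with the `32 x 32` correlation matrix `cor` (rows/columns
#'   in stimulus-id order; `NA` for zero-variance activity vectors) and the
#'   `activity` matrix (stimuli x basis-layer-2 units).
#' @export
basis_similarity <- function(conn, layout, up = unit_params(),
                             suppress = c("none", "all"), inhib_weight = 4,
                             ...) {
  suppress <- match.arg(suppress)
  stims <- stimulus_set()
  supp <- numeric(layout$n_units)
  if (suppress == "all") supp[unlist(layout$motor)] <- inhib_weight
  act <- matrix(NA_real_, nrow(stims), length(layout$basis2))
  for (s in seq_len(nrow(stims))) {
    st <- relax_network(conn, encode_stimulus(stims[s, ]), up,
                        i_inh_ext = supp, ...)
    act[s, ] <- st$r[layout$basis2]
  }
  zero_var <- apply(act, 1, sd) == 0
  if (any(zero_var))
    warning(sum(zero_var), " stimuli produced zero-variance basis activity; ",
            "their correlations are reported as NA")
  cc <- suppressWarnings(cor(t(act)))
  list(cor = cc, activity = act)
}

#' Stimulus-pair classification for similarity analyses
#'
#' Labels every unordered pair of the 32 stimuli by its task relation:
#' `"irrelevant"` if the two stimuli differ only along task-irrelevant
#' dimensions (same category), `"different_action"` if they require different
#' responses under the given contingency (one is the target category, the
#' other is not), `"same_action"` otherwise (different categories, same
#' required response).
#'
#' @param target_category Target category of the contingency (1..4).
#' @return A data frame with columns `i`, `j` (stimulus ids, `i < j`) and
#'   `relation`.
#' @export
stimulus_pair_relations <- function(target_category = 1L) {
  stims <- stimulus_set()
  idx <- which(upper.tri(matrix(0, 32, 32)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  ci <- stims$category[i]; cj <- stims$category[j]
  relation <- ifelse(ci == cj, "irrelevant",
                     ifelse((ci == target_category) != (cj == target_category),
                            "different_action", "same_action"))
  data.frame(i = i, j = j, relation = relation)
}
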