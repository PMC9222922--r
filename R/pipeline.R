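# End-to-end convenience wrapper: discovery -> dating -> stage grouping.

#' Run discovery and dating over a whole clade
#'
#' Screens the focal genome for retrogene/parent pairs, resolves
#' structurally ambiguous pairs with cross-species synteny scores, dates
#' every retained pair onto a phylogenetic stage, and groups the staged
#' events into the young (PS1-PS7) and old (PS8-PS9) movement counts used
#' by the traffic test.
#'
#' @param clade a `sim_clade` from [simulate_clade()], or any list with
#'   elements `annotations` (named list of [annotation_set]s),
#'   `tree` ([staged_tree]) and `ortholog_map`.
#' @param id_cfg an [identification_config].
#' @param syn_cfg a [synteny_config].
#' @return list with `pairs` (staged pair table), `dropped`, and `groups`
#'   (see [group_stages()]).
#' @export
retro_pipeline <- function(clade, id_cfg = identification_config(),
                           syn_cfg = synteny_config()) {
  focal <- clade$tree$focal_species
  ann <- clade$annotations[[focal]]
  others <- clade$annotations[setdiff(names(clade$annotations), focal)]
  cand <- candidate_pairs(ann, id_cfg)
  gids <- unique(c(cand$gene_a, cand$gene_b))
  scores <- if (length(gids))
    synteny_scores_for(gids, ann, others, clade$ortholog_map, syn_cfg)
  else NULL
  res <- identify_retro_pairs(ann, id_cfg, synteny_scores = scores,
                              candidates = cand)
  pairs <- if (nrow(res$pairs))
    date_pairs(res$pairs, ann, others, clade$tree, clade$ortholog_map,
               syn_cfg)
  else cbind(res$pairs, stage = character(0),
             outgroup_checked = logical(0))
  list(pairs = pairs, dropped = res$dropped,
       groups = if (nrow(pairs)) group_stages(pairs) else NULL)
}
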