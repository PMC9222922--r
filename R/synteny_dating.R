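# Synteny-based dating of retroduplication events onto phylogenetic stages.

#' Configuration for synteny conservation checks
#'
#' @param min_conserved_neighbors flanking genes that must be conserved in
#'   order around the locus for synteny support (default 2).
#' @param flank_window genes inspected on each side of the locus.
#' @return list of class `synteny_config`.
#' @export
synteny_config <- function(min_conserved_neighbors = 2L,
                           flank_window = 10L) {
  stopifnot(min_conserved_neighbors >= 1L,
            flank_window >= min_conserved_neighbors)
  structure(list(min_conserved_neighbors = as.integer(min_conserved_neighbors),
                 flank_window = as.integer(flank_window)),
            class = "synteny_config")
}

# focal -> other gene-id lookup from a long-format ortholog map.
# Errors when the map has no rows for the species pair.
.ortholog_lookup <- function(map, from_sp, to_sp) {
  f <- map[map$species_a == from_sp & map$species_b == to_sp,
           c("gene_a", "gene_b")]
  r <- map[map$species_b == from_sp & map$species_a == to_sp,
           c("gene_b", "gene_a")]
  names(r) <- c("gene_a", "gene_b")
  both <- rbind(f, r)
  if (!nrow(both))
    stop("species pair missing from ortholog map: ", from_sp, " / ", to_sp)
  stats::setNames(both$gene_b, both$gene_a)
}

# Flank ids nearest-first on each side of `pos` within `window`.
.flanks <- function(ord, pos, window) {
  left <- ord[rev(seq.int(max(1L, pos - window), pos - 1L))]
  right <- ord[seq.int(pos + 1L, min(length(ord), pos + window))]
  if (pos == 1L) left <- character(0)
  if (pos == length(ord)) right <- character(0)
  list(left = left, right = right)
}

#' Count order-conserved flanking genes around a locus in another species
#'
#' Walks outward from the focal gene and from its ortholog simultaneously
#' and counts how far the flanking genes (mapped through the ortholog
#' table) remain collinear; the two sides are summed. The whole locus may
#' be inverted between species, so both relative orientations are tried
#' and the better one is used; gene strand is ignored. Returns 0 when the
#' gene has no ortholog in the other species.
#'
#' @param focal_gene gene id in the focal annotation.
#' @param focal_ann,other_ann [annotation_set]s.
#' @param lookup named vector focal gene id -> other-species gene id (see
#'   [read_ortholog_map()]).
#' @param cfg a [synteny_config].
#' @return Integer conserved-neighbor count.
#' @export
conserved_neighbor_count <- function(focal_gene, focal_ann, other_ann,
                                     lookup, cfg = synteny_config()) {
  chr <- focal_ann$genes$chromosome[match(focal_gene,
                                          focal_ann$genes$gene_id)]
  if (is.na(chr)) stop("gene not in focal annotation: ", focal_gene)
  ord <- focal_ann$gene_order[[chr]]
  pos <- match(focal_gene, ord)
  g2 <- lookup[focal_gene]
  if (is.na(g2) || !(g2 %in% other_ann$genes$gene_id)) return(0L)
  chr2 <- other_ann$genes$chromosome[match(g2, other_ann$genes$gene_id)]
  ord2 <- other_ann$gene_order[[chr2]]
  pos2 <- match(g2, ord2)
  fl <- .flanks(ord, pos, cfg$flank_window)
  fl2 <- .flanks(ord2, pos2, cfg$flank_window)
  run <- function(focal_side, other_side) {
    k <- 0L
    while (k < length(focal_side) && k < length(other_side)) {
      o <- lookup[focal_side[k + 1L]]
      if (is.na(o) || o != other_side[k + 1L]) break
      k <- k + 1L
    }
    k
  }
  same <- run(fl$left, fl2$left) + run(fl$right, fl2$right)
  flipped <- run(fl$left, fl2$right) + run(fl$right, fl2$left)
  max(same, flipped)
}

#' Is a gene's neighborhood syntenically conserved in another species?
#'
#' TRUE when at least `cfg$min_conserved_neighbors` flanking genes are
#' collinear around the orthologous locus ([conserved_neighbor_count()]).
#'
#' @inheritParams conserved_neighbor_count
#' @export
synteny_conserved <- function(focal_gene, focal_ann, other_ann, lookup,
                              cfg = synteny_config()) {
  conserved_neighbor_count(focal_gene, focal_ann, other_ann, lookup, cfg) >=
    cfg$min_conserved_neighbors
}

#' Cross-species synteny-conservation scores for a set of genes
#'
#' Sum of [conserved_neighbor_count()] over all non-focal species of a
#' clade. Used to resolve parent/retro assignment when exon structure is
#' ambiguous (multiple short introns or tied exon counts).
#'
#' @param gene_ids character vector of focal gene ids.
#' @param focal_ann focal [annotation_set].
#' @param clade named list of non-focal [annotation_set]s.
#' @param ortholog_map data.frame as in [read_ortholog_map()].
#' @param cfg a [synteny_config].
#' @return Named numeric vector of scores.
#' @export
synteny_scores_for <- function(gene_ids, focal_ann, clade, ortholog_map,
                               cfg = synteny_config()) {
  scores <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  for (sp in names(clade)) {
    lookup <- .ortholog_lookup(ortholog_map, focal_ann$species_id, sp)
    for (g in gene_ids)
      scores[g] <- scores[g] +
        conserved_neighbor_count(g, focal_ann, clade[[sp]], lookup, cfg)
  }
  scores
}

#' Date one retroduplication event onto a phylogenetic stage
#'
#' The stage call is the most distant stage (largest PS rank) among species
#' in which the retrogene is present with synteny support; the focal
#' species itself supports PS1, so an event found nowhere else is called
#' PS1. Outgroup species never advance the call; they are only checked for
#' absence, recorded in `outgroup_checked`.
#'
#' @param retro_id retrogene id in the focal annotation.
#' @param focal_ann focal [annotation_set].
#' @param clade named list of non-focal [annotation_set]s (staged species
#'   and outgroups of `tree`).
#' @param tree a [staged_tree].
#' @param ortholog_map data.frame as in [read_ortholog_map()].
#' @param cfg a [synteny_config].
#' @return list of class `stage_call`: `retro_id`, `stage`,
#'   `supporting_species`, `outgroup_checked`.
#' @export
date_pair <- function(retro_id, focal_ann, clade, tree, ortholog_map,
                      cfg = synteny_config()) {
  if (!retro_id %in% focal_ann$genes$gene_id)
    stop("retrogene absent from focal species: ", retro_id)
  supporting <- tree$focal_species
  best <- 1L
  for (sp in names(tree$stages)) {
    if (!sp %in% names(clade)) next
    lookup <- .ortholog_lookup(ortholog_map, focal_ann$species_id, sp)
    present <- !is.na(lookup[retro_id]) &&
      lookup[retro_id] %in% clade[[sp]]$genes$gene_id
    if (!present) next
    if (!synteny_conserved(retro_id, focal_ann, clade[[sp]], lookup, cfg))
      next
    supporting <- c(supporting, sp)
    best <- max(best, stage_rank(tree, tree$stages[[sp]]))
  }
  out_ok <- TRUE
  for (og in tree$outgroups) {
    if (!og %in% names(clade)) next
    lookup <- .ortholog_lookup(ortholog_map, focal_ann$species_id, og)
    if (!is.na(lookup[retro_id]) &&
        lookup[retro_id] %in% clade[[og]]$genes$gene_id &&
        synteny_conserved(retro_id, focal_ann, clade[[og]], lookup, cfg))
      out_ok <- FALSE
  }
  structure(list(retro_id = retro_id,
                 stage = tree$stage_levels[best],
                 supporting_species = supporting,
                 outgroup_checked = out_ok),
            class = "stage_call")
}

#' Date every discovered pair
#'
#' @param pairs `pairs` data.frame from [identify_retro_pairs()].
#' @inheritParams date_pair
#' @return The input data.frame with `stage` and `outgroup_checked`
#'   columns appended.
#' @export
date_pairs <- function(pairs, focal_ann, clade, tree, ortholog_map,
                       cfg = synteny_config()) {
  calls <- lapply(pairs$retro_id, date_pair, focal_ann = focal_ann,
                  clade = clade, tree = tree, ortholog_map = ortholog_map,
                  cfg = cfg)
  pairs$stage <- vapply(calls, `[[`, "", "stage")
  pairs$outgroup_checked <- vapply(calls, `[[`, NA, "outgroup_checked")
  pairs
}

#' Group staged events into age classes and count movement directions
#'
#' Young events are those at stages PS1-PS7 (lineages with differentiated
#' sex chromosomes); old events are PS8-PS9. The young group is further
#' split into PS1-PS4 and PS5-PS7.
#'
#' @param staged data.frame with columns `direction`
#'   (`"X->A"`/`"A->A"`/`"A->X"`) and `stage` (`"PS1"`..`"PS9"`).
#' @return list with [movement_counts()] elements `young`, `old`, and
#'   `young_finer` (itself a list `PS1_4`, `PS5_7`).
#' @export
group_stages <- function(staged) {
  rank <- as.integer(sub("^PS", "", staged$stage))
  count <- function(sel) {
    d <- staged$direction[sel]
    movement_counts(n_XA = sum(d == "X->A"), n_AA = sum(d == "A->A"),
                    n_AX = sum(d == "A->X"))
  }
  list(young = count(rank >= 1L & rank <= 7L),
       old = count(rank >= 8L & rank <= 9L),
       young_finer = list(PS1_4 = count(rank <= 4L),
                          PS5_7 = count(rank >= 5L & rank <= 7L)))
}
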