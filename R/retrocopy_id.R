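# Discovery of retrogene/parental pairs by local protein alignment and
# intron-loss (exon-junction) evidence.

.pkg_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

#' Configuration for retrogene/parent pair identification
#'
#' Defaults implement the discovery filters: protein identity > 30%,
#' reciprocal alignment coverage > 70% of each protein, exon-junction
#' support extending at least 30 bp (10 aa) on both sides of the junction,
#' parental "short intron" ambiguity flag at 50 bp, and the requirement
#' that parent and retrogene lie on different chromosomes.
#'
#' @param min_identity minimum protein identity over aligned columns
#'   (exclusive threshold).
#' @param min_reciprocal_coverage minimum aligned fraction of each
#'   protein's full length (exclusive threshold).
#' @param junction_flank_bp required aligned flank on each side of an exon
#'   junction, in bp of CDS (must be a multiple of 3).
#' @param short_intron_bp parental genes whose longest intron is below this
#'   are flagged ambiguous and parent/retro assignment falls back on
#'   cross-species synteny conservation.
#' @param require_interchromosomal drop pairs whose two genes share a
#'   chromosome (chromosome arms sharing an `arm_group` count as one
#'   chromosome).
#' @param prescreen use a shared k-mer seed screen before alignment
#'   (a BLAST-like heuristic; exact alignment is run on every seeded pair).
#' @param seed_k,min_seed_kmers k-mer length and minimum number of shared
#'   k-mers for the seed screen.
#' @return A list of class `identification_config`.
#' @export
identification_config <- function(min_identity = 0.30,
                                  min_reciprocal_coverage = 0.70,
                                  junction_flank_bp = 30L,
                                  short_intron_bp = 50L,
                                  require_interchromosomal = TRUE,
                                  prescreen = TRUE,
                                  seed_k = 4L, min_seed_kmers = 3L) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_reciprocal_coverage > 0, min_reciprocal_coverage <= 1,
            junction_flank_bp %% 3L == 0L, junction_flank_bp > 0L)
  structure(list(min_identity = min_identity,
                 min_reciprocal_coverage = min_reciprocal_coverage,
                 junction_flank_bp = as.integer(junction_flank_bp),
                 short_intron_bp = as.integer(short_intron_bp),
                 require_interchromosomal = require_interchromosomal,
                 prescreen = prescreen, seed_k = as.integer(seed_k),
                 min_seed_kmers = as.integer(min_seed_kmers)),
            class = "identification_config")
}

#' Locally align two proteins and summarize the evidence
#'
#' Smith-Waterman-style local alignment (BLOSUM62, affine gaps: open 11,
#' extend 1; a gap of length L costs 11 + L). Identity is computed over
#' aligned columns (gaps included in the denominator); coverage of each
#' protein is the number of its residues inside the aligned region divided
#' by its full length.
#'
#' @param a,b protein sequences (character scalars).
#' @return A list of class `pair_evidence` with elements `identity`,
#'   `coverage_a`, `coverage_b`, `score`, `aligned_region` (per-gene 1-based
#'   aa intervals) and the gapped alignment strings in `aln`.
#' @export
align_protein_pair <- function(a, b) {
  if (!is.character(a) || !is.character(b) || !nzchar(a) || !nzchar(b))
    stop("empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1)
  p <- Biostrings::pattern(pa); s <- Biostrings::subject(pa)
  structure(list(
    gene_a = NA_character_, gene_b = NA_character_,
    identity = Biostrings::nmatch(pa) / Biostrings::nchar(pa),
    coverage_a = (Biostrings::end(p) - Biostrings::start(p) + 1L) / nchar(a),
    coverage_b = (Biostrings::end(s) - Biostrings::start(s) + 1L) / nchar(b),
    score = Biostrings::score(pa),
    aligned_region = list(a = c(Biostrings::start(p), Biostrings::end(p)),
                          b = c(Biostrings::start(s), Biostrings::end(s))),
    aln = list(a = as.character(p), b = as.character(s))),
    class = "pair_evidence")
}

# Seed screen: pairs of proteins sharing >= min_shared distinct k-mers.
# K-mers occurring in more than `max_bucket` proteins are skipped (crude
# low-complexity masking). Returns a 2-column matrix of indices (i < j).
.seed_pairs <- function(prots, k, min_shared, max_bucket = 50L) {
  n <- length(prots)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  kmers <- lapply(prots, function(p) {
    np <- nchar(p)
    if (np < k) return(character(0))
    unique(substring(p, 1:(np - k + 1L), k:np))
  })
  idx <- rep(seq_len(n), lengths(kmers))
  buckets <- split(idx, unlist(kmers, use.names = FALSE))
  keys <- unlist(lapply(buckets, function(g) {
    if (length(g) < 2L || length(g) > max_bucket) return(integer(0))
    cmb <- utils::combn(sort(g), 2L)
    cmb[1L, ] * (n + 1L) + cmb[2L, ]
  }), use.names = FALSE)
  if (!length(keys)) return(matrix(integer(0), ncol = 2))
  tab <- table(keys)
  hits <- as.integer(names(tab)[tab >= min_shared])
  cbind(hits %/% (n + 1L), hits %% (n + 1L))
}

#' Screen a genome for paralogous gene pairs
#'
#' All unordered gene pairs whose local protein alignment passes the
#' identity and reciprocal-coverage filters. With `cfg$prescreen` a shared
#' k-mer seed heuristic limits which pairs are aligned, in the same spirit
#' as BLAST seeding; every seeded pair is still scored by the exact local
#' alignment. Self pairs are excluded and output order is canonical
#' (`gene_a < gene_b`, sorted), independent of input gene order.
#'
#' @param ann an [annotation_set].
#' @param cfg an [identification_config].
#' @return data.frame with columns `gene_a`, `gene_b`, `identity`,
#'   `coverage_a`, `coverage_b`, `score`.
#' @export
candidate_pairs <- function(ann, cfg = identification_config()) {
  prots <- ann$protein
  ids <- names(prots)
  n <- length(prots)
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0), coverage_a = numeric(0),
                      coverage_b = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  # order-independent canonical indexing
  ord <- order(ids)
  prots <- prots[ord]; ids <- ids[ord]
  if (cfg$prescreen) {
    cand <- .seed_pairs(prots, cfg$seed_k, cfg$min_seed_kmers)
  } else {
    cand <- t(utils::combn(n, 2L))
  }
  if (!nrow(cand)) return(empty)
  # reciprocal coverage bounds the length ratio; 0.9 slack for gaps
  len <- nchar(prots)
  ratio <- pmin(len[cand[, 1L]], len[cand[, 2L]]) /
    pmax(len[cand[, 1L]], len[cand[, 2L]])
  cand <- cand[ratio > cfg$min_reciprocal_coverage * 0.9, , drop = FALSE]
  out <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    ev <- align_protein_pair(prots[[i]], prots[[j]])
    if (ev$identity > cfg$min_identity &&
        ev$coverage_a > cfg$min_reciprocal_coverage &&
        ev$coverage_b > cfg$min_reciprocal_coverage) {
      out[[r]] <- data.frame(gene_a = ids[i], gene_b = ids[j],
                             identity = ev$identity,
                             coverage_a = ev$coverage_a,
                             coverage_b = ev$coverage_b,
                             score = ev$score, stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$gene_a, res$gene_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# 1-based residue index containing the CDS junction after `cum_bp` coding
# bases; junctions on a codon boundary are assigned to the preceding residue.
.junction_residues <- function(g) {
  lens <- g$exons[, "end"] - g$exons[, "start"]
  cum <- cumsum(lens)
  cum <- cum[-length(cum)]
  as.integer(ceiling(cum / 3))
}

#' Count parent exon junctions supported by the retrogene alignment
#'
#' A parent junction is supported when its residue maps inside the aligned
#' region, the alignment has at least `junction_flank_bp/3` gapless aligned
#' residue pairs on both sides of it, and the retrogene does not itself
#' carry an intron at the mapped position. A pair qualifies as a
#' retroduplication when at least one junction is supported.
#'
#' @param parent,retro [gene_model]s; the parent must be multi-exon.
#' @param ev optional [align_protein_pair()] result for
#'   (parent protein, retro protein); recomputed when `NULL`.
#' @param cfg an [identification_config].
#' @return Integer count of supported junctions.
#' @export
junction_support <- function(parent, retro, ev = NULL,
                             cfg = identification_config()) {
  if (n_exons(parent) < 2L)
    stop("gene ", parent$gene_id,
         ": single-exon gene cannot show intron-loss evidence as a parent")
  if (is.null(ev)) ev <- align_protein_pair(parent$protein, retro$protein)
  flank_aa <- cfg$junction_flank_bp %/% 3L
  pch <- strsplit(ev$aln$a, "")[[1L]]
  sch <- strsplit(ev$aln$b, "")[[1L]]
  pidx <- cumsum(pch != "-") + ev$aligned_region$a[1L] - 1L
  pidx[pch == "-"] <- NA_integer_
  sidx <- cumsum(sch != "-") + ev$aligned_region$b[1L] - 1L
  sidx[sch == "-"] <- NA_integer_
  both <- pch != "-" & sch != "-"
  retro_junc <- if (n_exons(retro) >= 2L) .junction_residues(retro)
                else integer(0)
  supported <- 0L
  for (r in .junction_residues(parent)) {
    c0 <- which(!is.na(pidx) & pidx == r)
    if (!length(c0) || !both[c0]) next
    if (sum(both[seq_len(length(both)) < c0]) < flank_aa) next
    if (sum(both[seq_len(length(both)) > c0]) < flank_aa) next
    if (sidx[c0] %in% retro_junc) next
    supported <- supported + 1L
  }
  supported
}

#' Decide which gene of a pair is the parent
#'
#' The gene with more introns is the parent. When the putative parent's
#' longest intron is shorter than `cfg$short_intron_bp` (multiple short
#' introns can mimic a retrogene's structure), or when exon counts tie, the
#' decision falls back on cross-species synteny conservation: the gene with
#' the strictly greater conserved-neighbor score is the parent. Pairs that
#' remain unresolved are dropped with a recorded reason.
#'
#' @param a,b [gene_model]s.
#' @param synteny_scores optional named numeric vector (by gene id) of
#'   cross-species conserved-neighbor scores, e.g. from
#'   [synteny_scores_for()].
#' @param cfg an [identification_config].
#' @return list with `parent_id`, `retro_id`, `dropped` (logical), `reason`.
#' @export
assign_parent_retro <- function(a, b, synteny_scores = NULL,
                                cfg = identification_config()) {
  drop <- function(reason) list(parent_id = NA_character_,
                                retro_id = NA_character_,
                                dropped = TRUE, reason = reason)
  ok <- function(p, r) list(parent_id = p$gene_id, retro_id = r$gene_id,
                            dropped = FALSE, reason = NA_character_)
  by_synteny <- function() {
    if (is.null(synteny_scores) ||
        !all(c(a$gene_id, b$gene_id) %in% names(synteny_scores)))
      return(drop("ambiguous_structure_no_synteny_scores"))
    sa <- synteny_scores[[a$gene_id]]; sb <- synteny_scores[[b$gene_id]]
    if (sa > sb) return(ok(a, b))
    if (sb > sa) return(ok(b, a))
    drop("synteny_tie")
  }
  na <- n_exons(a); nb <- n_exons(b)
  if (na == nb) return(by_synteny())
  p <- if (na > nb) a else b
  r <- if (na > nb) b else a
  if (longest_intron(p) >= cfg$short_intron_bp) return(ok(p, r))
  # short-intron parent: require synteny to concur
  res <- by_synteny()
  if (res$dropped) return(res)
  res
}

#' Classify the movement direction of a retroduplication
#'
#' Directions follow the source -> target chromosome class of the event:
#' `"X->A"`, `"A->A"` (between distinct autosomes) or `"A->X"`. Chromosome
#' arms sharing an `arm_group` (2R/2L -> "2") are one chromosome, so
#' same-arm-group pairs are intrachromosomal and return `NA` when
#' `require_interchromosomal` is set.
#'
#' @param parent_chromosome,retro_chromosome chromosome names.
#' @param chromosomes chromosome table of an [annotation_set].
#' @param require_interchromosomal see [identification_config()].
#' @return `"X->A"`, `"A->A"`, `"A->X"`, or `NA_character_` for excluded
#'   intrachromosomal pairs.
#' @export
classify_direction <- function(parent_chromosome, retro_chromosome,
                               chromosomes,
                               require_interchromosomal = TRUE) {
  look <- function(chr) {
    i <- match(chr, chromosomes$name)
    if (is.na(i)) stop("unclassified chromosome: ", chr)
    chromosomes[i, ]
  }
  p <- look(parent_chromosome); r <- look(retro_chromosome)
  if (p$arm_group == r$arm_group) {
    if (require_interchromosomal) return(NA_character_)
    return("A->A")
  }
  if (p$sex_class == "X_like" && r$sex_class == "autosome") return("X->A")
  if (p$sex_class == "autosome" && r$sex_class == "X_like") return("A->X")
  "A->A"
}

#' Run the full retrogene/parent discovery on one genome
#'
#' Chains the alignment screen, parent assignment, junction-support filter
#' and direction classification, then applies a one-parent policy: a
#' retrogene matched by several candidate parents keeps the
#' highest-identity pair (ties broken by the longer parent protein).
#'
#' @param ann an [annotation_set] of the focal species.
#' @param cfg an [identification_config].
#' @param synteny_scores optional named conserved-neighbor scores used to
#'   resolve structurally ambiguous pairs (see [assign_parent_retro()]).
#' @param candidates optional precomputed [candidate_pairs()] table
#'   (avoids re-running the alignment screen).
#' @return list with `pairs` (data.frame: parent_id, retro_id, chromosomes,
#'   direction, identity, coverages, junctions_supported) and `dropped`
#'   (data.frame of rejected candidate pairs with reasons).
#' @export
identify_retro_pairs <- function(ann, cfg = identification_config(),
                                 synteny_scores = NULL,
                                 candidates = NULL) {
  cand <- if (is.null(candidates)) candidate_pairs(ann, cfg) else candidates
  rows <- list(); dropped <- list()
  note <- function(a, b, reason)
    data.frame(gene_a = a, gene_b = b, reason = reason,
               stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cand))) {
    ga <- get_gene(ann, cand$gene_a[r]); gb <- get_gene(ann, cand$gene_b[r])
    asg <- assign_parent_retro(ga, gb, synteny_scores, cfg)
    if (asg$dropped) {
      dropped[[length(dropped) + 1L]] <-
        note(ga$gene_id, gb$gene_id, asg$reason)
      next
    }
    parent <- if (asg$parent_id == ga$gene_id) ga else gb
    retro <- if (asg$parent_id == ga$gene_id) gb else ga
    if (n_exons(parent) < 2L) {
      dropped[[length(dropped) + 1L]] <-
        note(ga$gene_id, gb$gene_id, "parent_single_exon")
      next
    }
    if (n_exons(parent) <= n_exons(retro)) {
      dropped[[length(dropped) + 1L]] <-
        note(ga$gene_id, gb$gene_id, "retro_not_intron_reduced")
      next
    }
    ev <- align_protein_pair(parent$protein, retro$protein)
    js <- junction_support(parent, retro, ev, cfg)
    if (js < 1L) {
      dropped[[length(dropped) + 1L]] <-
        note(ga$gene_id, gb$gene_id, "no_supported_junction")
      next
    }
    dir <- classify_direction(parent$chromosome, retro$chromosome,
                              ann$chromosomes,
                              cfg$require_interchromosomal)
    if (is.na(dir)) {
      dropped[[length(dropped) + 1L]] <-
        note(ga$gene_id, gb$gene_id, "intrachromosomal")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      parent_id = parent$gene_id, retro_id = retro$gene_id,
      parent_chromosome = parent$chromosome,
      retro_chromosome = retro$chromosome, direction = dir,
      identity = ev$identity, coverage_parent = ev$coverage_a,
      coverage_retro = ev$coverage_b, junctions_supported = js,
      parent_protein_len = nchar(parent$protein),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_id = character(0), retro_id = character(0),
               parent_chromosome = character(0),
               retro_chromosome = character(0), direction = character(0),
               identity = numeric(0), coverage_parent = numeric(0),
               coverage_retro = numeric(0), junctions_supported = integer(0),
               parent_protein_len = integer(0), stringsAsFactors = FALSE)
  # one-parent policy
  if (nrow(pairs) > 1L) {
    pairs <- pairs[order(pairs$retro_id, -pairs$identity,
                         -pairs$parent_protein_len, pairs$parent_id), ,
                   drop = FALSE]
    pairs <- pairs[!duplicated(pairs$retro_id), , drop = FALSE]
  }
  pairs$parent_protein_len <- NULL
  pairs <- pairs[order(pairs$parent_id, pairs$retro_id), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(gene_a = character(0), gene_b = character(0),
                    reason = character(0), stringsAsFactors = FALSE))
}

#' Write a discovered pair table as TSV
#' @param pairs the `pairs` data.frame from [identify_retro_pairs()].
#' @param path output path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
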