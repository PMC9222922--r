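#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based half-open intervals. GFF3 on disk is
# 1-based inclusive; read_annotation()/write_annotation() are the only places
# where conversion happens.

#' Construct a single gene model
#'
#' A gene model carries one gene's location, its exon structure in
#' transcription order, and the protein/CDS of its representative
#' (longest-protein) isoform. Exons are 0-based half-open intervals; for
#' minus-strand genes they are stored in transcription order, i.e. reversed
#' genomic order, so that "first exon" always means the 5' exon of the mRNA.
#'
#' @param gene_id,species_id,chromosome character scalars.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start`, `end` (0-based
#'   half-open), one row per exon, rows in transcription order.
#' @param protein,cds character scalars (amino-acid and nucleotide sequence).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species_id, chromosome, strand, exons,
                       protein, cds) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"),
            is.matrix(exons), ncol(exons) == 2L, nrow(exons) >= 1L)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("gene ", gene_id, ": empty or inverted exon interval")
  g <- sort(exons[, "start"])
  e <- sort(exons[, "end"])
  if (nrow(exons) > 1L && any(e[-nrow(exons)] > g[-1L]))
    stop("gene ", gene_id, ": overlapping exons")
  if (3L * nchar(protein) > nchar(cds))
    stop("gene ", gene_id, ": protein longer than CDS allows")
  structure(list(gene_id = gene_id, species_id = species_id,
                 chromosome = chromosome, strand = strand,
                 span = c(start = min(exons[, "start"]),
                          end = max(exons[, "end"])),
                 exons = exons, protein = protein, cds = cds),
            class = "gene_model")
}

#' Length of the longest intron of a gene
#'
#' Introns are the gaps between consecutive exons in genomic coordinate
#' order. Single-exon genes have no introns and return 0. Short "longest
#' introns" (< 50 bp by default elsewhere) flag possible mis-assignment of
#' the parental/derived relationship during pair discovery.
#'
#' @param g a [gene_model].
#' @return Longest intron length in bp (0 for single-exon genes).
#' @export
longest_intron <- function(g) {
  stopifnot(inherits(g, "gene_model"))
  ex <- g$exons[order(g$exons[, "start"]), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2L) return(0L)
  max(ex[-1L, "start"] - ex[-n, "end"])
}

#' Intron lengths of a gene, genomic order
#' @param g a [gene_model].
#' @return Integer vector of length `exon count - 1` (possibly empty).
#' @export
intron_lengths <- function(g) {
  ex <- g$exons[order(g$exons[, "start"]), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2L) return(integer(0))
  ex[-1L, "start"] - ex[-n, "end"]
}

#' Number of exons
#' @param g a [gene_model].
#' @export
n_exons <- function(g) nrow(g$exons)

#' Assemble an annotation set
#'
#' The container all discovery and dating operations consume: a per-species
#' gene table, exon structures, sequences, chromosome metadata, and the gene
#' order along each chromosome.
#'
#' @param species_id character scalar.
#' @param genes data.frame with columns `gene_id`, `chromosome`, `strand`,
#'   `start`, `end`, `n_exons`, `placed` (logical: on a classified
#'   chromosome, hence eligible for traffic statistics).
#' @param exons named list (by `gene_id`) of exon matrices in transcription
#'   order, 0-based half-open.
#' @param protein named character vector of protein sequences (by gene_id).
#' @param cds named character vector of CDS sequences (by gene_id).
#' @param chromosomes data.frame with columns `name`, `sex_class`
#'   (`"X_like"`/`"autosome"`), `length`, `arm_group`. Chromosome arms that
#'   share an `arm_group` (e.g. 2R/2L -> "2") are treated as one chromosome
#'   by the direction classifier.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(species_id, genes, exons, protein, cds,
                           chromosomes) {
  stopifnot(is.data.frame(genes), is.list(exons),
            all(c("gene_id", "chromosome", "strand", "start", "end",
                  "n_exons", "placed") %in% names(genes)),
            all(c("name", "sex_class", "length", "arm_group") %in%
                  names(chromosomes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene ids in annotation set")
  if (!all(genes$gene_id %in% names(exons)))
    stop("missing exon structures for some genes")
  if (!all(chromosomes$sex_class %in% c("X_like", "autosome")))
    stop("sex_class must be 'X_like' or 'autosome'")
  ord <- order(genes$chromosome, genes$start)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  gene_order <- split(genes$gene_id, genes$chromosome)
  ann <- structure(list(species_id = species_id, genes = genes,
                        exons = exons, protein = protein, cds = cds,
                        chromosomes = chromosomes, gene_order = gene_order),
                   class = "annotation_set")
  ann
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", x$species_id, "-", nrow(x$genes), "genes on",
      nrow(x$chromosomes), "classified chromosomes\n")
  invisible(x)
}

#' Extract one gene as a gene_model
#' @param ann an [annotation_set].
#' @param gene_id gene identifier.
#' @export
get_gene <- function(ann, gene_id) {
  i <- match(gene_id, ann$genes$gene_id)
  if (is.na(i)) stop("gene not found: ", gene_id)
  row <- ann$genes[i, ]
  gene_model(gene_id = row$gene_id, species_id = ann$species_id,
             chromosome = row$chromosome, strand = row$strand,
             exons = ann$exons[[gene_id]],
             protein = unname(ann$protein[gene_id]),
             cds = unname(ann$cds[gene_id]))
}

#' Validate annotation-set invariants
#'
#' Checks exon ordering/overlap, sequence-length consistency and that the
#' stored gene order matches coordinate-sorted order. Used heavily by the
#' test suite on simulator output.
#'
#' @param ann an [annotation_set].
#' @return `TRUE` invisibly; stops on the first violation.
#' @export
validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  for (gid in ann$genes$gene_id) {
    g <- get_gene(ann, gid)           # constructor re-checks invariants
    if (nchar(g$cds) %% 3L != 0L)
      stop("gene ", gid, ": CDS length not a multiple of 3")
    if (sum(g$exons[, "end"] - g$exons[, "start"]) < nchar(g$cds))
      stop("gene ", gid, ": CDS longer than summed exon length")
  }
  for (chr in names(ann$gene_order)) {
    ids <- ann$gene_order[[chr]]
    st <- ann$genes$start[match(ids, ann$genes$gene_id)]
    if (is.unsorted(st))
      stop("gene order on ", chr, " not sorted by start")
  }
  invisible(TRUE)
}

#' Build a stage-labeled species tree
#'
#' Phylogenetic stages PS1..PS9 label consecutive branch intervals on the
#' focal species' root path, PS1 being the most recent. Every non-focal,
#' non-outgroup species carries the stage of the branch at which its lineage
#' joins the focal root path; the focal species itself sits at PS1.
#' Outgroup species carry no stage and are used only to confirm absence of a
#' retrogene beyond the oldest called stage.
#'
#' @param focal_species species id of the focal genome.
#' @param stages named character vector: species id -> stage label
#'   (`"PS1"`..`"PS9"`). Must not include the focal species or outgroups.
#' @param outgroups character vector of outgroup species ids.
#' @param n_stages number of stages in the layout (default 9).
#' @return An object of class `staged_tree`.
#' @export
staged_tree <- function(focal_species, stages, outgroups = character(0),
                        n_stages = 9L) {
  lv <- paste0("PS", seq_len(n_stages))
  stopifnot(all(stages %in% lv), !is.null(names(stages)),
            !focal_species %in% names(stages),
            !any(outgroups %in% names(stages)))
  structure(list(focal_species = focal_species,
                 stages = stages, outgroups = outgroups,
                 stage_levels = lv),
            class = "staged_tree")
}

#' Integer rank of a stage label within a tree's layout
#' @param tree a [staged_tree].
#' @param stage stage label(s).
#' @export
stage_rank <- function(tree, stage) match(stage, tree$stage_levels)

#' All species ids of a staged tree (focal first, then staged, then outgroups)
#' @param tree a [staged_tree].
#' @export
tree_species <- function(tree)
  c(tree$focal_species, names(tree$stages), tree$outgroups)
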