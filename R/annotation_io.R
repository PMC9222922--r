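# GFF3 + FASTA readers/writers. GFF3 is 1-based inclusive on disk; the
# in-memory model is 0-based half-open. These two functions are the only
# coordinate conversion points in the package.

#' Read an annotated genome into an annotation_set
#'
#' Expects a GFF3 with `gene`, `mRNA`, `exon` and `CDS` features and two
#' FASTA files (protein, CDS) whose sequence names are mRNA ids. For
#' multi-isoform genes the representative isoform is the one with the
#' longest protein, ties broken by lexicographic mRNA id. Genes whose
#' chromosome is absent from the chromosome table are kept (they remain
#' available to the alignment screen) but flagged `placed = FALSE` and are
#' excluded from chromosome-level traffic statistics.
#'
#' @param gff3_path path to a GFF3 file.
#' @param protein_fasta,cds_fasta paths to FASTA files keyed by mRNA id.
#' @param chrom_tsv path to a tab-separated chromosome table with columns
#'   `name`, `sex_class`, `length`, `arm_group`.
#' @param species_id species identifier to stamp on the result (defaults to
#'   the GFF3 file name without extension).
#' @return An [annotation_set].
#' @export
read_annotation <- function(gff3_path, protein_fasta, cds_fasta, chrom_tsv,
                            species_id = NULL) {
  if (is.null(species_id))
    species_id <- sub("\\.gff3?$", "", basename(gff3_path))
  gff <- as.data.frame(rtracklayer::readGFF(gff3_path))
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  chromosomes <- utils::read.delim(chrom_tsv, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "sex_class", "length", "arm_group") %in%
                  names(chromosomes)))

  prot <- Biostrings::readAAStringSet(protein_fasta)
  cds <- Biostrings::readDNAStringSet(cds_fasta)
  names(prot) <- sub("\\s.*", "", names(prot))
  names(cds) <- sub("\\s.*", "", names(cds))

  mrna <- gff[gff$type == "mRNA", ]
  missing_prot <- setdiff(mrna$ID, names(prot))
  if (length(missing_prot))
    stop("mRNA id(s) not found in protein FASTA: ",
         paste(utils::head(missing_prot, 5), collapse = ", "))
  missing_cds <- setdiff(mrna$ID, names(cds))
  if (length(missing_cds))
    stop("mRNA id(s) not found in CDS FASTA: ",
         paste(utils::head(missing_cds, 5), collapse = ", "))

  # longest-protein isoform per gene; ties -> lexicographic mRNA id
  plen <- Biostrings::width(prot)[match(mrna$ID, names(prot))]
  mrna <- mrna[order(mrna$Parent, -plen, mrna$ID), ]
  rep_mrna <- mrna[!duplicated(mrna$Parent), ]

  ex_feat <- gff[gff$type == "exon", ]
  genes_df <- list(); exons <- list()
  protein_v <- character(0); cds_v <- character(0)
  for (k in seq_len(nrow(rep_mrna))) {
    m <- rep_mrna[k, ]
    gid <- m$Parent
    ex <- ex_feat[ex_feat$Parent == m$ID, , drop = FALSE]
    if (!nrow(ex)) stop("mRNA without exons: ", m$ID)
    ex <- ex[order(ex$start), ]
    emat <- cbind(start = ex$start - 1L, end = ex$end)  # to 0-based half-open
    if (m$strand == "-") emat <- emat[rev(seq_len(nrow(emat))), , drop = FALSE]
    storage.mode(emat) <- "integer"
    p <- as.character(prot[[m$ID]])
    cc <- as.character(cds[[m$ID]])
    ok <- nchar(cc) %% 3L == 0L &&
      nchar(cc) %in% (3L * nchar(p) + c(0L, 3L))
    if (!ok) {
      warning("gene ", gid, ": CDS/protein length mismatch; excluded")
      next
    }
    genes_df[[gid]] <- data.frame(
      gene_id = gid, chromosome = as.character(m$seqid),
      strand = as.character(m$strand),
      start = m$start - 1L, end = as.integer(m$end),
      n_exons = nrow(emat),
      placed = as.character(m$seqid) %in% chromosomes$name,
      stringsAsFactors = FALSE)
    exons[[gid]] <- emat
    protein_v[gid] <- p
    cds_v[gid] <- cc
  }
  annotation_set(species_id, do.call(rbind, unname(genes_df)),
                 exons, protein_v, cds_v, chromosomes)
}

#' Write an annotation_set to GFF3 + FASTA + chromosome TSV
#'
#' Inverse of [read_annotation()]; writing then reading reproduces gene
#' order, exon intervals and sequences exactly. One mRNA (`<gene>-RA`) is
#' written per gene since the model keeps only the representative isoform.
#'
#' @param ann an [annotation_set].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (defaults to the species id).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_annotation <- function(ann, dir, prefix = ann$species_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff_path <- file.path(dir, paste0(prefix, ".gff3"))
  prot_path <- file.path(dir, paste0(prefix, ".protein.faa"))
  cds_path <- file.path(dir, paste0(prefix, ".cds.fna"))
  chrom_path <- file.path(dir, paste0(prefix, ".chromosomes.tsv"))

  lines <- "##gff-version 3"
  for (i in seq_len(nrow(ann$genes))) {
    row <- ann$genes[i, ]
    gid <- row$gene_id
    mid <- paste0(gid, "-RA")
    emat <- ann$exons[[gid]]
    eg <- emat[order(emat[, "start"]), , drop = FALSE]  # genomic order on disk
    g1 <- function(type, s, e, phase, attr)
      paste(row$chromosome, "retrotraffic", type, s + 1L, e, ".",
            row$strand, phase, attr, sep = "\t")
    lines <- c(lines,
      g1("gene", row$start, row$end, ".", paste0("ID=", gid)),
      g1("mRNA", row$start, row$end, ".", paste0("ID=", mid, ";Parent=", gid)))
    for (j in seq_len(nrow(eg))) {
      lines <- c(lines,
        g1("exon", eg[j, "start"], eg[j, "end"], ".",
           paste0("ID=", mid, "-E", j, ";Parent=", mid)),
        g1("CDS", eg[j, "start"], eg[j, "end"], "0",
           paste0("ID=", mid, "-C", j, ";Parent=", mid)))
    }
  }
  writeLines(lines, gff_path)

  mids <- paste0(ann$genes$gene_id, "-RA")
  p <- Biostrings::AAStringSet(unname(ann$protein[ann$genes$gene_id]))
  names(p) <- mids
  Biostrings::writeXStringSet(p, prot_path)
  cc <- Biostrings::DNAStringSet(unname(ann$cds[ann$genes$gene_id]))
  names(cc) <- mids
  Biostrings::writeXStringSet(cc, cds_path)
  utils::write.table(ann$chromosomes, chrom_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(gff3 = gff_path, protein = prot_path, cds = cds_path,
              chromosomes = chrom_path))
}

#' Write a staged tree as Newick + stage table
#'
#' The Newick file records the ladderized topology (each stage's species
#' attach successively closer to the focal tip); the stage TSV
#' (`species_id`, `stage`) is the authoritative branch labeling, with
#' outgroups marked `stage = "outgroup"`.
#'
#' @param tree a [staged_tree].
#' @param newick_path,stage_tsv output paths.
#' @export
write_staged_tree <- function(tree, newick_path, stage_tsv) {
  ranks <- stage_rank(tree, tree$stages)
  nwk <- tree$focal_species
  for (r in sort(unique(ranks))) {
    sp <- names(tree$stages)[ranks == r]
    inner <- if (length(sp) > 1L)
      paste0("(", paste(sp, collapse = ","), ")") else sp
    nwk <- paste0("(", nwk, ",", inner, ")")
  }
  for (og in tree$outgroups) nwk <- paste0("(", nwk, ",", og, ")")
  writeLines(paste0(nwk, ";"), newick_path)
  df <- data.frame(
    species_id = c(tree$focal_species, names(tree$stages), tree$outgroups),
    stage = c("PS1", unname(tree$stages),
              rep("outgroup", length(tree$outgroups))),
    role = c("focal", rep("staged", length(tree$stages)),
             rep("outgroup", length(tree$outgroups))),
    stringsAsFactors = FALSE)
  utils::write.table(df, stage_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(newick = newick_path, stages = stage_tsv))
}

#' Read a staged tree from Newick + stage table
#'
#' @param newick_path Newick file whose tips are species ids.
#' @param stage_tsv stage table written by [write_staged_tree()].
#' @return A [staged_tree].
#' @export
read_staged_tree <- function(newick_path, stage_tsv) {
  phy <- ape::read.tree(newick_path)
  df <- utils::read.delim(stage_tsv, stringsAsFactors = FALSE)
  stopifnot(all(df$species_id %in% phy$tip.label))
  focal <- df$species_id[df$role == "focal"]
  staged <- df[df$role == "staged", ]
  stages <- stats::setNames(staged$stage, staged$species_id)
  staged_tree(focal, stages, outgroups = df$species_id[df$role == "outgroup"])
}

#' Read/write an ortholog map
#'
#' Cross-species gene correspondences as a four-column TSV
#' (`species_a`, `gene_a`, `species_b`, `gene_b`). The dating module
#' requires a map anchored on the focal species; for real data this is an
#' externally computed (e.g. reciprocal-best-hit) table, for synthetic data
#' the simulator emits it.
#'
#' @param path TSV path.
#' @return data.frame with the four columns above.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species_a", "gene_a", "species_b", "gene_b") %in%
                  names(df)))
  df
}

#' @rdname read_ortholog_map
#' @param map data.frame with columns `species_a`, `gene_a`, `species_b`,
#'   `gene_b`.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
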