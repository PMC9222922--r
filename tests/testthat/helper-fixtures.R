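# In-code fixtures shared across test files.

# Mosquito-style chromosome table with split arms (used by direction tests).
armed_chromosomes <- function() {
  data.frame(name = c("X", "2R", "2L", "3R", "3L"),
             sex_class = c("X_like", rep("autosome", 4)),
             length = c(24e6, 60e6, 49e6, 53e6, 42e6),
             arm_group = c("X", "2", "2", "3", "3"),
             stringsAsFactors = FALSE)
}

# Whole-chromosome table matching the simulator's layout.
plain_chromosomes <- function() {
  data.frame(name = c("X", "2", "3"), sex_class = c("X_like", "autosome",
                                                    "autosome"),
             length = c(24e6, 98e6, 84e6), arm_group = c("X", "2", "3"),
             stringsAsFactors = FALSE)
}

# A minimal single-exon gene model with consistent dummy sequences.
toy_gene <- function(gene_id, chromosome = "2", start = 0L, n_aa = 10L,
                     strand = "+", species = "SPX") {
  cds <- paste(rep("ATG", n_aa), collapse = "")
  gene_model(gene_id, species, chromosome, strand,
             cbind(start = start, end = start + 3L * n_aa),
             protein = paste(rep("M", n_aa), collapse = ""), cds = cds)
}

# Build an annotation set of single-exon dummy genes laid out in the given
# per-chromosome order (named list chromosome -> gene ids). Used by the
# synteny tests, where only presence and order matter.
toy_annotation <- function(species, order_by_chrom,
                           chromosomes = plain_chromosomes()) {
  rows <- list(); exons <- list(); prot <- character(0); cds <- character(0)
  for (chr in names(order_by_chrom)) {
    cur <- 1000L
    for (gid in order_by_chrom[[chr]]) {
      rows[[gid]] <- data.frame(gene_id = gid, chromosome = chr,
                                strand = "+", start = cur,
                                end = cur + 30L, n_exons = 1L,
                                placed = TRUE, stringsAsFactors = FALSE)
      exons[[gid]] <- cbind(start = cur, end = cur + 30L)
      prot[gid] <- "MMMMMMMMMM"
      cds[gid] <- paste(rep("ATG", 10), collapse = "")
      cur <- cur + 5000L
    }
  }
  annotation_set(species, do.call(rbind, unname(rows)), exons, prot, cds,
                 chromosomes)
}

# Identity ortholog lookup for toy annotations that share gene ids up to a
# species prefix ("A_g1" <-> "B_g1").
prefix_lookup <- function(from_ids, from_prefix, to_prefix) {
  stats::setNames(sub(paste0("^", from_prefix), to_prefix, from_ids),
                  from_ids)
}

# A multi-exon gene whose CDS is a specified protein back-translated with
# one fixed codon per amino acid; exon lengths given in bp.
protein_gene <- function(gene_id, protein, exon_lens,
                         intron_lens = rep(200L, max(0, length(exon_lens) - 1)),
                         chromosome = "2", strand = "+", start = 1000L,
                         species = "SPX") {
  codon <- c(A="GCT", R="CGT", N="AAT", D="GAT", C="TGT", Q="CAA", E="GAA",
             G="GGT", H="CAT", I="ATT", L="CTT", K="AAA", M="ATG", F="TTT",
             P="CCT", S="TCT", T="ACT", W="TGG", Y="TAT", V="GTT")
  cds <- paste(codon[strsplit(protein, "")[[1]]], collapse = "")
  stopifnot(sum(exon_lens) == nchar(cds))
  k <- length(exon_lens)
  st <- integer(k); en <- integer(k); cur <- start
  for (i in seq_len(k)) {
    st[i] <- cur; en[i] <- cur + exon_lens[i]
    cur <- en[i] + if (i < k) intron_lens[i] else 0L
  }
  gene_model(gene_id, species, chromosome, strand,
             cbind(start = st, end = en), protein = protein, cds = cds)
}

# Random protein over the full amino-acid alphabet.
random_protein <- function(n_aa) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")
  paste(sample(aa, n_aa, replace = TRUE), collapse = "")
}

# Small simulation scenario for fast module tests.
small_scenario <- function(seed = 7L, ...) {
  sim_scenario(seed = seed, n_background_genes = 60L, ...)
}
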