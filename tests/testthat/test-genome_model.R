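# Gene/annotation data model and GFF3+FASTA round trips.

test_that("longest_intron measures the widest exon gap", {
  g <- toy_gene("g")
  g$exons <- cbind(start = c(0L, 200L), end = c(100L, 300L))
  expect_equal(longest_intron(g), 100L)

  expect_equal(longest_intron(toy_gene("single")), 0L)

  g$exons <- cbind(start = c(0L, 60L, 999L), end = c(50L, 90L, 1100L))
  # brute force over consecutive gaps: 60-50 = 10, 999-90 = 909
  expect_equal(longest_intron(g), 909L)
  expect_equal(intron_lengths(g), c(10L, 909L))
})

test_that("gene_model rejects malformed exon structures", {
  expect_error(gene_model("bad", "S", "2", "+",
                          cbind(start = c(0L, 50L), end = c(60L, 100L)),
                          "M", "ATG"),
               "overlapping")
  expect_error(gene_model("bad", "S", "2", "+",
                          cbind(start = 10L, end = 10L), "M", "ATG"),
               "empty or inverted")
  expect_error(gene_model("bad", "S", "2", "+",
                          cbind(start = 0L, end = 30L),
                          protein = strrep("M", 20), cds = strrep("ATG", 10)),
               "protein longer")
})

write_toy_gff <- function(dir) {
  # g1: 3 exons (90/120/90 bp); g2: two isoforms, 100 aa and 250 aa;
  # g3: two isoforms of equal length (tie -> lexicographic mRNA id)
  lines <- c("##gff-version 3")
  add <- function(chr, type, s, e, id, parent = NULL, strand = "+") {
    attrs <- paste0("ID=", id,
                    if (!is.null(parent)) paste0(";Parent=", parent))
    c(paste(chr, "t", type, s, e, ".", strand,
            if (type == "CDS") "0" else ".", attrs, sep = "\t"))
  }
  lines <- c(lines,
    add("2", "gene", 101, 700, "g1"),
    add("2", "mRNA", 101, 700, "g1-RA", "g1"),
    add("2", "exon", 101, 190, "g1-RA-e1", "g1-RA"),
    add("2", "exon", 291, 410, "g1-RA-e2", "g1-RA"),
    add("2", "exon", 611, 700, "g1-RA-e3", "g1-RA"),
    add("2", "gene", 2001, 2750, "g2"),
    add("2", "mRNA", 2001, 2300, "g2-RA", "g2"),
    add("2", "exon", 2001, 2300, "g2-RA-e1", "g2-RA"),
    add("2", "mRNA", 2001, 2750, "g2-RB", "g2"),
    add("2", "exon", 2001, 2750, "g2-RB-e1", "g2-RB"),
    add("X", "gene", 501, 800, "g3"),
    add("X", "mRNA", 501, 800, "g3-RB", "g3"),
    add("X", "exon", 501, 800, "g3-RB-e1", "g3-RB"),
    add("X", "mRNA", 501, 800, "g3-RA", "g3"),
    add("X", "exon", 501, 800, "g3-RA-e1", "g3-RA"))
  gff <- file.path(dir, "toy.gff3")
  writeLines(lines, gff)
  prots <- c(`g1-RA` = strrep("M", 100), `g2-RA` = strrep("A", 100),
             `g2-RB` = strrep("V", 250), `g3-RA` = strrep("L", 100),
             `g3-RB` = strrep("K", 100))
  cdss <- vapply(nchar(prots), function(n) strrep("ATG", n), "")
  names(cdss) <- names(prots)
  pf <- file.path(dir, "toy.faa"); cf <- file.path(dir, "toy.fna")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prots), pf)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cdss), cf)
  ct <- file.path(dir, "toy.chrom.tsv")
  utils::write.table(plain_chromosomes(), ct, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(gff = gff, prot = pf, cds = cf, chrom = ct)
}

test_that("read_annotation parses structures and picks longest isoform", {
  d <- withr::local_tempdir()
  f <- write_toy_gff(d)
  ann <- read_annotation(f$gff, f$prot, f$cds, f$chrom, species_id = "toy")
  expect_setequal(ann$genes$gene_id, c("g1", "g2", "g3"))
  expect_equal(sort(ann$genes$n_exons), c(1L, 1L, 3L))
  # longest isoform wins; equal lengths fall back to lexicographic id
  expect_equal(nchar(ann$protein[["g2"]]), 250L)
  expect_equal(unname(ann$protein["g3"]), strrep("L", 100))
  # 1-based inclusive GFF -> 0-based half-open internal
  expect_equal(unname(ann$exons[["g1"]][1, ]), c(100L, 190L))
})

test_that("read_annotation errors on unresolvable ids, warns on mismatch", {
  d <- withr::local_tempdir()
  f <- write_toy_gff(d)
  prots <- Biostrings::readAAStringSet(f$prot)
  Biostrings::writeXStringSet(prots[names(prots) != "g1-RA"], f$prot)
  expect_error(read_annotation(f$gff, f$prot, f$cds, f$chrom), "g1-RA")

  f <- write_toy_gff(d)
  cds <- Biostrings::readDNAStringSet(f$cds)
  cds[["g1-RA"]] <- Biostrings::DNAString(strrep("ATG", 120))  # wrong length
  Biostrings::writeXStringSet(cds, f$cds)
  expect_warning(ann <- read_annotation(f$gff, f$prot, f$cds, f$chrom),
                 "mismatch")
  expect_false("g1" %in% ann$genes$gene_id)
})

test_that("genes on unlisted scaffolds are retained but unplaced", {
  d <- withr::local_tempdir()
  f <- write_toy_gff(d)
  chroms <- plain_chromosomes()
  utils::write.table(chroms[chroms$name != "X", ], f$chrom, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- read_annotation(f$gff, f$prot, f$cds, f$chrom)
  expect_true("g3" %in% ann$genes$gene_id)
  expect_false(ann$genes$placed[ann$genes$gene_id == "g3"])
  expect_true(all(ann$genes$placed[ann$genes$gene_id != "g3"]))
})

test_that("write -> read round-trips a simulated annotation exactly", {
  cl <- simulate_clade(small_scenario())
  ann <- cl$annotations[["S00"]]
  d <- withr::local_tempdir()
  paths <- write_annotation(ann, d)
  back <- read_annotation(paths["gff3"], paths["protein"], paths["cds"],
                          paths["chromosomes"], species_id = "S00")
  expect_identical(back$gene_order, ann$gene_order)
  expect_identical(back$genes$gene_id, ann$genes$gene_id)
  expect_identical(back$genes$strand, ann$genes$strand)
  for (gid in ann$genes$gene_id)
    expect_identical(unname(back$exons[[gid]]), unname(ann$exons[[gid]]))
  expect_identical(back$protein[ann$genes$gene_id],
                   ann$protein[ann$genes$gene_id])
  expect_identical(back$cds[ann$genes$gene_id],
                   ann$cds[ann$genes$gene_id])
})

test_that("simulated genes satisfy the intron/exon invariants", {
  cl <- simulate_clade(small_scenario())
  ann <- cl$annotations[["S00"]]
  expect_true(validate_annotation(ann))
  for (gid in ann$genes$gene_id) {
    g <- get_gene(ann, gid)
    il <- intron_lengths(g)
    expect_length(il, n_exons(g) - 1L)
    if (length(il)) expect_true(all(il >= 1L))
    expect_lte(3L * nchar(g$protein), nchar(g$cds))
  }
})

test_that("staged_tree checks stage labels and exposes ranks", {
  tr <- staged_tree("F", c(A = "PS2", B = "PS5"), outgroups = "OG")
  expect_equal(stage_rank(tr, c("PS1", "PS5", "PS9")), c(1L, 5L, 9L))
  expect_setequal(tree_species(tr), c("F", "A", "B", "OG"))
  expect_error(staged_tree("F", c(A = "PS10")))
  expect_error(staged_tree("F", c(F = "PS1")))
})

test_that("staged tree round-trips through Newick + stage table", {
  cl <- simulate_clade(small_scenario())
  d <- withr::local_tempdir()
  write_staged_tree(cl$tree, file.path(d, "t.nwk"), file.path(d, "s.tsv"))
  back <- read_staged_tree(file.path(d, "t.nwk"), file.path(d, "s.tsv"))
  expect_identical(back$focal_species, cl$tree$focal_species)
  expect_identical(back$stages[names(cl$tree$stages)], cl$tree$stages)
  expect_identical(sort(back$outgroups), sort(cl$tree$outgroups))
})
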