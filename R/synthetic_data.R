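# Synthetic test worlds: annotated clades with planted retroduplications of
# known direction and stage (plus decoy duplicates), and replicate
# expression data with known sex-bias effects and spermatogenesis-stage
# trends. Every stage of the pipeline is testable against the generator's
# ground-truth ledger, with no external data.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

#' Default planted-event table
#'
#' Nine true retroduplications, one per phylogenetic stage, cycling over
#' the three movement directions, plus one decoy of each class (a tandem
#' duplicate that keeps its introns, a truncated copy, and a low-identity
#' homolog).
#'
#' @param identity protein identity target of the true plants.
#' @return data.frame with columns `event_id`, `direction`, `stage`,
#'   `identity`, `decoy`.
#' @export
default_planted_events <- function(identity = 0.9) {
  dirs <- rep(c("X->A", "A->A", "A->X"), 3)
  true <- data.frame(
    event_id = sprintf("ev%02d", 1:9), direction = dirs,
    stage = paste0("PS", 1:9), identity = identity, decoy = "none",
    stringsAsFactors = FALSE)
  dec <- data.frame(
    event_id = c("dtandem", "dtrunc", "dlowid"),
    direction = c("A->A", "X->A", "X->A"), stage = "PS1",
    identity = c(0.75, 0.9, 0.25),
    decoy = c("tandem", "truncated", "low_identity"),
    stringsAsFactors = FALSE)
  rbind(true, dec)
}

#' Define a simulation scenario
#'
#' The scenario fixes the clade layout (a focal species, one species per
#' phylogenetic stage PS1..PS9, and outgroups), the chromosome complement
#' (one X-like chromosome and two autosomes), the background gene count,
#' the planted retroduplication events, and the expression parameters
#' (per-group effect sizes on the log2 scale, replicate noise, replicate
#' numbers). A single seed fixes all randomness.
#'
#' @param seed integer seed governing every random draw.
#' @param n_background_genes background (non-retrogene) gene families.
#' @param chrom_names,chrom_sex_class,chrom_lengths chromosome layout;
#'   defaults emulate a mosquito karyotype collapsed to whole chromosomes
#'   (X ~ 24 Mb plus two metacentric autosomes).
#' @param gene_fractions fraction of background genes per chromosome.
#' @param planted_events data.frame as from [default_planted_events()].
#' @param n_stages number of phylogenetic stages (9).
#' @param outgroups number of outgroup species.
#' @param effect_log2 sex-bias effect size (log2 fold change) for truly
#'   biased genes.
#' @param sigma replicate standard deviation on the log2 scale.
#' @param n_reps replicates per sex group.
#' @param n_stage_reps replicates per spermatogenesis stage.
#' @param stage_sigma replicate sd of the stage matrices on the
#'   ln(FPKM+1) scale (0 = noise-free stage profiles).
#' @param aa_len_range protein length range of background genes (aa).
#' @param exon_range exon-count range of background genes.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(seed = 42L,
                         n_background_genes = 300L,
                         chrom_names = c("X", "2", "3"),
                         chrom_sex_class = c("X_like", "autosome",
                                             "autosome"),
                         chrom_lengths = c(24e6, 98e6, 84e6),
                         gene_fractions = c(0.2, 0.45, 0.35),
                         planted_events = default_planted_events(),
                         n_stages = 9L, outgroups = 2L,
                         effect_log2 = 1, sigma = 0.35,
                         n_reps = 4L, n_stage_reps = 2L,
                         stage_sigma = 0,
                         aa_len_range = c(120L, 260L),
                         exon_range = c(2L, 6L)) {
  stopifnot(sum(chrom_sex_class == "X_like") == 1L,
            length(chrom_names) == 3L,
            abs(sum(gene_fractions) - 1) < 1e-9,
            all(planted_events$stage %in% paste0("PS", seq_len(n_stages))))
  low <- planted_events$decoy == "none" & planted_events$identity < 0.3
  if (any(low))
    warning("non-decoy plant(s) below 30% identity are undiscoverable ",
            "by design: ",
            paste(planted_events$event_id[low], collapse = ", "))
  structure(as.list(environment()), class = "sim_scenario")
}

# Random CDS of `n_aa` codons (ATG + sense codons, no stops).
.random_cds <- function(n_aa) {
  paste0("ATG", paste(sample(.sense_codons(), n_aa - 1L, replace = TRUE),
                      collapse = ""))
}

# Mutate a CDS toward a protein identity target. Substitutions are
# codon-level: a fraction (1 - identity) of residues get a codon of a
# different amino acid; a further 10% get a synonymous codon so DNA
# diverges faster than protein.
.mutate_cds <- function(cds, identity) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  gc <- Biostrings::GENETIC_CODE
  by_aa <- .codons_by_aa()
  n <- length(codons)
  n_sub <- round((1 - identity) * n)
  pos_pool <- 2:n
  subs <- if (n_sub > 0) sample(pos_pool, min(n_sub, length(pos_pool)))
          else integer(0)
  for (i in subs) {
    aa <- gc[[codons[i]]]
    other <- setdiff(names(by_aa), aa)
    codons[i] <- sample(unlist(by_aa[sample(other, 1L)]), 1L)
  }
  syn_pool <- setdiff(pos_pool, subs)
  syn <- sample(syn_pool, round(0.1 * length(syn_pool)))
  for (i in syn) {
    alt <- setdiff(by_aa[[gc[[codons[i]]]]], codons[i])
    if (length(alt)) codons[i] <- sample(alt, 1L)
  }
  paste(codons, collapse = "")
}

.translate_cds <- function(cds)
  as.character(Biostrings::translate(Biostrings::DNAString(cds)))

# Split `total` bp into k exon lengths, each >= min_len.
.split_exons <- function(total, k, min_len = 60L) {
  if (k == 1L) return(total)
  slack <- total - k * min_len
  cuts <- sort(sample.int(slack + 1L, k - 1L, replace = TRUE) - 1L)
  lens <- diff(c(0L, cuts, slack)) + min_len
  stopifnot(sum(lens) == total)
  lens
}

# Build the exon matrix (0-based half-open, transcription order) for a gene
# laid out at genomic `start` with transcription-order exon/intron lengths.
.layout_exons <- function(start, exon_lens, intron_lens, strand) {
  k <- length(exon_lens)
  glens <- if (strand == "-") rev(exon_lens) else exon_lens
  gintr <- if (strand == "-") rev(intron_lens) else intron_lens
  st <- integer(k); en <- integer(k)
  cur <- start
  for (i in seq_len(k)) {
    st[i] <- cur; en[i] <- cur + glens[i]
    cur <- en[i] + if (i < k) gintr[i] else 0L
  }
  m <- cbind(start = st, end = en)
  if (strand == "-") m <- m[rev(seq_len(k)), , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Simulate an annotated clade with planted retroduplications
#'
#' Background gene families (2-6 exons, random coding sequence) occupy the
#' same order on every species' chromosomes, so their synteny is perfectly
#' conserved. Each planted event copies its parent's CDS into a single
#' intronless gene, mutated to the prescribed protein identity, inserted at
#' a fixed slot of the prescribed chromosome in the focal species and in
#' every species whose stage is at or below the event's stage; species
#' beyond the stage (and outgroups) lack the retrogene entirely. Decoys are
#' planted per their class: tandem duplicates keep the parent's intron
#' structure next to the parent, truncated copies cover only 60% of the
#' parent, low-identity copies fall below the identity filter.
#'
#' @param s a [sim_scenario()].
#' @return list of class `sim_clade`: `annotations` (named list of
#'   [annotation_set]s, focal first), `tree` ([staged_tree]),
#'   `ortholog_map`, `ledger` (ground truth: `events` data.frame and,
#'   after [simulate_expression()], `expression`), and `scenario`.
#' @export
simulate_clade <- function(s = sim_scenario()) .with_seed(s$seed, {
  chroms <- data.frame(name = s$chrom_names, sex_class = s$chrom_sex_class,
                       length = s$chrom_lengths,
                       arm_group = s$chrom_names, stringsAsFactors = FALSE)
  focal <- "S00"
  staged_sp <- sprintf("S%02d", seq_len(s$n_stages))
  ogs <- if (s$outgroups > 0) sprintf("OG%d", seq_len(s$outgroups))
         else character(0)
  tree <- staged_tree(focal,
                      stats::setNames(paste0("PS", seq_len(s$n_stages)),
                                      staged_sp),
                      outgroups = ogs, n_stages = s$n_stages)

  # --- background families ------------------------------------------------
  n_bg <- s$n_background_genes
  fam_ids <- sprintf("fam%04d", seq_len(n_bg))
  fam_chrom <- rep(s$chrom_names,
                   times = round(s$gene_fractions * n_bg))[seq_len(n_bg)]
  fams <- list()
  for (i in seq_len(n_bg)) {
    n_aa <- sample(seq(s$aa_len_range[1], s$aa_len_range[2]), 1L)
    k <- sample(seq(s$exon_range[1], s$exon_range[2]), 1L)
    cds <- .random_cds(n_aa)
    fams[[fam_ids[i]]] <- list(
      fam = fam_ids[i], chromosome = fam_chrom[i],
      strand = sample(c("+", "-"), 1L, prob = c(0.7, 0.3)),
      exon_lens = .split_exons(3L * n_aa, k),
      intron_lens = if (k > 1L) sample(80:2000, k - 1L, replace = TRUE)
                    else integer(0),
      cds = cds, protein = .translate_cds(cds))
  }
  base_order <- split(fam_ids, fam_chrom)[s$chrom_names]
  names(base_order) <- s$chrom_names

  # --- planted events -----------------------------------------------------
  ev <- s$planted_events
  autosomes <- s$chrom_names[s$chrom_sex_class == "autosome"]
  xchr <- s$chrom_names[s$chrom_sex_class == "X_like"]
  used_parents <- character(0)
  events <- list(); retro_fams <- list()
  for (r in seq_len(nrow(ev))) {
    e <- ev[r, ]
    src <- switch(e$direction,
                  `X->A` = xchr, `A->X` = sample(autosomes, 1L),
                  `A->A` = sample(autosomes, 1L))
    tgt <- switch(e$direction,
                  `X->A` = sample(autosomes, 1L), `A->X` = xchr,
                  `A->A` = setdiff(autosomes, src))
    pool <- setdiff(base_order[[src]], used_parents)
    parent_fam <- sample(pool, 1L)
    used_parents <- c(used_parents, parent_fam)
    pf <- fams[[parent_fam]]
    rid <- paste0("retro_", e$event_id)
    mut <- .mutate_cds(pf$cds, e$identity)
    rf <- if (e$decoy == "tandem") {
      list(fam = rid, chromosome = pf$chromosome, strand = pf$strand,
           exon_lens = pf$exon_lens, intron_lens = pf$intron_lens,
           cds = mut, protein = .translate_cds(mut))
    } else if (e$decoy == "truncated") {
      n_aa <- nchar(pf$protein)
      keep <- 3L * floor(0.6 * n_aa)
      tcds <- substr(mut, 1L, keep)
      list(fam = rid, chromosome = tgt, strand = "+",
           exon_lens = keep, intron_lens = integer(0),
           cds = tcds, protein = .translate_cds(tcds))
    } else {
      list(fam = rid, chromosome = tgt, strand = "+",
           exon_lens = nchar(mut), intron_lens = integer(0),
           cds = mut, protein = .translate_cds(mut))
    }
    # fixed insertion anchor: retro goes right after this background gene
    anchor <- if (e$decoy == "tandem") parent_fam else {
      ord <- base_order[[rf$chromosome]]
      ord[sample(3:(length(ord) - 3L), 1L)]
    }
    present_in <- if (e$decoy == "none") {
      c(focal, staged_sp[seq_len(stage_rank(tree, e$stage))])
    } else focal                         # decoys only confuse the focal scan
    retro_fams[[rid]] <- rf
    events[[r]] <- data.frame(
      event_id = e$event_id, parent_fam = parent_fam, retro_fam = rid,
      direction = e$direction, stage = e$stage, decoy = e$decoy,
      identity_target = e$identity, parent_chromosome = pf$chromosome,
      retro_chromosome = rf$chromosome, anchor_fam = anchor,
      stringsAsFactors = FALSE)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(0), parent_fam = character(0),
               retro_fam = character(0), direction = character(0),
               stage = character(0), decoy = character(0),
               identity_target = numeric(0),
               parent_chromosome = character(0),
               retro_chromosome = character(0),
               anchor_fam = character(0), stringsAsFactors = FALSE)

  # --- per-species assembly ----------------------------------------------
  all_sp <- c(focal, staged_sp, ogs)
  all_fams <- c(fams, retro_fams)
  anns <- list()
  for (sp in all_sp) {
    order_sp <- base_order
    for (r in seq_len(nrow(events))) {
      present <- if (events$decoy[r] == "none") {
        sp == focal || (sp %in% staged_sp &&
          stage_rank(tree, tree$stages[[sp]]) <=
            stage_rank(tree, events$stage[r]))
      } else sp == focal
      if (!present) next
      chr <- events$retro_chromosome[r]
      pos <- match(events$anchor_fam[r], order_sp[[chr]])
      order_sp[[chr]] <- append(order_sp[[chr]], events$retro_fam[r],
                                after = pos)
    }
    rows <- list(); exons <- list()
    prot <- character(0); cds <- character(0)
    for (chr in s$chrom_names) {
      cur <- 1000L
      for (fam in order_sp[[chr]]) {
        f <- all_fams[[fam]]
        gid <- paste0(sp, "_", fam)
        em <- .layout_exons(cur, f$exon_lens, f$intron_lens, f$strand)
        span <- sum(f$exon_lens) + sum(f$intron_lens)
        rows[[gid]] <- data.frame(
          gene_id = gid, chromosome = chr, strand = f$strand,
          start = cur, end = cur + span, n_exons = length(f$exon_lens),
          placed = TRUE, stringsAsFactors = FALSE)
        exons[[gid]] <- em
        prot[gid] <- f$protein
        cds[gid] <- f$cds
        cur <- cur + span + 5000L
      }
    }
    anns[[sp]] <- annotation_set(sp, do.call(rbind, unname(rows)),
                                 exons, prot, cds, chroms)
  }

  # --- focal-anchored ortholog map (shared family = ortholog) -------------
  maps <- list()
  for (sp in setdiff(all_sp, focal)) {
    shared <- intersect(sub("^[^_]+_", "", anns[[focal]]$genes$gene_id),
                        sub("^[^_]+_", "", anns[[sp]]$genes$gene_id))
    maps[[sp]] <- data.frame(
      species_a = focal, gene_a = paste0(focal, "_", shared),
      species_b = sp, gene_b = paste0(sp, "_", shared),
      stringsAsFactors = FALSE)
  }
  ortholog_map <- do.call(rbind, maps)
  rownames(ortholog_map) <- NULL

  events$parent_id <- if (nrow(events))
    paste0(focal, "_", events$parent_fam) else character(0)
  events$retro_id <- if (nrow(events))
    paste0(focal, "_", events$retro_fam) else character(0)
  structure(list(annotations = anns, tree = tree,
                 ortholog_map = ortholog_map,
                 ledger = list(events = events),
                 scenario = s),
            class = "sim_clade")
})

#' Closed-form power of the equal-variance two-sample t test
#'
#' Analytic oracle for the sex-bias caller: the probability that a
#' two-tailed Student's t test at level `alpha` detects a mean difference
#' `delta` with per-group sd `sigma` and `n` replicates per group.
#'
#' @param delta true difference of group means.
#' @param sigma common within-group standard deviation.
#' @param n replicates per group.
#' @param alpha significance level.
#' @return Power in `[0, 1]`.
#' @export
t_test_power <- function(delta, sigma, n, alpha = 0.05) {
  df <- 2 * n - 2
  ncp <- delta / (sigma * sqrt(2 / n))
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Simulate replicate expression data with known truth
#'
#' Generates the three platform datasets for the focal species. Sex-organ
#' data (microarray scale and RNA-seq TPM) get per-gene baselines plus the
#' scenario's log2 effect for truly biased genes and Normal replicate
#' noise on the log scale. The spermatogenesis matrices encode the MSCI
#' motif: X-linked parents of X->A events decline after the premeiotic
#' stage while their autosomal retrogenes rise; all other genes get a
#' gently declining baseline profile. True labels are appended to the
#' clade's ledger.
#'
#' @param clade a `sim_clade` from [simulate_clade()].
#' @return The clade with `expression` (list of three
#'   [expression_matrix()] objects: `microarray`, `rnaseq`, `stages`) and
#'   `ledger$expression` (gene_id, true_bias, true_profile) attached.
#' @export
simulate_expression <- function(clade) .with_seed(clade$scenario$seed + 1L, {
  s <- clade$scenario
  focal <- clade$tree$focal_species
  ann <- clade$annotations[[focal]]
  genes <- ann$genes$gene_id
  ev <- clade$ledger$events
  true_bias <- stats::setNames(rep("unbiased", length(genes)), genes)
  real <- ev[ev$decoy == "none", ]
  true_bias[real$retro_id] <- ifelse(real$direction == "X->A",
                                     "male", "female")
  true_bias[real$parent_id] <- "female"

  n <- s$n_reps
  mk_sex <- function(base_mu, platform, male_lab, female_lab) {
    samples <- c(paste0(male_lab, "_", seq_len(n)),
                 paste0(female_lab, "_", seq_len(n)))
    groups <- stats::setNames(rep(c(male_lab, female_lab), each = n),
                              samples)
    base <- stats::rnorm(length(genes), base_mu, 1)
    mu_m <- base + ifelse(true_bias == "male", s$effect_log2, 0)
    mu_f <- base + ifelse(true_bias == "female", s$effect_log2, 0)
    mus <- cbind(matrix(mu_m, length(genes), n),
                 matrix(mu_f, length(genes), n))
    vals <- mus + matrix(stats::rnorm(length(mus), 0, s$sigma),
                         nrow = length(genes))
    dimnames(vals) <- list(genes, samples)
    if (platform == "rnaseq_TPM") vals <- 2^vals  # lognormal TPM scale
    normalize_expression(vals, platform, groups)
  }
  microarray <- mk_sex(6, "microarray_log2RMA", "testis", "ovary")
  rnaseq <- mk_sex(5, "rnaseq_TPM", "male_repro", "female_repro")

  # spermatogenesis stage profiles on the ln(FPKM+1) scale
  prof <- matrix(rep(c(1.8, 1.6, 1.5, 1.4), each = length(genes)),
                 nrow = length(genes),
                 dimnames = list(genes, .STAGES))
  xa <- real[real$direction == "X->A", ]
  for (g in xa$parent_id) prof[g, ] <- c(3.0, 2.2, 1.5, 1.2)  # MSCI decline
  for (g in xa$retro_id) prof[g, ] <- c(1.0, 1.5, 2.0, 2.5)   # escape/rise
  ns <- s$n_stage_reps
  samples <- paste0(rep(.STAGES, each = ns), "_", seq_len(ns))
  groups <- stats::setNames(rep(.STAGES, each = ns), samples)
  lnvals <- prof[, rep(seq_len(4L), each = ns)] +
    matrix(stats::rnorm(length(genes) * 4L * ns, 0, s$stage_sigma),
           nrow = length(genes))
  lnvals[lnvals < 0] <- 0
  dimnames(lnvals) <- list(genes, samples)
  stages <- normalize_expression(exp(lnvals) - 1, "stage_FPKM", groups)

  true_profile <- stats::setNames(rep("premeiotic_max", length(genes)),
                                  genes)
  true_profile[xa$retro_id] <- "later_stage_max"
  clade$expression <- list(microarray = microarray, rnaseq = rnaseq,
                           stages = stages)
  clade$ledger$expression <- data.frame(
    gene_id = genes, true_bias = unname(true_bias),
    true_profile = unname(true_profile), stringsAsFactors = FALSE)
  clade
})

#' Write a simulated clade to disk in the package's exchange formats
#'
#' One GFF3/protein-FASTA/CDS-FASTA/chromosome-TSV quartet per species,
#' plus the Newick+stage tree, the ortholog map, the ground-truth ledger
#' TSV, and (when present) the expression TSVs with sample sheets.
#'
#' @param clade a `sim_clade`.
#' @param dir output directory.
#' @return The directory path, invisibly.
#' @export
write_clade <- function(clade, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(clade$annotations))
    write_annotation(clade$annotations[[sp]], dir)
  write_staged_tree(clade$tree, file.path(dir, "tree.nwk"),
                    file.path(dir, "stages.tsv"))
  write_ortholog_map(clade$ortholog_map, file.path(dir, "orthologs.tsv"))
  utils::write.table(clade$ledger$events, file.path(dir, "ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(clade$expression)) {
    for (nm in names(clade$expression))
      write_expression(clade$expression[[nm]],
                       file.path(dir, paste0(nm, ".expression.tsv")),
                       file.path(dir, paste0(nm, ".samples.tsv")))
  }
  invisible(dir)
}
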