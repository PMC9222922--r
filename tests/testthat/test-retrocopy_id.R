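# Protein-alignment screen, junction-support filter, parent assignment and
# direction classification.

test_that("self-alignment gives identity 1 and full coverage", {
  set.seed(1)
  p <- random_protein(100)
  ev <- align_protein_pair(p, p)
  expect_equal(ev$identity, 1.0)
  expect_equal(ev$coverage_a, 1.0)
  expect_equal(ev$coverage_b, 1.0)
  expect_error(align_protein_pair("", p), "empty")
})

test_that("a half-length truncation covers ~50% of the full protein", {
  set.seed(2)
  b <- random_protein(200)
  a <- substr(b, 1, 100)                  # a is b's first half
  ev <- align_protein_pair(a, b)
  expect_gt(ev$coverage_a, 0.95)
  expect_lt(abs(ev$coverage_b - 0.5), 0.05)
})

test_that("alignment scores match an exhaustive Gotoh oracle", {
  set.seed(3)
  ab4 <- c("A", "R", "N", "D")            # 4-letter alphabet, short strings
  for (rep in 1:40) {
    na <- sample(5:20, 1); nb <- sample(5:20, 1)
    a <- paste(sample(ab4, na, TRUE), collapse = "")
    b <- if (rep %% 4 == 0) substr(a, 2, min(na, nb)) else
      paste(sample(ab4, nb, TRUE), collapse = "")
    if (!nzchar(b)) next
    ev <- align_protein_pair(a, b)
    expect_equal(ev$score, oracle_sw_score(a, b, blosum62),
                 info = paste(a, b))
  }
})

test_that("random unrelated proteins fail the discovery filters", {
  set.seed(4)
  cfg <- identification_config()
  rejected <- vapply(1:100, function(i) {
    ev <- align_protein_pair(random_protein(100), random_protein(100))
    ev$identity <= cfg$min_identity ||
      ev$coverage_a <= cfg$min_reciprocal_coverage ||
      ev$coverage_b <= cfg$min_reciprocal_coverage
  }, NA)
  expect_true(all(rejected))
})

test_that("candidate screen finds the planted copy and only it", {
  ev1 <- data.frame(event_id = "e1", direction = "X->A", stage = "PS1",
                    identity = 0.95, decoy = "none",
                    stringsAsFactors = FALSE)
  cl <- simulate_clade(sim_scenario(seed = 11, n_background_genes = 50,
                                    planted_events = ev1))
  cand <- candidate_pairs(cl$annotations[["S00"]])
  expect_equal(nrow(cand), 1L)
  truth <- cl$ledger$events
  expect_setequal(c(cand$gene_a, cand$gene_b),
                  c(truth$parent_id, truth$retro_id))
  expect_gt(cand$identity, 0.9)
})

test_that("low-identity and truncated decoys are rejected by the screen", {
  dec <- data.frame(event_id = c("lo", "tr"), direction = "X->A",
                    stage = "PS1", identity = c(0.25, 0.9),
                    decoy = c("low_identity", "truncated"),
                    stringsAsFactors = FALSE)
  cl <- simulate_clade(sim_scenario(seed = 12, n_background_genes = 50,
                                    planted_events = dec))
  cand <- candidate_pairs(cl$annotations[["S00"]])
  expect_equal(nrow(cand), 0L)
})

test_that("junction support counts junctions with intact flanks", {
  set.seed(5)
  p <- random_protein(100)
  parent <- protein_gene("par", p, exon_lens = c(90L, 120L, 90L))
  retro <- protein_gene("ret", p, exon_lens = 300L, chromosome = "3")
  # both junctions (residues 30 and 70) inside a full-length alignment
  expect_equal(junction_support(parent, retro), 2L)

  # junction 5 aa from the protein end: flank too short on one side
  parent2 <- protein_gene("par2", p, exon_lens = c(285L, 15L))
  expect_equal(junction_support(parent2, retro), 0L)

  # retro retains an intron exactly at the first parent junction
  retro2 <- protein_gene("ret2", p, exon_lens = c(90L, 210L),
                         chromosome = "3")
  expect_equal(junction_support(parent, retro2), 1L)

  expect_error(junction_support(retro, parent), "single-exon")
})

test_that("parent assignment follows introns, then synteny", {
  set.seed(6)
  p <- random_protein(120)
  multi <- protein_gene("m", p, exon_lens = c(120L, 150L, 90L))
  single <- protein_gene("s", p, exon_lens = 360L, chromosome = "3")
  asg <- assign_parent_retro(multi, single)
  expect_false(asg$dropped)
  expect_equal(asg$parent_id, "m")

  # short-intron parent: synteny must concur (scores 8 vs 2)
  shorti <- protein_gene("m2", p, exon_lens = c(120L, 150L, 90L),
                         intron_lens = c(40L, 40L))
  two_ex <- protein_gene("s2", p, exon_lens = c(180L, 180L),
                         intron_lens = 400L, chromosome = "3")
  asg <- assign_parent_retro(shorti, two_ex,
                             synteny_scores = c(m2 = 8, s2 = 2))
  expect_false(asg$dropped)
  expect_equal(asg$parent_id, "m2")
  # ... and without scores the pair is dropped, not guessed
  asg <- assign_parent_retro(shorti, two_ex)
  expect_true(asg$dropped)

  # identical exon counts + synteny tie -> dropped with reason
  twin <- protein_gene("t1", p, exon_lens = c(180L, 180L))
  twin2 <- protein_gene("t2", p, exon_lens = c(180L, 180L),
                        chromosome = "3")
  asg <- assign_parent_retro(twin, twin2,
                             synteny_scores = c(t1 = 4, t2 = 4))
  expect_true(asg$dropped)
  expect_equal(asg$reason, "synteny_tie")
})

test_that("direction classification collapses chromosome arms", {
  chroms <- armed_chromosomes()
  expect_equal(classify_direction("X", "2L", chroms), "X->A")
  expect_equal(classify_direction("3L", "X", chroms), "A->X")
  expect_equal(classify_direction("2R", "3L", chroms), "A->A")
  # same arm group = intrachromosomal
  expect_true(is.na(classify_direction("2R", "2L", chroms)))
  expect_equal(classify_direction("2R", "2L", chroms,
                                  require_interchromosomal = FALSE),
               "A->A")
  expect_error(classify_direction("Y", "2L", chroms), "unclassified")
})

test_that("pair discovery is invariant to input gene ordering", {
  ev1 <- data.frame(event_id = "e1", direction = "A->A", stage = "PS1",
                    identity = 0.9, decoy = "none", stringsAsFactors = FALSE)
  cl <- simulate_clade(sim_scenario(seed = 13, n_background_genes = 40,
                                    planted_events = ev1))
  ann <- cl$annotations[["S00"]]
  set.seed(99)
  perm <- sample(nrow(ann$genes))
  shuffled <- annotation_set(ann$species_id, ann$genes[perm, ],
                             ann$exons, ann$protein[perm], ann$cds[perm],
                             ann$chromosomes)
  expect_identical(candidate_pairs(ann), candidate_pairs(shuffled))
  expect_identical(identify_retro_pairs(ann)$pairs,
                   identify_retro_pairs(shuffled)$pairs)
})

test_that("discovery recovers planted pairs with correct parent/direction", {
  cl <- simulate_clade(small_scenario(seed = 21))
  res <- retro_pipeline(cl)
  truth <- cl$ledger$events[cl$ledger$events$decoy == "none", ]
  found <- res$pairs[order(res$pairs$retro_id), ]
  truth <- truth[order(truth$retro_id), ]
  expect_equal(found$retro_id, truth$retro_id)
  expect_equal(found$parent_id, truth$parent_id)
  expect_equal(found$direction, truth$direction)
  expect_true(all(found$junctions_supported >= 1L))
  expect_true(all(found$identity > 0.3))
})
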