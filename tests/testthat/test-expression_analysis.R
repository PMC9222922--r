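# Sex-bias calls, stage profiles, paired Wilcoxon and cross-tabulation.

sex_matrix <- function(vals_m, vals_f, platform = "microarray_log2RMA",
                       genes = paste0("g", seq_len(nrow(vals_m)))) {
  n <- ncol(vals_m)
  v <- cbind(vals_m, vals_f)
  rownames(v) <- genes
  colnames(v) <- c(paste0("t", 1:n), paste0("o", 1:n))
  groups <- stats::setNames(rep(c("testis", "ovary"), each = n),
                            colnames(v))
  expression_matrix(platform, v, groups)
}

test_that("normalization applies the platform transforms", {
  v <- matrix(c(0, exp(1) - 1, 4), 1,
              dimnames = list("g", c("s1", "s2", "s3")))
  gr <- stats::setNames(rep("premeiotic", 3), colnames(v))
  m <- normalize_expression(v, "stage_FPKM", gr)
  expect_equal(unname(m$values[1, ]), c(0, 1, log(5)))

  m2 <- normalize_expression(matrix(5, 1, dimnames = list("g", "s1")),
                             "rnaseq_TPM",
                             c(s1 = "male_repro"))
  expect_equal(unname(m2$values[1, 1]), 5.001)

  m3 <- normalize_expression(matrix(-2.5, 1, dimnames = list("g", "s1")),
                             "microarray_log2RMA", c(s1 = "testis"))
  expect_equal(unname(m3$values[1, 1]), -2.5)  # passthrough

  expect_error(normalize_expression(matrix(-1, 1,
                                           dimnames = list("g", "s1")),
                                    "rnaseq_TPM", c(s1 = "male_repro")),
               "negative")
})

test_that("sex-bias calls follow the t test and the mean direction", {
  m <- sex_matrix(matrix(c(5, 5, 5, 5), 1), matrix(c(5, 5, 5, 5), 1))
  expect_equal(call_sex_bias(m, "g1")$call, "unbiased")

  m <- sex_matrix(matrix(c(8, 8.1, 7.9, 8), 1),
                  matrix(c(5, 5.1, 4.9, 5), 1))
  cb <- call_sex_bias(m, "g1")
  expect_equal(cb$call, "male")
  expect_lt(cb$p_value, 0.05)

  # swapping the group labels flips the call and keeps p
  v <- m$values
  sw <- expression_matrix("microarray_log2RMA", v,
                          stats::setNames(rep(c("ovary", "testis"),
                                              each = 4), colnames(v)))
  cb2 <- call_sex_bias(sw, "g1")
  expect_equal(cb2$call, "female")
  expect_equal(cb2$p_value, cb$p_value)

  expect_equal(call_sex_bias(m, "nope")$call, "no_data")
  one <- expression_matrix("microarray_log2RMA",
                           matrix(c(1, 2, 3), 1,
                                  dimnames = list("g1", c("a", "b", "c"))),
                           c(a = "testis", b = "ovary", c = "ovary"))
  expect_warning(nd <- call_sex_bias(one, "g1"), "replicates")
  expect_equal(nd$call, "no_data")
})

test_that("null simulations give type-I error near alpha", {
  set.seed(20)
  n_genes <- 2000
  m <- sex_matrix(matrix(rnorm(n_genes * 4, 6, 0.4), n_genes),
                  matrix(rnorm(n_genes * 4, 6, 0.4), n_genes))
  calls <- call_sex_bias_all(m)
  rate <- mean(calls$call != "unbiased")
  bound <- 2.576 * sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(rate - 0.05), bound)
})

test_that("empirical power matches the closed-form t-test power", {
  set.seed(21)
  n_genes <- 1000; n <- 4; delta <- 1; sigma <- 0.35
  m <- sex_matrix(matrix(rnorm(n_genes * n, 6 + delta, sigma), n_genes),
                  matrix(rnorm(n_genes * n, 6, sigma), n_genes))
  calls <- call_sex_bias_all(m)
  emp <- mean(calls$call == "male")
  pow <- t_test_power(delta, sigma, n)
  expect_gt(emp, 0.8)
  expect_lt(abs(emp - pow), 2.576 * sqrt(pow * (1 - pow) / n_genes))
})

test_that("stage profiles classify by strict later-stage maximum", {
  expect_equal(classify_stage_profile(c(3, 1, 1, 1)), "premeiotic_max")
  expect_equal(classify_stage_profile(c(1, 1, 1, 2)), "later_stage_max")
  expect_equal(classify_stage_profile(c(2, 2, 2, 2)), "premeiotic_max")
  expect_equal(classify_stage_profile(c(2, NA, 2, 2)), "no_data")
  # invariance under monotone transforms of all four means
  set.seed(22)
  for (i in 1:50) {
    mns <- runif(4, 0, 3)
    cls <- classify_stage_profile(mns)
    expect_equal(classify_stage_profile(exp(mns)), cls)
    expect_equal(classify_stage_profile(2 * mns + 1), cls)
  }
})

test_that("stage_profile averages ln(FPKM+1) within stages", {
  raw <- matrix(c(exp(2) - 1, exp(4) - 1, 0, 0, 0, 0, exp(1) - 1,
                  exp(1) - 1), 1)
  rownames(raw) <- "g1"
  colnames(raw) <- paste0("s", 1:8)
  gr <- stats::setNames(rep(c("premeiotic", "meiosis_I", "meiosis_II",
                              "postmeiotic"), each = 2), colnames(raw))
  m <- normalize_expression(raw, "stage_FPKM", gr)
  expect_equal(unname(stage_profile(m, "g1")), c(3, 0, 0, 1))
})

test_that("paired Wilcoxon matches sign-assignment enumeration", {
  expect_equal(paired_wilcoxon(1:8, 1:8), 1)
  set.seed(23)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    a <- sample(0:6, n, replace = TRUE)       # plenty of ties and zeros
    b <- sample(0:6, n, replace = TRUE)
    if (all(a == b)) next
    for (alt in c("two_sided", "greater", "less")) {
      expect_equal(paired_wilcoxon(a, b, alt),
                   oracle_signrank_p(a, b, alt),
                   tolerance = 1e-12,
                   info = paste(alt, paste(a, collapse = ","),
                                paste(b, collapse = ",")))
    }
  }
  # constant unit shift, n = 10, one-tailed: the single most extreme of
  # the 2^10 sign assignments
  b <- rnorm(10)
  expect_equal(paired_wilcoxon(b + 1, b, "one_tailed"), 1 / 1024)
})

test_that("paired Wilcoxon agrees with wilcox.test where both are exact", {
  set.seed(24)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)          # continuous: no ties
    w <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, exact = TRUE))
    expect_equal(paired_wilcoxon(a, b, "two_sided"), w$p.value,
                 tolerance = 1e-9)
  }
  # large-sample branch: normal approximation with continuity correction
  a <- rnorm(40); b <- rnorm(40)
  w <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                           exact = FALSE, correct = TRUE))
  expect_equal(paired_wilcoxon(a, b, "two_sided"), w$p.value,
               tolerance = 1e-9)
})

paper_bias_df <- function() {
  # published microarray counts: 17 sex-biased young retrogenes (11 male),
  # 7 sex-biased old (1 male); plus the unbiased/no-data remainder
  df <- data.frame(
    gene_id = sprintf("r%02d", 1:37),
    bias = c(rep("male", 11), rep("female", 6), rep("unbiased", 10),
             rep("male", 1), rep("female", 6), rep("unbiased", 3)),
    age_group = c(rep("young", 27), rep("old", 10)),
    stringsAsFactors = FALSE)
  df
}

test_that("crosstab reproduces the young/old male-bias table", {
  rep <- crosstab_report(paper_bias_df())
  expect_equal(unname(rep$bias_by_age$table["young", "male"]), 11)
  expect_equal(rep$bias_by_age$odds_ratio, 11)
  expect_equal(unname(rep$bias_by_age$pct_male_among_biased["young"]),
               100 * 11 / 17, tolerance = 1e-9)
  expect_equal(unname(rep$bias_by_age$pct_male_among_biased["old"]),
               100 * 1 / 7, tolerance = 1e-9)
  expect_equal(unname(round(rep$bias_by_age$ci["low"], 2)), 1.06)
  expect_error(crosstab_report(paper_bias_df()[0, ]), "empty join")
})

test_that("crosstab profile table matches the later-stage/bias split", {
  # 19 young X->A retrogenes: 12 later-stage-max (10 male), 7
  # premeiotic-max (1 male, 6 female/unbiased)
  df <- data.frame(
    gene_id = sprintf("x%02d", 1:19),
    bias = c(rep("male", 10), "female", "unbiased",
             "male", rep("female", 5), "unbiased"),
    age_group = "young", direction = "X->A",
    profile = c(rep("later_stage_max", 12), rep("premeiotic_max", 7)),
    stringsAsFactors = FALSE)
  rep <- crosstab_report(df)
  pr <- rep$profile_by_bias
  expect_equal(unname(pr$table["later_stage_max", "male"]), 10)
  expect_equal(pr$pct_later_stage, 100 * 12 / 19, tolerance = 1e-9)
  expect_equal(pr$pct_male_among_later, 100 * 10 / 12, tolerance = 1e-9)
  expect_equal(pr$odds_ratio, 30)
  expect_lt(pr$fisher_p, 0.05)
})

test_that("expression matrices round-trip through TSV", {
  cl <- simulate_expression(simulate_clade(small_scenario()))
  m <- cl$expression$microarray
  d <- withr::local_tempdir()
  write_expression(m, file.path(d, "e.tsv"), file.path(d, "s.tsv"))
  back <- read_expression(file.path(d, "e.tsv"), file.path(d, "s.tsv"),
                          "microarray_log2RMA", normalized = TRUE)
  expect_equal(back$values, m$values, tolerance = 1e-9)
  expect_identical(back$sample_groups, m$sample_groups)
})
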