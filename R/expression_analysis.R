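# Sex-bias and spermatogenesis-stage expression classification.

.PLATFORMS <- c("microarray_log2RMA", "rnaseq_TPM", "stage_FPKM")
.STAGES <- c("premeiotic", "meiosis_I", "meiosis_II", "postmeiotic")

#' Construct an expression matrix with replicate structure
#'
#' @param platform one of `"microarray_log2RMA"`, `"rnaseq_TPM"`,
#'   `"stage_FPKM"`.
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_groups named character vector mapping every sample id to
#'   its group label (testis/ovary, male_repro/female_repro, or the four
#'   spermatogenesis stages).
#' @return list of class `expression_matrix`.
#' @export
expression_matrix <- function(platform, values, sample_groups) {
  platform <- match.arg(platform, .PLATFORMS)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (!all(colnames(values) %in% names(sample_groups)))
    stop("every sample must have a group label")
  structure(list(platform = platform, values = values,
                 sample_groups = sample_groups[colnames(values)]),
            class = "expression_matrix")
}

#' Normalize raw expression values by platform
#'
#' Microarray values arrive already log2-RMA normalized and pass through;
#' RNA-seq TPM values get the small offset `TPM + 1e-3`; spermatogenesis
#' stage FPKM values are transformed `ln(FPKM + 1)` per sample (stage means
#' are averaged later, on the log scale).
#'
#' @param values raw numeric matrix (genes x samples).
#' @param platform platform tag, see [expression_matrix()].
#' @param sample_groups sample -> group labels.
#' @return An [expression_matrix()] on the platform's working scale.
#' @export
normalize_expression <- function(values, platform, sample_groups) {
  platform <- match.arg(platform, .PLATFORMS)
  if (platform %in% c("rnaseq_TPM", "stage_FPKM") && any(values < 0))
    stop("negative raw expression values for platform ", platform)
  v <- switch(platform,
              microarray_log2RMA = values,
              rnaseq_TPM = values + 1e-3,
              stage_FPKM = log(values + 1))
  expression_matrix(platform, v, sample_groups)
}

# The male/female group labels present in a matrix.
.sex_groups <- function(m) {
  gr <- unique(m$sample_groups)
  if (all(c("testis", "ovary") %in% gr)) c("testis", "ovary")
  else if (all(c("male_repro", "female_repro") %in% gr))
    c("male_repro", "female_repro")
  else stop("no recognizable male/female sample groups: ",
            paste(gr, collapse = ", "))
}

#' Classify one gene's sex bias
#'
#' Two-tailed Student's t test (equal-variance) between the male and
#' female reproductive-organ groups; `male` when p < alpha and the male
#' mean is higher, `female` when p < alpha and the female mean is higher,
#' `unbiased` otherwise, `no_data` when the gene is absent or either group
#' has fewer than 2 replicates. When both groups are constant the p value
#' degenerates to 1 (equal means) or 0 (different means).
#'
#' @param m an [expression_matrix()] (microarray or RNA-seq).
#' @param gene gene id.
#' @param alpha significance level (default 0.05, no multiplicity
#'   correction).
#' @return list of class `sex_bias_call`: `gene_id`, `call`, `p_value`,
#'   `mean_male`, `mean_female`, `platform`.
#' @export
call_sex_bias <- function(m, gene, alpha = 0.05) {
  sg <- .sex_groups(m)
  out <- function(call, p = NA_real_, mm = NA_real_, mf = NA_real_)
    structure(list(gene_id = gene, call = call, p_value = p,
                   mean_male = mm, mean_female = mf,
                   platform = m$platform), class = "sex_bias_call")
  if (!gene %in% rownames(m$values)) return(out("no_data"))
  male <- m$values[gene, m$sample_groups == sg[1]]
  female <- m$values[gene, m$sample_groups == sg[2]]
  if (length(male) < 2L || length(female) < 2L) {
    warning("gene ", gene, ": fewer than 2 replicates per group")
    return(out("no_data"))
  }
  if (stats::sd(male) == 0 && stats::sd(female) == 0) {
    p <- if (mean(male) == mean(female)) 1 else 0
  } else {
    p <- stats::t.test(male, female, var.equal = TRUE)$p.value
  }
  call <- if (p < alpha && mean(male) > mean(female)) "male"
    else if (p < alpha && mean(female) > mean(male)) "female"
    else "unbiased"
  out(call, p, mean(male), mean(female))
}

#' Sex-bias calls for every gene of a matrix
#'
#' @inheritParams call_sex_bias
#' @param genes gene ids (defaults to all rows).
#' @return data.frame with one row per gene: `gene_id`, `call`,
#'   `p_value`, `mean_male`, `mean_female`, `platform`.
#' @export
call_sex_bias_all <- function(m, genes = rownames(m$values), alpha = 0.05) {
  calls <- lapply(genes, function(g) call_sex_bias(m, g, alpha))
  data.frame(gene_id = genes,
             call = vapply(calls, `[[`, "", "call"),
             p_value = vapply(calls, `[[`, 0, "p_value"),
             mean_male = vapply(calls, `[[`, 0, "mean_male"),
             mean_female = vapply(calls, `[[`, 0, "mean_female"),
             platform = m$platform, stringsAsFactors = FALSE)
}

#' Mean stage profile of a gene across spermatogenesis
#'
#' Per-stage means on the `ln(FPKM + 1)` scale, in the order premeiotic,
#' meiosis I, meiosis II, postmeiotic.
#'
#' @param m a `stage_FPKM` [expression_matrix()].
#' @param gene gene id.
#' @return Named numeric vector of the four stage means (`NA` for stages
#'   without samples or when the gene is absent).
#' @export
stage_profile <- function(m, gene) {
  stopifnot(m$platform == "stage_FPKM")
  means <- stats::setNames(rep(NA_real_, 4L), .STAGES)
  if (!gene %in% rownames(m$values)) return(means)
  for (s in .STAGES) {
    v <- m$values[gene, m$sample_groups == s]
    if (length(v)) means[s] <- mean(v)
  }
  means
}

#' Classify a spermatogenesis stage profile
#'
#' `later_stage_max` when the maximum over meiosis I, meiosis II and
#' postmeiotic strictly exceeds the premeiotic mean (the pattern expected
#' of autosomal retrogenes escaping meiotic sex chromosome inactivation);
#' `premeiotic_max` otherwise, including exact ties. Any missing stage mean
#' gives `no_data`.
#'
#' @param stage_means numeric vector of the four stage means (see
#'   [stage_profile()]).
#' @return `"later_stage_max"`, `"premeiotic_max"` or `"no_data"`.
#' @export
classify_stage_profile <- function(stage_means) {
  if (length(stage_means) != 4L || anyNA(stage_means)) return("no_data")
  if (max(stage_means[2:4]) > stage_means[1]) "later_stage_max"
  else "premeiotic_max"
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon convention); ties in the
#' absolute differences get midranks. For n <= `exact_max` the null
#' distribution of the signed-rank statistic is computed exactly (a
#' shift-algorithm convolution over the doubled midranks, equivalent to
#' enumerating all 2^n sign assignments); larger samples use the normal
#' approximation with continuity correction and the tie-corrected variance
#' `sum(rank^2)/4`. All differences zero gives p = 1.
#'
#' @param a,b paired numeric vectors.
#' @param alternative `"two_sided"`, `"greater"` (a tends larger) or
#'   `"less"`; `"one_tailed"` is accepted as an alias for `"greater"`.
#' @param exact_max largest n for the exact distribution.
#' @return p value.
#' @export
paired_wilcoxon <- function(a, b, alternative = "two_sided",
                            exact_max = 25L) {
  stopifnot(length(a) == length(b))
  if (alternative == "one_tailed") alternative <- "greater"
  alternative <- match.arg(alternative, c("two_sided", "greater", "less"))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))       # doubled midranks are integers
    S <- sum(r2)
    f <- rep(0, S + 1L)                  # counts of sum of chosen ranks
    f[1L] <- 1
    for (rr in r2) {
      g <- f
      g[(rr + 1L):(S + 1L)] <- g[(rr + 1L):(S + 1L)] + f[1L:(S + 1L - rr)]
      f <- g
    }
    f <- f / 2^n
    w2 <- round(2 * W)
    vals <- 0:S
    p <- switch(alternative,
      greater = sum(f[vals >= w2 - 1e-9]),
      less = sum(f[vals <= w2 + 1e-9]),
      two_sided = sum(f[abs(vals - S / 2) >= abs(w2 - S / 2) - 1e-9]))
    return(min(1, p))
  }
  mu <- sum(r) / 2
  sigma <- sqrt(sum(r^2) / 4)
  p <- switch(alternative,
    greater = stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE),
    less = stats::pnorm((W - mu + 0.5) / sigma),
    two_sided = 2 * stats::pnorm((abs(W - mu) - 0.5) / sigma,
                                 lower.tail = FALSE))
  min(1, p)
}

#' Cross-tabulate bias, age, direction and stage-profile calls
#'
#' Joins per-gene labels and reproduces the study-style contingency
#' summaries: male bias by age group (young PS1-7 vs old PS8-9) with odds
#' ratio, Woolf CI and Fisher p; male bias by movement direction among
#' young events; and, when profiles are present, the
#' later-stage-maximum vs premeiotic-maximum by male/non-male table.
#' Percentages are reported among sex-biased genes (male + female) for the
#' bias tables and among genes with a called profile for the profile
#' table.
#'
#' @param df data.frame with columns `gene_id`, `bias` (`male`, `female`,
#'   `unbiased`, `no_data`), `age_group` (`young`/`old`), and optionally
#'   `direction` and `profile` (`later_stage_max`/`premeiotic_max`/`NA`).
#' @return Nested list with components `bias_by_age`,
#'   `bias_by_direction`, and (when profiles exist) `profile_by_bias`.
#' @export
crosstab_report <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("gene_id", "bias", "age_group") %in% names(df)))
  if (!nrow(df)) stop("empty join: no genes to cross-tabulate")
  biased <- df[df$bias %in% c("male", "female"), ]
  ct <- function(a, b, c_, d_) c(a, b, c_, d_)
  n_y_m <- sum(biased$age_group == "young" & biased$bias == "male")
  n_y_f <- sum(biased$age_group == "young" & biased$bias == "female")
  n_o_m <- sum(biased$age_group == "old" & biased$bias == "male")
  n_o_f <- sum(biased$age_group == "old" & biased$bias == "female")
  tab_age <- matrix(ct(n_y_m, n_y_f, n_o_m, n_o_f), 2, byrow = TRUE,
                    dimnames = list(c("young", "old"),
                                    c("male", "female")))
  out <- list(bias_by_age = list(
    table = tab_age,
    pct_male_among_biased = c(
      young = 100 * n_y_m / max(1L, n_y_m + n_y_f),
      old = 100 * n_o_m / max(1L, n_o_m + n_o_f)),
    odds_ratio = as.numeric(odds_ratio(tab_age)),
    ci = woolf_ci(tab_age),
    fisher_p = fisher_exact(tab_age)))
  if ("direction" %in% names(df)) {
    by <- biased[biased$age_group == "young", ]
    dirs <- sort(unique(by$direction))
    pct <- vapply(dirs, function(d) {
      sel <- by$direction == d
      100 * sum(by$bias[sel] == "male") / max(1L, sum(sel))
    }, 0)
    out$bias_by_direction <- list(
      table = table(direction = by$direction, bias = by$bias),
      pct_male_among_biased_young = stats::setNames(pct, dirs))
  }
  if ("profile" %in% names(df)) {
    pf <- df[!is.na(df$profile) & df$profile != "no_data" &
               df$bias != "no_data", ]
    if (nrow(pf)) {
      later <- pf$profile == "later_stage_max"
      male <- pf$bias == "male"
      tab_pr <- matrix(ct(sum(later & male), sum(later & !male),
                          sum(!later & male), sum(!later & !male)),
                       2, byrow = TRUE,
                       dimnames = list(c("later_stage_max",
                                         "premeiotic_max"),
                                       c("male", "not_male")))
      out$profile_by_bias <- list(
        table = tab_pr,
        pct_later_stage = 100 * sum(later) / nrow(pf),
        pct_male_among_later = 100 * sum(later & male) /
          max(1L, sum(later)),
        odds_ratio = as.numeric(odds_ratio(tab_pr)),
        ci = woolf_ci(tab_pr),
        fisher_p = fisher_exact(tab_pr))
    }
  }
  out
}

#' Read an expression TSV plus sample sheet
#'
#' The expression table has gene ids in the first column and one column
#' per sample; the sample sheet is a TSV with columns `sample_id`,
#' `group`.
#'
#' @param expr_tsv,sheet_tsv file paths.
#' @param platform platform tag, see [expression_matrix()].
#' @param normalized set `TRUE` when the values are already on the
#'   platform's working scale (skips [normalize_expression()]).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(expr_tsv, sheet_tsv, platform,
                            normalized = FALSE) {
  tab <- utils::read.delim(expr_tsv, stringsAsFactors = FALSE,
                           check.names = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab[[1]]
  sheet <- utils::read.delim(sheet_tsv, stringsAsFactors = FALSE)
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  if (normalized) expression_matrix(platform, v, groups)
  else normalize_expression(v, platform, groups)
}

#' Write an expression matrix and its sample sheet
#' @param m an [expression_matrix()].
#' @param expr_tsv,sheet_tsv output paths.
#' @export
write_expression <- function(m, expr_tsv, sheet_tsv) {
  tab <- data.frame(gene_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, expr_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(m$sample_groups),
               group = unname(m$sample_groups)),
    sheet_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr = expr_tsv, sheet = sheet_tsv))
}
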