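# Interchromosomal gene-traffic expectations and significance tests
# (the out-of-the-X analysis), plus the 2x2 contingency statistics used by
# the expression comparisons.

#' Observed movement counts for one stage group
#'
#' @param n_XA,n_AA,n_AX non-negative integer counts of X->A, A->A (between
#'   distinct autosomes) and A->X events.
#' @return Named integer vector of class `movement_counts` with an
#'   `n_total` attribute.
#' @export
movement_counts <- function(n_XA = 0L, n_AA = 0L, n_AX = 0L) {
  x <- c(`X->A` = as.integer(n_XA), `A->A` = as.integer(n_AA),
         `A->X` = as.integer(n_AX))
  stopifnot(all(x >= 0L))
  structure(x, n_total = sum(x), class = "movement_counts")
}

#' @export
print.movement_counts <- function(x, ...) {
  cat(sprintf("movement counts (n = %d): X->A %d, A->A %d, A->X %d\n",
              attr(x, "n_total"), x[["X->A"]], x[["A->A"]], x[["A->X"]]))
  invisible(x)
}

#' Build a random-movement expectation model
#'
#' Parameterizes the expected share of each movement direction under random
#' interchromosomal traffic. Each ordered chromosome pair (s, t), s != t,
#' carries weight `w = G_s * D_s * A_t * F_t`: the number of source genes
#' `G_s`, a source dosage weight `D_s` (the mRNA pool a source gene
#' contributes; with full dosage compensation of the X this stays 1),
#' a target insertion weight `A_t` (opportunity to land, by default
#' proportional to chromosome length) and a target fixation weight `F_t`
#' (relative effective population size: X = 0.75, autosomes = 1).
#'
#' @param chromosomes data.frame with columns `name`, `sex_class`
#'   (`"X_like"`/`"autosome"`) and, unless overridden, `length`.
#' @param gene_counts named numeric `G_c` per chromosome.
#' @param dosage named numeric `D_c`; default 1 for every chromosome.
#' @param insertion named numeric `A_t`; default `chromosomes$length`.
#' @param fixation named numeric `F_t`; default 0.75 for the X-like
#'   chromosome and 1 for autosomes.
#' @return list of class `expectation_model`.
#' @export
expectation_model <- function(chromosomes, gene_counts,
                              dosage = NULL, insertion = NULL,
                              fixation = NULL) {
  nm <- chromosomes$name
  stopifnot(length(nm) >= 2L, all(nm %in% names(gene_counts)))
  if (sum(chromosomes$sex_class == "X_like") != 1L)
    stop("expectation model needs exactly one X_like chromosome")
  if (sum(chromosomes$sex_class == "autosome") < 2L)
    stop("expectation model needs at least two autosomes")
  if (is.null(dosage)) dosage <- stats::setNames(rep(1, length(nm)), nm)
  if (is.null(insertion))
    insertion <- stats::setNames(chromosomes$length, nm)
  if (is.null(fixation))
    fixation <- stats::setNames(
      ifelse(chromosomes$sex_class == "X_like", 0.75, 1), nm)
  w <- list(G = gene_counts[nm], D = dosage[nm], A = insertion[nm],
            F = fixation[nm])
  if (any(unlist(w[c("D", "A", "F")]) <= 0) || any(w$G < 0))
    stop("model weights must be positive (gene counts non-negative)")
  structure(list(chromosomes = chromosomes, weights = w),
            class = "expectation_model")
}

#' Expected direction frequencies under random movement
#'
#' Sums the pair weights `G_s * D_s * A_t * F_t` over every ordered
#' interchromosomal pair, classifies each pair as X->A, A->A or A->X, and
#' normalizes to frequencies.
#'
#' @param model an [expectation_model].
#' @return Named numeric vector over `X->A`, `A->A`, `A->X`, summing to 1.
#' @export
expected_frequencies <- function(model) {
  stopifnot(inherits(model, "expectation_model"))
  chrom <- model$chromosomes
  w <- model$weights
  nm <- chrom$name
  cls <- stats::setNames(chrom$sex_class, nm)
  tot <- c(`X->A` = 0, `A->A` = 0, `A->X` = 0)
  for (s in nm) for (t in nm) {
    if (s == t) next
    wt <- w$G[[s]] * w$D[[s]] * w$A[[t]] * w$F[[t]]
    dir <- if (cls[[s]] == "X_like" && cls[[t]] == "autosome") "X->A"
      else if (cls[[s]] == "autosome" && cls[[t]] == "X_like") "A->X"
      else if (cls[[s]] == "autosome" && cls[[t]] == "autosome") "A->A"
      else next  # X->X impossible with a single X
    tot[dir] <- tot[dir] + wt
  }
  if (sum(tot) <= 0) stop("all pair weights are zero")
  tot / sum(tot)
}

#' Excess (or deficit) of observed over expected movement shares
#'
#' `100 * (observed_share - expected_share) / expected_share` per
#' direction; negative values are deficits, and -100 means the direction
#' was expected but never observed. A direction with zero expected share
#' but positive observations is undefined and reported `NA` with a
#' warning.
#'
#' @param observed a [movement_counts()].
#' @param expected_freq named frequencies from [expected_frequencies()]
#'   (or supplied directly, e.g. printed values).
#' @return Named numeric vector of percentages.
#' @export
excess_rate <- function(observed, expected_freq) {
  n <- attr(observed, "n_total")
  if (is.null(n)) n <- sum(observed)
  stopifnot(n > 0)
  dirs <- names(observed)
  share <- as.numeric(observed) / n
  ef <- expected_freq[dirs]
  out <- 100 * (share - ef) / ef
  bad <- ef == 0 & share > 0
  if (any(bad)) {
    warning("observed events in direction(s) with zero expected share: ",
            paste(dirs[bad], collapse = ", "))
    out[bad] <- NA_real_
  }
  stats::setNames(as.numeric(out), dirs)
}

#' Monte-Carlo chi-square test of observed traffic against expectation
#'
#' Draws `n_perm` multinomial samples of the observed total under the
#' expected frequencies, computes the Pearson chi-square statistic of each
#' replicate against the expected counts, and reports the add-one
#' estimate `p = (1 + #[replicate >= observed]) / (n_perm + 1)`.
#' Reproducible bit-for-bit for a given `(seed, n_perm)`.
#'
#' @param observed a [movement_counts()].
#' @param expected_freq named frequencies (see [excess_rate()]).
#' @param n_perm number of Monte-Carlo replicates.
#' @param seed integer RNG seed (local to this call).
#' @return list of class `traffic_test`: `statistic`, `p_perm`,
#'   `n_permutations`, `expected_n`.
#' @export
permutation_chisq <- function(observed, expected_freq, n_perm = 1e6,
                              seed = 1L) {
  n <- attr(observed, "n_total")
  if (is.null(n)) n <- sum(observed)
  stopifnot(n > 0)
  dirs <- names(observed)
  p <- expected_freq[dirs] / sum(expected_freq[dirs])
  en <- n * p
  keep <- p > 0
  stat_of <- function(x) sum((x[keep] - en[keep])^2 / en[keep])
  obs_stat <- stat_of(as.numeric(observed))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n_perm <- as.integer(n_perm)
  draws <- stats::rmultinom(n_perm, size = n, prob = p)
  stats <- colSums((draws[keep, , drop = FALSE] - en[keep])^2 / en[keep])
  list(statistic = obs_stat,
       p_perm = (1 + sum(stats >= obs_stat - 1e-12)) / (n_perm + 1),
       n_permutations = n_perm,
       expected_n = stats::setNames(as.numeric(en), dirs))
}

#' Full traffic summary for one stage group
#'
#' @param observed a [movement_counts()].
#' @param expected_freq named frequencies.
#' @param n_perm,seed passed to [permutation_chisq()].
#' @return list of class `traffic_result` with `observed`,
#'   `observed_share`, `expected_freq`, `expected_n`, `excess_pct`,
#'   `p_perm`, `n_permutations`.
#' @export
traffic_result <- function(observed, expected_freq, n_perm = 1e6,
                           seed = 1L) {
  n <- attr(observed, "n_total")
  test <- permutation_chisq(observed, expected_freq, n_perm, seed)
  structure(list(observed = observed,
                 observed_share = as.numeric(observed) / n,
                 expected_freq = expected_freq[names(observed)],
                 expected_n = test$expected_n,
                 excess_pct = excess_rate(observed, expected_freq),
                 p_perm = test$p_perm,
                 n_permutations = test$n_permutations),
            class = "traffic_result")
}

#' @export
print.traffic_result <- function(x, ...) {
  df <- data.frame(observed = as.integer(x$observed),
                   obs_share_pct = round(100 * x$observed_share, 2),
                   exp_share_pct = round(100 * x$expected_freq, 2),
                   expected_n = round(x$expected_n, 2),
                   excess_pct = round(x$excess_pct, 2),
                   row.names = names(x$observed))
  print(df)
  cat(sprintf("Monte-Carlo chi-square p = %.4g (%d replicates)\n",
              x$p_perm, x$n_permutations))
  invisible(x)
}

.as_2x2 <- function(table) {
  m <- matrix(as.numeric(table), nrow = 2, byrow = TRUE)
  if (any(m < 0) || any(!is.finite(m))) stop("2x2 table must be >= 0")
  m
}

#' Odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)` for the table `rbind(c(a, b), c(c, d))`. Tables with a
#' zero cell get the Haldane-Anscombe +0.5 correction in every cell, with
#' a `corrected` attribute flagging it.
#'
#' @param table 2x2 matrix or length-4 vector (row-major: a, b, c, d).
#' @return Odds ratio (attribute `corrected` when +0.5 was applied).
#' @export
odds_ratio <- function(table) {
  m <- .as_2x2(table)
  corrected <- any(m == 0)
  if (corrected) m <- m + 0.5
  structure(m[1, 1] * m[2, 2] / (m[1, 2] * m[2, 1]), corrected = corrected)
}

#' Woolf confidence interval for an odds ratio
#'
#' Normal-approximation interval on the log odds ratio:
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param table 2x2 counts as in [odds_ratio()].
#' @param level confidence level.
#' @return Named vector `c(low, or, high)`; attribute `corrected` when the
#'   +0.5 zero-cell correction was applied.
#' @export
woolf_ci <- function(table, level = 0.95) {
  m <- .as_2x2(table)
  corrected <- any(m == 0)
  if (corrected) m <- m + 0.5
  or <- m[1, 1] * m[2, 2] / (m[1, 2] * m[2, 1])
  se <- sqrt(sum(1 / m))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(c(low = exp(log(or) - z * se), or = or,
              high = exp(log(or) + z * se)),
            corrected = corrected)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of
#' all tables at most as probable as the observed one (the standard
#' two-sided rule).
#'
#' @param table 2x2 counts as in [odds_ratio()].
#' @return Two-sided p value.
#' @export
fisher_exact <- function(table) {
  m <- .as_2x2(table)
  stats::fisher.test(round(m))$p.value
}
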