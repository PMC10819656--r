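# Cohort-level statistics: paired comparisons, one-way repeated-measures
# ANOVA with Bonferroni-adjusted pairwise tests, Cohen's d effect sizes,
# fold/percent changes and summary tables.

#' Paired t-test with effect size
#'
#' Two-sided paired t-test of `post` against `pre`, with a summary-statistic
#' Cohen's d attached. A zero-variance difference vector (identical pairs or
#' a constant shift) is degenerate for the t statistic and raises an error.
#'
#' @param pre,post Numeric vectors of equal length >= 2, paired by subject.
#' @param d_variant Effect-size variant passed to [cohen_d()].
#' @return A one-row tibble: `statistic`, `p_value`, `effect_size`,
#'   `variant_tag`, `n`.
#' @export
paired_t <- function(pre, post, d_variant = "pooled_hedges") {
  n <- length(pre)
  if (length(post) != n || n < 2) {
    rlang::abort("pre and post must be paired vectors of equal length >= 2")
  }
  diffs <- post - pre
  if (stats::sd(diffs) == 0) {
    rlang::abort("differences have zero variance; the paired t statistic is undefined")
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  d <- cohen_d(mean(pre), stats::sd(pre), mean(post), stats::sd(post), n,
               variant = d_variant)
  tibble(
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    effect_size = d,
    variant_tag = d_variant,
    n = n
  )
}

#' Cohen's d from summary statistics
#'
#' Standardised pre/post difference in three variants:
#' \describe{
#'   \item{`pooled`}{`|post_mean - pre_mean| / sqrt((pre_sd^2 + post_sd^2)/2)`.}
#'   \item{`pooled_hedges` (default)}{the pooled value times the
#'     small-sample bias correction `J = 1 - 3/(4*(n - 1) - 1)`, the
#'     paired-design degrees of freedom.}
#'   \item{`glass`}{`|post_mean - pre_mean| / post_sd`.}
#' }
#'
#' @param pre_mean,pre_sd,post_mean,post_sd Group summary statistics
#'   (SDs >= 0, not both zero).
#' @param n Number of paired subjects (needed for `pooled_hedges`).
#' @param variant One of `"pooled"`, `"pooled_hedges"`, `"glass"`.
#' @return The effect size (non-negative scalar).
#' @examples
#' cohen_d(1.5, 0.3, 20.7, 2.6, n = 14) # large lactate effect
#' @export
cohen_d <- function(pre_mean, pre_sd, post_mean, post_sd, n = NULL,
                    variant = c("pooled_hedges", "pooled", "glass")) {
  variant <- match.arg(variant)
  if (pre_sd < 0 || post_sd < 0 || (pre_sd == 0 && post_sd == 0)) {
    rlang::abort("SDs must be non-negative and not both zero")
  }
  delta <- abs(post_mean - pre_mean)
  if (variant == "glass") {
    if (post_sd == 0) rlang::abort("glass variant requires post_sd > 0")
    return(delta / post_sd)
  }
  d <- delta / sqrt((pre_sd^2 + post_sd^2) / 2)
  if (variant == "pooled_hedges") {
    if (is.null(n) || n < 2) rlang::abort("pooled_hedges requires n >= 2")
    d <- d * (1 - 3 / (4 * (n - 1) - 1))
  }
  d
}

#' Fold change of a cohort mean
#'
#' @param pre_mean Baseline mean (> 0).
#' @param post_mean Post mean.
#' @return `post_mean / pre_mean`.
#' @examples
#' fold_change(1.5, 20.7) # ~14-fold
#' @export
fold_change <- function(pre_mean, post_mean) {
  if (pre_mean <= 0) rlang::abort("pre_mean must be positive")
  post_mean / pre_mean
}

#' Percent change of a cohort mean
#'
#' @param pre_mean Baseline mean (> 0).
#' @param post_mean Post mean.
#' @return `100 * (post_mean - pre_mean) / pre_mean`.
#' @examples
#' pct_change(97.1, 141.8) # ~46% glucose rise
#' @export
pct_change <- function(pre_mean, post_mean) {
  if (pre_mean <= 0) rlang::abort("pre_mean must be positive")
  100 * (post_mean - pre_mean) / pre_mean
}

#' One-way repeated-measures ANOVA with Bonferroni pairwise tests
#'
#' Within-subject one-way ANOVA over timepoints (subjects as the error
#' stratum, via `stats::aov` with an `Error(subject)` term), followed by all
#' pairwise paired t-tests with Bonferroni adjustment (raw p times the
#' number of comparisons, capped at 1). No sphericity correction is
#' applied. With two timepoints the omnibus F equals the squared paired-t
#' statistic.
#'
#' @param values Numeric matrix, subjects in rows, timepoints in columns
#'   (complete: no missing cells; >= 3 subjects, >= 2 timepoints).
#' @return A list: `f` and `p_value` (omnibus), `df` (numerator,
#'   denominator), and `pairwise`, a tibble of all timepoint pairs with raw
#'   and Bonferroni-adjusted p-values.
#' @export
rm_anova_bonferroni <- function(values) {
  values <- as.matrix(values)
  if (any(is.na(values))) rlang::abort("missing cells are not supported; no imputation is performed")
  n <- nrow(values)
  k <- ncol(values)
  if (n < 3 || k < 2) rlang::abort("need >= 3 subjects and >= 2 timepoints")
  tp <- colnames(values) %||% paste0("t", seq_len(k))

  long <- data.frame(
    y = as.vector(values),
    time = factor(rep(tp, each = n), levels = tp),
    subject = factor(rep(seq_len(n), times = k))
  )
  ss_time <- n * sum((colMeans(values) - mean(values))^2)
  if (ss_time == 0) {
    omnibus <- list(f = 0, p_value = 1, df = c(k - 1, (n - 1) * (k - 1)))
  } else {
    fit <- stats::aov(y ~ time + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    rn <- trimws(rownames(tab))
    i_t <- match("time", rn)
    i_r <- match("Residuals", rn)
    omnibus <- list(
      f = tab[i_t, "F value"],
      p_value = tab[i_t, "Pr(>F)"],
      df = c(tab[i_t, "Df"], tab[i_r, "Df"])
    )
  }

  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  pw <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- stats::t.test(values[, i2], values[, i1], paired = TRUE)
    tibble(
      timepoint_1 = tp[i1], timepoint_2 = tp[i2],
      statistic = unname(tt$statistic), p_raw = tt$p.value
    )
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_bonferroni <- pmin(pw$p_raw * m, 1)
  c(omnibus, list(pairwise = pw, n = n, k = k))
}

#' Table-style cohort summary
#'
#' Summarises a cohort table — one row per subject x timepoint, derived
#' quantities in columns — as mean and SD per variable per timepoint, and
#' (for variables observed at both the first and last timepoint level)
#' adds the paired-t p-value and Cohen's d for that pre/post contrast.
#'
#' @param table A data frame with columns `subject`, `timepoint` and one
#'   column per summarised variable (>= 2 subjects; no duplicate
#'   subject-timepoint keys).
#' @param d_variant Effect-size variant for the pre/post contrast.
#' @return A list with `summary` (tibble: variable, timepoint, mean, sd, n)
#'   and `comparisons` (tibble: variable, p_value, effect_size, variant_tag,
#'   n), serialisable to CSV/JSON.
#' @export
summarize_cohort <- function(table, d_variant = "pooled_hedges") {
  table <- as_tibble(table)
  if (!all(c("subject", "timepoint") %in% names(table))) {
    rlang::abort("table needs 'subject' and 'timepoint' columns")
  }
  if (anyDuplicated(table[, c("subject", "timepoint")]) > 0) {
    rlang::abort("duplicate subject x timepoint keys")
  }
  if (length(unique(table$subject)) < 2) rlang::abort("need >= 2 subjects")
  vars <- setdiff(names(table), c("subject", "timepoint"))
  tps <- if (is.factor(table$timepoint)) levels(table$timepoint) else
    unique(table$timepoint)

  summ <- dplyr::bind_rows(lapply(vars, function(v) {
    dplyr::bind_rows(lapply(tps, function(tp) {
      x <- table[[v]][table$timepoint == tp]
      x <- x[!is.na(x)]
      if (length(x) == 0) return(NULL)
      tibble(variable = v, timepoint = tp, mean = mean(x),
             sd = stats::sd(x), n = length(x))
    }))
  }))

  pre_tp <- tps[1]
  post_tp <- tps[length(tps)]
  comparisons <- dplyr::bind_rows(lapply(vars, function(v) {
    wide <- merge(
      table[table$timepoint == pre_tp, c("subject", v)],
      table[table$timepoint == post_tp, c("subject", v)],
      by = "subject", suffixes = c("_pre", "_post")
    )
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
    if (nrow(wide) < 2) return(NULL)
    res <- tryCatch(
      paired_t(wide[[paste0(v, "_pre")]], wide[[paste0(v, "_post")]],
               d_variant = d_variant),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble(variable = v), res)
  }))
  list(summary = summ, comparisons = comparisons)
}
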