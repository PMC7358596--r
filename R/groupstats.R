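## Group-comparison statistics for the energy channels (one-way ANOVA and
## Tukey's HSD across pharmacological classes) and the cAMP-reversion
## normalisation used in functional validation assays.

#' One-way fixed-effects analysis of variance
#'
#' Standard between/within sums-of-squares decomposition with the p-value
#' from the F distribution.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as `values`.
#' @return An object of class `anova_result`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `group_means`, `grand_mean`, `ss_between`,
#'   `ss_within`.
#' @export
#' @examples
#' tr <- load_fixture("training_all")
#' one_way_anova(tr$dg_gdp, tr$bib_class)$f_stat   # ~84.09
one_way_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  counts <- table(groups)
  if (length(counts) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2L)) {
    stop("degenerate group(s) with fewer than 2 values: ",
         paste(names(counts)[counts < 2L], collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm(values ~ groups)
  aov_tab <- stats::anova(fit)
  structure(list(
    f_stat = aov_tab[["F value"]][1L],
    df_between = aov_tab[["Df"]][1L],
    df_within = aov_tab[["Df"]][2L],
    p_value = aov_tab[["Pr(>F)"]][1L],
    group_means = vapply(levels(groups),
                         function(g) mean(values[groups == g]), 0),
    grand_mean = mean(values),
    ss_between = aov_tab[["Sum Sq"]][1L],
    ss_within = aov_tab[["Sum Sq"]][2L]
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  invisible(x)
}

#' Tukey's honestly-significant-difference pairwise comparisons
#'
#' Studentized-range comparisons of all group pairs with the pooled
#' within-group variance; unequal group sizes use the Tukey-Kramer
#' standard error \eqn{\sqrt{s^2/2\,(1/n_a + 1/n_b)}}. Adjusted p-values
#' come from the studentized range distribution with `g` groups and
#' `n - g` degrees of freedom.
#'
#' @inheritParams one_way_anova
#' @param alpha confidence level for the intervals (default 0.05).
#' @return An object of class `tukey_result`: a data frame with one row
#'   per unordered group pair (`group_a`, `group_b`, `diff`, `q`,
#'   `p_adj`, `lwr`, `upr`).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  counts <- table(groups)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  g <- length(counts)
  n <- length(values)
  means <- vapply(levels(groups), function(l) mean(values[groups == l]), 0)
  s2 <- sum(vapply(levels(groups), function(l)
    sum((values[groups == l] - means[[l]])^2), 0)) / (n - g)
  pairs <- utils::combn(levels(groups), 2L)
  rows <- apply(pairs, 2L, function(pr) {
    a <- pr[1L]; b <- pr[2L]
    diff <- means[[a]] - means[[b]]
    se <- sqrt(s2 / 2 * (1 / counts[[a]] + 1 / counts[[b]]))
    q <- abs(diff) / se
    crit <- stats::qtukey(1 - alpha, g, n - g)
    data.frame(group_a = a, group_b = b, diff = diff, q = q,
               p_adj = stats::ptukey(q, g, n - g, lower.tail = FALSE),
               lwr = diff - crit * se, upr = diff + crit * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("tukey_result", "data.frame"),
            alpha = alpha, df = n - g, n_groups = g)
}

#' Percent reversion of the 5-oxo-ETE effect in a cAMP assay
#'
#' Normalises a forskolin-stimulated cAMP readout: the agonist
#' (5-oxo-ETE) condition anchors 100% inhibition and the forskolin-only
#' condition 0%, so a test compound's reversion of the agonist effect is
#' \deqn{100 \times \frac{\bar{x}_{compound} - \bar{x}_{fsk+5oxoETE}}
#'       {\bar{x}_{fsk} - \bar{x}_{fsk+5oxoETE}}.}
#' The standard error is taken across the compound replicates (each
#' replicate normalised against the fixed condition means).
#'
#' @param records data frame with columns `condition` (one of
#'   `forskolin_only`, `fsk_plus_5oxoETE`,
#'   `fsk_plus_5oxoETE_plus_compound`), `luminescence` (> 0),
#'   `compound_id`, `replicate`.
#' @param compound_id which compound's rows to normalise.
#' @return list with `percent`, `se` (`NA` for a single replicate), `n`.
#' @export
camp_reversion <- function(records, compound_id) {
  needed <- c("condition", "luminescence", "compound_id", "replicate")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L) {
    stop("records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(records$luminescence <= 0)) {
    stop("luminescence values must be positive", call. = FALSE)
  }
  m_fsk <- mean(records$luminescence[records$condition == "forskolin_only"])
  m_oxo <- mean(records$luminescence[
    records$condition == "fsk_plus_5oxoETE"])
  comp <- records$luminescence[
    records$condition == "fsk_plus_5oxoETE_plus_compound" &
      records$compound_id == compound_id]
  if (is.nan(m_fsk) || is.nan(m_oxo) || length(comp) == 0L) {
    stop("all three conditions need at least one replicate", call. = FALSE)
  }
  denom <- m_fsk - m_oxo
  if (abs(denom) < .Machine$double.eps^0.5 * max(abs(m_fsk), 1)) {
    stop("no 5-oxo-ETE inhibition: forskolin-only and agonist condition ",
         "means coincide", call. = FALSE)
  }
  rev_i <- 100 * (comp - m_oxo) / denom
  list(percent = mean(rev_i),
       se = if (length(rev_i) > 1L)
         stats::sd(rev_i) / sqrt(length(rev_i)) else NA_real_,
       n = length(rev_i))
}
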