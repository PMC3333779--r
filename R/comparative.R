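#' Two-group Mann-Whitney (Wilcoxon rank-sum) comparison
#'
#' Two-sided Mann-Whitney U test between two groups of organism-level
#' measures. The exact null distribution is used when both groups have at
#' most `exact_max` observations and the data are tie-free; otherwise the
#' tie-corrected normal approximation with continuity correction is used
#' (the behaviour of [stats::wilcox.test()], which performs the test).
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param labels Group labels for reporting.
#' @param exact_max Largest per-group size for exact enumeration (default 8).
#' @param alternative Test sidedness (default two-sided).
#' @param correct Apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return A `group_comparison` object: test name, U statistic, p-value and
#'   per-group summaries.
#' @export
mann_whitney <- function(a, b, labels = c("a", "b"), exact_max = 8L,
                         alternative = "two.sided", correct = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stopf("both groups must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= exact_max && length(b) <= exact_max && !has_ties
  ht <- stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                           correct = correct)
  new_group_comparison(
    test = "Mann-Whitney",
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    groups = data.frame(
      label = labels,
      n = c(length(a), length(b)),
      median = c(stats::median(a), stats::median(b)),
      mean = c(mean(a), mean(b)),
      stringsAsFactors = FALSE
    )
  )
}

#' Kruskal-Wallis comparison across two or more groups
#'
#' Tie-corrected Kruskal-Wallis H test (chi-square approximation with k-1
#' degrees of freedom, via [stats::kruskal.test()]).
#'
#' @param groups A list of two or more non-empty numeric vectors.
#' @param labels Optional group labels.
#' @return A `group_comparison` object.
#' @export
kruskal_wallis <- function(groups, labels = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stopf("need at least 2 groups")
  }
  if (any(lengths(groups) == 0L)) stopf("all groups must be non-empty")
  labels <- labels %||% names(groups) %||% as.character(seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    # All observations tied: no rank variation, H is 0 by convention (the
    # tie-corrected statistic is 0/0 in stats::kruskal.test).
    return(new_group_comparison(
      test = "Kruskal-Wallis", statistic = 0, p_value = 1,
      groups = data.frame(label = labels, n = lengths(groups),
                          median = vapply(groups, stats::median, numeric(1)),
                          mean = vapply(groups, mean, numeric(1)),
                          stringsAsFactors = FALSE),
      df = length(groups) - 1
    ))
  }
  ht <- stats::kruskal.test(groups)
  new_group_comparison(
    test = "Kruskal-Wallis",
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    groups = data.frame(
      label = labels,
      n = lengths(groups),
      median = vapply(groups, stats::median, numeric(1)),
      mean = vapply(groups, mean, numeric(1)),
      stringsAsFactors = FALSE
    ),
    df = unname(ht$parameter)
  )
}

new_group_comparison <- function(test, statistic, p_value, groups,
                                 trait = NA_character_, df = NULL) {
  structure(
    list(trait = trait, test = test, statistic = statistic,
         p_value = p_value, df = df, groups = groups),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test%s: statistic = %.4g, p = %.4g\n", x$test,
              if (is.na(x$trait)) "" else paste0(" [", x$trait, "]"),
              x$statistic, x$p_value))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Chi-square test of independence between two categorical traits
#'
#' Pearson chi-square on the contingency table of two paired categorical
#' vectors (no continuity correction), used to assess interdependence
#' between lifestyle annotations. Pairs with a missing value in either trait
#' are dropped. A warning is issued when any expected cell count is below 5.
#'
#' @param trait_a,trait_b Paired categorical vectors of equal length.
#' @return A list: `statistic`, `df`, `p_value`, `table`.
#' @export
chi_square_independence <- function(trait_a, trait_b) {
  if (length(trait_a) != length(trait_b)) stopf("traits must be paired")
  keep <- !is.na(trait_a) & !is.na(trait_b)
  a <- factor(trait_a[keep])
  b <- factor(trait_b[keep])
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stopf("each trait needs at least 2 observed categories")
  }
  tab <- table(a, b)
  exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(exp_counts < 5)) {
    warnf("expected counts below 5 in %d cells; chi-square approximation weak",
          sum(exp_counts < 5))
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, table = tab)
}

#' Pearson correlation with significance test
#'
#' Sample Pearson correlation with a two-sided p-value from the t
#' distribution with n-2 degrees of freedom (via [stats::cor.test()]).
#' Binary variables (such as the 0/1 habitat code) may be supplied directly,
#' yielding the point-biserial correlation.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, non-degenerate.
#' @return A `correlation_result`: `r`, `p_value`, `n`, `controlling`.
#' @export
pearson_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stopf("degenerate input: a variable has zero variance")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ht$estimate), p_value = ht$p.value, n = n,
                 controlling = NA_character_),
            class = "correlation_result")
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` after removing the linear effect of a
#' third variable `z`:
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}
#' with a two-sided p-value from \eqn{t = r\sqrt{(n-3)/(1-r^2)}} on n-3
#' degrees of freedom.
#'
#' @param x,y,z Numeric vectors of equal length, n >= 4.
#' @return A `correlation_result` with `controlling = "z"`.
#' @export
partial_correlation <- function(x, y, z) {
  keep <- !is.na(x) & !is.na(y) & !is.na(z)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep]); z <- as.numeric(z[keep])
  n <- length(x)
  if (n < 4L) stopf("need at least 4 complete triples")
  if (stats::var(x) == 0 || stats::var(y) == 0 || stats::var(z) == 0) {
    stopf("degenerate input: a variable has zero variance")
  }
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stopf("partial correlation undefined: z is collinear with x or y")
  }
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(-1, min(1, r))
  tt <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 3)
  structure(list(r = r, p_value = p, n = n, controlling = "z"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: r = %.4f, p = %.4g, n = %d\n",
              if (is.na(x$controlling)) "Pearson correlation" else
                sprintf("Partial correlation (controlling %s)",
                        x$controlling),
              x$r, x$p_value, x$n))
  invisible(x)
}

#' Compare a bias measure across phenotype groups
#'
#' Joins genome profiles to phenotype annotations on `organism_id`, drops
#' organisms missing the trait, and compares the chosen bias measure across
#' the trait's groups: Mann-Whitney for two groups, Kruskal-Wallis for more.
#' Groups smaller than `min_group` are dropped with a message.
#'
#' @param profiles A genome profile table.
#' @param annotations A phenotype table ([read_phenotype_table()]).
#' @param trait Trait column name (e.g. `"habitat"`, `"oxygen"`).
#' @param measure Profile column to compare (default `"cai_ave"`).
#' @param min_group Minimum organisms per group (default 3).
#' @return A `group_comparison` object with group sizes and medians.
#' @export
compare_trait_groups <- function(profiles, annotations, trait,
                                 measure = "cai_ave", min_group = 3L) {
  stopifnot(is.data.frame(profiles), is.data.frame(annotations))
  if (!measure %in% names(profiles)) {
    stopf("measure '%s' not in profiles (available: %s)", measure,
          paste(setdiff(names(profiles), "organism_id"), collapse = ", "))
  }
  if (!trait %in% names(annotations)) {
    stopf("trait '%s' not in annotations (available: %s)", trait,
          paste(setdiff(names(annotations), "organism_id"), collapse = ", "))
  }
  joined <- merge(profiles[, c("organism_id", measure)],
                  annotations[, c("organism_id", trait)],
                  by = "organism_id")
  joined <- joined[!is.na(joined[[trait]]) & !is.na(joined[[measure]]), ,
                   drop = FALSE]
  if (nrow(joined) == 0L) stopf("no organisms with both '%s' and '%s'",
                                trait, measure)
  groups <- split(joined[[measure]], joined[[trait]])
  small <- lengths(groups) < min_group
  if (any(small)) {
    message(sprintf("dropping %d group(s) with fewer than %d organisms: %s",
                    sum(small), min_group,
                    paste(names(groups)[small], collapse = ", ")))
    groups <- groups[!small]
  }
  if (length(groups) < 2L) {
    stopf("fewer than 2 populated groups for trait '%s'", trait)
  }
  res <- if (length(groups) == 2L) {
    mann_whitney(groups[[1L]], groups[[2L]], labels = names(groups))
  } else {
    kruskal_wallis(groups)
  }
  res$trait <- trait
  res
}
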