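#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator of the survival function; the median is the
#' earliest time at which S(t) drops to 0.5 or below, undefined (NA) when
#' the curve never reaches 0.5. With no censoring the estimate equals the
#' empirical survival function.
#'
#' @param time Follow-up times (months).
#' @param event Logical/0-1; `TRUE` = progression or death observed,
#'   `FALSE` = censored.
#' @param group Optional group labels for stratified estimates.
#' @return List with `curve` (tibble: group, time, n_risk, n_event, surv at
#'   event times) and `median` (named by group).
#' @export
km_estimate <- function(time, event, group = NULL) {
  stopifnot(length(time) == length(event), all(time >= 0))
  df <- data.frame(time = time, event = as.integer(event),
                   group = if (is.null(group)) "all" else as.character(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  s <- summary(fit, censored = FALSE)
  if (length(s$time) == 0) {
    curve <- tibble(group = character(0), time = numeric(0),
                    n_risk = numeric(0), n_event = numeric(0),
                    surv = numeric(0))
  } else {
    grp <- if (is.null(s$strata)) rep("all", length(s$time))
           else sub("^group=", "", as.character(s$strata))
    curve <- tibble(group = grp, time = s$time, n_risk = s$n.risk,
                    n_event = s$n.event, surv = s$surv)
  }
  tab <- summary(fit)$table
  med <- if (is.matrix(tab)) setNames(unname(tab[, "median"]),
                                      sub("^group=", "", rownames(tab)))
         else setNames(unname(tab[["median"]]), "all")
  list(curve = curve, median = med)
}

#' Two-group log-rank test
#'
#' Two-sided log-rank chi-square on 1 degree of freedom. Invariant under
#' swapping the group labels.
#'
#' @param time,event Survival input as in [km_estimate()].
#' @param group Two-level group labels.
#' @return List with `statistic` (chi-square), `p.value`, and the
#'   observed/expected event table.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  if (n_distinct(group) != 2)
    stop("log-rank test requires exactly two non-empty groups",
         call. = FALSE)
  if (sum(event) < 1)
    stop("log-rank test requires at least one event", call. = FALSE)
  df <- data.frame(time = time, event = as.integer(event), group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p.value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Correlation between two numeric vectors
#'
#' Pearson for the parametric case, Spearman rank correlation for the
#' nonparametric case. A constant vector makes the Pearson coefficient
#' undefined and is an explicit error.
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped;
#'   at least 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate` (r), `p.value`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("correlation requires at least 3 complete pairs", call. = FALSE)
  if (method == "pearson" && (stats::sd(x) == 0 || stats::sd(y) == 0))
    stop("Pearson correlation undefined for a constant vector",
         call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       n = length(x), method = method)
}

#' Mann-Whitney U test
#'
#' Exact enumeration for combined sample sizes up to 16 without ties,
#' normal approximation with continuity and tie correction otherwise.
#'
#' @param x,y The two samples.
#' @return List with `U`, `p.value`, and `exact` (whether the exact
#'   distribution was used).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  exact <- (length(x) + length(y)) <= 16 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value, exact = exact)
}

#' 2x2 association test with automatic test choice
#'
#' Uses Fisher's exact test when any expected cell count is below 5,
#' otherwise the chi-square test with continuity correction; the test
#' actually applied is reported. `both = TRUE` returns both p-values.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param both Also report the p-value of the test not selected.
#' @return List with `p.value`, `test_used`, `expected`, and optionally
#'   `p_chisq` / `p_fisher`.
#' @export
assoc_2x2 <- function(tab, both = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0))
    stop("assoc_2x2() expects a 2x2 matrix of non-negative counts",
         call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- any(expected < 5)
  p_fisher <- fisher.test(tab)$p.value
  p_chisq <- suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
  out <- list(
    p.value = if (use_fisher) p_fisher else p_chisq,
    test_used = if (use_fisher) "fisher" else "chisq",
    expected = expected
  )
  if (both) { out$p_fisher <- p_fisher; out$p_chisq <- p_chisq }
  out
}

#' Per-gene mutation frequency table
#'
#' Counts mutations and mutated patients per gene over one somatic set
#' per patient (baseline sets, or emergent-at-PD sets). Patient
#' percentages use as denominator the number of patients whose panel
#' covers the gene: genes present only in panel version 3 are counted over
#' the v3-sequenced patients and flagged `panel_restricted`.
#'
#' @param calls Tibble of kept somatic calls with `patient_id` and `gene`
#'   columns (e.g. bound rows of `somatic_set$calls`).
#' @param patients Tibble with `patient_id` and `panel_version` for every
#'   analysed patient (including patients without mutations).
#' @return List: `table` (gene, n_mutations, n_patients,
#'   pct_patients, panel_restricted; sorted by mutation count),
#'   `total_mutations`, `n_patients`, `n_positive`, `pct_positive`,
#'   `mean_mutations_per_positive`.
#' @export
summarize_frequencies <- function(calls, patients) {
  stopifnot(all(c("patient_id", "gene") %in% names(calls)),
            all(c("patient_id", "panel_version") %in% names(patients)))
  patients <- distinct(patients, .data$patient_id, .data$panel_version)
  n_all <- nrow(patients)
  n_v3 <- sum(patients$panel_version == "v3")
  v2_genes <- panel_genes("v2")
  tab <- calls %>%
    group_by(.data$gene) %>%
    summarise(n_mutations = n(),
              n_patients = n_distinct(.data$patient_id),
              .groups = "drop") %>%
    mutate(panel_restricted = !.data$gene %in% v2_genes,
           denom = ifelse(.data$panel_restricted, n_v3, n_all),
           pct_patients = round(100 * .data$n_patients / .data$denom, 1)) %>%
    select(-"denom") %>%
    arrange(desc(.data$n_mutations), .data$gene)
  pos <- n_distinct(calls$patient_id)
  list(table = tab,
       total_mutations = nrow(calls),
       n_patients = n_all,
       n_positive = pos,
       pct_positive = round(100 * pos / n_all, 1),
       mean_mutations_per_positive =
         if (pos > 0) nrow(calls) / pos else NA_real_)
}

#' Exact power of the two-sided binomial test
#'
#' Enumerates the rejection region of the exact two-sided binomial test of
#' H0: p = p0 at level `alpha` (two-sided p-value by the minimum-likelihood
#' rule, as in `binom.test`) and sums the alternative probability mass over
#' it. Used at the design stage to size a cohort for demonstrating improved
#' mutation-detection sensitivity.
#'
#' @param p0 Null detection probability.
#' @param p1 Alternative detection probability.
#' @param n Number of evaluable trials. If the informative fraction of
#'   patients is `prevalence`, pass `n_evaluable(n_total, prevalence)`.
#' @param alpha Two-sided significance level.
#' @return Power in [0, 1].
#' @export
binomial_power <- function(p0, p1, n, alpha = 0.05) {
  if (p0 <= 0 || p0 >= 1 || p1 <= 0 || p1 >= 1)
    stop("p0 and p1 must lie strictly between 0 and 1", call. = FALSE)
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  x <- 0:n
  d0 <- dbinom(x, n, p0)
  rel_tol <- 1 + 1e-7
  pval <- vapply(seq_along(x),
                 function(i) sum(d0[d0 <= d0[i] * rel_tol]), numeric(1))
  sum(dbinom(x[pval <= alpha], n, p1))
}

#' Evaluable sample size at a given alteration prevalence
#'
#' @param n_total Total enrolled patients.
#' @param prevalence Expected fraction carrying an informative alteration.
#' @return `round(prevalence * n_total)`.
#' @export
n_evaluable <- function(n_total, prevalence = 0.4) {
  round(prevalence * n_total)
}
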