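#' Unpaired two-sided Student's t-test
#'
#' Classical pooled-variance two-group comparison (the default across the
#' two-group readouts); a Welch variant is available behind `welch`.
#' Degenerate inputs (zero variance in both groups) are handled by
#' convention: equal means give p = 1, different means p = 0, both flagged.
#'
#' @param a,b numeric value vectors (each at least 2 values).
#' @param welch if TRUE use the Welch (unequal-variance) test.
#' @return list: `t`, `df`, `p`, `mean_diff` (mean(b) - mean(a)),
#'   `degenerate` flag.
#' @export
ttestUnpaired <- function(a, b, welch = FALSE) {
  .stopIf(length(a) < 2 || length(b) < 2, "each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf * sign(mean(b) - mean(a)),
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0, mean_diff = mean(b) - mean(a),
                degenerate = TRUE))
  }
  tt <- stats::t.test(b, a, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(b) - mean(a), degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Nonparametric two-group comparison. The p-value is exact (by enumeration
#' of rank allocations) when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction is used. All-tied inputs return p = 1.
#'
#' @param a,b numeric value vectors.
#' @param alternative test sidedness (default two-sided).
#' @return list: `U` (statistic for the first sample), `p`, `exact` flag.
#' @export
mannWhitney <- function(a, b, alternative = "two.sided") {
  .stopIf(length(a) < 1 || length(b) < 1, "each group needs >= 1 value")
  if (length(unique(c(a, b))) == 1L)
    return(list(U = length(a) * length(b) / 2, p = 1, exact = FALSE))
  useExact <- (length(a) + length(b) <= 12) && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = useExact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = useExact)
}

#' Two-way repeated-measures ANOVA (mixed design)
#'
#' Between-subjects factor (e.g. genotype) crossed with a within-subjects
#' factor (e.g. time or task), one value per subject and within-level
#' (balanced complete design; aggregate per-day values first, no imputation
#' here). Fitted via `aov` with a subject error stratum; the between effect
#' is tested against subjects-within-groups, the within and interaction
#' effects against the residual stratum. Degrees of freedom are uncorrected
#' (no sphericity correction), noted in the output.
#'
#' @param data data.frame in long format.
#' @param value,group,subject,within column names.
#' @return data.frame ANOVA table (`effect`, `df`, `ss`, `ms`, `f`, `p`)
#'   with attribute `sphericity = "uncorrected"`.
#' @export
anova2RM <- function(data, value = "value", group = "group",
                     subject = "subject", within = "within") {
  d <- data.frame(value = data[[value]], group = factor(data[[group]]),
                  subject = factor(data[[subject]]),
                  within = factor(data[[within]]))
  .stopIf(anyNA(d$value), "missing cells are not supported (pre-aggregate)")
  tab <- table(d$subject, d$within)
  .stopIf(any(tab != 1L),
          "design must be complete: one value per subject x within-level")
  .stopIf(any(rowSums(table(d$subject, d$group) > 0) != 1L),
          "each subject must belong to exactly one group")
  if (nlevels(d$within) == 1L) {
    fit <- stats::aov(value ~ group, data = d)
    s <- summary(fit)[[1]]
    out <- data.frame(effect = c("group", "residuals"),
                      df = s[["Df"]], ss = s[["Sum Sq"]], ms = s[["Mean Sq"]],
                      f = s[["F value"]], p = s[["Pr(>F)"]])
  } else {
    fit <- stats::aov(value ~ group * within + Error(subject), data = d)
    s <- summary(fit)
    bet <- s[["Error: subject"]][[1]]
    wit <- s[["Error: Within"]][[1]]
    out <- data.frame(
      effect = c("group", "subjects", "within", "group:within", "residuals"),
      df = c(bet[["Df"]], wit[["Df"]]),
      ss = c(bet[["Sum Sq"]], wit[["Sum Sq"]]),
      ms = c(bet[["Mean Sq"]], wit[["Mean Sq"]]),
      f = c(bet[["F value"]], wit[["F value"]]),
      p = c(bet[["Pr(>F)"]], wit[["Pr(>F)"]]))
  }
  attr(out, "sphericity") <- "uncorrected"
  out
}

#' Sidak familywise adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1.
#'
#' @param p raw p-value(s) in `[0, 1]`.
#' @param m number of comparisons in the family.
#' @return adjusted p-value(s).
#' @export
sidakAdjust <- function(p, m = length(p)) {
  .stopIf(m < 1, "m must be at least 1")
  .stopIf(any(p < 0 | p > 1), "p-values must be in [0, 1]")
  pmin(1, 1 - (1 - p)^m)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values with enforced monotonicity (`stats::p.adjust`,
#' method "BH").
#'
#' @param p raw p-values in `[0, 1]`.
#' @return q-values (empty input gives empty output).
#' @export
bhFdr <- function(p) {
  if (!length(p)) return(numeric(0))
  .stopIf(any(p < 0 | p > 1), "p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Dunnett many-to-one adjustment by Monte-Carlo multivariate t
#'
#' Adjusts t-statistics of k treatment-vs-control contrasts for multiplicity
#' under the equicorrelated multivariate-t reference distribution
#' (correlation `rho`, about 1/2 for balanced groups): the adjusted p of a
#' contrast is `P(max_j |T_j| >= |t|)`, estimated from `nDraws` seeded draws.
#' Works for arbitrary k and df; the Monte-Carlo standard error is reported,
#' and adjusted p-values never fall below the raw two-sided p.
#'
#' @param t observed t-statistic(s) of the contrasts.
#' @param df error degrees of freedom.
#' @param k number of contrasts (default `length(t)`).
#' @param rho common correlation between contrasts.
#' @param nDraws Monte-Carlo draws.
#' @param seed integer seed.
#' @return data.frame: `t`, `raw_p`, `adj_p`, `mc_se`.
#' @export
dunnettAdjust <- function(t, df, k = length(t), rho = 0.5, nDraws = 1e5,
                          seed = 1) {
  .stopIf(k < 1, "k must be at least 1")
  .stopIf(df < 1, "df must be at least 1")
  .stopIf(rho < 0 || rho >= 1, "rho must be in [0, 1)")
  set.seed(seed)
  x0 <- stats::rnorm(nDraws)
  maxAbsZ <- rep(-Inf, nDraws)
  for (j in seq_len(k)) {
    z <- sqrt(rho) * x0 + sqrt(1 - rho) * stats::rnorm(nDraws)
    maxAbsZ <- pmax(maxAbsZ, abs(z))
  }
  scale <- sqrt(stats::rchisq(nDraws, df) / df)
  maxAbsT <- maxAbsZ / scale
  rawP <- 2 * stats::pt(-abs(t), df)
  adjP <- vapply(abs(t), function(ti) mean(maxAbsT >= ti), numeric(1))
  adjP <- pmax(adjP, rawP)  # multiplicity property, robust to MC noise
  data.frame(t = t, raw_p = rawP, adj_p = pmin(adjP, 1),
             mc_se = sqrt(adjP * (1 - adjP) / nDraws))
}

#' Dunnett posthoc test against a control group
#'
#' Builds the treatment-vs-control contrasts from a one-way layout (pooled
#' within-group variance) and adjusts them with [dunnettAdjust()].
#'
#' @param values numeric observations.
#' @param group group label per observation.
#' @param control label of the control group.
#' @param nDraws,seed Monte-Carlo settings, see [dunnettAdjust()].
#' @return data.frame with one row per treatment group: `comparison`,
#'   `mean_diff`, `t`, `raw_p`, `adj_p`, `mc_se`.
#' @export
dunnettTest <- function(values, group, control, nDraws = 1e5, seed = 1) {
  group <- as.character(group)
  .stopIf(!control %in% group, "control group '%s' not found", control)
  gs <- split(values, group)
  treatments <- setdiff(names(gs), control)
  .stopIf(!length(treatments), "need at least one treatment group")
  n <- lengths(gs)
  N <- sum(n)
  kG <- length(gs)
  mse <- sum(vapply(gs, function(v) sum((v - mean(v))^2), numeric(1))) /
    (N - kG)
  df <- N - kG
  n0 <- n[[control]]
  tStat <- vapply(treatments, function(g) {
    (mean(gs[[g]]) - mean(gs[[control]])) /
      sqrt(mse * (1 / n[[g]] + 1 / n0))
  }, numeric(1))
  rho <- mean(n[treatments] / (n[treatments] + n0))
  adj <- dunnettAdjust(tStat, df, k = length(treatments), rho = rho,
                       nDraws = nDraws, seed = seed)
  data.frame(comparison = paste(treatments, "-", control),
             mean_diff = vapply(treatments, function(g)
               mean(gs[[g]]) - mean(gs[[control]]), numeric(1)),
             adj, row.names = NULL)
}

#' Auto scaling (unit variance) of a feature table
#'
#' Per column: `(x - mean) / sd`. Constant columns cannot be scaled and are
#' returned as NA, with their names in the `flagged` attribute.
#'
#' @param table numeric matrix or data.frame (samples x features).
#' @return scaled matrix with attribute `flagged`.
#' @export
autoScale <- function(table) {
  m <- as.matrix(table)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  flag <- s == 0
  s[flag] <- NA_real_
  out <- sweep(sweep(m, 2, mu), 2, s, "/")
  attr(out, "flagged") <- colnames(m)[flag]
  out
}

#' Range scaling of a feature table
#'
#' Per column: `(x - mean) / (max - min)`. Constant columns are returned as
#' NA, with their names in the `flagged` attribute.
#'
#' @param table numeric matrix or data.frame (samples x features).
#' @return scaled matrix with attribute `flagged`.
#' @export
rangeScale <- function(table) {
  m <- as.matrix(table)
  mu <- colMeans(m)
  rng <- apply(m, 2, function(x) diff(range(x)))
  flag <- rng == 0
  rng[flag] <- NA_real_
  out <- sweep(sweep(m, 2, mu), 2, rng, "/")
  attr(out, "flagged") <- colnames(m)[flag]
  out
}
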