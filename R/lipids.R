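#' Volcano screening of a two-group lipid table
#'
#' Per species: log2 fold change of group means (test group over reference)
#' and a two-sided pooled t-test, by default on log2-transformed intensities
#' (the lipidomics convention for area-ratio data), plus Benjamini-Hochberg
#' q-values. Positive log2 fold change means higher in the test group.
#'
#' @param x a [LipidTable-class], or a samples x species matrix.
#' @param reference label of the reference group (fold changes are
#'   test/reference). Defaults to the first group level.
#' @param groups group label per sample (required for a plain matrix).
#' @param logTransform if TRUE (default) the t-test runs on log2 intensities.
#' @return data.frame with one row per species: `species`, `log2_fc`, `p`,
#'   `q`, `neg_log10_p`.
#' @export
volcanoTable <- function(x, reference = NULL, groups = NULL,
                         logTransform = TRUE) {
  if (methods::is(x, "LipidTable")) {
    m <- intensities(x)
    groups <- sampleGroups(x)
  } else {
    m <- as.matrix(x)
    .stopIf(is.null(groups), "groups must be given for a plain matrix")
  }
  lv <- unique(groups)
  .stopIf(length(lv) != 2, "need exactly 2 groups")
  if (is.null(reference)) reference <- lv[1]
  .stopIf(!reference %in% lv, "unknown reference group '%s'", reference)
  test <- setdiff(lv, reference)
  aIdx <- groups == reference
  bIdx <- groups == test
  .stopIf(sum(aIdx) < 2 || sum(bIdx) < 2, "need >= 2 samples per group")
  .stopIf(logTransform && any(m <= 0),
          "non-positive intensity with log transform requested")
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("L%03d", seq_len(ncol(m)))
  tm <- if (logTransform) log2(m) else m
  res <- lapply(seq_len(ncol(m)), function(j) {
    p <- ttestUnpaired(tm[aIdx, j], tm[bIdx, j])$p
    data.frame(species = colnames(m)[j],
               log2_fc = log2(mean(m[bIdx, j]) / mean(m[aIdx, j])), p = p)
  })
  out <- do.call(rbind, res)
  out$q <- bhFdr(out$p)
  out$neg_log10_p <- -log10(out$p)
  rownames(out) <- NULL
  out
}

#' Range-normalize values to [0, 1] for scatter display
#'
#' `(x - min) / (max - min)`; used to overlay species with very different
#' absolute intensities in one scatter panel.
#'
#' @param values numeric vector with `max > min`.
#' @return values scaled to `[0, 1]`.
#' @export
rangeNormForPlots <- function(values) {
  r <- range(values)
  .stopIf(r[2] <= r[1], "constant vector cannot be range-normalized")
  (values - r[1]) / (r[2] - r[1])
}
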