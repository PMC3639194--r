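# Chi-square differential expression between two count libraries.

#' Pearson chi-square test on a 2x2 count table
#'
#' Tests the 2x2 table `[[a, a_rest], [b, b_rest]]` (feature vs rest of
#' library, one row per library) with Pearson's chi-square without continuity
#' correction (df = 1). When any expected cell is below 5 the test falls back
#' to Fisher's exact test and says so in `method`.
#'
#' @param a,a_rest feature and remaining counts in library A.
#' @param b,b_rest feature and remaining counts in library B.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @param fisher_fallback fall back to Fisher's exact test when an expected
#'   cell is < 5 (default TRUE).
#' @return list: `chi2` (NA for the Fisher branch), `p`, `method`.
#' @export
chisq_2x2 <- function(a, a_rest, b, b_rest, correct = FALSE,
                      fisher_fallback = TRUE) {
  cells <- c(a, a_rest, b, b_rest)
  if (any(cells < 0)) stop("negative cell count")
  if (a + a_rest <= 0 || b + b_rest <= 0) stop("zero row total")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (fisher_fallback && any(expected < 5)) {
    p <- stats::fisher.test(round(tab))$p.value
    return(list(chi2 = NA_real_, p = min(p, 1), method = "fisher"))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value), method = "chi-square")
}

#' Differential expression between two libraries
#'
#' One chi-square (or Fisher fallback) test per feature with a + b > 0,
#' Benjamini-Hochberg adjustment across the tested features, and a combined
#' significance call `p_adj < alpha & |log2fc| >= min_abs_log2fc`. Counts are
#' normalized to counts per million for reporting; a pseudocount of 0.5 is
#' added to both normalized values for the fold change only (never for the
#' test) when either raw count is zero.
#'
#' @param counts matrix or data.frame of feature counts with feature names as
#'   row names and library ids as columns, or a tag table.
#' @param pair character vector of two library ids `(A, B)`.
#' @param totals named totals per library. Defaults to the tag table's
#'   `total_reads` when `counts` is a tag table, else to column sums.
#' @param alpha BH-adjusted significance level (default 0.01).
#' @param min_abs_log2fc minimum absolute log2 fold change (default 1).
#' @param correct continuity correction, passed to [chisq_2x2()].
#' @return data.frame: `feature`, `a`, `b`, `cpm_a`, `cpm_b`, `log2fc`,
#'   `chi2`, `p`, `p_adj`, `method`, `significant`. The log2 fold change is
#'   oriented B over A.
#' @export
call_differential <- function(counts, pair, totals = NULL, alpha = 0.01,
                              min_abs_log2fc = 1, correct = FALSE) {
  stopifnot(length(pair) == 2L)
  if (inherits(counts, "tag_table")) {
    if (is.null(totals)) {
      libs <- tag_libraries(counts)
      totals <- setNames(libs$total_reads, libs$id)
    }
    counts <- tag_counts(counts)
  }
  counts <- as.matrix(counts)
  missing <- setdiff(pair, colnames(counts))
  if (length(missing)) stop("unknown library id(s): ", paste(missing, collapse = ", "))
  if (is.null(totals)) totals <- colSums(counts)
  nA <- unname(totals[pair[1]]); nB <- unname(totals[pair[2]])
  a <- counts[, pair[1]]; b <- counts[, pair[2]]
  feats <- rownames(counts)
  if (is.null(feats)) feats <- as.character(seq_len(nrow(counts)))
  keep <- (a + b) > 0
  a <- a[keep]; b <- b[keep]; feats <- feats[keep]
  n <- length(a)
  chi2 <- p <- numeric(n)
  method <- character(n)
  for (i in seq_len(n)) {
    r <- chisq_2x2(a[i], nA - a[i], b[i], nB - b[i], correct = correct)
    chi2[i] <- if (is.null(r$chi2)) NA_real_ else r$chi2
    p[i] <- r$p
    method[i] <- r$method
  }
  cpm_a <- 1e6 * a / nA
  cpm_b <- 1e6 * b / nB
  pseudo <- (a == 0) | (b == 0)
  log2fc <- ifelse(pseudo,
                   log2((cpm_b + 0.5) / (cpm_a + 0.5)),
                   log2(cpm_b / cpm_a))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(feature = feats, a = a, b = b, cpm_a = cpm_a, cpm_b = cpm_b,
             log2fc = log2fc, chi2 = chi2, p = p, p_adj = p_adj,
             method = method,
             significant = p_adj < alpha & abs(log2fc) >= min_abs_log2fc,
             row.names = NULL, stringsAsFactors = FALSE)
}
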