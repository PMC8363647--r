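#' Chi-squared enrichment test for a binary feature
#'
#' Compares the rate of a binary transcript feature (e.g. "has a uORF")
#' between a gene list and the background (by convention the rest of the
#' chip). Builds the 2x2 table, computes Pearson's chi-squared statistic
#' (no continuity correction by default) with its two-sided p-value, plus
#' the sample odds ratio (a*d)/(b*c).
#'
#' @param list_a character vector, the gene list of interest.
#' @param background character vector, the comparison set (typically
#'   `setdiff(universe, list_a)`).
#' @param feature_flags named logical vector (gene -> feature present).
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return one-row data.frame: `feature_in_list`, `list_size`,
#'   `feature_in_bg`, `bg_size`, `statistic`, `p`, `odds_ratio`,
#'   `direction`. Zero margins give `p = NA` and `direction =
#'   "untestable"`.
#' @export
binary_feature_test <- function(list_a, background, feature_flags,
                                correct = FALSE) {
  fa <- feature_flags[list_a]
  fb <- feature_flags[background]
  if (anyNA(fa) || anyNA(fb)) stop("feature_flags must cover all genes")
  a <- sum(fa); b <- sum(!fa)
  c_ <- sum(fb); d <- sum(!fb)
  tab <- matrix(c(a, b, c_, d), 2)
  res <- data.frame(feature_in_list = a, list_size = a + b,
                    feature_in_bg = c_, bg_size = c_ + d,
                    statistic = NA_real_, p = NA_real_,
                    odds_ratio = NA_real_, direction = "untestable",
                    stringsAsFactors = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(res)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  res$statistic <- unname(ct$statistic)
  res$p <- ct$p.value
  res$odds_ratio <- if (b > 0 && c_ > 0) (a * d) / (b * c_) else Inf
  ra <- a / (a + b); rb <- c_ / (c_ + d)
  res$direction <- if (ra >= rb) "enriched" else "depleted"
  res
}

#' Welch t-test for a continuous feature
#'
#' Compares the mean of a continuous transcript feature (5'UTR length,
#' folding score) between a gene list and the background with an unpaired
#' two-sided Welch two-sample t-test.
#'
#' @param list_a,background gene id vectors.
#' @param values named numeric vector (gene -> value).
#' @return one-row data.frame: `mean_list`, `mean_bg`, `statistic`
#'   (t value), `p`, `direction` (`"higher"`/`"lower"` in the list).
#' @export
continuous_feature_test <- function(list_a, background, values) {
  va <- values[list_a]
  vb <- values[background]
  if (anyNA(va) || anyNA(vb)) stop("values must cover all genes")
  if (length(va) < 2 || length(vb) < 2)
    stop("need at least two values per group")
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    if (mean(va) == mean(vb)) {
      return(data.frame(mean_list = mean(va), mean_bg = mean(vb),
                        statistic = 0, p = 1, direction = "higher",
                        stringsAsFactors = FALSE))
    }
    stop("degenerate variance in both groups")
  }
  tt <- stats::t.test(va, vb)
  data.frame(mean_list = mean(va), mean_bg = mean(vb),
             statistic = unname(tt$statistic), p = tt$p.value,
             direction = if (mean(va) >= mean(vb)) "higher" else "lower",
             stringsAsFactors = FALSE)
}

#' Run the full feature-enrichment panel on a gene list
#'
#' Applies the chi-squared test to the binary features (TOP/TOP-like,
#' uORF presence, ARE presence, TISU) and the Welch t-test to the
#' continuous ones (5'UTR length, folding score), list vs the rest of
#' the chip.
#'
#' @param list_a gene list (e.g. the UP list).
#' @param features a `feature_table` from [annotate_transcripts()]
#'   covering the whole chip.
#' @return data.frame, one row per feature, with `feature`, `test`,
#'   `statistic`, `p`, `odds_ratio` (NA for t-tests), `direction`.
#' @export
feature_enrichment_panel <- function(list_a, features) {
  universe <- features$gene_id
  bg <- setdiff(universe, list_a)
  flags <- list(
    top = stats::setNames(features$top_class != "none", universe),
    uorf = stats::setNames(features$n_uorf > 0, universe),
    are = stats::setNames(features$n_are > 0, universe),
    tisu = stats::setNames(features$tisu, universe))
  vals <- list(
    utr5_len = stats::setNames(features$utr5_len, universe),
    utr5_mfe = stats::setNames(features$utr5_mfe, universe))
  rows <- list()
  for (f in names(flags)) {
    r <- binary_feature_test(list_a, bg, flags[[f]])
    rows[[f]] <- data.frame(feature = f, test = "chisq",
                            statistic = r$statistic, p = r$p,
                            odds_ratio = r$odds_ratio,
                            direction = r$direction,
                            stringsAsFactors = FALSE)
  }
  for (f in names(vals)) {
    r <- continuous_feature_test(list_a, bg, vals[[f]])
    rows[[f]] <- data.frame(feature = f, test = "t",
                            statistic = r$statistic, p = r$p,
                            odds_ratio = NA_real_, direction = r$direction,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' GO-term over-representation by Fisher's exact test
#'
#' For every term, counts annotated genes in the query list versus a
#' reference list, tests independence with Fisher's exact test (two-sided)
#' and reports the sample odds ratio. Terms annotating no gene in either
#' set are skipped.
#'
#' @param list_a query gene list.
#' @param reference reference gene list (defaults in callers to the whole
#'   universe).
#' @param annotation data.frame with columns `gene_id`, `term` (one pair
#'   per row).
#' @param correction `"none"` (default; raw p-values) or `"BH"`.
#' @return data.frame sorted by p: `term`, `in_list`, `list_size`,
#'   `in_ref`, `ref_size`, `odds_ratio`, `p` (+ `adjusted_p` under BH).
#' @export
go_overrepresentation <- function(list_a, reference, annotation,
                                  correction = c("none", "BH")) {
  correction <- match.arg(correction)
  if (!nrow(annotation)) stop("empty annotation map")
  ann <- annotation[annotation$gene_id %in% union(list_a, reference), ]
  by_term <- split(ann$gene_id, ann$term)
  if (!length(by_term) || !any(unlist(by_term) %in% list_a))
    stop("annotation map covers no gene of the query list")
  nA <- length(list_a); nR <- length(reference)
  rows <- lapply(names(by_term), function(tm) {
    genes <- unique(by_term[[tm]])
    a <- sum(list_a %in% genes)
    c_ <- sum(reference %in% genes)
    if (a == 0 && c_ == 0) return(NULL)
    b <- nA - a; d <- nR - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    or <- if (b > 0 && c_ > 0) (a * d) / (b * c_) else Inf
    data.frame(term = tm, in_list = a, list_size = nA,
               in_ref = c_, ref_size = nR, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$term), , drop = FALSE]
  if (correction == "BH") out$adjusted_p <- stats::p.adjust(out$p, "BH")
  row.names(out) <- NULL
  out
}
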