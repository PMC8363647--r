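#' All-pairs tumour-vs-control fold-change matrix
#'
#' For an unpaired two-class design every tumour array is compared with
#' every control array: column (t, c) holds \eqn{d_g = M_{g,t} - M_{g,c}},
#' the per-gene log2 fold change of polysomal association.
#'
#' @param m an `mvalue_table` from [compute_m_values()], or a list with a
#'   gene x array matrix `M` and `metadata` containing `array_id`, `group`.
#' @return object of class `fc_matrix`: list with `d` (gene x comparison
#'   matrix) and `pairs` (data.frame of tumour/control array ids).
#' @export
pairwise_fold_changes <- function(m) {
  md <- m$metadata
  if (is.null(md$group) || anyNA(md$group)) stop("missing group labels")
  t_idx <- which(md$group == "tumour")
  c_idx <- which(md$group == "control")
  if (!length(t_idx) || !length(c_idx))
    stop("need at least one tumour and one control array")
  pairs <- expand.grid(control = c_idx, tumour = t_idx,
                       KEEP.OUT.ATTRS = FALSE)[, c("tumour", "control")]
  d <- m$M[, pairs$tumour, drop = FALSE] - m$M[, pairs$control, drop = FALSE]
  prov <- data.frame(tumour = md$array_id[pairs$tumour],
                     control = md$array_id[pairs$control],
                     stringsAsFactors = FALSE)
  colnames(d) <- paste(prov$tumour, prov$control, sep = ".vs.")
  if (any(!is.finite(d))) stop("fold-change matrix contains non-finite values")
  structure(list(d = d, pairs = prov), class = "fc_matrix")
}

# per-column ranks, 1 = most extreme in the requested direction,
# ties get the average rank
.rank_columns <- function(d, direction) {
  s <- if (direction == "up") -d else d
  apply(s, 2, rank, ties.method = "average")
}

#' Rank product of a fold-change matrix
#'
#' Within each comparison genes are ranked 1 = most extreme in the
#' requested direction (largest fold change for `"up"`, smallest for
#' `"down"`), ties receiving the average rank. The rank product is the
#' geometric mean of a gene's ranks across comparisons; small values flag
#' consistently extreme genes.
#'
#' @param fc an `fc_matrix` from [pairwise_fold_changes()] (or a plain
#'   numeric matrix of per-comparison log2 fold changes).
#' @param direction `"up"` or `"down"`.
#' @return named numeric vector of per-gene rank products, in `[1, G]`.
#' @export
rank_product <- function(fc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  d <- if (inherits(fc, "fc_matrix")) fc$d else as.matrix(fc)
  r <- .rank_columns(d, direction)
  if (is.null(dim(r))) r <- matrix(r, ncol = ncol(d))  # single-gene guard
  rp <- exp(rowMeans(log(r)))
  names(rp) <- rownames(d)
  rp
}

#' Permutation p-values and pfp for rank products
#'
#' The null distribution is obtained by independently permuting every
#' comparison column across genes and recomputing rank products; because
#' within-column ranks are fixed, this is equivalent to randomly permuting
#' each column's rank vector. The p-value of gene g is the (smoothed)
#' fraction of null rank products at or below its observed one,
#' \eqn{p_g = (1 + \#\{RP_{null} \le RP_g\}) / (1 + n_{perm} G)},
#' and the percentage of false prediction is
#' \eqn{pfp_g = p_g \cdot G / rank_g} with \eqn{rank_g} the gene's position
#' in the sorted list.
#'
#' With `exhaustive = TRUE` the null is enumerated over all column
#' permutations exactly (pooled over genes every permutation reduces to an
#' independent draw of one rank per column, so the exhaustive null is the
#' full product grid of the k rank vectors, G^k combinations); p-values
#' are then exact tail probabilities without smoothing. Feasible for small
#' G and k only.
#'
#' Two sampling schemes are available. `"column"` (the classical
#' rank-product null) permutes every comparison column independently; it
#' treats the k comparisons as independent, which they are not when the
#' same arrays are reused across all tumour x control pairs, making the
#' scheme anticonservative for all-pairs designs. `"label"` permutes the
#' tumour/control labels across arrays and rebuilds the fold-change
#' matrix, preserving the within-array dependence; it is the calibrated
#' null for the unpaired all-pairs design and requires the `m` argument.
#'
#' @param fc an `fc_matrix` or numeric matrix of log2 fold changes.
#' @param n_perm number of random permutations (ignored when exhaustive).
#' @param seed integer seed for the permutation stream (required unless
#'   exhaustive).
#' @param direction `"up"` or `"down"`.
#' @param exhaustive enumerate the complete permutation null instead of
#'   sampling (guarded to G^k <= 2e6; `"column"` scheme only).
#' @param null_scheme `"column"` (classical) or `"label"` (array-label
#'   permutation).
#' @param m the `mvalue_table` behind `fc`; required for the `"label"`
#'   scheme.
#' @return data.frame with columns `gene`, `rp`, `rank`, `pval`, `pfp`.
#' @export
permutation_pfp <- function(fc, n_perm = 1000, seed = NULL,
                            direction = c("up", "down"),
                            exhaustive = FALSE,
                            null_scheme = c("column", "label"), m = NULL) {
  direction <- match.arg(direction)
  null_scheme <- match.arg(null_scheme)
  d <- if (inherits(fc, "fc_matrix")) fc$d else as.matrix(fc)
  G <- nrow(d)
  k <- ncol(d)
  r <- .rank_columns(d, direction)
  if (is.null(dim(r))) r <- matrix(r, ncol = k)
  logr <- log(r)
  obs <- rowSums(logr)                     # k * log RP
  eps <- 1e-9
  if (exhaustive) {
    if (null_scheme != "column")
      stop("exhaustive enumeration is defined for the column scheme")
    if (G^k > 2e6) stop("exhaustive null too large (G^k > 2e6)")
    null_sum <- 0
    for (j in seq_len(k)) null_sum <- as.vector(outer(null_sum, logr[, j], "+"))
    null_sum <- sort(null_sum)
    cnt <- findInterval(obs + eps, null_sum)
    pval <- cnt / length(null_sum)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    if (is.null(seed)) stop("seed is required for the permutation null")
    set.seed(as.integer(seed))
    ord <- order(obs)
    obs_sorted <- obs[ord] + eps
    if (null_scheme == "column") {
      cnt_sorted <- rp_null_counts_column(logr, obs_sorted, as.integer(n_perm))
    } else {
      if (is.null(m)) stop("null_scheme = 'label' needs the mvalue_table (m)")
      md <- m$metadata
      M <- m$M[, c(which(md$group == "tumour"), which(md$group == "control")),
               drop = FALSE]
      cnt_sorted <- rp_null_counts_label(M, sum(md$group == "tumour"),
                                         as.integer(n_perm),
                                         if (direction == "up") -1 else 1,
                                         obs_sorted)
    }
    cnt <- numeric(G)
    cnt[ord] <- cnt_sorted
    pval <- (1 + cnt) / (1 + n_perm * G)
  }
  rp <- exp(obs / k)
  rk <- rank(rp, ties.method = "first")
  data.frame(gene = if (is.null(rownames(d))) as.character(seq_len(G)) else rownames(d),
             rp = rp, rank = rk, pval = pval, pfp = pval * G / rk,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided rank-product differential-translation test
#'
#' Runs [permutation_pfp()] in both directions on the all-pairs
#' fold-change matrix and reports, per gene, the linear fold change
#' (2^mean log2 difference) together with UP and DOWN ranks, p-values and
#' pfp values. Every gene appears in both lists.
#'
#' @inheritParams permutation_pfp
#' @param monotone_pfp also report cumulative-min (monotonized) pfp
#'   columns `pfp_up_mono` / `pfp_down_mono` (the raw definition stays the
#'   reported default).
#' @return data.frame of class `rankprod_result` with columns `gene`,
#'   `FC`, `rank_up`, `rp_up`, `pval_up`, `pfp_up`, `rank_down`, `rp_down`,
#'   `pval_down`, `pfp_down`.
#' @export
rank_product_test <- function(fc, n_perm = 1000, seed = NULL,
                              exhaustive = FALSE, monotone_pfp = FALSE,
                              null_scheme = c("column", "label"), m = NULL) {
  null_scheme <- match.arg(null_scheme)
  d <- if (inherits(fc, "fc_matrix")) fc$d else as.matrix(fc)
  up <- permutation_pfp(fc, n_perm, seed, "up", exhaustive, null_scheme, m)
  dn <- permutation_pfp(fc, n_perm,
                        if (is.null(seed)) NULL else as.integer(seed) + 1L,
                        "down", exhaustive, null_scheme, m)
  res <- data.frame(gene = up$gene,
                    FC = 2^rowMeans(d),
                    rank_up = up$rank, rp_up = up$rp,
                    pval_up = up$pval, pfp_up = up$pfp,
                    rank_down = dn$rank, rp_down = dn$rp,
                    pval_down = dn$pval, pfp_down = dn$pfp,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (monotone_pfp) {
    res$pfp_up_mono <- .monotonize(res$pfp_up, res$rank_up)
    res$pfp_down_mono <- .monotonize(res$pfp_down, res$rank_down)
  }
  class(res) <- c("rankprod_result", "data.frame")
  res
}

.monotonize <- function(pfp, rk) {
  o <- order(rk, decreasing = TRUE)
  out <- numeric(length(pfp))
  out[o] <- cummin(pfp[o])
  out
}

#' Select significantly regulated genes
#'
#' A gene is called UP when its linear fold change is at least
#' `fc_threshold` and its UP pfp is strictly below `pfp_threshold`;
#' DOWN symmetrically with FC at most `1/fc_threshold`.
#'
#' @param res a `rankprod_result`.
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param pfp_threshold pfp threshold (default 0.2, strict `<`).
#' @return list with character vectors `up` and `down`, each sorted by
#'   list rank.
#' @export
significant_genes <- function(res, fc_threshold = 2, pfp_threshold = 0.2) {
  if (fc_threshold <= 0 || pfp_threshold <= 0) stop("thresholds must be > 0")
  up <- res[res$FC >= fc_threshold & res$pfp_up < pfp_threshold, ]
  dn <- res[res$FC <= 1 / fc_threshold & res$pfp_down < pfp_threshold, ]
  list(up = up$gene[order(up$rank_up)],
       down = dn$gene[order(dn$rank_down)])
}

#' Two-arm volcano table
#'
#' Emits every gene twice: once on the UP arm with its probability of
#' being upregulated and once on the DOWN arm with its probability of
#' being downregulated.
#'
#' @param res a `rankprod_result`.
#' @return data.frame with columns `gene`, `FC`, `neg_log10_p`, `arm`.
#' @export
volcano_table <- function(res) {
  rbind(
    data.frame(gene = res$gene, FC = res$FC,
               neg_log10_p = -log10(res$pval_up), arm = "up",
               stringsAsFactors = FALSE),
    data.frame(gene = res$gene, FC = res$FC,
               neg_log10_p = -log10(res$pval_down), arm = "down",
               stringsAsFactors = FALSE)
  )
}

#' Pearson correlation distance between arrays
#'
#' @param m an `mvalue_table` (or matrix with arrays in columns).
#' @return symmetric array x array matrix of `1 - Pearson r`.
#' @export
pearson_distance_matrix <- function(m) {
  M <- if (inherits(m, "mvalue_table")) m$M else as.matrix(m)
  if (ncol(M) < 2) stop("need at least two arrays")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(M)[sds == 0]
    stop("zero-variance array: ", paste(bad, collapse = ", "))
  }
  D <- 1 - stats::cor(M)
  diag(D) <- 0
  D
}

#' Average-linkage clustering of arrays on Pearson distance
#'
#' @param m an `mvalue_table` or matrix with arrays in columns.
#' @return an [stats::hclust] merge tree.
#' @export
cluster_arrays <- function(m) {
  D <- pearson_distance_matrix(m)
  stats::hclust(stats::as.dist(D), method = "average")
}
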