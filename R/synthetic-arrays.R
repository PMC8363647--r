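#' Simulation design for a synthetic polysome-profiling experiment
#'
#' Encodes the study design being emulated: two-colour arrays with dye
#' swaps, 8 tumour and 2 control samples with 3 repeats each, a planted
#' fraction of genes with shifted polysomal/subpolysomal ratio, and an
#' additive-normal-background + exponential-signal intensity model (so
#' the normexp correction is well specified on synthetic data).
#'
#' @param n_genes number of genes (default 500).
#' @param n_tumour_samples,n_control_samples biological samples per group
#'   (defaults 8 and 2).
#' @param n_repeats arrays per sample (default 3).
#' @param frac_up,frac_down fractions of genes planted with increased /
#'   decreased polysomal association (defaults 0.10 and 0.05).
#' @param effect_log2 planted M-value shift in log2 units (default 2).
#' @param noise_sd per-gene, per-array Gaussian noise on M (default 0.5).
#' @param background_mean,background_sd additive normal background on
#'   intensities (defaults 80, 12).
#' @param signal_scale mean of the exponential true-signal component
#'   (default 2000).
#' @param baseline_sdlog sd of the per-gene log-normal baseline abundance
#'   multiplier, creating a realistic intensity dynamic range (default 0.3).
#' @param dye_swap_repeats which repeat indices are dye-swapped
#'   (default 2: the middle repeat of each sample).
#' @param seed integer seed.
#' @return object of class `sim_design`.
#' @export
sim_design <- function(n_genes = 500, n_tumour_samples = 8,
                       n_control_samples = 2, n_repeats = 3,
                       frac_up = 0.10, frac_down = 0.05,
                       effect_log2 = 2, noise_sd = 0.5,
                       background_mean = 80, background_sd = 12,
                       signal_scale = 2000, baseline_sdlog = 0.3,
                       dye_swap_repeats = 2, seed = 1) {
  if (frac_up + frac_down > 1) stop("frac_up + frac_down must be <= 1")
  if (min(n_genes, n_tumour_samples, n_control_samples, n_repeats) < 1)
    stop("all counts must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (signal_scale <= 0 || background_sd <= 0) stop("scales must be > 0")
  structure(as.list(environment()), class = "sim_design")
}

#' Plant the differential-translation ground truth
#'
#' Assigns `up` / `down` / `null` status to each gene: the first
#' `round(frac_up * n_genes)` genes are up, the next block down, the rest
#' null (gene order is arbitrary, so a deterministic assignment loses no
#' generality).
#'
#' @param design a [sim_design()].
#' @return data.frame with columns `gene_id`, `status`.
#' @export
plant_truth <- function(design) {
  G <- design$n_genes
  n_up <- round(design$frac_up * G)
  n_dn <- round(design$frac_down * G)
  status <- rep("null", G)
  if (n_up > 0) status[seq_len(n_up)] <- "up"
  if (n_dn > 0) status[n_up + seq_len(n_dn)] <- "down"
  data.frame(gene_id = sprintf("g%04d", seq_len(G)), status = status,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-colour array experiment
#'
#' Intensity model per gene, array and channel:
#' truncated-normal background plus an exponential signal whose mean is a
#' per-gene log-normal baseline times `signal_scale`, split between the
#' polysome channel (scaled by \eqn{2^{M/2}}) and the subpolysome channel
#' (scaled by \eqn{2^{-M/2}}). The per-array true M is 0 for null genes
#' and \eqn{\pm}`effect_log2` for planted genes on tumour arrays, plus
#' N(0, `noise_sd`) noise. Dye-swapped arrays have their channels
#' exchanged; metadata records group, sample, replicate and dye swap.
#'
#' @param design a [sim_design()].
#' @param truth optional truth table from [plant_truth()] (generated from
#'   the design when omitted).
#' @return list with `experiment` (an [array_experiment()]), `truth`, and
#'   `true_m` (the gene x array matrix of noiseless planted M values).
#' @export
gen_array_experiment <- function(design, truth = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (is.null(truth)) truth <- plant_truth(design)
  set.seed(design$seed)
  G <- design$n_genes
  samples <- c(sprintf("T%d", seq_len(design$n_tumour_samples)),
               sprintf("C%d", seq_len(design$n_control_samples)))
  groups <- rep(c("tumour", "control"),
                c(design$n_tumour_samples, design$n_control_samples))
  md <- do.call(rbind, lapply(seq_along(samples), function(i) {
    data.frame(array_id = sprintf("%s_r%d", samples[i], seq_len(design$n_repeats)),
               sample_id = samples[i], group = groups[i],
               replicate = seq_len(design$n_repeats),
               dye_swap = seq_len(design$n_repeats) %in% design$dye_swap_repeats,
               stringsAsFactors = FALSE)
  }))
  n_arr <- nrow(md)
  mu_g <- ifelse(truth$status == "up", design$effect_log2,
                 ifelse(truth$status == "down", -design$effect_log2, 0))
  base_g <- design$signal_scale * exp(stats::rnorm(G, 0, design$baseline_sdlog))
  red <- green <- true_m <- matrix(0, G, n_arr)
  for (a in seq_len(n_arr)) {
    m_true <- if (md$group[a] == "tumour") mu_g else rep(0, G)
    m_arr <- m_true + stats::rnorm(G, 0, design$noise_sd)
    s0 <- stats::rexp(G, rate = 1 / base_g)
    poly <- s0 * 2^(m_arr / 2)
    subp <- s0 * 2^(-m_arr / 2)
    bg1 <- pmax(stats::rnorm(G, design$background_mean, design$background_sd), 0)
    bg2 <- pmax(stats::rnorm(G, design$background_mean, design$background_sd), 0)
    # a dye swap exchanges the composed channels wholesale, so a swapped
    # array is the exact channel-exchanged twin of its unswapped version
    ch1 <- bg1 + poly
    ch2 <- bg2 + subp
    if (md$dye_swap[a]) {
      red[, a] <- ch2
      green[, a] <- ch1
    } else {
      red[, a] <- ch1
      green[, a] <- ch2
    }
    true_m[, a] <- m_true
  }
  exp <- array_experiment(truth$gene_id, red, green, md)
  dimnames(true_m) <- list(truth$gene_id, md$array_id)
  list(experiment = exp, truth = truth, true_m = true_m)
}

#' Generate a synthetic GO annotation map
#'
#' Assigns genes to invented GO-like terms. Background terms annotate
#' genes at a uniform rate; `n_enriched` terms annotate genes planted as
#' `up` at `enrich_factor` times the background rate, emulating the
#' functional coherence of a translationally upregulated set.
#'
#' @param truth truth table from [plant_truth()].
#' @param n_terms total number of terms (default 30).
#' @param base_rate annotation probability per gene per term (default 0.05).
#' @param n_enriched number of up-enriched terms (default 3).
#' @param enrich_factor rate multiplier for up genes in enriched terms
#'   (default 3).
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `term`.
#' @export
gen_go_map <- function(truth, n_terms = 30, base_rate = 0.05,
                       n_enriched = 3, enrich_factor = 3, seed = 1) {
  set.seed(as.integer(seed))
  terms <- sprintf("GO:SYN%04d", seq_len(n_terms))
  rows <- lapply(seq_len(n_terms), function(t) {
    rate <- rep(base_rate, nrow(truth))
    if (t <= n_enriched)
      rate[truth$status == "up"] <- pmin(base_rate * enrich_factor, 1)
    hit <- stats::runif(nrow(truth)) < rate
    if (!any(hit)) return(NULL)
    data.frame(gene_id = truth$gene_id[hit], term = terms[t],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
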