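#' Fit the normal + exponential convolution model by moments
#'
#' Models one channel's foreground intensities as \eqn{X = B + S} with
#' background \eqn{B \sim N(\mu, \sigma^2)} and true signal
#' \eqn{S \sim Exp(mean = \alpha)}. The fit is closed-form
#' method-of-moments: the third central moment of the convolution is
#' \eqn{2\alpha^3} (the normal part is symmetric), the variance is
#' \eqn{\sigma^2 + \alpha^2} and the mean is \eqn{\mu + \alpha}.
#'
#' If the implied background variance is non-positive (data skewed enough
#' that the exponential component absorbs all the variance), the fit falls
#' back to a nominal narrow background, \eqn{\sigma = 0.1\alpha}, and
#' re-derives \eqn{\mu} from the mean.
#'
#' @param x numeric vector of foreground intensities (one channel, one
#'   array); at least 50 finite, non-negative values.
#' @return an object of class `normexp_params`: list with elements `mu`,
#'   `sigma`, `alpha`.
#' @examples
#' set.seed(1)
#' x <- pmax(rnorm(5000, 100, 15), 0) + rexp(5000, 1 / 200)
#' fit_normexp(x)
#' @export
fit_normexp <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("intensities must be finite")
  if (any(x < 0)) stop("intensities must be non-negative")
  if (length(x) < 50L) stop("need at least 50 intensities to fit normexp")
  m1 <- mean(x)
  v <- mean((x - m1)^2)
  m3 <- mean((x - m1)^3)
  if (v <= 0) stop("zero variance: cannot fit normexp to constant intensities")
  if (m3 <= 0) {
    stop("non-positive skewness: intensities carry no exponential signal component")
  }
  alpha <- (m3 / 2)^(1 / 3)
  sigma2 <- v - alpha^2
  if (sigma2 <= 0) {
    sigma <- 0.1 * alpha
  } else {
    sigma <- sqrt(sigma2)
  }
  mu <- m1 - alpha
  structure(list(mu = mu, sigma = sigma, alpha = alpha),
            class = "normexp_params")
}

#' @export
print.normexp_params <- function(x, ...) {
  cat(sprintf("normexp parameters: mu = %.4g, sigma = %.4g, alpha = %.4g\n",
              x$mu, x$sigma, x$alpha))
  invisible(x)
}

#' Background-correct intensities under the normexp model
#'
#' Returns the posterior mean of the true signal given the observation,
#' \eqn{E[S | X = x]}, under the normal background + exponential signal
#' convolution. With \eqn{m = x - \mu - \sigma^2/\alpha} the conditional
#' expectation is \eqn{m + \sigma \phi(m/\sigma) / \Phi(m/\sigma)}. The
#' Mills-ratio term is evaluated in log space so the result stays accurate
#' (and strictly positive) far into the left tail.
#'
#' @param x numeric vector of observed intensities.
#' @param params a `normexp_params` object (or list with `mu`, `sigma`,
#'   `alpha`).
#' @return corrected signal estimates, strictly positive, same length as
#'   `x`, monotone non-decreasing in `x`.
#' @export
normexp_correct <- function(x, params) {
  if (any(!is.finite(x))) stop("non-finite intensity passed to normexp_correct")
  mu <- params$mu
  sigma <- params$sigma
  alpha <- params$alpha
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  m <- x - mu - sigma^2 / alpha
  z <- m / sigma
  # Mills ratio phi(z)/Phi(z) via log-space dnorm/pnorm: stable for z << 0
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  out <- m + sigma * mills
  # z + mills(z) > 0 analytically; guard against rounding at extreme z
  pmax(out, .Machine$double.xmin)
}

#' Construct a two-colour array experiment container
#'
#' @param probe_id character vector of probe identifiers.
#' @param red_fg,green_fg numeric matrices (probe x array) of red / green
#'   foreground intensities.
#' @param metadata data.frame with one row per array and columns
#'   `array_id`, `sample_id`, `group` (`"tumour"` or `"control"`),
#'   `replicate`, `dye_swap` (logical). On a dye-swapped array the red
#'   channel carries the subpolysomal pool.
#' @return an object of class `array_experiment`.
#' @export
array_experiment <- function(probe_id, red_fg, green_fg, metadata) {
  red_fg <- as.matrix(red_fg)
  green_fg <- as.matrix(green_fg)
  if (!identical(dim(red_fg), dim(green_fg)))
    stop("red and green matrices must have identical dimensions")
  if (length(probe_id) != nrow(red_fg))
    stop("probe_id length must match intensity rows")
  need <- c("array_id", "sample_id", "group", "replicate", "dye_swap")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (nrow(metadata) != ncol(red_fg))
    stop("metadata rows must match number of arrays")
  if (min(red_fg) < 0 || min(green_fg) < 0) stop("intensities must be >= 0")
  if (!any(metadata$group == "tumour") || !any(metadata$group == "control"))
    stop("need at least one tumour and one control array")
  colnames(red_fg) <- colnames(green_fg) <- metadata$array_id
  structure(list(probe_id = as.character(probe_id),
                 red_fg = red_fg, green_fg = green_fg,
                 metadata = as.data.frame(metadata)),
            class = "array_experiment")
}

#' @export
print.array_experiment <- function(x, ...) {
  cat(sprintf("array_experiment: %d probes x %d arrays (%d tumour, %d control)\n",
              length(x$probe_id), nrow(x$metadata),
              sum(x$metadata$group == "tumour"),
              sum(x$metadata$group == "control")))
  invisible(x)
}

#' Compute dye-swap-aware M-values from a two-colour experiment
#'
#' Each channel of each array is background-corrected with its own
#' moment-fitted normexp model, then M = log2(red/green) is formed and
#' negated on dye-swapped arrays so that M always means
#' log2(polysome/subpolysome). Probes mapping to the same gene are
#' averaged (arithmetic mean of M).
#'
#' @param exp an [array_experiment()].
#' @param probe_map optional data.frame with columns `probe_id`, `gene_id`;
#'   by default probes are genes (identity map).
#' @param center logical; subtract the per-array median M (off by default).
#' @return an object of class `mvalue_table`: list with `M` (gene x array
#'   matrix), `metadata`, and the per-array fitted `normexp` parameters.
#' @export
compute_m_values <- function(exp, probe_map = NULL, center = FALSE) {
  if (!inherits(exp, "array_experiment")) stop("exp must be an array_experiment")
  md <- exp$metadata
  if (anyNA(md$dye_swap) || anyNA(md$group)) stop("array metadata incomplete")
  n_arr <- nrow(md)
  Mp <- matrix(NA_real_, length(exp$probe_id), n_arr,
               dimnames = list(exp$probe_id, md$array_id))
  fits <- vector("list", n_arr)
  names(fits) <- md$array_id
  for (a in seq_len(n_arr)) {
    pr <- fit_normexp(exp$red_fg[, a])
    pg <- fit_normexp(exp$green_fg[, a])
    r <- normexp_correct(exp$red_fg[, a], pr)
    g <- normexp_correct(exp$green_fg[, a], pg)
    m <- log2(r / g)
    if (md$dye_swap[a]) m <- -m
    Mp[, a] <- m
    fits[[a]] <- list(red = pr, green = pg)
  }
  if (is.null(probe_map)) {
    gene <- exp$probe_id
  } else {
    idx <- match(exp$probe_id, probe_map$probe_id)
    if (anyNA(idx)) stop("probe_map does not cover all probes")
    gene <- as.character(probe_map$gene_id[idx])
  }
  M <- rowsum(Mp, gene, reorder = FALSE) / as.vector(table(factor(gene, levels = unique(gene))))
  if (center) M <- sweep(M, 2, apply(M, 2, stats::median))
  stopifnot(all(is.finite(M)))
  structure(list(M = M, metadata = md, normexp = fits), class = "mvalue_table")
}

#' @export
print.mvalue_table <- function(x, ...) {
  cat(sprintf("mvalue_table: %d genes x %d arrays\n", nrow(x$M), ncol(x$M)))
  invisible(x)
}
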