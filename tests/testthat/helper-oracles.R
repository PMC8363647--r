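# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# all permutations of 1..n as a matrix (n! x n)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Exhaustive rank-product p-values by literally enumerating every
# combination of column permutations (k = 2 columns) and pooling the
# resulting rank products over genes.
oracle_rp_exhaustive <- function(d, direction) {
  G <- nrow(d); k <- ncol(d)
  stopifnot(k == 2)
  s <- if (direction == "up") -d else d
  r <- apply(s, 2, rank, ties.method = "average")
  P <- all_perms(G)
  nperm <- nrow(P)
  obs <- r[, 1] * r[, 2]
  cnt <- numeric(G)
  total <- 0
  for (a in seq_len(nperm)) {
    r1 <- r[P[a, ], 1]
    for (b in seq_len(nperm)) {
      vals <- r1 * r[P[b, ], 2]
      for (g in seq_len(G)) cnt[g] <- cnt[g] + sum(vals <= obs[g] + 1e-9)
      total <- total + G
    }
  }
  cnt / total
}

# maximum nested base pairs by memoized pair-the-last-base recursion
# (different decomposition from the package's DP)
oracle_max_pairs <- function(seq, min_loop = 3, wobble = TRUE) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  pairable <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G") ||
    (wobble && ((a == "G" && b == "T") || (a == "T" && b == "G")))
  }
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- f(i, j - 1L)
    for (l in i:(j - min_loop - 1L)) {
      if (pairable(v[l], v[j])) {
        left <- if (l > i) f(i, l - 1L) else 0L
        cand <- left + 1L + f(l + 1L, j - 1L)
        if (cand > best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  if (n < 2) 0L else f(1L, n)
}

# brute-force uORF enumeration walking the concatenated sequence codon by
# codon from every candidate start
oracle_uorfs <- function(utr5, cds, min_len = 9) {
  v <- strsplit(paste0(utr5, cds), "")[[1]]
  L <- length(v); L5 <- nchar(utr5)
  found <- list()
  for (st in seq_len(L5)) {
    if (st + 2L > L) next
    if (!(v[st] == "A" && v[st + 1L] == "T" && v[st + 2L] == "G")) next
    j <- st + 3L
    while (j + 2L <= L) {
      cod <- paste0(v[j], v[j + 1L], v[j + 2L])
      if (cod == "TAA" || cod == "TAG" || cod == "TGA") {
        if (j + 2L < L && (j + 2L - st + 1L) >= min_len)
          found[[length(found) + 1L]] <- c(start = st, stop_end = j + 2L)
        break
      }
      j <- j + 3L
    }
  }
  found
}

# leftmost non-overlapping ARE count by manual stepping
oracle_are_count <- function(s) {
  n <- 0L; pos <- 1L
  while (pos + 8L <= nchar(s)) {
    w <- substr(s, pos, pos + 8L)
    ok <- substr(w, 1, 7) == "TATTTAT" &&
      substr(w, 8, 8) %in% c("A", "T") && substr(w, 9, 9) %in% c("A", "T")
    if (ok) { n <- n + 1L; pos <- pos + 9L } else pos <- pos + 1L
  }
  n
}

# TOP classification by a single leftmost regex match
oracle_top <- function(s, min_run = 4) {
  m <- regexpr(sprintf("C[CT]{%d,}", min_run), s)
  if (m == 1) "TOP" else if (m >= 2 && m <= 5) "TOP_like" else "none"
}

# E[S | X = x] under Normal(mu, sigma^2) + Exp(mean alpha) by quadrature.
# The posterior of S is concentrated near max(0, x - mu) with width ~sigma,
# so integrate over a finite window covering it (an infinite range makes
# integrate() miss the narrow peak).
oracle_normexp_conditional <- function(x, mu, sigma, alpha) {
  hi <- max(0, x - mu) + 40 * sigma
  # rescale by the posterior's peak density so the integrals stay O(1)
  # even deep in the left tail (integrate()'s absolute tolerance would
  # otherwise swamp them); the scale cancels in the ratio
  peak <- stats::dnorm(x - max(0, x - mu - sigma^2 / alpha), mu, sigma)
  f <- function(s) stats::dexp(s, 1 / alpha) *
    (stats::dnorm(x - s, mu, sigma) / peak)
  num <- stats::integrate(function(s) s * f(s), 0, hi, rel.tol = 1e-11,
                          subdivisions = 2000L)$value
  den <- stats::integrate(f, 0, hi, rel.tol = 1e-11,
                          subdivisions = 2000L)$value
  num / den
}

# two-sided Fisher p for a 2x2 table (a, b; c, d) directly from
# hypergeometric point masses on the table's own margins
oracle_fisher_p <- function(a, b, c_, d) {
  m1 <- a + b          # list size
  m2 <- c_ + d         # reference size
  k <- a + c_          # annotated total
  support <- max(0, k - m2):min(k, m1)
  dens <- stats::dhyper(support, m1, m2, k)
  dobs <- stats::dhyper(a, m1, m2, k)
  sum(dens[dens <= dobs * (1 + 1e-7)])
}

# Mann-Whitney U by direct pairwise comparison counting, exact two-sided
# p by enumeration over group assignments
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ustat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U_obs <- ustat(x, y)
  pool <- c(x, y)
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  devs <- apply(combos, 2, function(ix) {
    abs(ustat(pool[ix], pool[-ix]) - mu)
  })
  list(U = U_obs, p = mean(devs >= abs(U_obs - mu) - 1e-9))
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# rasterize an ellipse mask (pixel-centre inclusion), optionally rotated
rasterize_ellipse <- function(cx, cy, a, b, theta, nr, nc) {
  xs <- matrix(rep(1:nc, each = nr), nr)
  ys <- matrix(rep(1:nr, nc), nr)
  ct <- cos(theta); st <- sin(theta)
  u <- (xs - cx) * ct + (ys - cy) * st
  v <- -(xs - cx) * st + (ys - cy) * ct
  (u / a)^2 + (v / b)^2 <= 1
}
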