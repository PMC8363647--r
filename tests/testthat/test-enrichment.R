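test_that("binary feature test reproduces odds ratio and chi-squared exactly", {
  # 20/100 in list vs 50/1000 in background: OR = (20*950)/(80*50)
  universe <- sprintf("g%04d", 1:1100)
  lst <- universe[1:100]
  bg <- universe[101:1100]
  flags <- setNames(rep(FALSE, 1100), universe)
  flags[lst[1:20]] <- TRUE
  flags[bg[1:50]] <- TRUE
  r <- binary_feature_test(lst, bg, flags)
  expect_equal(r$odds_ratio, 4.75)
  # direct Pearson formula oracle
  tab <- matrix(c(20, 80, 50, 950), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  expect_equal(r$statistic, x2, tolerance = 1e-12)
  expect_equal(r$p, pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(r$direction, "enriched")
})

test_that("identical feature rates give chi-squared 0 and p 1", {
  universe <- sprintf("g%03d", 1:200)
  lst <- universe[1:50]; bg <- universe[51:200]
  flags <- setNames(logical(200), universe)
  flags[lst] <- rep(c(TRUE, FALSE), 25)    # rate 0.5 in the list
  flags[bg] <- rep(c(TRUE, FALSE), 75)     # rate 0.5 in the background
  r <- binary_feature_test(lst, bg, flags)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
})

test_that("zero margins are flagged untestable", {
  universe <- sprintf("g%03d", 1:100)
  flags <- setNames(rep(FALSE, 100), universe)
  r <- binary_feature_test(universe[1:20], universe[21:100], flags)
  expect_true(is.na(r$p))
  expect_equal(r$direction, "untestable")
})

test_that("random 2x2 tables match the closed-form chi-squared oracle", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(50:400, 1)
    universe <- sprintf("g%04d", 1:n)
    nl <- sample(10:(n - 10), 1)
    flags <- setNames(runif(n) < runif(1, 0.1, 0.9), universe)
    lst <- universe[1:nl]; bg <- universe[(nl + 1):n]
    a <- sum(flags[lst]); b <- nl - a
    c_ <- sum(flags[bg]); d <- (n - nl) - c_
    tab <- matrix(c(a, b, c_, d), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    x2 <- sum((tab - E)^2 / E)
    r <- binary_feature_test(lst, bg, flags)
    expect_equal(r$p, pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("continuous feature test equals the Welch formula", {
  set.seed(52)
  universe <- sprintf("g%03d", 1:120)
  vals <- setNames(rnorm(120, 100, 25), universe)
  lst <- universe[1:30]; bg <- universe[31:120]
  r <- continuous_feature_test(lst, bg, vals)
  m1 <- mean(vals[lst]); m2 <- mean(vals[bg])
  v1 <- var(vals[lst]) / 30; v2 <- var(vals[bg]) / 90
  tstat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / 29 + v2^2 / 89)
  expect_equal(r$statistic, tstat, tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-abs(tstat), df), tolerance = 1e-10)
  # identical groups -> t = 0, p = 1
  vals2 <- setNames(rep(c(1, 2), 60), universe)
  r2 <- continuous_feature_test(universe[1:60], universe[61:120], vals2)
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  expect_equal(r2$p, 1, tolerance = 1e-12)
})

test_that("a planted short-5'UTR list is detected as shorter with p < 0.01", {
  set.seed(53)
  universe <- sprintf("g%04d", 1:1500)
  vals <- setNames(c(rnorm(150, 70, 30), rnorm(1350, 150, 30)), universe)
  r <- continuous_feature_test(universe[1:150], universe[151:1500], vals)
  expect_equal(r$direction, "lower")
  expect_lt(r$p, 0.01)
})

test_that("GO over-representation equals hypergeometric tail sums", {
  set.seed(54)
  universe <- sprintf("g%04d", 1:300)
  lst <- universe[1:40]
  ann <- do.call(rbind, lapply(1:8, function(t) {
    genes <- sample(universe, sample(15:80, 1))
    data.frame(gene_id = genes, term = sprintf("T%02d", t))
  }))
  res <- go_overrepresentation(lst, universe, ann)
  for (i in seq_len(nrow(res))) {
    row <- res[i, ]
    p_oracle <- oracle_fisher_p(row$in_list, row$list_size - row$in_list,
                                row$in_ref, row$ref_size - row$in_ref)
    expect_equal(row$p, p_oracle, tolerance = 1e-10)
  }
  expect_false(is.unsorted(res$p))
})

test_that("degenerate GO inputs behave as specified", {
  universe <- sprintf("g%03d", 1:50)
  ann <- data.frame(gene_id = universe[1:10], term = "T01")
  # query equal to reference: p = 1 everywhere
  r <- go_overrepresentation(universe, universe, ann)
  expect_true(all(r$p == 1))
  # term annotating nothing in either set is skipped
  ann2 <- rbind(ann, data.frame(gene_id = "not_in_universe", term = "T99"))
  r2 <- go_overrepresentation(universe[1:5], universe, ann2)
  expect_false("T99" %in% r2$term)
  expect_error(go_overrepresentation(universe[1:5], universe,
                                     ann[0, ]), "empty")
  # BH adjustment appears on request
  r3 <- go_overrepresentation(universe[1:5], universe, ann, correction = "BH")
  expect_true("adjusted_p" %in% names(r3))
})

test_that("chi-squared and Fisher agree on well-filled tables", {
  set.seed(55)
  universe <- sprintf("g%04d", 1:400)
  flags <- setNames(runif(400) < 0.4, universe)
  lst <- universe[1:120]; bg <- universe[121:400]
  a <- sum(flags[lst]); c_ <- sum(flags[bg])
  if (min(a, 120 - a, c_, 280 - c_) >= 20) {
    pc <- binary_feature_test(lst, bg, flags)$p
    pf <- fisher.test(matrix(c(a, 120 - a, c_, 280 - c_), 2))$p.value
    # tight relative agreement in the rejection region; for large p the
    # discrete two-sided conventions drift apart and absolute closeness
    # is the meaningful comparison
    if (pf < 0.5) {
      expect_lt(abs(pc - pf) / pf, 0.10)
    } else {
      expect_lt(abs(pc - pf), 0.10)
    }
  }
})
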