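test_that("all-pairs fold changes match a nested-loop reference", {
  set.seed(3)
  M <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("a%d", 1:5)))
  md <- data.frame(array_id = colnames(M),
                   group = c("tumour", "tumour", "tumour", "control", "control"))
  fc <- pairwise_fold_changes(list(M = M, metadata = md))
  expect_equal(ncol(fc$d), 3 * 2)
  ref <- NULL
  for (t in 1:3) for (c in 4:5) ref <- cbind(ref, M[, t] - M[, c])
  expect_equal(unname(fc$d), unname(ref))
  # one tumour (M = 3) x one control (M = 1): single column holding 2
  fc1 <- pairwise_fold_changes(list(
    M = matrix(c(3, 1), 1, dimnames = list("g", c("t", "c"))),
    metadata = data.frame(array_id = c("t", "c"),
                          group = c("tumour", "control"))))
  expect_equal(unname(fc1$d), matrix(2))
  expect_error(pairwise_fold_changes(list(M = M,
    metadata = data.frame(array_id = colnames(M), group = rep("tumour", 5)))),
    "at least one")
})

test_that("rank products follow the geometric-mean-of-ranks definition", {
  d <- cbind(c(5, 3, 1), c(2, 6, 4))
  rownames(d) <- c("a", "b", "c")
  # up direction: column ranks of (5,3,1) are (1,2,3); of (2,6,4) are (3,1,2)
  expect_equal(unname(rank_product(d, "up")),
               c(sqrt(1 * 3), sqrt(2 * 1), sqrt(3 * 2)))
  # k = 1: RP equals the column rank
  expect_equal(unname(rank_product(d[, 1, drop = FALSE], "down")), c(3, 2, 1))
  # ties -> average ranks, against an independent sort-based reference
  set.seed(11)
  dt <- matrix(sample(1:4, 18, replace = TRUE), 6, 3)
  got <- rank_product(dt, "down")
  ref <- exp(rowMeans(log(apply(dt, 2, function(col) {
    o <- sort(col)
    vapply(col, function(v) mean(which(o == v)), numeric(1))
  }))))
  expect_equal(unname(got), unname(ref))
})

test_that("exhaustive permutation p-values equal full enumeration", {
  set.seed(4)
  for (rep in 1:3) {
    d <- matrix(rnorm(8), 4, 2, dimnames = list(letters[1:4], NULL))
    if (rep == 3) d[1:2, 1] <- 1  # force a tie
    for (dir in c("up", "down")) {
      got <- permutation_pfp(d, direction = dir, exhaustive = TRUE)
      expect_equal(got$pval, oracle_rp_exhaustive(d, dir), tolerance = 1e-12)
    }
  }
})

test_that("pfp equals pval * G / rank, with rank-1 gene pfp = pval * G", {
  set.seed(8)
  d <- matrix(rnorm(50 * 4), 50, 4)
  res <- permutation_pfp(d, n_perm = 50, seed = 1, direction = "up")
  expect_equal(res$pfp, res$pval * nrow(d) / res$rank)
  top <- res[res$rank == 1, ]
  expect_equal(top$pfp, top$pval * nrow(d))
  expect_true(all(sort(res$rank) == 1:50))
})

test_that("sign symmetry: negating fold changes swaps UP and DOWN exactly", {
  set.seed(12)
  d <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(sprintf("g%02d", 1:30), NULL))
  up <- permutation_pfp(d, n_perm = 200, seed = 5, direction = "up")
  dn <- permutation_pfp(-d, n_perm = 200, seed = 5, direction = "down")
  expect_equal(up$rp, dn$rp)
  expect_equal(up$pval, dn$pval)
})

test_that("gene relabelling permutes results consistently", {
  set.seed(13)
  d <- matrix(rnorm(25 * 3), 25, 3, dimnames = list(sprintf("g%02d", 1:25), NULL))
  perm <- sample(25)
  r1 <- permutation_pfp(d, n_perm = 100, seed = 2, direction = "up")
  r2 <- permutation_pfp(d[perm, ], n_perm = 100, seed = 2, direction = "up")
  expect_equal(r2$rp[order(r2$gene)], r1$rp[order(r1$gene)])
  expect_equal(r2$rank[order(r2$gene)], r1$rank[order(r1$gene)])
})

test_that("significance thresholds apply FC >= 2 and pfp < 0.2 strictly", {
  res <- data.frame(gene = c("worked_example", "lowfc", "boundary", "dn"),
                    FC = c(6.4, 1.5, 4, 0.2),
                    rank_up = 1:4, rp_up = 1:4,
                    pval_up = c(2.85e-7, 0.001, 0.001, 0.9),
                    pfp_up = c(0.000227273, 0.01, 0.2, 1),
                    rank_down = 4:1, rp_down = 4:1,
                    pval_down = c(1, 1, 1, 1e-4),
                    pfp_down = c(1, 1, 1, 0.01))
  sg <- significant_genes(res)
  expect_equal(sg$up, "worked_example")   # FC 6.4 at pfp 2.3e-4 passes
  expect_false("lowfc" %in% sg$up)        # FC below 2
  expect_false("boundary" %in% sg$up)     # pfp exactly 0.2 is excluded
  expect_equal(sg$down, "dn")
})

test_that("volcano table emits every gene on both arms", {
  set.seed(14)
  d <- matrix(rnorm(10 * 2), 10, 2, dimnames = list(letters[1:10], NULL))
  res <- rank_product_test(d, n_perm = 50, seed = 3)
  v <- volcano_table(res)
  expect_equal(nrow(v), 20)
  expect_equal(sort(unique(v$arm)), c("down", "up"))
  g <- v[v$gene == "a", ]
  expect_equal(g$neg_log10_p[g$arm == "up"], -log10(res$pval_up[res$gene == "a"]))
  expect_equal(g$neg_log10_p[g$arm == "down"], -log10(res$pval_down[res$gene == "a"]))
})

test_that("Pearson distance matches the direct formula and flags degeneracy", {
  set.seed(15)
  M <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("a", 1:5)))
  D <- pearson_distance_matrix(M)
  for (i in 1:5) for (j in 1:5) {
    r <- sum((M[, i] - mean(M[, i])) * (M[, j] - mean(M[, j]))) /
      sqrt(sum((M[, i] - mean(M[, i]))^2) * sum((M[, j] - mean(M[, j]))^2))
    expect_equal(D[i, j], 1 - r, tolerance = 1e-12)
  }
  expect_equal(diag(D), setNames(rep(0, 5), colnames(M)))
  M2 <- cbind(x = M[, 1], y = M[, 1], z = -M[, 1])
  D2 <- pearson_distance_matrix(M2)
  expect_equal(D2["x", "y"], 0)
  expect_equal(D2["x", "z"], 2)
  expect_error(pearson_distance_matrix(cbind(a = rep(1, 10), b = rnorm(10))),
               "zero-variance array: a")
})

test_that("label and column permutation schemes agree on direction ordering", {
  set.seed(16)
  d <- sim_design(n_genes = 80, seed = 16)
  sim <- gen_array_experiment(d)
  mv <- compute_m_values(sim$experiment)
  fc <- pairwise_fold_changes(mv)
  rl <- rank_product_test(fc, n_perm = 100, seed = 1, null_scheme = "label", m = mv)
  rc <- rank_product_test(fc, n_perm = 100, seed = 1)
  # same observed statistics regardless of null scheme
  expect_equal(rl$rp_up, rc$rp_up)
  expect_equal(rl$rank_up, rc$rank_up)
  # planted up genes sit at the top of both UP lists
  up <- sim$truth$status == "up"
  expect_gt(mean(rank(rc$rank_up)[!up]) , mean(rank(rc$rank_up)[up]))
})
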