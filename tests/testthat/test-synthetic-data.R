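test_that("design invariants are validated", {
  expect_error(sim_design(frac_up = 0.7, frac_down = 0.4), "<= 1")
  expect_error(sim_design(n_genes = 0), "counts")
  expect_error(sim_design(noise_sd = -1), "noise_sd")
})

test_that("generators are deterministic given the seed", {
  d <- sim_design(n_genes = 50, seed = 77)
  a <- gen_array_experiment(d)
  b <- gen_array_experiment(d)
  expect_identical(a$experiment$red_fg, b$experiment$red_fg)
  expect_identical(a$experiment$green_fg, b$experiment$green_fg)
  t1 <- gen_transcripts(d)
  t2 <- gen_transcripts(d)
  expect_identical(t1$records, t2$records)
  p1 <- gen_particle_field(n_fields = 2, particles_per_field = 5, seed = 77)
  p2 <- gen_particle_field(n_fields = 2, particles_per_field = 5, seed = 77)
  expect_identical(p1$grids, p2$grids)
  expect_identical(p1$truth, p2$truth)
})

test_that("planted fractions and statuses are respected", {
  d <- sim_design(n_genes = 200, frac_up = 0.1, frac_down = 0.05, seed = 1)
  tr <- plant_truth(d)
  expect_equal(sum(tr$status == "up"), 20)
  expect_equal(sum(tr$status == "down"), 10)
  expect_equal(anyDuplicated(tr$gene_id), 0)
})

test_that("dye-swapped arrays carry exchanged channels", {
  d <- sim_design(n_genes = 100, seed = 2, dye_swap_repeats = integer())
  d_sw <- sim_design(n_genes = 100, seed = 2, dye_swap_repeats = 1:3)
  plain <- gen_array_experiment(d)$experiment
  swapped <- gen_array_experiment(d_sw)$experiment
  # same seed stream: the swapped twin has red/green exchanged
  expect_equal(plain$red_fg, swapped$green_fg)
  expect_equal(plain$green_fg, swapped$red_fg)
  expect_true(all(swapped$metadata$dye_swap))
})

test_that("zero effect leaves tumour and control M indistinguishable", {
  d <- sim_design(n_genes = 500, frac_up = 0, frac_down = 0,
                  effect_log2 = 0, seed = 3)
  sim <- gen_array_experiment(d)
  e <- sim$experiment
  # generator-level contract: dye-adjusted raw log-ratios carry no
  # tumour/control difference (downstream per-array background fits add
  # their own sampling noise and are tested in the preprocess module)
  m_raw <- log2(e$red_fg / e$green_fg)
  m_raw[, e$metadata$dye_swap] <- -m_raw[, e$metadata$dye_swap]
  t_m <- as.vector(m_raw[, e$metadata$group == "tumour"])
  c_m <- as.vector(m_raw[, e$metadata$group == "control"])
  expect_gt(suppressWarnings(ks.test(t_m, c_m))$p.value, 0.01)
})

test_that("planted effect separates cleanly from null genes after preprocessing", {
  d <- sim_design(n_genes = 300, seed = 4)
  sim <- gen_array_experiment(d)
  mv <- compute_m_values(sim$experiment)
  tum <- mv$metadata$group == "tumour"
  diff_g <- rowMeans(mv$M[, tum, drop = FALSE]) -
    rowMeans(mv$M[, !tum, drop = FALSE])
  up <- sim$truth$status == "up"
  null <- sim$truth$status == "null"
  # conditional-mean correction shrinks low-intensity ratios toward zero,
  # so the recovered shift sits below the planted 2 but far above the null
  expect_gt(mean(diff_g[up]), 1)
  expect_lt(mean(diff_g[up]), 2.05)
  expect_gt(min(diff_g[up]) - max(diff_g[null]), -0.3)
  expect_gt(mean(diff_g[up]) - mean(diff_g[null]),
            4 * sd(diff_g[null]))
})

test_that("feature probability zero yields motif-free transcripts", {
  d <- sim_design(n_genes = 30, seed = 5)
  spec0 <- feature_spec(
    up = list(p_top = 0, p_top_like = 0, uorf_lambda = 0, are_lambda = 0, p_tisu = 0),
    down = list(p_top = 0, p_top_like = 0, uorf_lambda = 0, are_lambda = 0, p_tisu = 0),
    null = list(p_top = 0, p_top_like = 0, uorf_lambda = 0, are_lambda = 0, p_tisu = 0))
  tr <- gen_transcripts(d, spec0)
  ft <- annotate_transcripts(tr$records, tr$tisu_list)
  expect_true(all(ft$top_class == "none"))
  expect_true(all(ft$n_uorf == 0))
  expect_true(all(ft$n_are == 0))
  expect_true(all(!ft$tisu))
})

test_that("planted ARE fraction tracks the requested probability", {
  d <- sim_design(n_genes = 1000, seed = 6)
  # are_lambda chosen so P(>=1 ARE) = 0.3: lambda = -log(0.7)
  lam <- -log(0.7)
  spec <- feature_spec(up = list(are_lambda = lam),
                       down = list(are_lambda = lam),
                       null = list(are_lambda = lam))
  tr <- gen_transcripts(d, spec)
  phat <- mean(tr$truth$n_are > 0)
  expect_lt(abs(phat - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("infeasible planting requests fail naming the gene", {
  expect_error(build_transcript("gX", utr5_len = 15, n_uorf = 2),
               "gX")
  expect_error(build_transcript("gY", utr5_len = 6, top_class = "TOP"),
               "gY")
})

test_that("CDS sequences are well-formed", {
  d <- sim_design(n_genes = 40, seed = 8)
  tr <- gen_transcripts(d)
  expect_true(all(substr(tr$records$cds, 1, 3) == "ATG"))
  expect_true(all(nchar(tr$records$cds) %% 3 == 0))
  last <- substring(tr$records$cds, nchar(tr$records$cds) - 2)
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  expect_true(all(grepl("^[ACGT]*$", tr$records$utr5)))
})

test_that("particle truth obeys the class mix and unit contracts", {
  pf <- gen_particle_field(n_fields = 2, particles_per_field = 6,
                           class_mix = c(1, 0, 0), seed = 9)
  expect_true(all(pf$truth$class == "elongated"))
  # halving the pixel size leaves truth areas unchanged (um^2 invariant)
  p1 <- gen_particle_field(n_fields = 1, particles_per_field = 4,
                           pixel_size_um = 0.02, seed = 10)
  p2 <- gen_particle_field(n_fields = 1, particles_per_field = 4,
                           pixel_size_um = 0.01, seed = 10)
  expect_equal(p1$truth$area_um2, p2$truth$area_um2)
  # planted classes satisfy their defining inequalities
  pf3 <- gen_particle_field(n_fields = 2, particles_per_field = 9, seed = 11)
  tt <- pf3$truth
  r <- tt$major_um / tt$minor_um
  expect_true(all(r[tt$class == "elongated"] > 3))
  expect_true(all(tt$area_um2[tt$class == "enlarged"] > 0.5))
  expect_true(all(tt$area_um2[tt$class == "other"] < 0.5))
  expect_error(gen_particle_field(1, 5, class_mix = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(gen_particle_field(1, 400, field_um = 3, seed = 1),
               "place|small")
})
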