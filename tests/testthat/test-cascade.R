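cascade_contrasts <- c("VKR2011_vs_MAL2011", "VKR2012_vs_MAL2012",
                       "VKR2012_vs_NG2012", "VKR2012_vs_TEN2012")

test_that("consistency filter keeps all-pass probes and drops violators", {
  fc <- matrix(1, 3, 4, dimnames = list(c("P1", "P2", "P3"),
                                        cascade_contrasts))
  q <- matrix(0.01, 3, 4, dimnames = dimnames(fc))
  fc["P2", "VKR2012_vs_NG2012"] <- -0.5        # down in one comparison
  q["P3", "VKR2011_vs_MAL2011"] <- 0.2         # not significant in one
  ct <- contrast_table_from_wide(fc, q)
  cfg <- cascade_config()
  expect_equal(step_up_consistent(ct, cfg), "P1", ignore_attr = TRUE)
  cfg_any <- cascade_config(significance_mode = "any")
  expect_setequal(step_up_consistent(ct, cfg_any), c("P1", "P3"))
})

test_that("year-increase filter uses a strict inequality", {
  fc <- matrix(1, 3, 4, dimnames = list(c("P1", "P2", "P3"),
                                        cascade_contrasts))
  fc["P1", "VKR2012_vs_MAL2012"] <- 2     # up in 2012 -> kept
  fc["P2", "VKR2012_vs_MAL2012"] <- 1     # tie -> dropped
  fc["P3", "VKR2012_vs_MAL2012"] <- 0.5   # down -> dropped
  ct <- contrast_table_from_wide(fc)
  out <- step_year_increase(c("P1", "P2", "P3"), ct, cascade_config())
  expect_equal(out, "P1")
})

test_that("VK7-vs-TEN filter applies sign and q threshold at the boundary", {
  fc <- matrix(1, 3, 4, dimnames = list(c("P1", "P2", "P3"),
                                        cascade_contrasts))
  q <- matrix(0.01, 3, 4, dimnames = dimnames(fc))
  q["P1", "VKR2012_vs_TEN2012"] <- 0.049
  q["P2", "VKR2012_vs_TEN2012"] <- 0.051
  fc["P3", "VKR2012_vs_TEN2012"] <- -2   # the CYP6Z3 pattern: higher in TEN
  ct <- contrast_table_from_wide(fc, q)
  out <- step_vk7_over_ten(c("P1", "P2", "P3"), ct, cascade_config())
  expect_equal(out, "P1")
})

test_that("probe-to-gene collapse averages fold change on the FC scale", {
  fc <- matrix(log2(c(8, 9, 10, 11)), 4, 4,
               dimnames = list(sprintf("P%d", 1:4), cascade_contrasts))
  ct <- contrast_table_from_wide(fc)
  map <- data.frame(probe_id = sprintf("P%d", 1:4), gene_id = "G1")
  g <- collapse_probes_to_genes(sprintf("P%d", 1:4), map, ct,
                                contrast = "VKR2012_vs_MAL2012")
  expect_equal(nrow(g), 1)
  expect_equal(g$mean_FC, 9.5)
  expect_equal(g$n_probes, 4)
  # empty input
  empty <- collapse_probes_to_genes(character(), map, ct)
  expect_equal(nrow(empty), 0)
  # unmapped probes survive under their own id
  g2 <- collapse_probes_to_genes(c("P1", "PX"), map,
                                 contrast_table_from_wide(
                                   matrix(1, 2, 4,
                                          dimnames = list(c("P1", "PX"),
                                                          cascade_contrasts))),
                                 contrast = "VKR2012_vs_MAL2012")
  expect_setequal(g2$gene_id, c("G1", "PX"))
  expect_equal(attr(g2, "unmapped"), "PX")
})

test_that("a many-to-one probe map collapses to the expected gene count", {
  # 157 probes over 136 genes (21 duplicate probes), mirroring the shape of
  # a candidate list with alternative transcripts removed
  probes <- sprintf("P%03d", 1:157)
  gene_of <- c(sprintf("G%03d", 1:136), sprintf("G%03d", 1:21))
  map <- data.frame(probe_id = probes, gene_id = gene_of)
  fc <- matrix(1, 157, 4, dimnames = list(probes, cascade_contrasts))
  g <- collapse_probes_to_genes(probes, map, contrast_table_from_wide(fc),
                                contrast = "VKR2012_vs_MAL2012")
  expect_equal(nrow(g), 136)
  expect_equal(sum(g$n_probes), 157)
})

test_that("down-regulated mirror reverses every inequality and skips step E", {
  fc <- matrix(-1, 3, 4, dimnames = list(c("P1", "P2", "P3"),
                                         cascade_contrasts))
  fc["P2", "VKR2012_vs_TEN2012"] <- 0.5   # up in VK7 vs TEN -> excluded
  fc["P3", "VKR2011_vs_MAL2011"] <- 0.5   # up in one rs contrast -> excluded
  ct <- contrast_table_from_wide(fc)
  out <- down_regulated_mirror(ct, cascade_config())
  expect_equal(out$probes, "P1")
})

test_that("cascade recovers planted classes and excludes them per step", {
  truth <- expression_truth(n_probes = 400, seed = 21)
  design <- hybridization_design(rbind(as.data.frame(loop_design(2011)),
                                       as.data.frame(loop_design(2012))),
                                 require_connected = FALSE)
  sim <- simulate_two_color_experiment(design, truth, noise_sd = 0,
                                       dye_bias = 0, array_effect_sd = 0,
                                       seed = 21)
  fit_year <- function(yr, cts) {
    sub <- hybridization_design(as.data.frame(
      design[grepl(yr, design$cy3_sample), ]))
    ints <- sim$intensities[sim$intensities$array_id %in% sub$array_id, ]
    fit_contrasts(normalize_intensities(ints), sub, cts)
  }
  ct <- merge_contrast_tables(
    fit_year("2011", "VKR2011_vs_MAL2011"),
    fit_year("2012", c("VKR2012_vs_MAL2012", "VKR2012_vs_NG2012",
                       "VKR2012_vs_TEN2012")))
  cfg <- cascade_config()
  of_class <- function(cls) truth$probe_id[truth$planted_class == cls]
  sAC <- step_up_consistent(ct, cfg)
  expect_length(intersect(sAC, of_class("fails_step_A")), 0)
  expect_length(intersect(sAC, of_class("fails_step_B")), 0)
  expect_length(intersect(sAC, of_class("fails_step_C")), 0)
  sE <- step_year_increase(sAC, ct, cfg)
  expect_length(intersect(sE, of_class("fails_step_E")), 0)
  sD <- step_vk7_over_ten(sE, ct, cfg)
  expect_length(intersect(sD, of_class("fails_step_D")), 0)
  expect_setequal(sD, of_class("cascade_candidate"))
  res <- run_cascade(ct, cfg, probe_gene_map = truth[, c("probe_id", "gene_id")])
  expect_setequal(res$down_regulated$probes, of_class("down_regulated"))
  # purity: rerunning yields identical sets
  res2 <- run_cascade(ct, cfg, probe_gene_map = truth[, c("probe_id", "gene_id")])
  expect_identical(res$steps, res2$steps)
})

test_that("planted classes are recovered under realistic noise", {
  truth <- expression_truth(n_probes = 500, seed = 31)
  design <- hybridization_design(rbind(as.data.frame(loop_design(2011)),
                                       as.data.frame(loop_design(2012))),
                                 require_connected = FALSE)
  sim <- simulate_two_color_experiment(design, truth, noise_sd = 0.25,
                                       dye_bias = 0.1, array_effect_sd = 0.1,
                                       seed = 31)
  fit_year <- function(yr, cts) {
    sub <- hybridization_design(as.data.frame(
      design[grepl(yr, design$cy3_sample), ]))
    ints <- sim$intensities[sim$intensities$array_id %in% sub$array_id, ]
    fit_contrasts(normalize_intensities(ints), sub, cts)
  }
  ct <- merge_contrast_tables(
    fit_year("2011", "VKR2011_vs_MAL2011"),
    fit_year("2012", c("VKR2012_vs_MAL2012", "VKR2012_vs_NG2012",
                       "VKR2012_vs_TEN2012")))
  res <- run_cascade(ct, cascade_config(),
                     probe_gene_map = truth[, c("probe_id", "gene_id")])
  cand <- truth$probe_id[truth$planted_class == "cascade_candidate"]
  sens <- length(intersect(res$candidate_probes, cand)) / length(cand)
  expect_gte(sens, 0.9)
  fails <- truth$probe_id[grepl("^fails_step", truth$planted_class)]
  expect_length(intersect(res$candidate_probes, fails), 0)
  down <- truth$probe_id[truth$planted_class == "down_regulated"]
  sens_down <- length(intersect(res$down_regulated$probes, down)) / length(down)
  expect_gte(sens_down, 0.9)
  # up- and down-regulated lists are disjoint
  expect_length(intersect(res$candidate_probes, res$down_regulated$probes), 0)
})

test_that("hierarchical clustering is deterministic with sensible merges", {
  prof <- rbind(A = c(0, 0, 0), B = c(3, 3, 3), C = c(3.1, 3.1, 3.1))
  cl <- cluster_candidates(prof)
  # B and C (distance 0.173) merge before either joins A (distance >= 5.196)
  expect_equal(cl$hclust$merge[1, ], c(-2, -3))
  expect_equal(cl$heights[1], sqrt(3 * 0.1^2), tolerance = 1e-10)
  # identical profiles merge at height zero
  cl0 <- cluster_candidates(rbind(A = c(1, 2), B = c(1, 2)))
  expect_equal(cl0$heights, 0)
  # permuting rows leaves merge heights unchanged
  set.seed(1)
  prof2 <- matrix(rnorm(30), 10, 3,
                  dimnames = list(sprintf("P%02d", 1:10), NULL))
  h1 <- cluster_candidates(prof2)$heights
  h2 <- cluster_candidates(prof2[sample(10), , drop = FALSE])$heights
  expect_equal(h1, h2)
  # single probe: degenerate single-leaf result
  cl1 <- cluster_candidates(prof[1, , drop = FALSE])
  expect_null(cl1$hclust)
  expect_equal(cl1$order, "A")
})

test_that("missing cascade contrasts are a configuration error", {
  fc <- matrix(1, 2, 3, dimnames = list(c("P1", "P2"),
                                        cascade_contrasts[1:3]))
  ct <- contrast_table_from_wide(fc)
  expect_error(step_up_consistent(ct, cascade_config()),
               "VKR2012_vs_TEN2012")
})
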