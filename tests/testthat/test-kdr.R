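test_that("allele frequency point estimates and boundaries behave", {
  af <- allele_frequency(102, 124)
  expect_equal(round(af$f, 3), 0.823)
  # boundary: all-mutant sample
  b <- allele_frequency(50, 50)
  expect_equal(b$f, 1)
  expect_equal(b$ci_high, 1)
  expect_lt(b$ci_low, 1)
  z <- allele_frequency(0, 50)
  expect_equal(z$ci_low, 0)
  expect_error(allele_frequency(3, 0), "positive")
  expect_error(allele_frequency(5, 4), "count_mutant")
})

test_that("Clopper-Pearson and Wilson intervals match independent oracles", {
  for (x in c(5, 22, 60, 102)) {
    cp <- allele_frequency(x, 124, ci_method = "clopper_pearson")
    bt <- stats::binom.test(x, 124)$conf.int
    expect_equal(cp$ci_low, bt[1], tolerance = 1e-6)
    expect_equal(cp$ci_high, bt[2], tolerance = 1e-6)
    wi <- allele_frequency(x, 124, ci_method = "wilson")
    pt <- stats::prop.test(x, 124, correct = FALSE)$conf.int
    expect_equal(wi$ci_low, pt[1], tolerance = 1e-6)
    expect_equal(wi$ci_high, pt[2], tolerance = 1e-6)
  }
})

test_that("intervals contain the point estimate and stay in [0, 1]", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(10:300, 1)
    x <- sample(0:n, 1)
    for (m in c("clopper_pearson", "wilson")) {
      ci <- allele_frequency(x, n, ci_method = m)
      expect_gte(ci$f, ci$ci_low)
      expect_lte(ci$f, ci$ci_high)
      expect_gte(ci$ci_low, 0)
      expect_lte(ci$ci_high, 1)
    }
  }
})

test_that("Clopper-Pearson coverage holds at the study's sample size", {
  set.seed(7)
  n <- 124
  for (f in seq(0.1, 0.9, by = 0.2)) {
    x <- rbinom(500, n, f)
    ci <- allele_frequency(x, n)
    cover <- mean(ci$ci_low <= f & f <= ci$ci_high)
    expect_gte(cover, 0.95)
  }
})

test_that("the bundled field table reproduces every printed frequency", {
  rows <- kdr_field_counts()
  out <- allele_frequency_table(rows)
  expect_equal(round(out$f, 3), out$f_printed)
})

test_that("Fisher exact test matches enumeration and symmetry properties", {
  # identical proportions -> p = 1
  same <- fisher_exact_2x2(matrix(c(10, 20, 10, 20), 2, byrow = TRUE))
  expect_equal(same$p, 1)
  expect_equal(same$odds_ratio, 1)
  # hand-enumerable table
  tab <- matrix(c(3, 7, 8, 2), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab)$p, enumerate_fisher_p(3, 7, 8, 2),
               tolerance = 1e-12)
  # invariance under swapping rows and under swapping columns
  set.seed(3)
  for (i in 1:25) {
    t0 <- matrix(rpois(4, 8), 2)
    p0 <- fisher_exact_2x2(t0)$p
    expect_equal(fisher_exact_2x2(t0[2:1, ])$p, p0)
    expect_equal(fisher_exact_2x2(t0[, 2:1])$p, p0)
    # agreement with the reference implementation
    expect_equal(p0, stats::fisher.test(t0)$p.value, tolerance = 1e-12)
  }
})

test_that("allele-survival test is oriented and validated", {
  dead <- list(locus = "L1014F", site = "VK7", round = "Oct-11",
               count_wildtype = 42, count_mutant = 194)
  surv <- list(locus = "L1014F", site = "VK7", round = "Oct-11",
               count_wildtype = 15, count_mutant = 133)
  res <- fisher_survival_test(dead, surv)
  expect_lt(res$p_two_tailed, 0.05)
  expect_gt(res$odds_ratio, 1)   # mutant allele raises odds of survival
  other <- surv
  other$round <- "Jun-12"
  expect_error(fisher_survival_test(dead, other), "disagree")
})

test_that("chi-square homogeneity matches hand computation", {
  rows2 <- matrix(c(30, 70, 30, 70), 2, byrow = TRUE)
  res <- chi_square_homogeneity(rows2)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # 2x2 statistic equals the squared two-proportion z statistic
  tab <- matrix(c(25, 75, 40, 60), 2, byrow = TRUE)
  r <- chi_square_homogeneity(tab)
  p1 <- 25 / 100; p2 <- 40 / 100; pp <- 65 / 200
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(r$statistic, z^2, tolerance = 1e-12)
  expect_equal(r$df, 1)
  # 3x2 statistic vs manual expected counts
  tab3 <- matrix(c(10, 30, 20, 20, 30, 10), 3, byrow = TRUE)
  expd <- outer(rowSums(tab3), colSums(tab3)) / sum(tab3)
  expect_equal(chi_square_homogeneity(tab3)$statistic,
               sum((tab3 - expd)^2 / expd), tolerance = 1e-12)
  expect_equal(chi_square_homogeneity(tab3)$df, 2)
  # low expected count flag
  tiny <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_true(chi_square_homogeneity(tiny)$low_expected)
})

test_that("EM equals direct counting when no phase is ambiguous", {
  gt <- data.frame(status = "control",
                   genotype_1014 = c("LL", "FF", "FF", "LF", "FF"),
                   genotype_1575 = c("NN", "NN", "NY", "NN", "YY"))
  em <- em_haplotype_frequencies(gt)
  # haplotype copies: 2 LN + (FN FN) + (FN FY) + (LN FN) + (FY FY)
  expect_equal(em$frequencies,
               c("L-N" = 3, "L-Y" = 0, "F-N" = 4, "F-Y" = 3) / 10)
  expect_equal(sum(em$frequencies), 1)
  expect_true(em$converged)
})

test_that("EM converges monotonically to the grid-search optimum", {
  set.seed(11)
  for (i in 1:10) {
    f <- rgamma(4, 1); f <- f / sum(f)
    gt <- random_unphased_genotypes(sample(10:40, 1), f)
    em <- em_haplotype_frequencies(gt)
    expect_true(all(diff(em$loglik_trace) >= -1e-9))
    expect_equal(sum(em$frequencies), 1, tolerance = 1e-9)
    expect_lt(max(abs(em$frequencies - grid_haplotype_mle(gt))), 1e-3)
  }
})

test_that("EM flags non-convergence and rejects empty input", {
  set.seed(5)
  gt <- random_unphased_genotypes(60, c(0.3, 0.1, 0.3, 0.3))
  em <- em_haplotype_frequencies(gt, max_iter = 1)
  expect_false(em$converged)
  expect_error(em_haplotype_frequencies(gt[0, ]), "no specimens")
})

test_that("haplotype association reproduces a hand cross-product", {
  # all specimens homozygous: phase unambiguous, counts fully observed
  mk <- function(n_fy, n_fn, status) {
    data.frame(status = status,
               genotype_1014 = "FF",
               genotype_1575 = rep(c("YY", "NN"), c(n_fy, n_fn)))
  }
  gt <- rbind(mk(15, 35, "survivor"), mk(5, 45, "dead"))
  res <- haplotype_association(gt)
  fy <- res[res$haplotype == "F-Y", ]
  # copy counts: survivors 30 F-Y / 70 F-N, dead 10 / 90
  expect_equal(fy$case_count, 30)
  expect_equal(fy$control_count, 10)
  expect_equal(fy$odds_ratio, (30 * 90) / (70 * 10), tolerance = 1e-12)
  # identical distributions -> OR 1, chi-square 0
  gt0 <- rbind(mk(10, 40, "survivor"), mk(10, 40, "dead"))
  res0 <- haplotype_association(gt0)
  expect_equal(res0$odds_ratio, rep(1, nrow(res0)))
  expect_equal(res0$chi_square, rep(0, nrow(res0)))
  expect_error(haplotype_association(gt[gt$status == "dead", ]),
               "non-empty")
})

test_that("triallelic 1014 codes are rejected unless collapsed", {
  gt <- data.frame(status = c("survivor", "dead"),
                   genotype_1014 = c("LS", "FF"),
                   genotype_1575 = c("NN", "NN"))
  expect_error(em_haplotype_frequencies(gt), "L1014S")
  em <- em_haplotype_frequencies(gt, allow_triallelic = TRUE)
  expect_equal(unname(em$frequencies[["L-N"]]), 0.5)
})

test_that("genotype CSV and VCF exports round-trip / parse", {
  gt <- simulate_genotypes(n_per_arm = 20, n_control = 10, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_genotypes(gt, path)
  back <- read_genotypes(path)
  expect_equal(back, as.data.frame(gt), ignore_attr = TRUE)
  vcf <- tempfile(fileext = ".vcf")
  write_kdr_vcf(gt, vcf)
  lines <- readLines(vcf)
  expect_equal(sum(!startsWith(lines, "#")), 2)
  body <- strsplit(lines[!startsWith(lines, "#")][1], "\t")[[1]]
  expect_equal(length(body), 9 + nrow(gt))
  # heterozygote count in the VCF matches the table
  expect_equal(sum(body == "0/1"), sum(gt$genotype_1014 == "LF"))
})
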