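#' Mutant allele frequency with confidence interval
#'
#' Point estimate `count_mutant / n_alleles` with a binomial confidence
#' interval: Clopper-Pearson exact (beta quantiles; default) or Wilson
#' score. Vectorized over counts.
#'
#' @param count_mutant mutant allele count (F or Y).
#' @param n_alleles total alleles genotyped (2 x specimens).
#' @param ci_method "clopper_pearson" (default) or "wilson".
#' @param conf confidence level (default 0.95).
#' @return data.frame: f, ci_low, ci_high.
#' @export
allele_frequency <- function(count_mutant, n_alleles,
                             ci_method = c("clopper_pearson", "wilson"),
                             conf = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(conf > 0, conf < 1)
  if (any(n_alleles <= 0)) stop("n_alleles must be positive")
  if (any(count_mutant < 0 | count_mutant > n_alleles)) {
    stop("count_mutant must lie in [0, n_alleles]")
  }
  x <- count_mutant
  n <- n_alleles
  a <- 1 - conf
  if (ci_method == "clopper_pearson") {
    lo <- ifelse(x == 0, 0, stats::qbeta(a / 2, x, n - x + 1))
    hi <- ifelse(x == n, 1, stats::qbeta(1 - a / 2, x + 1, n - x))
  } else {
    z <- stats::qnorm(1 - a / 2)
    p <- x / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- pmax(0, centre - half)
    hi <- pmin(1, centre + half)
  }
  data.frame(f = x / n, ci_low = lo, ci_high = hi)
}

#' Allele frequencies for a table of allele-count rows
#'
#' @param rows data.frame with columns count_wildtype, count_mutant,
#'   n_alleles (plus any metadata columns, carried through).
#' @inheritParams allele_frequency
#' @return `rows` with f, ci_low, ci_high appended.
#' @export
allele_frequency_table <- function(rows,
                                   ci_method = c("clopper_pearson", "wilson"),
                                   conf = 0.95) {
  stopifnot(all(c("count_wildtype", "count_mutant", "n_alleles") %in%
                  names(rows)))
  if (any(rows$count_wildtype + rows$count_mutant != rows$n_alleles)) {
    stop("count_wildtype + count_mutant must equal n_alleles in every row")
  }
  cbind(rows, allele_frequency(rows$count_mutant, rows$n_alleles,
                               ci_method = ci_method, conf = conf))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test: with margins fixed, the two-sided p-value is the
#' sum of hypergeometric probabilities of all tables no more probable than
#' the observed one (with the customary 1e-7 relative tolerance for ties).
#' The odds ratio is the sample cross-product ratio `ad/bc`, with a Haldane
#' 0.5 added to every cell only when some cell is zero.
#'
#' @param tab 2x2 integer matrix (rows: groups; columns: allele classes).
#' @return list: p (two-tailed), odds_ratio.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c          # column-1 margin
  n <- b + d
  k <- a + b          # row-1 margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  if (any(tab == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  list(p = p, odds_ratio = or)
}

#' Allele-survival association by Fisher exact test
#'
#' Compares mutant allele frequencies between dead and surviving specimens
#' of one collection round with a two-sided Fisher exact test. The odds
#' ratio is oriented so that OR > 1 means the mutant allele increases the
#' odds of survival (survivors are the cases).
#'
#' @param dead,survivor allele-count rows (lists or one-row data.frames with
#'   count_wildtype, count_mutant and matching locus/site/round metadata).
#' @return list: p_two_tailed, odds_ratio, table.
#' @export
fisher_survival_test <- function(dead, survivor) {
  for (f in c("locus", "site", "round")) {
    if (!is.null(dead[[f]]) && !is.null(survivor[[f]]) &&
        dead[[f]] != survivor[[f]]) {
      stop("dead and survivor rows disagree on ", f, ": ",
           dead[[f]], " vs ", survivor[[f]])
    }
  }
  tab <- rbind(survivor = c(mutant = survivor$count_mutant,
                            wildtype = survivor$count_wildtype),
               dead = c(dead$count_mutant, dead$count_wildtype))
  ft <- fisher_exact_2x2(tab)
  list(p_two_tailed = ft$p, odds_ratio = ft$odds_ratio, table = tab)
}

#' Chi-square homogeneity test of allele frequencies across samples
#'
#' Pearson chi-square (no continuity correction) on a k x 2 allele-count
#' table; df = k - 1. A `low_expected` flag marks tables with any expected
#' count below 1, where the asymptotic p-value is unreliable.
#'
#' @param counts k x 2 matrix (rows: samples; columns: wildtype, mutant) or
#'   a data.frame of allele-count rows with count_wildtype / count_mutant.
#' @return list: statistic, df, p, low_expected.
#' @export
chi_square_homogeneity <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- as.matrix(counts[, c("count_wildtype", "count_mutant")])
  }
  stopifnot(ncol(counts) == 2, nrow(counts) >= 2)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, low_expected = any(expected < 1))
}

GENOTYPES_1014 <- c("LL", "LF", "FF")
GENOTYPES_1575 <- c("NN", "NY", "YY")

validate_genotypes <- function(genotypes, allow_triallelic = FALSE) {
  stopifnot(all(c("genotype_1014", "genotype_1575", "status") %in%
                  names(genotypes)))
  g1 <- genotypes$genotype_1014
  g2 <- genotypes$genotype_1575
  if (any(grepl("S", g1))) {
    if (!allow_triallelic) {
      stop("L1014S alleles observed; the association machinery is ",
           "biallelic (rerun with allow_triallelic = TRUE to collapse S ",
           "into L)")
    }
    g1 <- gsub("S", "L", g1)
    g1[g1 == "FL"] <- "LF"
  }
  ok <- g1 %in% GENOTYPES_1014 & g2 %in% GENOTYPES_1575
  if (any(!ok, na.rm = TRUE)) {
    bad <- unique(c(g1[!ok & !is.na(ok)], g2[!ok & !is.na(ok)]))
    stop("invalid genotype code(s): ", paste(bad, collapse = ", "))
  }
  genotypes$genotype_1014 <- g1
  genotypes$genotype_1575 <- g2
  complete <- !is.na(g1) & !is.na(g2)
  attr(genotypes, "incomplete") <- which(!complete)
  genotypes[complete, , drop = FALSE]
}

#' Allele counts per locus from a genotype table
#'
#' @param genotypes KdrGenotypeTable data.frame.
#' @param locus "L1014F" or "N1575Y".
#' @param by metadata columns to stratify by (default status).
#' @return data.frame of allele-count rows.
#' @export
allele_counts_from_genotypes <- function(genotypes,
                                         locus = c("L1014F", "N1575Y"),
                                         by = "status") {
  locus <- match.arg(locus)
  col <- if (locus == "L1014F") "genotype_1014" else "genotype_1575"
  mutant_char <- if (locus == "L1014F") "F" else "Y"
  g <- genotypes[[col]]
  mut <- vapply(strsplit(g, ""), function(x) sum(x == mutant_char), 0L)
  agg <- stats::aggregate(cbind(count_mutant = mut, n_alleles = 2L),
                          by = genotypes[, by, drop = FALSE], FUN = sum)
  agg$count_wildtype <- agg$n_alleles - agg$count_mutant
  agg$locus <- locus
  agg[, c(by, "locus", "count_wildtype", "count_mutant", "n_alleles")]
}

# 9 unambiguous genotype-class haplotype contributions + the double-het.
# Order of haplotypes: L-N, L-Y, F-N, F-Y.
.fixed_hap_contrib <- list(
  "LL/NN" = c(2, 0, 0, 0), "LL/NY" = c(1, 1, 0, 0), "LL/YY" = c(0, 2, 0, 0),
  "FF/NN" = c(0, 0, 2, 0), "FF/NY" = c(0, 0, 1, 1), "FF/YY" = c(0, 0, 0, 2),
  "LF/NN" = c(1, 0, 1, 0), "LF/YY" = c(0, 1, 0, 1)
)

genotype_class_counts <- function(genotypes) {
  cls <- paste(genotypes$genotype_1014, genotypes$genotype_1575, sep = "/")
  table(factor(cls, levels = c(names(.fixed_hap_contrib), "LF/NY")))
}

# multinomial log-likelihood of genotype-class counts given hap freqs
hap_loglik <- function(counts, f) {
  pr <- c(
    "LL/NN" = f[1]^2, "LL/NY" = 2 * f[1] * f[2], "LL/YY" = f[2]^2,
    "FF/NN" = f[3]^2, "FF/NY" = 2 * f[3] * f[4], "FF/YY" = f[4]^2,
    "LF/NN" = 2 * f[1] * f[3], "LF/YY" = 2 * f[2] * f[4],
    "LF/NY" = 2 * f[1] * f[4] + 2 * f[2] * f[3]
  )
  nz <- counts > 0
  if (any(pr[nz] <= 0)) return(-Inf)
  sum(counts[nz] * log(pr[names(counts)[nz]]))
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood haplotype frequencies for the 1014 / 1575 kdr loci
#' from unphased genotypes under Hardy-Weinberg random haplotype pairing.
#' Every genotype class except the double heterozygote LF/NY contributes
#' fixed haplotype counts; the double heterozygotes are split between the
#' cis {L-N, F-Y} and trans {L-Y, F-N} resolutions by expectation-
#' maximization, initialized from an equal split.
#'
#' @param genotypes KdrGenotypeTable data.frame (rows with missing
#'   genotypes are dropped).
#' @param tol convergence tolerance on the max absolute frequency change
#'   (default 1e-8).
#' @param max_iter iteration cap; non-convergence flags the result rather
#'   than discarding it.
#' @param allow_triallelic collapse observed 1014S alleles into L.
#' @return list of class `hap_freqs`: frequencies (named, sums to 1),
#'   log_likelihood, loglik_trace, n_iterations, converged, n_specimens.
#' @export
em_haplotype_frequencies <- function(genotypes, tol = 1e-8, max_iter = 1000,
                                     allow_triallelic = FALSE) {
  genotypes <- validate_genotypes(genotypes, allow_triallelic)
  if (nrow(genotypes) == 0) stop("no specimens with complete genotypes")
  counts <- genotype_class_counts(genotypes)
  n2 <- 2 * sum(counts)
  fixed <- Reduce(`+`, Map(function(cls, contrib) counts[[cls]] * contrib,
                           names(.fixed_hap_contrib), .fixed_hap_contrib))
  n_dh <- counts[["LF/NY"]]
  # equal-split initialization
  f <- (fixed + n_dh * c(0.5, 0.5, 0.5, 0.5)) / n2
  trace <- hap_loglik(counts, f)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    denom <- f[1] * f[4] + f[2] * f[3]
    t_cis <- if (denom > 0) f[1] * f[4] / denom else 0.5
    f_new <- (fixed + n_dh * c(t_cis, 1 - t_cis, 1 - t_cis, t_cis)) / n2
    trace <- c(trace, hap_loglik(counts, f_new))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(
    frequencies = setNames(as.numeric(f), HAPLOTYPES),
    log_likelihood = trace[length(trace)],
    loglik_trace = trace,
    n_iterations = iter,
    converged = converged,
    n_specimens = sum(counts)
  ), class = "hap_freqs")
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat("Two-locus kdr haplotype frequencies (EM,", x$n_iterations,
      "iterations,", if (x$converged) "converged" else "NOT converged", ")\n")
  print(round(x$frequencies, 4))
  cat("log-likelihood:", x$log_likelihood, "\n")
  invisible(x)
}

# expected haplotype copy counts for a genotype subset given freqs f
expected_hap_counts <- function(genotypes, f) {
  counts <- genotype_class_counts(genotypes)
  fixed <- Reduce(`+`, Map(function(cls, contrib) counts[[cls]] * contrib,
                           names(.fixed_hap_contrib), .fixed_hap_contrib))
  denom <- f[1] * f[4] + f[2] * f[3]
  t_cis <- if (denom > 0) f[1] * f[4] / denom else 0.5
  setNames(fixed + counts[["LF/NY"]] * c(t_cis, 1 - t_cis, 1 - t_cis, t_cis),
           HAPLOTYPES)
}

#' Haplotype-survival association
#'
#' Tests each kdr haplotype for association with surviving insecticide
#' exposure. Haplotype copy counts per outcome group are obtained from the
#' EM phase resolution — either a single EM over the pooled sample with
#' per-group expected-count partition (default) or a separate EM per group
#' — and each haplotype is scored on a 2x2 (haplotype vs all others) x
#' (survivor vs dead) table: cross-product odds ratio (Haldane 0.5 on zero
#' cells) and 1-df Pearson chi-square. OR > 1 means the haplotype increases
#' the odds of survival.
#'
#' @param genotypes KdrGenotypeTable including both outcome groups.
#' @param mode "pooled" (default) or "per_group" EM.
#' @param case,control status labels for the two groups (default
#'   survivor / dead).
#' @inheritParams em_haplotype_frequencies
#' @return data.frame: haplotype, case_count, control_count, case_freq,
#'   control_freq, odds_ratio, chi_square, p. Haplotypes with zero expected
#'   copies in both groups are omitted (listed in the `omitted` attribute).
#' @export
haplotype_association <- function(genotypes, mode = c("pooled", "per_group"),
                                  case = "survivor", control = "dead",
                                  tol = 1e-8, max_iter = 1000,
                                  allow_triallelic = FALSE) {
  mode <- match.arg(mode)
  genotypes <- validate_genotypes(genotypes, allow_triallelic)
  gcase <- genotypes[genotypes$status == case, , drop = FALSE]
  gctrl <- genotypes[genotypes$status == control, , drop = FALSE]
  if (nrow(gcase) == 0 || nrow(gctrl) == 0) {
    stop("both status groups must be non-empty (case: ", nrow(gcase),
         ", control: ", nrow(gctrl), ")")
  }
  if (mode == "pooled") {
    fit <- em_haplotype_frequencies(rbind(gcase, gctrl), tol = tol,
                                    max_iter = max_iter)
    cnt_case <- expected_hap_counts(gcase, fit$frequencies)
    cnt_ctrl <- expected_hap_counts(gctrl, fit$frequencies)
  } else {
    fit_case <- em_haplotype_frequencies(gcase, tol = tol, max_iter = max_iter)
    fit_ctrl <- em_haplotype_frequencies(gctrl, tol = tol, max_iter = max_iter)
    cnt_case <- fit_case$frequencies * 2 * fit_case$n_specimens
    cnt_ctrl <- fit_ctrl$frequencies * 2 * fit_ctrl$n_specimens
  }
  tot_case <- sum(cnt_case)
  tot_ctrl <- sum(cnt_ctrl)
  keep <- cnt_case + cnt_ctrl > 1e-6   # omit all-but-absent haplotypes
  rows <- lapply(HAPLOTYPES[keep], function(h) {
    a <- cnt_case[[h]]; b <- tot_case - a
    c <- cnt_ctrl[[h]]; d <- tot_ctrl - c
    if (any(c(a, b, c, d) == 0)) {
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    } else {
      or <- (a * d) / (b * c)
    }
    tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi <- sum((tab - expd)^2 / expd)
    data.frame(haplotype = h, case_count = a, control_count = c,
               case_freq = a / tot_case, control_freq = c / tot_ctrl,
               odds_ratio = or, chi_square = chi,
               p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omitted") <- HAPLOTYPES[!keep]
  attr(out, "orientation") <- paste0("OR > 1: haplotype increases odds of ",
                                     case, " (cases) vs ", control)
  out
}

#' Read / write a kdr genotype table CSV
#'
#' Columns: specimen_id, site, round, status, genotype_1014 (LL/LF/FF),
#' genotype_1575 (NN/NY/YY).
#' @param path file path.
#' @rdname genotype_io
#' @export
read_genotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @param genotypes KdrGenotypeTable data.frame.
#' @rdname genotype_io
#' @export
write_genotypes <- function(genotypes, path) {
  utils::write.csv(genotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Emit a genotype table as a minimal two-site VCF
#'
#' Writes diploid GT records for the two kdr sites (named kdr_1014 and
#' kdr_1575; REF = wildtype allele) for interoperability with variant
#' tooling. Positions are nominal.
#'
#' @param genotypes KdrGenotypeTable data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_kdr_vcf <- function(genotypes, path) {
  gt <- function(g, wild) {
    n_mut <- vapply(strsplit(g, ""), function(x) sum(x != wild), 0L)
    c("0/0", "0/1", "1/1")[n_mut + 1L]
  }
  ids <- genotypes$specimen_id
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=anoresist",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"),
    paste(c("2L", "1014", "kdr_1014", "L", "F", ".", ".", ".", "GT",
            gt(genotypes$genotype_1014, "L")), collapse = "\t"),
    paste(c("2L", "1575", "kdr_1575", "N", "Y", ".", ".", ".", "GT",
            gt(genotypes$genotype_1575, "N")), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
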