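# Shared fixture builders and independent oracles used across the suite.

# dye-swap pair A<->B (no replicates beyond the two arrays)
dyeswap_pair <- function() {
  hybridization_design(data.frame(
    array_id = c("a1", "a2"),
    cy3_sample = c("A", "B"),
    cy5_sample = c("B", "A"),
    replicate = c(1, 1)
  ))
}

# intensity table realizing given per-array M values at A = const, cy3 = 1
intensities_from_M <- function(M_by_array, probe_ids) {
  rows <- lapply(names(M_by_array), function(aid) {
    data.frame(probe_id = probe_ids, array_id = aid,
               cy3 = 1, cy5 = 2^M_by_array[[aid]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# long-format contrast table from a wide matrix of log2FC (and optional q)
contrast_table_from_wide <- function(fc, q = NULL, p = NULL) {
  if (is.null(q)) q <- matrix(0.01, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  if (is.null(p)) p <- q
  do.call(rbind, lapply(colnames(fc), function(ct) {
    data.frame(probe_id = rownames(fc), contrast = ct,
               log2FC = fc[, ct], p = p[, ct], q = q[, ct], flag = "ok",
               stringsAsFactors = FALSE)
  }))
}

# draw n specimens as random haplotype pairs (no survival conditioning)
random_unphased_genotypes <- function(n, freqs) {
  g14 <- c("L", "L", "F", "F")
  g15 <- c("N", "Y", "N", "Y")
  h1 <- sample(4, n, replace = TRUE, prob = freqs)
  h2 <- sample(4, n, replace = TRUE, prob = freqs)
  data.frame(
    specimen_id = sprintf("S%04d", seq_len(n)),
    site = "VK7", round = "R1", status = "control",
    genotype_1014 = ifelse(g14[h1] == g14[h2], paste0(g14[h1], g14[h2]), "LF"),
    genotype_1575 = ifelse(g15[h1] == g15[h2], paste0(g15[h1], g15[h2]), "NY"),
    stringsAsFactors = FALSE
  )
}

# Brute-force ML of two-locus haplotype frequencies: every stationary point
# of the genotype likelihood lies on the one-parameter ridge traced by the
# cis fraction t of the double-heterozygote class, so a fine grid over t
# searches the whole simplex region that can contain the maximum.
grid_haplotype_mle <- function(genotypes, step = 5e-4) {
  lv <- c("LL/NN", "LL/NY", "LL/YY", "FF/NN", "FF/NY", "FF/YY",
          "LF/NN", "LF/YY", "LF/NY")
  counts <- table(factor(paste(genotypes$genotype_1014,
                               genotypes$genotype_1575, sep = "/"),
                         levels = lv))
  fixed <- c(2 * counts[["LL/NN"]] + counts[["LL/NY"]] + counts[["LF/NN"]],
             2 * counts[["LL/YY"]] + counts[["LL/NY"]] + counts[["LF/YY"]],
             2 * counts[["FF/NN"]] + counts[["FF/NY"]] + counts[["LF/NN"]],
             2 * counts[["FF/YY"]] + counts[["FF/NY"]] + counts[["LF/YY"]])
  ndh <- counts[["LF/NY"]]
  n2 <- 2 * nrow(genotypes)
  cnt <- as.numeric(counts)
  ll <- function(f) {
    pr <- c(f[1]^2, 2 * f[1] * f[2], f[2]^2, f[3]^2, 2 * f[3] * f[4],
            f[4]^2, 2 * f[1] * f[3], 2 * f[2] * f[4],
            2 * f[1] * f[4] + 2 * f[2] * f[3])
    nz <- cnt > 0
    if (any(pr[nz] <= 0)) return(-Inf)
    sum(cnt[nz] * log(pr[nz]))
  }
  best <- NULL
  bestll <- -Inf
  for (t in seq(0, 1, by = step)) {
    f <- (fixed + ndh * c(t, 1 - t, 1 - t, t)) / n2
    l <- ll(f)
    if (l > bestll) { bestll <- l; best <- f }
  }
  stats::setNames(best, c("L-N", "L-Y", "F-N", "F-Y"))
}

# Exhaustive two-sided Fisher p by direct enumeration over the support,
# computing table probabilities from log-binomial coefficients.
enumerate_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  supp <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, supp) + lchoose(r2, c1 - supp) - lchoose(r1 + r2, c1)
  pr <- exp(lp)
  min(1, sum(pr[pr <= pr[a - supp[1] + 1] * (1 + 1e-7)]))
}
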