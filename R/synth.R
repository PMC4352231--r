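#' @importFrom stats rnorm rbinom runif setNames
NULL

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

SYNTH_POPULATIONS <- c("VKR2011", "VKC2011", "MAL2011",
                       "VKR2012", "TEN2012", "MAL2012", "NG2012")

SYNTH_CLASSES <- c("cascade_candidate", "fails_step_A", "fails_step_B",
                   "fails_step_C", "fails_step_D", "fails_step_E",
                   "down_regulated", "null")

# Per-class log2 offsets from a probe's baseline, one column per population.
# Designed so that cascade_candidate passes every cascade filter and each
# fails_step_X class violates the corresponding filter (fails_step_B probes,
# whose VK7/MAL-2012 fold change is negative while the 2011 one is positive,
# necessarily also fail the year-increase filter: the two filters compare the
# same pair of fold changes).
class_offsets <- function() {
  z <- setNames(numeric(length(SYNTH_POPULATIONS)), SYNTH_POPULATIONS)
  off <- function(...) {
    v <- z
    args <- list(...)
    v[names(args)] <- unlist(args)
    v
  }
  # separations are ~3+ SD of the contrast estimator at the default noise
  # (0.25 per channel, 3 replicates/edge), so planted classes are reliably
  # recovered / excluded, while staying inside the fold-change range typical
  # of field detoxification genes (FC ~2-20)
  rbind(
    cascade_candidate = off(VKR2011 = 2, VKC2011 = 0.5, VKR2012 = 3,
                            TEN2012 = 1),
    fails_step_A = off(VKR2011 = -1, VKC2011 = 0.5, VKR2012 = 3,
                       TEN2012 = 1),
    fails_step_B = off(VKR2011 = 2, VKC2011 = 0.5, VKR2012 = 3,
                       MAL2012 = 4, TEN2012 = 1),
    fails_step_C = off(VKR2011 = 2, VKC2011 = 0.5, VKR2012 = 3,
                       NG2012 = 4, TEN2012 = 1),
    fails_step_D = off(VKR2011 = 2, VKC2011 = 0.5, VKR2012 = 3,
                       TEN2012 = 4),
    fails_step_E = off(VKR2011 = 4, VKC2011 = 0.5, VKR2012 = 3,
                       TEN2012 = 1),
    down_regulated = off(VKR2011 = -2, VKC2011 = -0.5, VKR2012 = -3,
                         TEN2012 = -1),
    null = z
  )
}

#' Planted expression ground truth for the synthetic array experiment
#'
#' Generates a probe table with per-population true log2 abundances and a
#' planted class per probe. `cascade_candidate` probes satisfy every
#' candidate filter (up-regulated in VK7 vs both susceptible colonies in
#' both years, stronger in 2012 than 2011, and higher in VK7 than Tengrela);
#' each `fails_step_X` class violates the named filter; `down_regulated`
#' probes mirror the candidates with all signs reversed; `null` probes are
#' flat. Genes carry 1-4 probes so the probe-to-gene collapse is exercised.
#'
#' @param n_probes number of probes (default 1000, a desk-scale stand-in for
#'   the 8x15K array).
#' @param class_fractions named fractions over the planted classes; must sum
#'   to at most 1, remainder is `null`.
#' @param baseline_range range of per-probe baseline log2 abundance.
#' @param seed RNG seed.
#' @return data.frame: `probe_id`, `gene_id`, `planted_class`, one numeric
#'   column per population (true log2 level).
#' @export
expression_truth <- function(n_probes = 1000,
                             class_fractions = c(cascade_candidate = 0.05,
                                                 fails_step_A = 0.02,
                                                 fails_step_B = 0.02,
                                                 fails_step_C = 0.02,
                                                 fails_step_D = 0.02,
                                                 fails_step_E = 0.02,
                                                 down_regulated = 0.04),
                             baseline_range = c(6, 12),
                             seed = 1) {
  stopifnot(n_probes >= 1, all(class_fractions >= 0),
            sum(class_fractions) <= 1)
  bad <- setdiff(names(class_fractions), SYNTH_CLASSES)
  if (length(bad) > 0) stop("unknown planted class: ", paste(bad, collapse = ", "))
  with_seed(seed, {
    n_cls <- round(n_probes * class_fractions)
    cls <- c(rep(names(n_cls), n_cls),
             rep("null", n_probes - sum(n_cls)))
    cls <- sample(cls)
    baseline <- runif(n_probes, baseline_range[1], baseline_range[2])
    # genes carry 1-4 probes; draw gene sizes until probes are covered
    sizes <- sample(1:4, n_probes, replace = TRUE,
                    prob = c(0.55, 0.25, 0.12, 0.08))
    gene_of <- rep(seq_along(sizes), sizes)[seq_len(n_probes)]
    off <- class_offsets()
    levels <- matrix(baseline, n_probes, length(SYNTH_POPULATIONS)) +
      off[cls, , drop = FALSE]
    colnames(levels) <- SYNTH_POPULATIONS
    out <- data.frame(
      probe_id = sprintf("P%05d", seq_len(n_probes)),
      gene_id = sprintf("G%05d", gene_of),
      planted_class = cls,
      stringsAsFactors = FALSE
    )
    cbind(out, as.data.frame(levels))
  })
}

#' Simulate a two-colour loop-design array experiment
#'
#' Intensities are generated on the log2 scale as
#' `true level + array effect + dye bias (cy5 channel only) + noise`
#' and exponentiated, so the downstream log-ratio model is exactly the
#' generating model. Noise is additive Gaussian per probe per channel.
#'
#' @param design a [hybridization_design()].
#' @param truth an [expression_truth()] table covering every population in
#'   the design.
#' @param noise_sd per-channel Gaussian noise SD (log2 units).
#' @param dye_bias constant log2 offset added to the cy5 channel; a vector
#'   of length `nrow(truth)` gives a per-probe dye bias.
#' @param array_effect_sd SD of the per-array random offset (log2 units).
#' @param seed RNG seed.
#' @return list with `intensities` (probe_id, array_id, cy3, cy5), `design`
#'   and `truth`.
#' @export
simulate_two_color_experiment <- function(design, truth, noise_sd = 0.25,
                                          dye_bias = 0.1,
                                          array_effect_sd = 0.1, seed = 1) {
  stopifnot(inherits(design, "hybridization_design"),
            noise_sd >= 0, array_effect_sd >= 0)
  pops <- design_populations(design)
  missing <- setdiff(pops, names(truth))
  if (length(missing) > 0) {
    stop("design references population(s) absent from truth: ",
         paste(missing, collapse = ", "))
  }
  n_probes <- nrow(truth)
  if (length(dye_bias) == 1) dye_bias <- rep(dye_bias, n_probes)
  stopifnot(length(dye_bias) == n_probes)
  with_seed(seed, {
    array_eff <- rnorm(nrow(design), 0, array_effect_sd)
    res <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      g <- truth[[design$cy3_sample[i]]] + array_eff[i] +
        rnorm(n_probes, 0, noise_sd)
      r <- truth[[design$cy5_sample[i]]] + array_eff[i] + dye_bias +
        rnorm(n_probes, 0, noise_sd)
      res[[i]] <- data.frame(probe_id = truth$probe_id,
                             array_id = design$array_id[i],
                             cy3 = 2^g, cy5 = 2^r,
                             stringsAsFactors = FALSE)
    }
    list(intensities = do.call(rbind, res), design = design, truth = truth)
  })
}

HAPLOTYPES <- c("L-N", "L-Y", "F-N", "F-Y")

# genotype codes from a pair of haplotype indices
.geno_1014 <- c("L", "L", "F", "F")
.geno_1575 <- c("N", "Y", "N", "Y")

haplotypes_to_genotypes <- function(h1, h2) {
  a1 <- .geno_1014[h1]; a2 <- .geno_1014[h2]
  b1 <- .geno_1575[h1]; b2 <- .geno_1575[h2]
  g1014 <- ifelse(a1 == a2, paste0(a1, a2),
                  "LF")
  g1575 <- ifelse(b1 == b2, paste0(b1, b2),
                  "NY")
  data.frame(genotype_1014 = g1014, genotype_1575 = g1575,
             stringsAsFactors = FALSE)
}

#' Simulate unphased kdr genotypes with a planted survival association
#'
#' Each specimen receives two haplotypes drawn i.i.d. from
#' `haplotype_freqs`; its odds of surviving insecticide exposure are
#' `baseline_odds` multiplied by `survival_or[h]` for each carried copy of
#' haplotype h. Phase is discarded: only the unphased single-locus genotypes
#' are returned. With the defaults the 1014F-1575Y haplotype raises the odds
#' of survival while L-Y has structural frequency zero (1575Y arises only on
#' a 1014F background).
#'
#' @param haplotype_freqs named frequencies for `L-N`, `L-Y`, `F-N`, `F-Y`;
#'   must sum to 1 within 1e-9.
#' @param survival_or named per-copy survival odds ratios.
#' @param n_per_arm specimens sampled into each of the dead and survivor
#'   arms (case-control style, emulating LT50 exposure outcomes).
#' @param n_control unexposed control specimens (no outcome conditioning).
#' @param baseline_odds survival odds of a specimen carrying no OR-modifying
#'   haplotype copies.
#' @param site,round metadata labels attached to every specimen.
#' @param seed RNG seed.
#' @return data.frame: specimen_id, site, round, status
#'   (control/dead/survivor), genotype_1014 (LL/LF/FF), genotype_1575
#'   (NN/NY/YY).
#' @export
simulate_genotypes <- function(haplotype_freqs = c("L-N" = 0.15, "L-Y" = 0,
                                                   "F-N" = 0.55, "F-Y" = 0.30),
                               survival_or = c("L-N" = 1, "L-Y" = 1,
                                               "F-N" = 1, "F-Y" = 2.7),
                               n_per_arm = 200, n_control = 0,
                               baseline_odds = 1,
                               site = "VK7", round = "R1", seed = 1) {
  if (!all(HAPLOTYPES %in% names(haplotype_freqs))) {
    stop("haplotype_freqs must name all of: ", paste(HAPLOTYPES, collapse = ", "))
  }
  f <- haplotype_freqs[HAPLOTYPES]
  if (abs(sum(f) - 1) > 1e-9) {
    stop("haplotype frequencies must sum to 1 (got ", sum(f), ")")
  }
  if (any(f < 0)) stop("haplotype frequencies must be non-negative")
  or <- survival_or[HAPLOTYPES]
  if (any(is.na(or)) || any(or <= 0)) {
    stop("survival_or must give a positive odds ratio for every haplotype")
  }
  with_seed(seed, {
    draw <- function(n) {
      h1 <- sample.int(4, n, replace = TRUE, prob = f)
      h2 <- sample.int(4, n, replace = TRUE, prob = f)
      odds <- baseline_odds * or[h1] * or[h2]
      surv <- rbinom(n, 1, odds / (1 + odds)) == 1
      cbind(haplotypes_to_genotypes(h1, h2), survived = surv)
    }
    dead <- survivor <- NULL
    guard <- 0
    while (is.null(dead) || nrow(dead) < n_per_arm ||
           nrow(survivor) < n_per_arm) {
      guard <- guard + 1
      if (guard > 200) stop("could not fill both outcome arms; odds too extreme")
      chunk <- draw(max(4 * n_per_arm, 400))
      dead <- rbind(dead, chunk[!chunk$survived, , drop = FALSE])
      survivor <- rbind(survivor, chunk[chunk$survived, , drop = FALSE])
    }
    dead <- dead[seq_len(n_per_arm), c("genotype_1014", "genotype_1575")]
    survivor <- survivor[seq_len(n_per_arm), c("genotype_1014", "genotype_1575")]
    parts <- list(
      cbind(status = "dead", dead),
      cbind(status = "survivor", survivor)
    )
    if (n_control > 0) {
      ctl <- draw(n_control)[, c("genotype_1014", "genotype_1575")]
      parts <- c(list(cbind(status = "control", ctl)), parts)
    }
    out <- do.call(rbind, parts)
    out <- data.frame(
      specimen_id = sprintf("S%05d", seq_len(nrow(out))),
      site = site, round = round,
      status = out$status,
      genotype_1014 = out$genotype_1014,
      genotype_1575 = out$genotype_1575,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    attr(out, "params") <- list(haplotype_freqs = f, survival_or = or,
                                n_per_arm = n_per_arm,
                                n_control = n_control,
                                baseline_odds = baseline_odds, seed = seed)
    out
  })
}

#' Simulate an efficiency-corrected qPCR plate
#'
#' Ct values are generated from the amplification model
#' `Ct = base_ct - log(level) / log(E)` plus Gaussian noise, so the
#' efficiency-corrected ddCt estimator recovers `relative_levels` in
#' expectation. Reference genes are constant across populations up to noise.
#'
#' @param relative_levels named vector, one entry per population-year, of
#'   true expression relative to the calibrator population (the calibrator
#'   should have level 1).
#' @param efficiencies named per-gene amplification efficiency, fold
#'   amplification per cycle, in (1, 2].
#' @param reference_genes names within `efficiencies` playing the reference
#'   (housekeeping) role; the rest are targets.
#' @param n_replicates biological replicates per population (default 6).
#' @param noise_sd Ct noise SD (cycles).
#' @param base_ct nominal Ct of a level-1 sample.
#' @param seed RNG seed.
#' @return data.frame: replicate_id, population_year, gene, role, Ct,
#'   efficiency.
#' @export
simulate_qpcr <- function(relative_levels,
                          efficiencies = c(CYP6P4 = 1.95, UBIQ = 1.9,
                                           ELF = 2.0, RPS7 = 1.85),
                          reference_genes = c("UBIQ", "ELF", "RPS7"),
                          n_replicates = 6, noise_sd = 0.2,
                          base_ct = 24, seed = 1) {
  stopifnot(n_replicates >= 1, noise_sd >= 0,
            all(reference_genes %in% names(efficiencies)))
  if (any(efficiencies <= 1) || any(efficiencies > 2)) {
    stop("amplification efficiencies must lie in (1, 2]")
  }
  if (any(relative_levels <= 0)) stop("relative_levels must be positive")
  pops <- names(relative_levels)
  genes <- names(efficiencies)
  with_seed(seed, {
    rows <- list()
    k <- 0
    for (p in pops) {
      for (r in seq_len(n_replicates)) {
        for (g in genes) {
          k <- k + 1
          is_ref <- g %in% reference_genes
          level <- if (is_ref) 1 else relative_levels[[p]]
          ct <- base_ct - log(level) / log(efficiencies[[g]]) +
            rnorm(1, 0, noise_sd)
          rows[[k]] <- data.frame(
            replicate_id = sprintf("%s_rep%d", p, r),
            population_year = p, gene = g,
            role = if (is_ref) "reference" else "target",
            Ct = ct, efficiency = efficiencies[[g]],
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  })
}
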