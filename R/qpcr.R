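#' Average technical replicate wells into per-biological-replicate Ct
#'
#' qPCR reactions run in technical triplicate are averaged to one Ct per
#' biological replicate per gene. Wells more than `outlier_cycles` from the
#' within-group median are flagged (column `n_outlier_wells`), not removed.
#'
#' @param wells data.frame: replicate_id, population_year, gene, role, Ct,
#'   efficiency, one row per well.
#' @param outlier_cycles flag threshold in cycles (default 0.5).
#' @return plate data.frame with one row per (replicate_id, gene).
#' @export
aggregate_technical_replicates <- function(wells, outlier_cycles = 0.5) {
  key <- interaction(wells$replicate_id, wells$gene, drop = TRUE)
  parts <- lapply(split(wells, key), function(w) {
    dev <- abs(w$Ct - stats::median(w$Ct))
    out <- w[1, , drop = FALSE]
    out$Ct <- mean(w$Ct)
    out$n_outlier_wells <- sum(dev > outlier_cycles)
    out
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

validate_plate <- function(plate, n_reference = 3) {
  need <- c("replicate_id", "population_year", "gene", "role", "Ct",
            "efficiency")
  missing <- setdiff(need, names(plate))
  if (length(missing) > 0) stop("plate lacks columns: ",
                                paste(missing, collapse = ", "))
  if (any(!is.finite(plate$Ct)) || any(plate$Ct <= 0)) {
    stop("Ct values must be finite and positive")
  }
  if (any(plate$efficiency <= 1 | plate$efficiency > 2)) {
    stop("amplification efficiencies must lie in (1, 2]")
  }
  refs <- unique(plate$gene[plate$role == "reference"])
  if (length(refs) != n_reference) {
    warning("expected ", n_reference, " reference genes, found ",
            length(refs))
  }
  if (!any(plate$role == "target")) stop("plate has no target genes")
  invisible(plate)
}

#' Efficiency-corrected relative expression (ddCt with per-primer efficiency)
#'
#' For each biological replicate and target gene, the target quantity
#' relative to the calibrator population is
#' `E_target^(Ct_cal_target - Ct_sample_target)` where `Ct_cal_*` is the
#' mean Ct of the calibrator population; it is normalized by the reference
#' factor, the geometric mean over the reference (housekeeping) genes of
#' `E_ref^(Ct_cal_ref - Ct_sample_ref)`. (With all efficiencies equal to 2
#' this reduces to the classical `2^-ddCt`.) Ratios are summarized per
#' population as mean and SEM over biological replicates; the calibrator
#' population's mean ratio is 1 by construction only in the noise-free
#' case, so the calibrator mean is reported like any other population.
#'
#' @param plate plate data.frame (one row per replicate per gene; run
#'   [aggregate_technical_replicates()] first if wells are technical
#'   replicates).
#' @param calibrator population_year label used as baseline.
#' @param ref_aggregation `"geomean"` (default): geometric mean of per-gene
#'   relative quantities; `"meanct"`: arithmetic mean of reference Ct
#'   values before applying a common (geometric-mean) efficiency.
#' @param n_reference expected number of reference genes (default 3).
#' @return list of class `relative_expression`: `ratios` (per replicate per
#'   target), `summary` (per population per target: mean ratio, SEM, n),
#'   `calibrator`. Replicates missing any reference Ct are dropped with a
#'   `dropped` attribute on `ratios`.
#' @export
relative_expression <- function(plate, calibrator,
                                ref_aggregation = c("geomean", "meanct"),
                                n_reference = 3) {
  ref_aggregation <- match.arg(ref_aggregation)
  validate_plate(plate, n_reference)
  if (!calibrator %in% plate$population_year) {
    stop("calibrator population not on plate: ", calibrator)
  }
  targets <- unique(plate$gene[plate$role == "target"])
  refs <- unique(plate$gene[plate$role == "reference"])
  eff <- vapply(c(targets, refs), function(g) {
    plate$efficiency[match(g, plate$gene)]
  }, 0)
  cal <- plate[plate$population_year == calibrator, ]
  cal_ct <- vapply(c(targets, refs), function(g) {
    mean(cal$Ct[cal$gene == g])
  }, 0)
  if (anyNA(cal_ct)) stop("calibrator population lacks Ct for some gene")

  reps <- unique(plate[, c("replicate_id", "population_year")])
  dropped <- character()
  rows <- list()
  for (i in seq_len(nrow(reps))) {
    rp <- plate[plate$replicate_id == reps$replicate_id[i], ]
    ref_ct <- vapply(refs, function(g) {
      ct <- rp$Ct[rp$gene == g]
      if (length(ct) == 0) NA_real_ else mean(ct)
    }, 0)
    if (anyNA(ref_ct)) {
      dropped <- c(dropped, reps$replicate_id[i])
      next
    }
    norm_factor <- if (ref_aggregation == "geomean") {
      exp(mean(log(eff[refs]^(cal_ct[refs] - ref_ct))))
    } else {
      e_common <- exp(mean(log(eff[refs])))
      e_common^(mean(cal_ct[refs]) - mean(ref_ct))
    }
    for (g in targets) {
      ct <- rp$Ct[rp$gene == g]
      if (length(ct) == 0) next
      qty <- eff[[g]]^(cal_ct[[g]] - mean(ct))
      rows[[length(rows) + 1]] <- data.frame(
        replicate_id = reps$replicate_id[i],
        population_year = reps$population_year[i],
        gene = g, ratio = qty / norm_factor,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) stop("all replicates dropped (missing reference Ct)")
  ratios <- do.call(rbind, rows)
  attr(ratios, "dropped") <- dropped
  agg <- lapply(split(ratios, ratios[, c("population_year", "gene")],
                      drop = TRUE), function(d) {
    data.frame(population_year = d$population_year[1], gene = d$gene[1],
               mean_ratio = mean(d$ratio),
               sem = stats::sd(d$ratio) / sqrt(nrow(d)),
               n = nrow(d), stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  structure(list(ratios = ratios, summary = summary,
                 calibrator = calibrator),
            class = "relative_expression")
}

#' @export
print.relative_expression <- function(x, ...) {
  cat("Relative expression (efficiency-corrected ddCt; calibrator: ",
      x$calibrator, ")\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Between-year comparison of normalized expression
#'
#' Two-sample two-tailed t-test on log-transformed relative expression
#' values of one target gene between two population-years (Welch by
#' default; pooled-variance by flag).
#'
#' @param result a `relative_expression` object (or its `ratios` table).
#' @param gene target gene.
#' @param year_a,year_b population_year labels to compare.
#' @param variant "welch" (default) or "pooled".
#' @return list: t, df, p, mean_log_a, mean_log_b, n_a, n_b.
#' @export
year_comparison <- function(result, gene, year_a, year_b,
                            variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  ratios <- if (inherits(result, "relative_expression")) result$ratios
            else result
  a <- log(ratios$ratio[ratios$gene == gene &
                          ratios$population_year == year_a])
  b <- log(ratios$ratio[ratios$gene == gene &
                          ratios$population_year == year_b])
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least 2 replicates per year (got ", length(a), " and ",
         length(b), ")")
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_log_a = mean(a), mean_log_b = mean(b),
       n_a = length(a), n_b = length(b))
}

#' Read / write a qPCR plate CSV
#'
#' Columns: replicate_id, population_year, gene, role, Ct, efficiency.
#' @param path file path.
#' @rdname qpcr_io
#' @export
read_qpcr_plate <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @param plate plate data.frame.
#' @rdname qpcr_io
#' @export
write_qpcr_plate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
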