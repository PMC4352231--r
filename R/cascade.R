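#' Configuration of the candidate-gene filtering cascade
#'
#' The cascade encodes three biological hypotheses as intersective filters
#' on the merged contrast table: candidate resistance genes are (steps A-C)
#' over-expressed in the resistant field populations relative to every
#' susceptible laboratory colony, (step E) more strongly over-expressed in
#' 2012 than 2011 as resistance escalated, and (step D) higher in the
#' intensely resistant VK7 population than in moderately resistant
#' Tengrela.
#'
#' @param q_threshold FDR threshold for "significant" (default 0.05).
#' @param resistant_vs_susceptible contrast labels for steps A-C.
#' @param vk7_vs_ten contrast label for step D.
#' @param year_pair ordered pair of contrast labels (2012 first) whose fold
#'   changes step E compares.
#' @param significance_mode `"all"`: q below threshold required in every
#'   step A-C contrast (strict reading of "consistently significant");
#'   `"any"`: in at least one.
#' @param na_q how to treat probes whose q is undefined: `"keep"` (default)
#'   passes the significance component on sign alone — undefined q arises
#'   only from exact zero-residual fits on noise-free data; `"drop"`
#'   excludes them.
#' @return a `cascade_config` list.
#' @export
cascade_config <- function(q_threshold = 0.05,
                           resistant_vs_susceptible = c("VKR2011_vs_MAL2011",
                                                        "VKR2012_vs_MAL2012",
                                                        "VKR2012_vs_NG2012"),
                           vk7_vs_ten = "VKR2012_vs_TEN2012",
                           year_pair = c("VKR2012_vs_MAL2012",
                                         "VKR2011_vs_MAL2011"),
                           significance_mode = c("all", "any"),
                           na_q = c("keep", "drop")) {
  stopifnot(q_threshold > 0, q_threshold < 1, length(year_pair) == 2,
            length(vk7_vs_ten) == 1)
  structure(list(q_threshold = q_threshold,
                 resistant_vs_susceptible = resistant_vs_susceptible,
                 vk7_vs_ten = vk7_vs_ten,
                 year_pair = year_pair,
                 significance_mode = match.arg(significance_mode),
                 na_q = match.arg(na_q)),
            class = "cascade_config")
}

check_cascade_contrasts <- function(contrasts, config) {
  need <- unique(c(config$resistant_vs_susceptible, config$vk7_vs_ten,
                   config$year_pair))
  have <- unique(contrasts$contrast)
  missing <- setdiff(need, have)
  if (length(missing) > 0) {
    stop("contrast table lacks contrast(s) required by the cascade: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

# wide matrices of log2FC / q, probes x contrasts
contrast_wide <- function(contrasts, value) {
  probes <- unique(contrasts$probe_id)
  cts <- unique(contrasts$contrast)
  m <- matrix(NA_real_, length(probes), length(cts),
              dimnames = list(probes, cts))
  m[cbind(match(contrasts$probe_id, probes),
          match(contrasts$contrast, cts))] <- contrasts[[value]]
  m
}

sig_pass <- function(qm, threshold, na_q) {
  if (na_q == "keep") ifelse(is.na(qm), TRUE, qm < threshold)
  else !is.na(qm) & qm < threshold
}

#' Steps A-C: consistent regulation across resistant-vs-susceptible contrasts
#'
#' Retains probes whose log2 fold change has the requested sign in every
#' configured resistant-vs-susceptible contrast and which meet the FDR
#' threshold under the configured significance mode. Probes missing any
#' configured contrast are excluded (reported via the `dropped_incomplete`
#' attribute), not an error.
#'
#' @param contrasts ContrastTable from [fit_contrasts()] /
#'   [merge_contrast_tables()].
#' @param config a [cascade_config()].
#' @param direction +1 for up-regulated (default), -1 for the
#'   down-regulated mirror.
#' @return character vector of surviving probe ids.
#' @export
step_up_consistent <- function(contrasts, config, direction = 1) {
  check_cascade_contrasts(contrasts, config)
  cts <- config$resistant_vs_susceptible
  fc <- contrast_wide(contrasts, "log2FC")[, cts, drop = FALSE]
  qm <- contrast_wide(contrasts, "q")[, cts, drop = FALSE]
  complete <- !is.na(rowSums(fc))
  sign_ok <- rowSums(direction * fc > 0) == length(cts)
  sp <- sig_pass(qm, config$q_threshold, config$na_q)
  sig_ok <- if (config$significance_mode == "all") {
    rowSums(sp) == length(cts)
  } else {
    rowSums(sp) >= 1
  }
  keep <- complete & sign_ok & sig_ok
  out <- rownames(fc)[keep]
  attr(out, "dropped_incomplete") <- rownames(fc)[!complete]
  out
}

#' Step E: stronger fold change in 2012 than 2011
#'
#' Retains survivors whose VK7/MAL log2 fold change is strictly greater in
#' 2012 than in 2011 (point estimates only; no test on the difference).
#' Under `direction = -1` (down-regulated mirror) this step is conventionally
#' skipped by the caller.
#'
#' @param survivors probe ids from the previous step.
#' @inheritParams step_up_consistent
#' @return surviving probe ids.
#' @export
step_year_increase <- function(survivors, contrasts, config) {
  check_cascade_contrasts(contrasts, config)
  fc <- contrast_wide(contrasts, "log2FC")
  surv <- intersect(survivors, rownames(fc))
  y12 <- fc[surv, config$year_pair[1]]
  y11 <- fc[surv, config$year_pair[2]]
  keep <- !is.na(y12) & !is.na(y11) & y12 > y11
  surv[keep]
}

#' Step D: significantly higher in VK7 than Tengrela
#'
#' @inheritParams step_year_increase
#' @param direction +1 retains probes significantly over-expressed in VK7
#'   vs TEN; -1 retains the under-expressed mirror.
#' @return surviving probe ids.
#' @export
step_vk7_over_ten <- function(survivors, contrasts, config, direction = 1) {
  check_cascade_contrasts(contrasts, config)
  ct <- config$vk7_vs_ten
  fc <- contrast_wide(contrasts, "log2FC")[, ct]
  qm <- contrast_wide(contrasts, "q")[, ct]
  surv <- intersect(survivors, names(fc))
  sp <- sig_pass(qm[surv], config$q_threshold, config$na_q)
  keep <- !is.na(fc[surv]) & (direction * fc[surv] > 0) & sp
  surv[keep]
}

#' Collapse probes to genes with mean fold change
#'
#' Aggregates a probe list to unique genes, averaging the per-probe fold
#' change (on the natural fold-change scale, `2^log2FC`) over the probes of
#' each gene on one reporting contrast. Probes absent from the map are
#' retained under their own probe_id as gene id and listed in the
#' `unmapped` attribute.
#'
#' @param probes character vector of probe ids.
#' @param probe_gene_map data.frame with columns probe_id, gene_id (one row
#'   per probe).
#' @param contrasts ContrastTable supplying fold changes.
#' @param contrast reporting contrast label for the mean FC.
#' @return data.frame: gene_id, mean_FC, n_probes (sorted by mean_FC
#'   descending).
#' @export
collapse_probes_to_genes <- function(probes, probe_gene_map, contrasts,
                                     contrast = "VKR2012_vs_MAL2012") {
  if (length(probes) == 0) {
    out <- data.frame(gene_id = character(), mean_FC = numeric(),
                      n_probes = integer(), stringsAsFactors = FALSE)
    attr(out, "unmapped") <- character()
    return(out)
  }
  if (anyDuplicated(probe_gene_map$probe_id)) {
    stop("probe_gene_map must map every probe to exactly one gene")
  }
  gene <- probe_gene_map$gene_id[match(probes, probe_gene_map$probe_id)]
  unmapped <- probes[is.na(gene)]
  gene[is.na(gene)] <- probes[is.na(gene)]
  fcw <- contrast_wide(contrasts, "log2FC")
  if (!contrast %in% colnames(fcw)) {
    stop("reporting contrast not present: ", contrast)
  }
  fc <- 2^fcw[probes, contrast]
  agg <- stats::aggregate(fc, by = list(gene_id = gene),
                          FUN = mean, na.rm = TRUE)
  cnt <- stats::aggregate(rep(1L, length(gene)), by = list(gene_id = gene),
                          FUN = sum)
  out <- data.frame(gene_id = agg$gene_id, mean_FC = agg$x,
                    n_probes = cnt$x, stringsAsFactors = FALSE)
  out <- out[order(-out$mean_FC, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}

#' Down-regulated mirror of the cascade
#'
#' Applies steps A-C and D with every inequality reversed (significant
#' down-regulation in all resistant-vs-susceptible contrasts, and
#' under-expression in VK7 relative to Tengrela); the year-increase step E
#' is not applied to the mirror.
#'
#' @inheritParams step_up_consistent
#' @param probe_gene_map optional map for the gene-level mirror list.
#' @return list with `probes` and (if a map is given) `genes`.
#' @export
down_regulated_mirror <- function(contrasts, config, probe_gene_map = NULL) {
  s1 <- step_up_consistent(contrasts, config, direction = -1)
  s2 <- step_vk7_over_ten(s1, contrasts, config, direction = -1)
  out <- list(probes = s2)
  if (!is.null(probe_gene_map)) {
    out$genes <- collapse_probes_to_genes(s2, probe_gene_map, contrasts,
                                          contrast = config$year_pair[1])
  }
  out
}

#' Hierarchically cluster candidate expression profiles
#'
#' Agglomerative clustering with Euclidean distance on per-probe log2
#' fold-change vectors (the three VK7-vs-susceptible comparisons in the
#' default pipeline). Average linkage; rows are sorted by probe_id before
#' clustering so tied merges resolve deterministically regardless of input
#' order.
#'
#' @param fc_profiles numeric matrix, probes (rownames) x contrasts.
#' @param linkage hclust agglomeration method (default "average").
#' @return list: `hclust` (the merge tree; NULL for a single probe),
#'   `order` (probe ids in leaf order), `heights` (merge heights), and the
#'   row-sorted `profiles` matrix for heatmap display.
#' @export
cluster_candidates <- function(fc_profiles, linkage = "average") {
  if (is.null(rownames(fc_profiles))) {
    stop("fc_profiles must have probe ids as rownames")
  }
  if (anyNA(fc_profiles)) stop("fc_profiles must be complete")
  fc_profiles <- fc_profiles[order(rownames(fc_profiles)), , drop = FALSE]
  if (nrow(fc_profiles) < 2) {
    return(list(hclust = NULL, order = rownames(fc_profiles),
                heights = numeric(), profiles = fc_profiles))
  }
  hc <- stats::hclust(stats::dist(fc_profiles, method = "euclidean"),
                      method = linkage)
  list(hclust = hc, order = hc$labels[hc$order], heights = hc$height,
       profiles = fc_profiles[hc$labels[hc$order], , drop = FALSE])
}

#' Run the full filtering cascade
#'
#' Applies steps A-C, E and D in the reporting order of the analysis
#' schema, collapses the final probe list to genes, builds the
#' down-regulated mirror, and clusters the candidate fold-change profiles.
#'
#' @inheritParams step_up_consistent
#' @param probe_gene_map data.frame probe_id -> gene_id.
#' @param cluster_contrasts contrasts forming the clustering profile
#'   (default: the step A-C contrasts).
#' @param linkage clustering linkage.
#' @return `cascade_result` list: `steps` (named probe-id sets in order
#'   up_consistent / year_increase / vk7_over_ten), `counts`,
#'   `candidate_probes`, `candidate_genes`, `down_regulated`, `clustering`.
#' @export
run_cascade <- function(contrasts, config = cascade_config(),
                        probe_gene_map = NULL,
                        cluster_contrasts = config$resistant_vs_susceptible,
                        linkage = "average") {
  check_cascade_contrasts(contrasts, config)
  sAC <- step_up_consistent(contrasts, config)
  sE <- step_year_increase(sAC, contrasts, config)
  sD <- step_vk7_over_ten(sE, contrasts, config)
  genes <- if (!is.null(probe_gene_map)) {
    collapse_probes_to_genes(sD, probe_gene_map, contrasts,
                             contrast = config$year_pair[1])
  }
  down <- down_regulated_mirror(contrasts, config, probe_gene_map)
  clustering <- if (length(sD) > 0) {
    fcw <- contrast_wide(contrasts, "log2FC")
    cluster_candidates(fcw[sD, cluster_contrasts, drop = FALSE],
                       linkage = linkage)
  }
  steps <- list(up_consistent = as.character(sAC),
                year_increase = as.character(sE),
                vk7_over_ten = as.character(sD))
  structure(list(
    steps = steps,
    counts = c(up_consistent = length(sAC), year_increase = length(sE),
               vk7_over_ten = length(sD),
               candidate_genes = if (is.null(genes)) NA_integer_ else nrow(genes),
               down_probes = length(down$probes),
               down_genes = if (is.null(down$genes)) NA_integer_ else nrow(down$genes)),
    candidate_probes = as.character(sD),
    candidate_genes = genes,
    down_regulated = down,
    clustering = clustering,
    config = config
  ), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Candidate-gene filtering cascade\n")
  cat(sprintf("  consistent up in resistant vs susceptible : %d probes\n",
              x$counts[["up_consistent"]]))
  cat(sprintf("  higher fold change in 2012 than 2011      : %d probes\n",
              x$counts[["year_increase"]]))
  cat(sprintf("  significantly higher in VK7 than TEN      : %d probes\n",
              x$counts[["vk7_over_ten"]]))
  if (!is.na(x$counts[["candidate_genes"]])) {
    cat(sprintf("  unique candidate genes                    : %d\n",
                x$counts[["candidate_genes"]]))
  }
  cat(sprintf("  down-regulated mirror                     : %d probes\n",
              x$counts[["down_probes"]]))
  invisible(x)
}

#' Serialize a candidate dendrogram to Newick
#'
#' @param clustering output of [cluster_candidates()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  if (is.null(clustering$hclust)) {
    writeLines(paste0("(", clustering$order, ");"), path)
    return(invisible(path))
  }
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("Newick export needs the 'ape' package")
  }
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}
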