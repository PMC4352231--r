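#' Default pipeline configuration
#'
#' Every threshold, method choice and seed of the pipeline lives in one
#' flat configuration list, recorded verbatim in the run manifest so a run
#' is reproducible from manifest plus inputs. Stage seeds are derived
#' deterministically from the master seed.
#'
#' @param seed master RNG seed.
#' @param stages stages to run, in dependency order.
#' @param ... named overrides merged over the defaults (nested lists merge
#'   one level deep, e.g. `synth = list(noise_sd = 0)`).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, stages = c("synth", "de", "cascade",
                                            "kdr", "qpcr"), ...) {
  cfg <- list(
    seed = seed,
    stages = stages,
    synth = list(n_probes = 1000, n_replicates = 3, noise_sd = 0.25,
                 dye_bias = 0.1, array_effect_sd = 0.1),
    de = list(method = "median", dye_effect = TRUE, epsilon = 1,
              contrasts = NULL),
    cascade = list(q_threshold = 0.05, significance_mode = "all",
                   na_q = "keep", linkage = "average"),
    kdr = list(haplotype_freqs = c("L-N" = 0.15, "L-Y" = 0, "F-N" = 0.55,
                                   "F-Y" = 0.30),
               survival_or = c("L-N" = 1, "L-Y" = 1, "F-N" = 1,
                               "F-Y" = 2.7),
               n_per_arm = 500, mode = "pooled"),
    qpcr = list(relative_levels = c(VK7_2011 = 1, VK7_2012 = 3,
                                    VK7_2013 = 9),
                n_replicates = 6, noise_sd = 0.2, calibrator = "VK7_2011")
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' @param path JSON file of overrides over [run_config()] defaults.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  known <- c("synth", "de", "cascade", "kdr", "qpcr")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("cascade" %in% config$stages) {
    if (!"de" %in% config$stages) {
      stop("stage 'cascade' needs stage 'de' upstream")
    }
    cc <- cascade_config(q_threshold = config$cascade$q_threshold,
                         significance_mode = config$cascade$significance_mode,
                         na_q = config$cascade$na_q)
    contrasts <- config$de$contrasts %||%
      unique(c(cc$resistant_vs_susceptible, cc$vk7_vs_ten, cc$year_pair))
    need <- unique(c(cc$resistant_vs_susceptible, cc$vk7_vs_ten,
                     cc$year_pair))
    missing <- setdiff(need, contrasts)
    if (length(missing) > 0) {
      stop("cascade stage enabled but contrast(s) not fitted by the de ",
           "stage: ", paste(missing, collapse = ", "))
    }
  }
  if ("de" %in% config$stages && !"synth" %in% config$stages) {
    stop("stage 'de' needs stage 'synth' upstream (or run the stages ",
         "manually on external intensity tables)")
  }
  invisible(config)
}

stage_fingerprint <- function(config, stage, extra = NULL) {
  payload <- paste(utils::capture.output(utils::str(
    list(seed = config$seed, params = config[[stage]], extra = extra)
  )), collapse = "\n")
  # md5 of the serialized parameters via a temp file (tools::md5sum is file-based)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(payload, tf)
  unname(tools::md5sum(tf))
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

#' Run the synthetic -> DE -> cascade (and kdr / qPCR) pipeline
#'
#' Executes the configured stages in dependency order into `out_dir`,
#' writing each stage's tables plus a JSON manifest holding the full
#' configuration, derived stage seeds, per-stage probe counts and md5
#' hashes of every output file. A stage whose parameter fingerprint and
#' output files are unchanged from a previous run in the same directory is
#' reused, not recomputed. Configuration problems (unknown stages, cascade
#' contrasts not fitted upstream) are reported before any computation.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @return the manifest list, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
             error = function(e) NULL)
  }
  manifest <- list(config = unclass(config), stages = list())
  seeds <- list(synth = config$seed, kdr = config$seed + 1000L,
                qpcr = config$seed + 2000L)

  reuse <- function(stage, fp, files) {
    !is.null(prev) && !is.null(prev$stages[[stage]]) &&
      identical(prev$stages[[stage]]$fingerprint, fp) &&
      all(file.exists(file.path(out_dir, files)))
  }
  record <- function(stage, fp, files, info = NULL) {
    manifest$stages[[stage]] <<- list(
      fingerprint = fp,
      files = as.list(hash_files(file.path(out_dir, files))),
      info = info
    )
  }

  sim <- NULL
  if ("synth" %in% config$stages) {
    fp <- stage_fingerprint(config, "synth")
    files <- c("truth.tsv", "design.tsv", "intensities.tsv")
    if (!reuse("synth", fp, files)) {
      truth <- expression_truth(n_probes = config$synth$n_probes,
                                seed = seeds$synth)
      design <- rbind(as.data.frame(loop_design(2011,
                                                config$synth$n_replicates)),
                      as.data.frame(loop_design(2012,
                                                config$synth$n_replicates)))
      design <- hybridization_design(design, require_connected = FALSE)
      sim <- simulate_two_color_experiment(
        design, truth, noise_sd = config$synth$noise_sd,
        dye_bias = config$synth$dye_bias,
        array_effect_sd = config$synth$array_effect_sd, seed = seeds$synth)
      write_tsv(truth, file.path(out_dir, "truth.tsv"))
      write_design(design, file.path(out_dir, "design.tsv"))
      write_intensity_table(sim$intensities,
                            file.path(out_dir, "intensities.tsv"))
    }
    record("synth", fp, files)
  }

  contrast_table <- NULL
  if ("de" %in% config$stages) {
    cc_default <- cascade_config()
    contrasts <- config$de$contrasts %||%
      unique(c(cc_default$resistant_vs_susceptible, cc_default$vk7_vs_ten,
               cc_default$year_pair))
    fp <- stage_fingerprint(config, "de",
                            extra = manifest$stages$synth$fingerprint)
    files <- "contrasts.tsv"
    if (reuse("de", fp, files)) {
      contrast_table <- read_contrast_table(file.path(out_dir,
                                                      "contrasts.tsv"))
    } else {
      design <- read_design(file.path(out_dir, "design.tsv"),
                            require_connected = FALSE)
      intensities <- read_intensity_table(file.path(out_dir,
                                                    "intensities.tsv"))
      tabs <- lapply(c("2011", "2012"), function(yr) {
        sub <- design[grepl(yr, design$cy3_sample) |
                        grepl(yr, design$cy5_sample), , drop = FALSE]
        sub <- hybridization_design(as.data.frame(sub))
        ints <- intensities[intensities$array_id %in% sub$array_id, ]
        norm <- normalize_intensities(ints, method = config$de$method,
                                      epsilon = config$de$epsilon)
        cts <- contrasts[vapply(contrasts, function(ct) {
          all(parse_contrast(ct) %in% design_populations(sub))
        }, TRUE)]
        fit_contrasts(norm, sub, cts, dye_effect = config$de$dye_effect)
      })
      contrast_table <- do.call(merge_contrast_tables, tabs)
      write_contrast_table(contrast_table,
                           file.path(out_dir, "contrasts.tsv"))
    }
    record("de", fp, files)
  }

  if ("cascade" %in% config$stages) {
    fp <- stage_fingerprint(config, "cascade",
                            extra = manifest$stages$de$fingerprint)
    files <- c("candidate_probes.tsv", "candidate_genes.tsv",
               "down_regulated_probes.tsv", "cluster_leaf_order.tsv")
    truth <- read_tsv(file.path(out_dir, "truth.tsv"))
    map <- truth[, c("probe_id", "gene_id")]
    cc <- cascade_config(q_threshold = config$cascade$q_threshold,
                         significance_mode = config$cascade$significance_mode,
                         na_q = config$cascade$na_q)
    res <- run_cascade(contrast_table, cc, probe_gene_map = map,
                       linkage = config$cascade$linkage)
    write_tsv(data.frame(probe_id = res$candidate_probes),
              file.path(out_dir, "candidate_probes.tsv"))
    write_tsv(res$candidate_genes, file.path(out_dir, "candidate_genes.tsv"))
    write_tsv(data.frame(probe_id = res$down_regulated$probes),
              file.path(out_dir, "down_regulated_probes.tsv"))
    write_tsv(data.frame(leaf = seq_along(res$clustering$order),
                         probe_id = res$clustering$order),
              file.path(out_dir, "cluster_leaf_order.tsv"))
    record("cascade", fp, files, info = as.list(res$counts))
  }

  if ("kdr" %in% config$stages) {
    fp <- stage_fingerprint(config, "kdr")
    files <- c("genotypes.csv", "haplotype_association.tsv")
    if (!reuse("kdr", fp, files)) {
      gt <- simulate_genotypes(haplotype_freqs = config$kdr$haplotype_freqs,
                               survival_or = config$kdr$survival_or,
                               n_per_arm = config$kdr$n_per_arm,
                               seed = seeds$kdr)
      write_genotypes(gt, file.path(out_dir, "genotypes.csv"))
      assoc <- haplotype_association(gt, mode = config$kdr$mode)
      write_tsv(assoc, file.path(out_dir, "haplotype_association.tsv"))
    }
    record("kdr", fp, files)
  }

  if ("qpcr" %in% config$stages) {
    fp <- stage_fingerprint(config, "qpcr")
    files <- c("qpcr_plate.csv", "relative_expression.tsv")
    if (!reuse("qpcr", fp, files)) {
      plate <- simulate_qpcr(
        relative_levels = config$qpcr$relative_levels,
        n_replicates = config$qpcr$n_replicates,
        noise_sd = config$qpcr$noise_sd, seed = seeds$qpcr)
      write_qpcr_plate(plate, file.path(out_dir, "qpcr_plate.csv"))
      rel <- relative_expression(plate, calibrator = config$qpcr$calibrator)
      write_tsv(rel$summary, file.path(out_dir, "relative_expression.tsv"))
    }
    record("qpcr", fp, files)
  }

  manifest$seeds <- seeds
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
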