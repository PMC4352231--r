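#' Hybridization design for a two-colour loop experiment
#'
#' A hybridization design records, for every array, which population sample
#' was labelled with cy3 and which with cy5, plus a biological-replicate
#' index. Populations are the nodes and arrays the edges of the design
#' graph; all pairwise contrasts are estimable if and only if that graph is
#' connected.
#'
#' @param arrays data.frame with columns `array_id`, `cy3_sample`,
#'   `cy5_sample`, `replicate` (optional `dye_orientation`).
#' @param require_connected error on a disconnected design graph (default
#'   TRUE). Simulation of several independent experiments at once may relax
#'   this; model fitting re-checks connectivity regardless.
#' @return A `hybridization_design` object (a validated data.frame).
#' @export
hybridization_design <- function(arrays, require_connected = TRUE) {
  required <- c("array_id", "cy3_sample", "cy5_sample", "replicate")
  missing <- setdiff(required, names(arrays))
  if (length(missing) > 0) {
    stop("design is missing columns: ", paste(missing, collapse = ", "))
  }
  keep <- c(required, intersect("dye_orientation", names(arrays)))
  arrays <- as.data.frame(arrays)[, keep]
  arrays$array_id <- as.character(arrays$array_id)
  arrays$cy3_sample <- as.character(arrays$cy3_sample)
  arrays$cy5_sample <- as.character(arrays$cy5_sample)
  if (anyDuplicated(arrays$array_id)) {
    stop("duplicated array_id in design")
  }
  if (any(arrays$cy3_sample == arrays$cy5_sample)) {
    bad <- arrays$array_id[arrays$cy3_sample == arrays$cy5_sample]
    stop("self-hybridization (cy3_sample == cy5_sample) on array(s): ",
         paste(bad, collapse = ", "))
  }
  if (require_connected) {
    comps <- design_components(arrays)
    if (length(comps) > 1) {
      stop("design graph is disconnected; components: ",
           paste(vapply(comps, paste, "", collapse = "+"), collapse = " | "))
    }
  }
  class(arrays) <- c("hybridization_design", "data.frame")
  arrays
}

#' @export
print.hybridization_design <- function(x, ...) {
  cat("Two-colour hybridization design:", nrow(x), "arrays,",
      length(design_populations(x)), "populations\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Populations appearing in a design
#' @param design a `hybridization_design`.
#' @return character vector of population labels (sorted).
#' @export
design_populations <- function(design) {
  sort(unique(c(design$cy3_sample, design$cy5_sample)))
}

# Connected components of the design graph (populations as nodes).
design_components <- function(design) {
  nodes <- sort(unique(c(design$cy3_sample, design$cy5_sample)))
  comp <- stats::setNames(seq_along(nodes), nodes)
  for (i in seq_len(nrow(design))) {
    a <- comp[[design$cy3_sample[i]]]
    b <- comp[[design$cy5_sample[i]]]
    if (a != b) comp[comp == b] <- a
  }
  unname(split(nodes, comp))
}

#' Emulated loop designs of the 2011 and 2012 array experiments
#'
#' The 2011 experiment compared deltamethrin-selected VK7 mosquitoes
#' (VKR2011), unexposed VK7 mosquitoes (VKC2011) and the Mali susceptible
#' colony (MAL2011) in a triangle with three biological replicates per
#' comparison. The 2012 experiment interwove deltamethrin-selected VK7
#' (VKR2012), unexposed Tengrela (TEN2012), and two susceptible colonies
#' (MAL2012, N'Gousso NG2012); all pairwise comparisons with three
#' replicates each. Dye orientation alternates across replicates so a dye
#' term is estimable.
#'
#' @param year 2011 or 2012.
#' @param n_replicates biological replicates per comparison (default 3).
#' @return A [hybridization_design()].
#' @export
loop_design <- function(year = c(2011, 2012), n_replicates = 3) {
  year <- match.arg(as.character(year[1]), c("2011", "2012"))
  pairs <- if (year == "2011") {
    list(c("VKR2011", "MAL2011"), c("VKC2011", "MAL2011"),
         c("VKR2011", "VKC2011"))
  } else {
    list(c("VKR2012", "MAL2012"), c("VKR2012", "NG2012"),
         c("VKR2012", "TEN2012"), c("TEN2012", "MAL2012"),
         c("TEN2012", "NG2012"), c("MAL2012", "NG2012"))
  }
  rows <- list()
  k <- 0L
  for (p in pairs) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      # alternate dye orientation across replicates (dye swap)
      fwd <- (r %% 2L) == 1L
      rows[[k]] <- data.frame(
        array_id = sprintf("A%s_%02d", year, k),
        cy3_sample = if (fwd) p[1] else p[2],
        cy5_sample = if (fwd) p[2] else p[1],
        replicate = r,
        stringsAsFactors = FALSE
      )
    }
  }
  hybridization_design(do.call(rbind, rows))
}

#' Read / write a design TSV
#'
#' Columns: array_id, cy3_sample, cy5_sample, replicate.
#' @param path file path.
#' @param require_connected passed to [hybridization_design()].
#' @rdname design_io
#' @export
read_design <- function(path, require_connected = TRUE) {
  hybridization_design(utils::read.delim(path, stringsAsFactors = FALSE),
                       require_connected = require_connected)
}

#' @param design a `hybridization_design`.
#' @rdname design_io
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
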