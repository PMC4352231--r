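#' Within-array normalization of two-colour intensities
#'
#' Computes per-probe log ratios `M = log2(cy5) - log2(cy3)` and average
#' log intensities `A = (log2(cy5) + log2(cy3)) / 2`, then centres M within
#' each array: `median` subtracts the per-array median of M; `loess`
#' subtracts an intensity-dependent smooth of M on A (lowess), removing
#' intensity-dependent dye bias.
#'
#' Intensities in `(0, epsilon)` are floored at `epsilon`; non-positive
#' intensities cannot be logged and are flagged (`flagged = TRUE`, M and A
#' set to NA) and excluded from model fitting. An array whose intensities
#' are all non-positive is a hard error.
#'
#' @param intensities data.frame with columns probe_id, array_id, cy3, cy5.
#' @param method "median" (default) or "loess".
#' @param epsilon background floor in intensity units (default 1).
#' @param span lowess span for `method = "loess"`.
#' @return data.frame: probe_id, array_id, M, A, flagged.
#' @export
normalize_intensities <- function(intensities, method = c("median", "loess"),
                                  epsilon = 1, span = 0.4) {
  method <- match.arg(method)
  stopifnot(all(c("probe_id", "array_id", "cy3", "cy5") %in%
                  names(intensities)), epsilon > 0)
  cy3 <- intensities$cy3
  cy5 <- intensities$cy5
  bad <- !is.finite(cy3) | !is.finite(cy5) | cy3 <= 0 | cy5 <= 0
  cy3 <- pmax(cy3, epsilon)
  cy5 <- pmax(cy5, epsilon)
  M <- ifelse(bad, NA_real_, log2(cy5) - log2(cy3))
  A <- ifelse(bad, NA_real_, (log2(cy5) + log2(cy3)) / 2)
  out <- data.frame(probe_id = intensities$probe_id,
                    array_id = intensities$array_id,
                    M = M, A = A, flagged = bad,
                    stringsAsFactors = FALSE)
  for (aid in unique(out$array_id)) {
    idx <- out$array_id == aid
    m <- out$M[idx]
    if (all(is.na(m))) stop("array ", aid, " has no usable intensities")
    if (method == "median") {
      out$M[idx] <- m - stats::median(m, na.rm = TRUE)
    } else {
      a <- out$A[idx]
      ok <- !is.na(m)
      fit <- stats::lowess(a[ok], m[ok], f = span)
      trend <- stats::approx(fit$x, fit$y, xout = a[ok], rule = 2)$y
      m[ok] <- m[ok] - trend
      out$M[idx] <- m
    }
  }
  out
}

#' Fixed-effects design matrix for log ratios of a loop design
#'
#' Each array contributes one row of the model
#' `E(M) = effect(cy5 population) - effect(cy3 population) (+ dye)`.
#' One reference population is absorbed (its column dropped), so
#' coefficients are log2 expression relative to the reference. When
#' `dye_effect` is TRUE a common dye coefficient is added whose entry is the
#' array's `dye_orientation` (+1 unless the design records the array in
#' swapped channel orientation), so that relabelling an array's channels and
#' negating its M leaves every estimate unchanged.
#'
#' @param design a [hybridization_design()]; an optional `dye_orientation`
#'   column (+1/-1) records channel orientation.
#' @param dye_effect include the common dye coefficient (default TRUE).
#' @param reference population absorbed as baseline (default: first in
#'   alphabetical order).
#' @return numeric matrix, one row per array, with attributes `populations`
#'   and `reference`.
#' @export
build_design_matrix <- function(design, dye_effect = TRUE, reference = NULL) {
  stopifnot(inherits(design, "hybridization_design"))
  comps <- design_components(design)
  if (length(comps) > 1) {
    stop("design graph is disconnected; components: ",
         paste(vapply(comps, paste, "", collapse = "+"), collapse = " | "))
  }
  pops <- design_populations(design)
  if (is.null(reference)) reference <- pops[1]
  if (!reference %in% pops) stop("reference population not in design: ", reference)
  coef_pops <- setdiff(pops, reference)
  orient <- design$dye_orientation
  if (is.null(orient)) orient <- rep(1, nrow(design))
  stopifnot(all(orient %in% c(-1, 1)))
  X <- matrix(0, nrow(design), length(coef_pops) + as.integer(dye_effect),
              dimnames = list(design$array_id,
                              c(coef_pops, if (dye_effect) "dye")))
  for (i in seq_len(nrow(design))) {
    c5 <- design$cy5_sample[i]
    c3 <- design$cy3_sample[i]
    if (c5 %in% coef_pops) X[i, c5] <- X[i, c5] + 1
    if (c3 %in% coef_pops) X[i, c3] <- X[i, c3] - 1
  }
  if (dye_effect) X[, "dye"] <- orient
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient; some effects are inestimable ",
         "(columns: ", paste(colnames(X), collapse = ", "), ")")
  }
  structure(X, populations = pops, reference = reference)
}

# contrast label "A_vs_B" <-> pair
contrast_label <- function(a, b) paste0(a, "_vs_", b)

parse_contrast <- function(label) {
  parts <- strsplit(label, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed contrast label: ", label)
  parts
}

#' Per-probe contrast estimates for a loop design
#'
#' Fits, for every probe, ordinary least squares of its normalized log
#' ratios on the loop-design matrix (population effects plus optional common
#' dye coefficient) and reports, per requested population contrast, the
#' log2 fold change, a two-sided t-test p-value on residual degrees of
#' freedom, and a Benjamini-Hochberg q-value computed within each contrast.
#'
#' Probes with zero residual degrees of freedom, or with an (to numerical
#' tolerance) exactly zero residual sum of squares, keep their estimates but
#' get `p = q = NA` and a flag — zero-residual fits arise on noise-free
#' synthetic data, where the estimate is exact and a p-value meaningless.
#'
#' @param normalized output of [normalize_intensities()].
#' @param design the [hybridization_design()] the intensities came from.
#' @param contrasts character vector of labels `"POPA_vs_POPB"` (log2FC of
#'   A over B) or list of population pairs.
#' @param dye_effect fit the common dye coefficient (default TRUE).
#' @param reference passed to [build_design_matrix()].
#' @return data.frame (ContrastTable): probe_id, contrast, log2FC, p, q,
#'   flag ("ok", "zero_residual", "no_df", "missing_arrays").
#' @export
fit_contrasts <- function(normalized, design, contrasts, dye_effect = TRUE,
                          reference = NULL) {
  if (is.list(contrasts)) {
    contrasts <- vapply(contrasts, function(p) contrast_label(p[1], p[2]), "")
  }
  X <- build_design_matrix(design, dye_effect = dye_effect,
                           reference = reference)
  pops <- attr(X, "populations")
  ref <- attr(X, "reference")
  # contrast vectors in coefficient space
  cvec <- function(label) {
    pr <- parse_contrast(label)
    if (!all(pr %in% pops)) {
      stop("contrast ", label, " references populations outside the design")
    }
    v <- setNames(numeric(ncol(X)), colnames(X))
    if (pr[1] != ref) v[pr[1]] <- 1
    if (pr[2] != ref) v[pr[2]] <- v[pr[2]] - 1
    v
  }
  cvs <- lapply(setNames(contrasts, contrasts), cvec)

  # wide matrix probes x arrays
  probes <- unique(normalized$probe_id)
  arrays <- rownames(X)
  Mw <- matrix(NA_real_, length(probes), length(arrays),
               dimnames = list(probes, arrays))
  ok <- !normalized$flagged & !is.na(normalized$M)
  Mw[cbind(match(normalized$probe_id[ok], probes),
           match(normalized$array_id[ok], arrays))] <- normalized$M[ok]

  XtXi <- solve(crossprod(X))
  H <- X %*% XtXi                       # arrays x p
  pfull <- ncol(X)
  complete <- !is.na(rowSums(Mw))

  est <- matrix(NA_real_, length(probes), length(contrasts),
                dimnames = list(probes, contrasts))
  pval <- est
  flag <- matrix("ok", length(probes), length(contrasts),
                 dimnames = list(probes, contrasts))

  fill <- function(rows, Xs, Ms, note) {
    # Ms: probes x arrays-subset; Xs matching design rows
    if (qr(Xs)$rank < ncol(Xs)) {
      flag[rows, ] <<- "missing_arrays"
      return(invisible())
    }
    XtXi_s <- solve(crossprod(Xs))
    B <- Ms %*% Xs %*% XtXi_s           # probes x p
    R <- Ms - B %*% t(Xs)
    rss <- rowSums(R^2)
    df <- nrow(Xs) - ncol(Xs)
    zero_res <- rss <= 1e-10 * pmax(rowSums(Ms^2), 1)
    s2 <- if (df > 0) rss / df else rep(NA_real_, length(rss))
    for (ct in names(cvs)) {
      cv <- cvs[[ct]]
      e <- drop(B %*% cv)
      est[rows, ct] <<- e
      vfac <- drop(t(cv) %*% XtXi_s %*% cv)
      if (df <= 0) {
        flag[rows, ct] <<- note %||% "no_df"
      } else {
        se <- sqrt(s2 * vfac)
        tt <- e / se
        pv <- 2 * stats::pt(-abs(tt), df)
        pv[zero_res] <- NA_real_
        pval[rows, ct] <<- pv
        flag[rows, ct][zero_res] <<- "zero_residual"
        if (!is.null(note)) flag[rows, ct][!zero_res] <<- note
      }
    }
    invisible()
  }

  if (any(complete)) fill(which(complete), X, Mw[complete, , drop = FALSE], NULL)
  for (i in which(!complete)) {
    have <- !is.na(Mw[i, ])
    if (sum(have) == 0) { flag[i, ] <- "missing_arrays"; next }
    fill(i, X[have, , drop = FALSE], Mw[i, have, drop = FALSE],
         "missing_arrays")
  }

  out <- data.frame(
    probe_id = rep(probes, times = length(contrasts)),
    contrast = rep(contrasts, each = length(probes)),
    log2FC = as.vector(est),
    p = as.vector(pval),
    flag = as.vector(flag),
    stringsAsFactors = FALSE
  )
  out$q <- NA_real_
  for (ct in contrasts) {
    idx <- out$contrast == ct
    out$q[idx] <- bh_adjust(out$p[idx])
  }
  out[, c("probe_id", "contrast", "log2FC", "p", "q", "flag")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values capped at 1 with enforced monotonicity; NA entries
#' (undefined p-values) stay NA and do not count toward the number of
#' tests.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Merge per-experiment contrast tables
#'
#' The 2011 and 2012 hybridizations are fitted as separate models; their
#' contrast tables are concatenated here for the downstream filtering
#' cascade. Probe sets need not be identical; duplicated
#' (probe_id, contrast) pairs are an error.
#'
#' @param ... ContrastTable data.frames from [fit_contrasts()].
#' @return single ContrastTable.
#' @export
merge_contrast_tables <- function(...) {
  out <- do.call(rbind, list(...))
  key <- paste(out$probe_id, out$contrast)
  if (anyDuplicated(key)) {
    stop("duplicated probe/contrast pairs across merged tables")
  }
  rownames(out) <- NULL
  out
}

#' Read / write a ContrastTable TSV
#' @param path file path.
#' @rdname contrast_io
#' @export
read_contrast_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param contrasts ContrastTable data.frame.
#' @rdname contrast_io
#' @export
write_contrast_table <- function(contrasts, path) {
  utils::write.table(contrasts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
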