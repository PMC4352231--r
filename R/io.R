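#' Read / write generic TSV tables
#'
#' Thin wrappers fixing the dialect used by every table the pipeline
#' exchanges (tab-separated, header, no quoting, no row names).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @rdname tsv_io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write an intensity table TSV
#'
#' Columns: probe_id, array_id, cy3, cy5.
#' @param intensities intensity data.frame.
#' @param path file path.
#' @rdname intensity_io
#' @export
write_intensity_table <- function(intensities, path) write_tsv(intensities, path)

#' @rdname intensity_io
#' @export
read_intensity_table <- function(path) read_tsv(path)

#' Bundled field allele counts for the kdr loci
#'
#' Loads the published allele counts of the L1014F and N1575Y mutations in
#' An. coluzzii from VK7 and Tengrela (2011-2013 collections, stratified by
#' deltamethrin exposure outcome), together with the frequencies and 95%
#' intervals as printed in the source study (columns `*_printed`) for
#' cross-checking.
#'
#' @return data.frame of allele-count rows.
#' @export
kdr_field_counts <- function() {
  path <- system.file("extdata", "kdr_allele_counts.csv",
                      package = "anoresist", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
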