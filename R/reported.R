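#' Worked-example table of conserved miRNA candidates
#'
#' The packaged table of nine conserved plant miRNA families used as the
#' package's worked example and as the default homology reference set:
#' family, miRBase-style id, mature sequence, star-mismatch count, the
#' magnitude of the reported folding free energy (kcal/mol) and the
#' MFEI. Feeding the `mfei` column to [summarize_mfei()] reproduces the
#' summary statistics quoted in the package documentation.
#'
#' @return a data.frame with columns `family`, `mirna_id`, `mature_seq`,
#'   `mismatch`, `delta_g_mag`, `mfei`.
#' @examples
#' summarize_mfei(reported_mirna_table()$mfei)
#' @export
reported_mirna_table <- function() {
  path <- system.file("extdata", "reported_mirnas.tsv", package = "mirssr",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
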