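#' Published mass-assignment table for Chroococcidiopsis cubana CCALA 043
#'
#' Sequence-derived protein masses (monoisotopic and average, with and
#' without the N-terminal methionine, in Da), the observed intact-cell
#' MALDI-TOF peak each protein was assigned to, and the sequence-derived
#' isoelectric point, for the 36 proteins assigned to characteristic peaks
#' of the CCALA 043 whole-cell fingerprint.
#'
#' @return data.frame with columns `accession`, `name`, `mono_mass`,
#'   `avg_mass`, `mono_mass_noMet`, `avg_mass_noMet`, `peak`, `pi`.
#' @export
ccala043_assignments <- function() {
  path <- system.file("extdata", "ccala043_proteins.csv",
                      package = "icmaldi", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
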