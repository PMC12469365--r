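#' Packaged RPE65 study data
#'
#' The package ships, as plain-text fixtures, the published per-variant data
#' of a minigene splice-assay study of *RPE65*: the 73-variant prioritized
#' candidate table (`rpe65_variants()`), the 59 quantified assays with their
#' adapted r./p. annotations and transcript identities (`rpe65_assays()`),
#' and the transcript model (`rpe65_model()`). Exon boundaries evidenced by
#' published r. intervals are exact; the exon 1-3 splits and the final exon
#' carry an `inferred` flag. The CDS and intron sequences are a SYNTHETIC
#' stand-in (see `rpe65_sequences_synthetic.json`): they reproduce every
#' published reference residue, reference nucleotide and frameshift
#' consequence relevant to the assays, but are not the RefSeq sequence.
#'
#' @param with_sequences Attach the synthetic CDS/intron sequences
#'   (default `TRUE`).
#' @return `rpe65_model()` returns a `transcript_model`; the others return
#'   tibbles.
#' @name rpe65_data
NULL

extdata <- function(file) {
  path <- system.file("extdata", file, package = "minisplice")
  if (path == "") stop("fixture not found: ", file, call. = FALSE)
  path
}

#' @rdname rpe65_data
#' @export
rpe65_model <- function(with_sequences = TRUE) {
  read_transcript_model(
    extdata("rpe65_model.json"),
    sequences_path = if (with_sequences) {
      extdata("rpe65_sequences_synthetic.json")
    })
}

#' @rdname rpe65_data
#' @export
rpe65_variants <- function() {
  read_variant_table(extdata("rpe65_variants_table1.tsv"))
}

#' @rdname rpe65_data
#' @param model Transcript model used to parse transcript identities.
#' @export
rpe65_assays <- function(model = rpe65_model()) {
  read_assay_table(extdata("rpe65_assays_table2.tsv"), model)
}
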