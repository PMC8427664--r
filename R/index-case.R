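#' The chromosome 6 index case
#'
#' A worked example: a previously characterized germline chromoanagenesis
#' event in which chromosome 6 (Hg19, 171,115,067 bp) carries four de novo
#' copy-number-neutral inversions — one ~95-Mb pericentric and three
#' paracentric (~46 Mb and two ~1 Mb) — joined by six breakpoint junctions,
#' one of which disrupts *ARID1B* in intron 4 and causes Coffin-Siris
#' syndrome 1 through haploinsufficiency.
#'
#' Only two breakend positions of this case were published to base-pair
#' precision (the *ARID1B* cut, chr6:157,240,695 / 157,240,708); the packaged
#' junction table reconstructs the remaining positions from the published
#' segment sizes and cytogenetic bands and is therefore a *synthetic
#' transcription*, shipped as `index_case_junctions.synthetic.tsv`. The
#' derivative architecture, orientations, junction count and junction
#' signatures all follow the published description exactly.
#'
#' @return `index_case_model()`: the chr6 [chromosome_model()] (Hg19 length,
#'   centromere 58,780,166-61,880,166). `index_case_junctions()`: the
#'   six-junction [junction_table()]. `index_case_signature_specs()`: a list
#'   of six [signature_call()] objects giving each junction's published
#'   nucleotide-level signature (used to plant synthetic sequence bundles).
#' @name index_case
NULL

#' @rdname index_case
#' @export
index_case_model <- function() {
  chromosome_model("chr6", 171115067, centromere = c(58780166, 61880166))
}

#' @rdname index_case
#' @export
index_case_junctions <- function() {
  read_junction_table(system.file("extdata",
                                  "index_case_junctions.synthetic.tsv",
                                  package = "cgrtools", mustWork = TRUE))
}

#' @rdname index_case
#' @export
index_case_signature_specs <- function() {
  list(
    J1 = signature_call("J1", "insertion", ins_seq = "G"),
    J2 = signature_call("J2", "blunt"),
    J3 = signature_call("J3", "insertion", ins_seq = "TTTGAAG",
                        template_hit = template_hit("proximal", -9, "forward")),
    J4 = signature_call("J4", "blunt"),
    J5 = signature_call("J5", "microhomology", mh_len = 1, mh_seq = "G"),
    J6 = signature_call("J6", "blunt")
  )
}

#' Packaged ARID1B transcript model
#'
#' Exon table for the canonical *ARID1B* transcript (NM_001374820.1-like,
#' plus strand, Hg19 coordinates). The packaged table is a synthetic
#' transcription: exact exon boundaries were not reproducible offline, so
#' the file preserves the features the analysis depends on — 20 exons, the
#' ~157.10-157.53 Mb genomic span, and the intron-4 boundaries bracketing
#' the published breakpoints.
#'
#' @return A data frame with columns `exon`, `start`, `end`.
#' @export
arid1b_exons <- function() {
  read_exon_table(system.file("extdata", "arid1b_exons.synthetic.tsv",
                              package = "cgrtools", mustWork = TRUE))
}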