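#' Consequence term normalization
#'
#' Annotation sources spell consequence terms two ways: Sequence Ontology
#' identifiers (`stop_gained`, `missense_variant`, `&`-separated in a VEP CSQ
#' block) and human-readable table labels (`"stop gained"`,
#' `"missense, splice region"`). [so_terms()] splits either spelling and maps
#' the readable labels onto SO terms, so the filtering rules see one
#' vocabulary.
#'
#' @param x Character vector of consequence strings.
#' @return A list of character vectors, one per input element.
#' @examples
#' so_terms(c("missense, splice region", "stop_gained&splice_region_variant"))
#' @export
so_terms <- function(x) {
  map_tbl <- c(
    "stop gained" = "stop_gained",
    "stop gain" = "stop_gained",
    "start lost" = "start_lost",
    "stop lost" = "stop_lost",
    "splice acceptor" = "splice_acceptor_variant",
    "splice donor" = "splice_donor_variant",
    "splice region" = "splice_region_variant",
    "splice polypyrimidine tract" = "splice_polypyrimidine_tract_variant",
    "missense" = "missense_variant",
    "frameshift" = "frameshift_variant",
    "in-frame deletion" = "inframe_deletion",
    "in-frame insertion" = "inframe_insertion",
    "inframe deletion" = "inframe_deletion",
    "inframe insertion" = "inframe_insertion",
    "protein altering" = "protein_altering_variant",
    "downstream gene" = "downstream_gene_variant",
    "upstream gene" = "upstream_gene_variant",
    "intron" = "intron_variant",
    "intergenic" = "intergenic_variant",
    "synonymous" = "synonymous_variant",
    "non coding transcript exon" = "non_coding_transcript_exon_variant",
    "non-coding transcript exon" = "non_coding_transcript_exon_variant"
  )
  lapply(x, function(s) {
    if (is.na(s) || s == "") return(character(0))
    parts <- trimws(strsplit(s, "[&,]")[[1]])
    parts <- parts[parts != ""]
    mapped <- unname(map_tbl[tolower(parts)])
    out <- ifelse(is.na(mapped), parts, mapped)
    gsub(" ", "_", out)
  })
}
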