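#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata/` directory.
#' @return Absolute path.
#' @export
repairsieve_extdata <- function(file) {
  path <- system.file("extdata", file, package = "repairsieve")
  if (path == "") abort(paste0("packaged data file not found: ", file))
  path
}

# Frozen checksums of the packaged fixtures; a mismatch means the installed
# copy was altered and every downstream count would be suspect.
fixture_md5 <- c(
  eobc_variants = "992f0219c56f43b129e43efdcceb98f6",
  eobc_patients = "bead8b031851827b746376d423601f94"
)

check_fixture <- function(path, name) {
  expected <- fixture_md5[[name]]
  actual <- unname(tools::md5sum(path))
  if (!identical(actual, expected)) {
    abort(paste0("fixture integrity error: ", name, " checksum mismatch (",
                 actual, " != ", expected, ")"))
  }
  invisible(path)
}

#' Bundled early-onset breast cancer screen fixtures
#'
#' `eobc_variants()` returns the 72 prioritized rare germline variants
#' reported by a published whole-exome screen of 63 Finnish women diagnosed
#' with breast cancer at or before age 40 and carrying no known pathogenic
#' BRCA1/2 variant; `eobc_patients()` returns the 63 patients with ages at
#' diagnosis, family-history (Lund) status, bilateral and triple-negative
#' flags, and the variants each carries. Both are exact transcriptions of
#' the published tables (only the sub-population Finnish gnomAD frequencies
#' were printed, so the global frequency columns are absent); the printed
#' subcategory labels ride along as metadata.
#'
#' @return A variant tibble ([read_variant_table()]) or a patient tibble
#'   ([read_patient_table()]).
#' @examples
#' nrow(eobc_variants())
#' sum(is_novel(eobc_variants()))
#' @export
eobc_variants <- function() {
  path <- repairsieve_extdata("eobc_variants.tsv")
  check_fixture(path, "eobc_variants")
  read_variant_table(path)
}

#' @rdname eobc_variants
#' @export
eobc_patients <- function() {
  path <- repairsieve_extdata("eobc_patients.tsv")
  check_fixture(path, "eobc_patients")
  read_patient_table(path)
}

#' @rdname eobc_variants
#' @export
dna_repair_panel <- function() {
  load_panel(repairsieve_extdata("dna_repair_panel.txt"),
             repairsieve_extdata("panel_aliases.tsv"))
}
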