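variant_table_cols <- c(
  "variant_id", "gene", "location", "nucleotide_change", "protein_change",
  "consequence", "subcategory", "af_exome_fin", "af_genome_fin",
  "af_exome_global", "af_genome_global", "sift", "polyphen", "revel",
  "cadd_phred"
)

#' Read a flat variant table
#'
#' Reads the tab-separated variant-table dialect used by the packaged
#' fixtures: one row per annotated variant, `NA` for absent values, with the
#' column set held in `variant_table_cols`. A row whose `variant_id`
#' is `NA` is identified only by chromosomal position (the table's way of
#' printing a variant with no dbSNP record); its `location` string is then
#' its working identifier. The printed `subcategory` label is kept verbatim
#' in `subcategory_printed` as table metadata; the cascade recomputes its own
#' call.
#'
#' This dialect carries no genomic alleles, so `ref`/`alt` are `NA` and rows
#' key on position plus identifier. Tables transcribing published variant
#' lists typically report only the sub-population frequencies that were
#' printed; unprinted frequency columns stay wholly `NA` (absent), which the
#' allele-frequency rule treats as "not reported".
#'
#' @param path Path to the TSV file (or a readr-compatible connection).
#' @return A tibble of annotated variants with the same column contract as
#'   [read_vcf_variants()], plus `location`, `nucleotide_change`,
#'   `protein_change` and `subcategory_printed`.
#' @export
read_variant_table <- function(path) {
  tab <- readr::read_tsv(
    path, na = "NA", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  unknown <- setdiff(names(tab), variant_table_cols)
  if (length(unknown) > 0) {
    abort(paste0("variant table error: unknown column(s): ",
                 paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(variant_table_cols, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("variant table error: missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tab) == 0) return(empty_variant_tbl())

  num <- function(col) {
    x <- tab[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort(paste0("variant table field error: non-numeric '", x[bad[1]],
                   "' in column ", col, ", row ", bad[1]))
    }
    out
  }
  loc <- parse_location(tab$location)
  out <- tibble(
    chrom = loc$chrom, pos = loc$pos,
    ref = NA_character_, alt = NA_character_,
    variant_id = tab$variant_id,
    gene = tab$gene,
    gene_id = NA_character_,
    consequence = purrr::map_chr(so_terms(tab$consequence), paste, collapse = "&"),
    canonical = TRUE,
    hgvs_c = tab$nucleotide_change,
    hgvs_p = tab$protein_change,
    sift = num("sift"), polyphen = num("polyphen"), revel = num("revel"),
    cadd_phred = num("cadd_phred"),
    af_exome_global = num("af_exome_global"),
    af_genome_global = num("af_genome_global"),
    af_exome_fin = num("af_exome_fin"),
    af_genome_fin = num("af_genome_fin"),
    carriers = list(character(0)),
    homozygotes = list(character(0)),
    location = tab$location,
    consequence_printed = tab$consequence,
    subcategory_printed = tab$subcategory
  )
  out$key <- variant_key_string(out)
  out
}

# "chr14:75039918" or "chr1:241861447-241861448" -> contig + first coordinate
parse_location <- function(x) {
  chrom <- sub(":.*$", "", x)
  pos <- suppressWarnings(as.integer(sub("-.*$", "", sub("^[^:]+:", "", x))))
  list(chrom = chrom, pos = pos)
}

#' Write a variant tibble in the flat table dialect
#'
#' Inverse of [read_variant_table()]: writing a table read by it reproduces
#' the file field-for-field. Extra columns produced by the cascade
#' (`retained`, `group`, ...) are appended after the dialect columns when
#' present.
#'
#' @param variants A variant tibble.
#' @param path Output TSV path.
#' @param extra_cols Additional column names to append when present.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path,
                                extra_cols = intersect(
                                  c("retained", "group", "subcategory",
                                    "af_class", "rule_trace"),
                                  names(variants))) {
  v <- as_tibble(variants)
  out <- tibble(
    variant_id = v$variant_id,
    gene = v$gene,
    location = if ("location" %in% names(v)) v$location else
      paste0("chr", norm_chrom(v$chrom), ":", v$pos),
    nucleotide_change = v$hgvs_c,
    protein_change = v$hgvs_p,
    consequence = if ("consequence_printed" %in% names(v)) v$consequence_printed else v$consequence,
    subcategory = if ("subcategory_printed" %in% names(v)) v$subcategory_printed else NA_character_,
    af_exome_fin = fmt_af(v$af_exome_fin),
    af_genome_fin = fmt_af(v$af_genome_fin),
    af_exome_global = fmt_af(v$af_exome_global),
    af_genome_global = fmt_af(v$af_genome_global),
    sift = fmt_af(v$sift),
    polyphen = fmt_af(v$polyphen),
    revel = fmt_af(v$revel),
    cadd_phred = fmt_af(v$cadd_phred)
  )
  for (col in extra_cols) out[[col]] <- v[[col]]
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

# Numbers round-trip through the table dialect exactly as printed: plain
# decimal notation up to 15 significant digits, scientific only when R's
# default formatting chooses it (matching how the fixtures were written).
fmt_af <- function(x) {
  if (is.character(x)) return(x)
  vapply(x, function(e) {
    if (is.na(e)) NA_character_ else format(e, trim = TRUE, digits = 15)
  }, character(1))
}
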