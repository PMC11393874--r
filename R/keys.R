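#' Variant key normalization
#'
#' A variant key is the quadruple (chromosome, position, ref, alt) under VCF
#' conventions: 1-based fully-closed coordinates, uppercase alleles. Keys are
#' compared after stripping any `"chr"` prefix from the contig name and after
#' parsimonious trimming of indel representations (common suffix removed
#' first, then the common prefix, advancing the position), so that the same
#' indel emitted in different but equivalent spellings by two callers compares
#' equal.
#'
#' @param keys A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return A tibble with the same rows, normalized in place, plus a `key`
#'   string column `chrom:pos:ref:alt` used for joins and set operations.
#' @examples
#' normalize_variant_keys(
#'   tibble::tibble(chrom = "chr7", pos = 100L, ref = "TCA", alt = "TCG")
#' )
#' @export
normalize_variant_keys <- function(keys) {
  keys <- as_tibble(keys)
  req <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(keys))
  if (length(missing_cols) > 0) {
    abort(paste0("variant keys need columns: ", paste(missing_cols, collapse = ", ")))
  }
  keys$chrom <- norm_chrom(keys$chrom)
  keys$pos <- as.integer(keys$pos)
  keys$ref <- toupper(keys$ref)
  keys$alt <- toupper(keys$alt)
  bad_pos <- !is.na(keys$pos) & keys$pos < 1L
  if (any(bad_pos)) abort("variant positions must be >= 1")
  has_alleles <- !is.na(keys$ref) & !is.na(keys$alt)
  if (any(has_alleles)) {
    bad <- has_alleles &
      (!grepl("^[ACGT]+$", keys$ref) | !grepl("^[ACGT]+$", keys$alt))
    if (any(bad)) {
      abort(paste0(
        "alleles must be non-empty A/C/G/T strings; offending rows: ",
        paste(which(bad), collapse = ", ")
      ))
    }
    trimmed <- trim_alleles(keys$pos[has_alleles], keys$ref[has_alleles],
                            keys$alt[has_alleles])
    keys$pos[has_alleles] <- trimmed$pos
    keys$ref[has_alleles] <- trimmed$ref
    keys$alt[has_alleles] <- trimmed$alt
  }
  keys$key <- variant_key_string(keys)
  keys
}

#' @rdname normalize_variant_keys
#' @export
variant_key_string <- function(keys) {
  paste(norm_chrom(keys$chrom), keys$pos,
        ifelse(is.na(keys$ref), ".", keys$ref),
        ifelse(is.na(keys$alt), ".", keys$alt),
        sep = ":")
}

norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

# Parsimonious indel trimming: drop the shared suffix, then the shared prefix
# (position advances with the prefix). Both alleles keep at least one base.
trim_alleles <- function(pos, ref, alt) {
  n <- length(ref)
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  list(pos = pos, ref = ref, alt = alt)
}

# Canonical sort order for key tibbles: contig (numeric where possible), then
# position, ref, alt.
arrange_keys <- function(keys) {
  chrom_rank <- suppressWarnings(as.numeric(norm_chrom(keys$chrom)))
  chrom_rank[is.na(chrom_rank)] <- 100 + as.integer(factor(norm_chrom(keys$chrom)[is.na(chrom_rank)]))
  keys[order(chrom_rank, keys$pos, keys$ref, keys$alt), , drop = FALSE]
}
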