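#' Dual-caller consensus intersection
#'
#' Independent variant callers run on the same sample rarely agree perfectly;
#' the consensus call set keeps exactly the variant keys reported by both.
#' Keys are compared after normalization ([normalize_variant_keys()]), so two
#' spellings of the same indel intersect correctly. The result is sorted by
#' (chromosome, position, ref, alt) and is symmetric in its arguments.
#'
#' @param callset_a,callset_b Data frames of variant keys (`chrom`, `pos`,
#'   `ref`, `alt`). A `build` attribute (set by [read_vcf_variants()] from the
#'   `##reference` meta line) is compared when present on both sides; mixed
#'   builds are an error.
#' @return A tibble of the shared keys.
#' @export
consensus_merge <- function(callset_a, callset_b) {
  build_a <- attr(callset_a, "build", exact = TRUE)
  build_b <- attr(callset_b, "build", exact = TRUE)
  if (!is.null(build_a) && !is.null(build_b) && !identical(build_a, build_b)) {
    abort(paste0("consensus merge error: mixed reference builds (",
                 build_a, " vs ", build_b, ")"))
  }
  a <- normalize_variant_keys(callset_a)
  b <- normalize_variant_keys(callset_b)
  shared <- a[!duplicated(a$key) & a$key %in% b$key,
              c("chrom", "pos", "ref", "alt", "key"), drop = FALSE]
  out <- as_tibble(arrange_keys(shared))
  if (!is.null(build_a)) attr(out, "build") <- build_a
  out
}

#' Merge per-patient variant sets into one cohort table
#'
#' Combines consensus-merged per-patient variant tibbles into a single cohort
#' table: rows with the same (variant key, gene) collapse into one record
#' whose `carriers` is the union of the patients carrying it. Annotation and
#' score fields are expected to agree across patients (they describe the same
#' allele); on disagreement the first-seen value is kept and a warning names
#' the variant.
#'
#' @param per_patient A named list, patient id -> variant tibble. Rows that
#'   already carry a non-empty `carriers` column keep those sample ids in the
#'   union.
#' @return One variant tibble with merged `carriers`.
#' @export
merge_cohort <- function(per_patient) {
  if (length(per_patient) == 0) return(empty_variant_tbl())
  if (is.null(names(per_patient)) || any(names(per_patient) == "")) {
    abort("merge_cohort needs a named list: patient id -> variants")
  }
  tagged <- imap(per_patient, function(v, pid) {
    v <- normalize_variant_keys(as_tibble(v))
    if (!"carriers" %in% names(v)) v$carriers <- list(character(0))
    v$carriers <- map(v$carriers, function(cc) unique(c(cc, pid)))
    v
  })
  all_rows <- list_rbind(unname(tagged))
  ann_cols <- setdiff(names(all_rows), c("carriers", "homozygotes"))
  split_id <- paste(all_rows$key, all_rows$gene, sep = "//")
  pieces <- split(all_rows, factor(split_id, levels = unique(split_id)))
  merged <- list_rbind(map(pieces, function(grp) {
    first <- grp[1, , drop = FALSE]
    for (col in ann_cols) {
      vals <- unique(grp[[col]][!is.na(grp[[col]])])
      if (length(vals) > 1) {
        warn(paste0("merge_cohort: conflicting '", col, "' for ", grp$key[1],
                    " (", grp$gene[1], "); keeping first-seen value"))
      }
    }
    first$carriers <- list(sort(unique(unlist(grp$carriers))))
    if ("homozygotes" %in% names(grp)) {
      first$homozygotes <- list(sort(unique(unlist(grp$homozygotes))))
    }
    first
  }))
  as_tibble(arrange_keys(merged))
}
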