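#' Filtering cascade configuration
#'
#' Collects every tunable of the two-round prioritization cascade. The
#' defaults are the published screening profile: CADD PHRED at least 20 (a
#' variant in the top 1% most deleterious genome-wide) or unscored; strict
#' round at allele frequency < 0.01 and REVEL > 0.75; relaxed round at
#' AF < 0.02 and REVEL > 0.4 (the REVEL operating point reported to balance
#' sensitivity and specificity); missing CADD, REVEL or AF values retained at
#' every step, because absence of a score is not evidence of harmlessness —
#' indels in particular are systematically unscored by CADD, and REVEL only
#' scores missense changes.
#'
#' Consequence strata: `group1_terms` are the truncating / splice-altering
#' classes that are prioritized on frequency alone; `group2_terms` are the
#' non-synonymous classes that additionally face the REVEL rule. The default
#' Group 2 set includes, beyond missense and frameshift, the in-frame indel,
#' protein-altering, downstream-gene and splice-region classes that the
#' published screen demonstrably retained; a stricter consequence policy can
#' drop them by passing narrower sets.
#'
#' `affected_genes` controls the gene universe re-screened by the relaxed
#' round: `"prefilter"` (default) uses every gene holding a variant that
#' survived the general filter (panel, CADD, canonical transcript), which is
#' the behavior the published variant table reflects; `"strict"` restricts to
#' genes of strict-round retainees.
#'
#' @param cadd_min Minimum CADD PHRED score (exactly `cadd_min` passes).
#' @param af_strict,af_relaxed Allele-frequency ceilings (exclusive) for the
#'   strict and relaxed rounds.
#' @param revel_strict,revel_relaxed REVEL floors (exclusive) for the two
#'   rounds.
#' @param group1_terms,group2_terms Character vectors of SO consequence terms
#'   defining the two strata; they must not overlap.
#' @param retain_missing_cadd,retain_missing_revel,retain_missing_af Keep
#'   variants whose score / all of whose frequencies are unreported?
#' @param affected_genes `"prefilter"` or `"strict"`, see above.
#' @return A `filter_config` list.
#' @export
filter_config <- function(cadd_min = 20,
                          af_strict = 0.01,
                          af_relaxed = 0.02,
                          revel_strict = 0.75,
                          revel_relaxed = 0.4,
                          group1_terms = c(
                            "splice_acceptor_variant", "splice_donor_variant",
                            "stop_gained", "start_lost",
                            "non_coding_transcript_exon_variant"
                          ),
                          group2_terms = c(
                            "missense_variant", "frameshift_variant",
                            "inframe_deletion", "inframe_insertion",
                            "protein_altering_variant", "splice_region_variant",
                            "downstream_gene_variant"
                          ),
                          retain_missing_cadd = TRUE,
                          retain_missing_revel = TRUE,
                          retain_missing_af = TRUE,
                          affected_genes = c("prefilter", "strict")) {
  affected_genes <- match.arg(affected_genes)
  stopifnot(
    is.finite(cadd_min), cadd_min >= 0,
    is.finite(af_strict), is.finite(af_relaxed),
    af_strict > 0, af_relaxed <= 1,
    is.finite(revel_strict), is.finite(revel_relaxed),
    revel_strict >= 0, revel_strict <= 1,
    revel_relaxed >= 0, revel_relaxed <= 1
  )
  if (af_strict > af_relaxed) {
    abort("filter_config: af_strict must be <= af_relaxed")
  }
  if (revel_relaxed > revel_strict) {
    abort("filter_config: revel_relaxed must be <= revel_strict")
  }
  if (length(intersect(group1_terms, group2_terms)) > 0) {
    abort("filter_config: group1_terms and group2_terms must be disjoint")
  }
  structure(
    list(
      cadd_min = cadd_min,
      af_strict = af_strict, af_relaxed = af_relaxed,
      revel_strict = revel_strict, revel_relaxed = revel_relaxed,
      group1_terms = group1_terms, group2_terms = group2_terms,
      retain_missing_cadd = retain_missing_cadd,
      retain_missing_revel = retain_missing_revel,
      retain_missing_af = retain_missing_af,
      affected_genes = affected_genes
    ),
    class = "filter_config"
  )
}

#' @rdname filter_config
#' @export
published_profile <- function() filter_config()

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat(sprintf("  CADD >= %g (missing %s)\n", x$cadd_min,
              if (x$retain_missing_cadd) "retained" else "dropped"))
  cat(sprintf("  strict round:  AF < %g, REVEL > %g\n", x$af_strict, x$revel_strict))
  cat(sprintf("  relaxed round: AF < %g, REVEL > %g\n", x$af_relaxed, x$revel_relaxed))
  cat(sprintf("  group 1: %s\n", paste(x$group1_terms, collapse = ", ")))
  cat(sprintf("  group 2: %s\n", paste(x$group2_terms, collapse = ", ")))
  cat(sprintf("  relaxed-round gene universe: %s\n", x$affected_genes))
  invisible(x)
}
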