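#' Individual cascade rules
#'
#' The vectorized predicates the cascade composes. Each implements one
#' published comparison with its missing-value convention:
#'
#' * `cadd_pass()`: scores *below* `cadd_min` are excluded, so a score of
#'   exactly `cadd_min` passes; unscored variants pass when
#'   `retain_missing_cadd` (CADD leaves many indels unscored).
#' * `revel_pass()`: strictly greater than the threshold; unscored variants
#'   pass when `retain_missing_revel` (REVEL only scores missense changes).
#' * `af_class()`: `"ULTRA_RARE"` when no frequency is reported at all,
#'   `"EXCLUDED"` when any reported frequency reaches the ceiling,
#'   `"RARE"` otherwise. Every reported frequency must stay below the
#'   ceiling; a frequency of exactly 0 is a reported value, not a missing one
#'   (databases do print 0 for known alleles unseen in a sub-population).
#' * `consequence_group()`: `"GROUP1"` when any term is in `group1_terms`
#'   (Group 1 takes precedence on overlap), else `"GROUP2"` on a
#'   `group2_terms` hit, else `"OTHER"`.
#'
#' @param score Numeric vector (NA = unscored).
#' @param config A [filter_config()].
#' @param threshold Rule threshold (round-specific).
#' @param variants Variant tibble with the four `af_*` columns.
#' @param terms A consequence string vector (or list from [so_terms()]).
#' @name cascade-rules
NULL

#' @rdname cascade-rules
#' @export
cadd_pass <- function(score, config = filter_config()) {
  if (any(!is.na(score) & score < 0)) {
    abort("cadd_pass: CADD PHRED scores cannot be negative")
  }
  ifelse(is.na(score), config$retain_missing_cadd, score >= config$cadd_min)
}

#' @rdname cascade-rules
#' @export
revel_pass <- function(score, threshold = NULL, config = filter_config()) {
  threshold <- threshold %||% config$revel_strict
  if (any(!is.na(score) & (score < 0 | score > 1))) {
    abort("revel_pass: REVEL scores must lie in [0, 1]")
  }
  ifelse(is.na(score), config$retain_missing_revel, score > threshold)
}

#' @rdname cascade-rules
#' @export
af_class <- function(variants, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  af <- cbind(variants$af_exome_global, variants$af_genome_global,
              variants$af_exome_fin, variants$af_genome_fin)
  n_present <- rowSums(!is.na(af))
  any_high <- rowSums(!is.na(af) & af >= threshold) > 0
  dplyr::case_when(
    n_present == 0 ~ "ULTRA_RARE",
    any_high ~ "EXCLUDED",
    TRUE ~ "RARE"
  )
}

#' @rdname cascade-rules
#' @export
consequence_group <- function(terms, config = filter_config()) {
  if (!is.list(terms)) terms <- so_terms(terms)
  purrr::map_chr(terms, function(tt) {
    if (length(intersect(tt, config$group1_terms)) > 0) return("GROUP1")
    if (length(intersect(tt, config$group2_terms)) > 0) return("GROUP2")
    "OTHER"
  })
}

#' Choose one transcript annotation per variant
#'
#' Given the competing transcript annotations of one variant (rows of a
#' tibble with `canonical` and `consequence`), returns the index of the
#' annotation the cascade should see: the canonical one if any; otherwise,
#' when every annotation carries only non-transcript terms (intergenic,
#' upstream, downstream), the first of them; otherwise `NA` — a variant
#' annotated only on non-canonical transcripts is excluded.
#'
#' @param annotations Tibble of transcript annotations for one variant.
#' @return Integer index into `annotations`, or `NA_integer_`.
#' @export
transcript_filter <- function(annotations) {
  if (nrow(annotations) == 0) return(NA_integer_)
  canon <- isTRUE_vec(annotations$canonical)
  if (any(canon)) return(which(canon)[1])
  nontx <- c("intergenic_variant", "upstream_gene_variant", "downstream_gene_variant")
  only_nontx <- purrr::map_lgl(so_terms(annotations$consequence),
                               function(tt) length(tt) > 0 && all(tt %in% nontx))
  if (all(only_nontx)) return(1L)
  NA_integer_
}
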