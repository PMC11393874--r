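# One round of the cascade, vectorized over the variant tibble. Returns the
# per-rule outcomes so callers can assemble calls and traces.
eval_round <- function(variants, panel, config, af_thr, revel_thr) {
  terms <- so_terms(variants$consequence)
  nontx <- c("intergenic_variant", "upstream_gene_variant", "downstream_gene_variant")
  pass_panel <- in_panel(variants, panel)
  pass_cadd <- as.logical(cadd_pass(variants$cadd_phred, config))
  pass_canon <- isTRUE_vec(variants$canonical) |
    purrr::map_lgl(terms, function(tt) length(tt) > 0 && all(tt %in% nontx))
  afc <- af_class(variants, af_thr)
  pass_af <- afc == "RARE" | (afc == "ULTRA_RARE" & config$retain_missing_af)
  group <- consequence_group(terms, config)
  pass_revel <- as.logical(revel_pass(variants$revel, revel_thr, config))
  retained <- pass_panel & pass_cadd & pass_canon & pass_af &
    (group == "GROUP1" | (group == "GROUP2" & pass_revel))
  list(
    pass_panel = pass_panel, pass_cadd = pass_cadd, pass_canon = pass_canon,
    af_class = afc, pass_af = pass_af, group = group,
    pass_revel = pass_revel, retained = retained
  )
}

round_trace <- function(variants, r, af_thr, revel_thr) {
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, trim = TRUE))
  pf <- function(p) ifelse(p, "pass", "fail")
  paste0(
    "panel=", pf(r$pass_panel),
    ";cadd=", pf(r$pass_cadd), "(", fmt(variants$cadd_phred), ")",
    ";canonical=", pf(r$pass_canon),
    ";af@", format(af_thr), "=", r$af_class,
    ";group=", r$group,
    ";revel@", format(revel_thr), "=",
    ifelse(r$group == "GROUP2", paste0(pf(r$pass_revel), "(", fmt(variants$revel), ")"),
           "skipped")
  )
}

prepare_variants <- function(variants) {
  v <- as_tibble(variants)
  if (!"key" %in% names(v)) {
    if (all(c("ref", "alt") %in% names(v)) && nrow(v) > 0 && !all(is.na(v$ref))) {
      v <- normalize_variant_keys(v)
    } else {
      v$key <- variant_key_string(v)
    }
  }
  # identical (key, gene) pairs are evaluated once
  v[!duplicated(paste(v$key, toupper(v$gene))), , drop = FALSE]
}

#' Strict screening round
#'
#' First pass of the cascade: panel restriction, CADD floor, canonical /
#' non-transcript rule, strict allele-frequency ceiling, consequence split
#' and — for Group 2 only — the strict REVEL floor. Group 1 retainees carry
#' no subcategory; Group 2 retainees are subcategory 1.
#'
#' @param variants Variant tibble.
#' @param panel Panel tibble from [load_panel()].
#' @param config A [filter_config()].
#' @return `list(calls = <tibble of retained calls>, affected_genes =
#'   <character>)`, where `affected_genes` are the gene symbols of the
#'   retainees.
#' @export
run_strict <- function(variants, panel, config = filter_config()) {
  v <- prepare_variants(variants)
  if (nrow(v) == 0) {
    return(list(calls = empty_calls_tbl(), affected_genes = character(0)))
  }
  r <- eval_round(v, panel, config, config$af_strict, config$revel_strict)
  calls <- tibble(
    key = v$key, variant_id = v$variant_id, gene = v$gene,
    retained = r$retained,
    group = r$group,
    subcategory = dplyr::case_when(
      r$retained & r$group == "GROUP2" ~ "SUB1",
      TRUE ~ "NONE"
    ),
    af_class = r$af_class,
    round = ifelse(r$retained, "strict", NA_character_),
    rule_trace = round_trace(v, r, config$af_strict, config$revel_strict)
  )
  retained <- calls[calls$retained, , drop = FALSE]
  list(calls = retained,
       affected_genes = sort(unique(retained$gene[!is.na(retained$gene)])))
}

#' Relaxed re-screening round
#'
#' Second pass: only variants in `affected_genes` are re-evaluated, under the
#' relaxed allele-frequency and REVEL thresholds; panel, CADD and canonical
#' rules are unchanged. Variants the strict round already retained are not
#' reported again. Group 2 retainees are subcategory 2; Group 1 retainees
#' (re-admitted on the relaxed frequency ceiling) carry no subcategory.
#'
#' @param variants Variant tibble (the full cohort).
#' @param affected_genes Gene symbols delimiting the re-screen.
#' @param panel,config As in [run_strict()].
#' @return Tibble of relaxed-round retained calls.
#' @export
run_relaxed <- function(variants, affected_genes, panel,
                        config = filter_config()) {
  v <- prepare_variants(variants)
  if (nrow(v) == 0) return(empty_calls_tbl())
  strict <- eval_round(v, panel, config, config$af_strict, config$revel_strict)
  in_scope <- toupper(v$gene) %in% toupper(affected_genes) & !strict$retained
  v2 <- v[in_scope, , drop = FALSE]
  if (nrow(v2) == 0) return(empty_calls_tbl())
  r <- eval_round(v2, panel, config, config$af_relaxed, config$revel_relaxed)
  calls <- tibble(
    key = v2$key, variant_id = v2$variant_id, gene = v2$gene,
    retained = r$retained,
    group = r$group,
    subcategory = dplyr::case_when(
      r$retained & r$group == "GROUP2" ~ "SUB2",
      TRUE ~ "NONE"
    ),
    af_class = r$af_class,
    round = ifelse(r$retained, "relaxed", NA_character_),
    rule_trace = round_trace(v2, r, config$af_relaxed, config$revel_relaxed)
  )
  calls[calls$retained, , drop = FALSE]
}

empty_calls_tbl <- function() {
  tibble(
    key = character(), variant_id = character(), gene = character(),
    retained = logical(), group = character(), subcategory = character(),
    af_class = character(), round = character(), rule_trace = character()
  )
}

#' Two-round variant prioritization cascade
#'
#' Runs the full prioritization: the strict round, the affected-gene
#' determination, and the relaxed re-screen, and returns one call per input
#' variant — retained or not — with the stratum (`group`), subcategory, the
#' allele-frequency class and an auditable `rule_trace`. The retained set is
#' the union of the two rounds; the result does not depend on input order.
#'
#' @param variants Variant tibble (see [read_variant_table()] /
#'   [read_vcf_variants()]).
#' @param panel Panel tibble from [load_panel()].
#' @param config A [filter_config()]; the default is the published profile.
#' @return A `priority_calls` tibble with columns `key`, `variant_id`,
#'   `gene`, `retained`, `group` (`GROUP1`/`GROUP2`/`OTHER`), `subcategory`
#'   (`SUB1`/`SUB2`/`NONE`), `af_class` (`RARE`/`ULTRA_RARE`/`EXCLUDED`),
#'   `round` (`strict`/`relaxed`/`NA`) and `rule_trace`. Stage counts for the
#'   screening funnel are attached as the `"stage_counts"` attribute, the
#'   affected-gene set as `"affected_genes"`.
#' @examples
#' panel <- load_panel(repairsieve_extdata("dna_repair_panel.txt"))
#' calls <- classify_variants(eobc_variants(), panel)
#' sum(calls$retained)
#' @export
classify_variants <- function(variants, panel, config = filter_config()) {
  v <- prepare_variants(variants)
  if (nrow(v) == 0) {
    out <- empty_calls_tbl()
    class(out) <- c("priority_calls", class(out))
    return(out)
  }
  strict <- eval_round(v, panel, config, config$af_strict, config$revel_strict)
  prefilter_pass <- strict$pass_panel & strict$pass_cadd & strict$pass_canon
  affected <- switch(
    config$affected_genes,
    prefilter = sort(unique(v$gene[prefilter_pass & !is.na(v$gene)])),
    strict = sort(unique(v$gene[strict$retained & !is.na(v$gene)]))
  )
  relaxed_scope <- toupper(v$gene) %in% toupper(affected) & !strict$retained
  relaxed <- eval_round(v, panel, config, config$af_relaxed, config$revel_relaxed)
  relaxed_retained <- relaxed_scope & relaxed$retained

  retained <- strict$retained | relaxed_retained
  round <- dplyr::case_when(
    strict$retained ~ "strict",
    relaxed_retained ~ "relaxed",
    TRUE ~ NA_character_
  )
  group <- ifelse(relaxed_retained, relaxed$group, strict$group)
  afc <- ifelse(relaxed_retained, relaxed$af_class, strict$af_class)
  subcategory <- dplyr::case_when(
    strict$retained & strict$group == "GROUP2" ~ "SUB1",
    relaxed_retained & relaxed$group == "GROUP2" ~ "SUB2",
    TRUE ~ "NONE"
  )
  trace <- round_trace(v, strict, config$af_strict, config$revel_strict)
  trace[relaxed_scope] <- paste0(
    trace[relaxed_scope], ";;relaxed:",
    round_trace(v[relaxed_scope, , drop = FALSE],
                lapply(relaxed, function(x) x[relaxed_scope]),
                config$af_relaxed, config$revel_relaxed)
  )
  out <- tibble(
    key = v$key, variant_id = v$variant_id, gene = v$gene,
    retained = retained, group = group, subcategory = subcategory,
    af_class = afc, round = round, rule_trace = trace
  )
  attr(out, "stage_counts") <- c(
    input = nrow(v),
    after_panel = sum(strict$pass_panel),
    after_cadd = sum(strict$pass_panel & strict$pass_cadd),
    after_canonical = sum(prefilter_pass),
    after_af_strict = sum(prefilter_pass & strict$pass_af),
    strict_retained = sum(strict$retained),
    relaxed_retained = sum(relaxed_retained),
    final_retained = sum(retained)
  )
  attr(out, "affected_genes") <- affected
  attr(out, "config") <- config
  class(out) <- c("priority_calls", class(out))
  out
}

#' @export
print.priority_calls <- function(x, ...) {
  counts <- attr(x, "stage_counts", exact = TRUE)
  cat("<priority_calls> ", nrow(x), " variants, ",
      sum(x$retained), " retained\n", sep = "")
  if (!is.null(counts)) {
    cat("  strict: ", counts[["strict_retained"]],
        " | relaxed: ", counts[["relaxed_retained"]], "\n", sep = "")
  }
  NextMethod()
}

#' Tidy and summary methods for priority calls
#'
#' `tidy()` returns the calls as a plain tibble (one row per variant);
#' `glance()` condenses the run into one row of funnel counts.
#'
#' @param x A `priority_calls` object from [classify_variants()].
#' @param ... Unused.
#' @method tidy priority_calls
#' @export
tidy.priority_calls <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "priority_calls")
  attr(out, "stage_counts") <- NULL
  attr(out, "affected_genes") <- NULL
  attr(out, "config") <- NULL
  as_tibble(out)
}

#' @rdname tidy.priority_calls
#' @method glance priority_calls
#' @export
glance.priority_calls <- function(x, ...) {
  counts <- attr(x, "stage_counts", exact = TRUE)
  tibble(
    n_variants = nrow(x),
    n_retained = sum(x$retained),
    n_strict = sum(x$round %in% "strict"),
    n_relaxed = sum(x$round %in% "relaxed"),
    n_group1 = sum(x$retained & x$group == "GROUP1"),
    n_sub1 = sum(x$subcategory == "SUB1"),
    n_sub2 = sum(x$subcategory == "SUB2"),
    n_affected_genes = length(attr(x, "affected_genes", exact = TRUE) %||% character(0))
  )
}

#' Plot the screening funnel of a prioritization run
#'
#' Bar chart of the per-stage record counts attached to a `priority_calls`
#' object: how many variants survive each rule of the strict round, and how
#' many each round retains.
#'
#' @param object A `priority_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot priority_calls
#' @export
autoplot.priority_calls <- function(object, ...) {
  counts <- attr(object, "stage_counts", exact = TRUE)
  df <- tibble(stage = factor(names(counts), levels = names(counts)),
               n = as.integer(counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "variants",
                  title = "Prioritization funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
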