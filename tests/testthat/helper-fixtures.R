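# Builders for in-code fixtures and the independent brute-force oracle.

make_variant <- function(chrom = "1", pos = 1000L, ref = "A", alt = "G",
                         variant_id = "rs1", gene = "WRN",
                         consequence = "missense_variant", canonical = TRUE,
                         revel = NA_real_, cadd_phred = 30,
                         af_exome_global = NA_real_, af_genome_global = NA_real_,
                         af_exome_fin = NA_real_, af_genome_fin = NA_real_,
                         carriers = character(0)) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    variant_id = variant_id, gene = gene, gene_id = NA_character_,
    consequence = consequence, canonical = canonical,
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    sift = NA_real_, polyphen = NA_real_,
    revel = revel, cadd_phred = cadd_phred,
    af_exome_global = af_exome_global, af_genome_global = af_genome_global,
    af_exome_fin = af_exome_fin, af_genome_fin = af_genome_fin,
    carriers = list(carriers), homozygotes = list(character(0))
  )
}

tiny_panel <- function(symbols = c("WRN", "RNF8", "POLQ", "BRCA2", "ATM")) {
  tibble::tibble(symbol = symbols,
                 aliases = rep(list(character(0)), length(symbols)),
                 gene_id = NA_character_)
}

# Brute-force oracle: the retention predicate of each round written as one
# flat boolean expression over the variant table, sharing no code with the
# cascade implementation.
oracle_classify <- function(v, panel_symbols,
                            cadd_min = 20, af_strict = 0.01, af_relaxed = 0.02,
                            revel_strict = 0.75, revel_relaxed = 0.4,
                            group1 = c("splice_acceptor_variant",
                                       "splice_donor_variant", "stop_gained",
                                       "start_lost",
                                       "non_coding_transcript_exon_variant"),
                            group2 = c("missense_variant", "frameshift_variant",
                                       "inframe_deletion", "inframe_insertion",
                                       "protein_altering_variant",
                                       "splice_region_variant",
                                       "downstream_gene_variant")) {
  terms <- strsplit(v$consequence, "&", fixed = TRUE)
  af <- cbind(v$af_exome_global, v$af_genome_global,
              v$af_exome_fin, v$af_genome_fin)
  af_ok <- function(thr) {
    apply(af, 1, function(a) all(is.na(a)) || all(a[!is.na(a)] < thr))
  }
  on_panel <- toupper(v$gene) %in% toupper(panel_symbols)
  cadd_ok <- is.na(v$cadd_phred) | v$cadd_phred >= cadd_min
  nontx <- c("intergenic_variant", "upstream_gene_variant",
             "downstream_gene_variant")
  canon_ok <- mapply(function(cn, tt) {
    (!is.na(cn) && cn) || (length(tt) > 0 && all(tt %in% nontx))
  }, v$canonical, terms)
  grp <- vapply(terms, function(tt) {
    if (any(tt %in% group1)) "GROUP1"
    else if (any(tt %in% group2)) "GROUP2"
    else "OTHER"
  }, character(1))
  revel_ok <- function(thr) is.na(v$revel) | v$revel > thr
  strict <- on_panel & cadd_ok & canon_ok & af_ok(af_strict) &
    (grp == "GROUP1" | (grp == "GROUP2" & revel_ok(revel_strict)))
  affected <- unique(toupper(v$gene[on_panel & cadd_ok & canon_ok]))
  relaxed <- !strict & toupper(v$gene) %in% affected &
    on_panel & cadd_ok & canon_ok & af_ok(af_relaxed) &
    (grp == "GROUP1" | (grp == "GROUP2" & revel_ok(revel_relaxed)))
  tibble::tibble(
    gene = v$gene,
    retained = strict | relaxed,
    group = grp,
    subcategory = ifelse(strict & grp == "GROUP2", "SUB1",
                         ifelse(relaxed & grp == "GROUP2", "SUB2", "NONE"))
  )
}

# A cohort of random (not fate-constructed) variants for oracle comparison.
random_variants <- function(n, seed, panel_symbols = tiny_panel()$symbol) {
  set.seed(seed)
  cons_pool <- c("missense_variant", "stop_gained", "frameshift_variant",
                 "synonymous_variant", "splice_acceptor_variant",
                 "splice_region_variant", "downstream_gene_variant",
                 "missense_variant&splice_region_variant",
                 "intron_variant")
  genes <- c(panel_symbols, "NOTAPANELGENE1", "NOTAPANELGENE2")
  maybe <- function(x, p_na) ifelse(runif(n) < p_na, NA_real_, x)
  tibble::tibble(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = as.integer(seq_len(n) * 17 + 11),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = "TT",
    variant_id = paste0("rs", seq_len(n)),
    gene = sample(genes, n, replace = TRUE),
    gene_id = NA_character_,
    consequence = sample(cons_pool, n, replace = TRUE),
    canonical = runif(n) < 0.9,
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    sift = NA_real_, polyphen = NA_real_,
    revel = maybe(round(runif(n), 3), 0.3),
    cadd_phred = maybe(round(runif(n, 0, 50), 1), 0.15),
    af_exome_global = maybe(signif(10^runif(n, -6, -0.5), 3), 0.4),
    af_genome_global = maybe(signif(10^runif(n, -6, -0.5), 3), 0.4),
    af_exome_fin = maybe(signif(10^runif(n, -6, -0.5), 3), 0.4),
    af_genome_fin = maybe(signif(10^runif(n, -6, -0.5), 3), 0.4),
    carriers = rep(list(character(0)), n),
    homozygotes = rep(list(character(0)), n)
  ) |> normalize_variant_keys()
}

# Minimal annotated VCF text for reader tests.
write_test_vcf <- function(path, records,
                           samples = c("P1", "P2"),
                           format_fields = c("Allele", "Consequence", "SYMBOL",
                                             "Gene", "CANONICAL", "HGVSc",
                                             "HGVSp", "SIFT", "PolyPhen",
                                             "REVEL", "CADD_PHRED",
                                             "gnomADe_AF", "gnomADg_AF",
                                             "gnomADe_FIN_AF", "gnomADg_FIN_AF")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh38",
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence ',
           'annotations. Format: ', paste(format_fields, collapse = "|"), '">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}
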