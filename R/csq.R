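#' Supported CSQ annotation fields
#'
#' Field names understood in a VEP-style `INFO/CSQ` transcript block. A VCF
#' may carry more fields; these are the ones mapped onto variant columns.
#' `Consequence`, `SYMBOL` and `CANONICAL` are mandatory.
#' @keywords internal
csq_supported_fields <- c(
  "Allele", "Consequence", "SYMBOL", "Gene", "CANONICAL", "HGVSc", "HGVSp",
  "SIFT", "PolyPhen", "REVEL", "CADD_PHRED",
  "gnomADe_AF", "gnomADg_AF", "gnomADe_FIN_AF", "gnomADg_FIN_AF"
)

csq_required_fields <- c("Consequence", "SYMBOL", "CANONICAL")

#' Parse the CSQ field schema from a VCF meta line
#'
#' VEP describes the layout of its per-transcript annotation block in the
#' `##INFO=<ID=CSQ,...>` meta line, as a `Format:` clause listing the
#' pipe-separated field names. This extracts that ordered list.
#'
#' @param header_text The VCF INFO meta line (or any text containing the
#'   `Format:` clause) describing the CSQ field.
#' @return Character vector of field names, in file order.
#' @examples
#' parse_csq_schema(
#'   '##INFO=<ID=CSQ,Number=.,Type=String,Description="... Format: Consequence|SYMBOL|CANONICAL|REVEL">'
#' )
#' @export
parse_csq_schema <- function(header_text) {
  header_text <- paste(header_text, collapse = " ")
  m <- regmatches(header_text, regexpr("Format:\\s*[A-Za-z0-9_|]+", header_text))
  if (length(m) == 0) {
    abort("CSQ schema error: no 'Format:' clause found in the INFO meta line")
  }
  fields <- strsplit(sub("^Format:\\s*", "", m), "|", fixed = TRUE)[[1]]
  missing_req <- setdiff(csq_required_fields, fields)
  if (length(missing_req) > 0) {
    abort(paste0("CSQ schema error: required field(s) absent: ",
                 paste(missing_req, collapse = ", ")))
  }
  fields
}

# VEP's minimal allele representation: the shared leading base of ref/alt is
# dropped; a fully trimmed-away allele prints as "-".
vep_allele <- function(ref, alt) {
  ifelse(
    nchar(ref) == 1 & nchar(alt) == 1,
    alt,
    ifelse(substr(ref, 1, 1) == substr(alt, 1, 1),
           ifelse(nchar(alt) > 1, substr(alt, 2, nchar(alt)), "-"),
           alt)
  )
}

blank_to_na <- function(x) {
  x[!is.na(x) & (x == "" | x == "." | x == "NA")] <- NA_character_
  x
}

parse_num_field <- function(x, field, where) {
  x <- blank_to_na(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(paste0("unparseable numeric value in field '", field, "' (", where,
                 "): ", paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

# SIFT/PolyPhen may arrive as "deleterious(0.02)" style strings; keep the
# numeric part.
parse_pred_score <- function(x, field, where) {
  x <- blank_to_na(x)
  has_paren <- !is.na(x) & grepl("\\([0-9.eE+-]+\\)", x)
  x[has_paren] <- sub("^.*\\(([0-9.eE+-]+)\\).*$", "\\1", x[has_paren])
  parse_num_field(x, field, where)
}

#' Read annotated variants from a VCF file
#'
#' Reads a VCF (plain or gzipped) whose `INFO/CSQ` field carries VEP-style
#' per-transcript annotations, and returns one row per (variant key, gene)
#' after transcript selection. Multi-allelic records are decomposed into one
#' key per alternate allele, with CSQ entries matched to the allele they
#' describe. Sample columns with a non-reference genotype for the allele
#' populate the `carriers` list column; `homozygotes` records samples carrying
#' two copies (flagged, not filtered).
#'
#' Transcript selection per (key, gene): the canonical annotation if one is
#' flagged; otherwise, if every annotation carries only non-transcript
#' consequence terms (intergenic, upstream, downstream), the first such
#' annotation; otherwise the gene's annotations are dropped as
#' non-canonical-only.
#'
#' Empty annotation fields are absent (`NA`); a frequency printed as `0` is a
#' reported value, not a missing one.
#'
#' @param path Path to a VCF file, or a `vcfR` object.
#' @param schema CSQ field names in file order; by default recovered from the
#'   file's own meta line with [parse_csq_schema()].
#' @return A tibble of annotated variants (see [read_variant_table()] for the
#'   column contract), with `carriers` and `homozygotes` list columns.
#' @export
read_vcf_variants <- function(path, schema = NULL) {
  vcf <- if (inherits(path, "vcfR")) path else vcfR::read.vcfR(path, verbose = FALSE)
  meta <- vcf@meta
  if (is.null(schema)) {
    csq_line <- grep("^##INFO=<ID=CSQ", meta, value = TRUE)
    if (length(csq_line) == 0) {
      abort("CSQ schema error: VCF has no ##INFO=<ID=CSQ,...> meta line and no schema was given")
    }
    schema <- parse_csq_schema(csq_line[1])
  }
  fix <- vcf@fix
  if (nrow(fix) == 0) return(empty_variant_tbl())
  gt <- if (ncol(vcf@gt) > 1) vcf@gt else NULL
  samples <- if (!is.null(gt)) colnames(gt)[-1] else character(0)

  build <- sub("^##reference=", "", grep("^##reference=", meta, value = TRUE))
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    info <- fix[i, "INFO"]
    csq_raw <- regmatches(info, regexpr("(?:^|;)CSQ=[^;]*", info))
    if (length(csq_raw) == 0) next
    entries <- strsplit(sub("^;?CSQ=", "", csq_raw), ",", fixed = TRUE)[[1]]
    parts <- lapply(entries, function(e) {
      p <- strsplit(e, "|", fixed = TRUE)[[1]]
      if (length(p) < length(schema)) p <- c(p, rep("", length(schema) - length(p)))
      if (length(p) > length(schema)) {
        abort(paste0("malformed CSQ entry at record ", i, ": ", length(p),
                     " fields where the schema declares ", length(schema)))
      }
      setNames(p, schema)
    })
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ref <- fix[i, "REF"]
    gts <- if (!is.null(gt)) sub(":.*$", "", gt[i, -1]) else character(0)
    for (j in seq_along(alts)) {
      alt <- alts[j]
      want <- c(alt, vep_allele(ref, alt))
      ent <- if ("Allele" %in% schema) {
        parts[purrr::map_lgl(parts, function(p) p[["Allele"]] %in% want)]
      } else {
        parts
      }
      if (length(ent) == 0) next
      gt_alleles <- strsplit(gts, "[/|]")
      hits <- purrr::map_lgl(gt_alleles, function(a) any(a == as.character(j)))
      homs <- purrr::map_lgl(gt_alleles, function(a) sum(a == as.character(j)) == 2)
      carriers <- samples[!is.na(hits) & hits]
      homozygotes <- samples[!is.na(homs) & homs]
      by_gene <- split(ent, purrr::map_chr(ent, function(p) blank_to_na(p[["SYMBOL"]]) %||% NA_character_))
      for (gene in names(by_gene)) {
        chosen <- choose_transcript(by_gene[[gene]])
        if (is.null(chosen)) next
        rows[[length(rows) + 1L]] <- csq_entry_row(
          chosen, i,
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = ref, alt = alt,
          id = blank_to_na(fix[i, "ID"]),
          carriers = carriers, homozygotes = homozygotes
        )
      }
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_variant_tbl())
  out <- normalize_variant_keys(list_rbind(rows))
  out <- out[!duplicated(paste(out$key, out$gene)), , drop = FALSE]
  if (length(build) > 0) attr(out, "build") <- build[1]
  out
}

# Transcript choice among one gene's CSQ entries (see read_vcf_variants).
choose_transcript <- function(entries) {
  canon <- purrr::map_lgl(entries, function(p) identical(p[["CANONICAL"]], "YES"))
  if (any(canon)) return(entries[[which(canon)[1]]])
  nontx <- c("intergenic_variant", "upstream_gene_variant", "downstream_gene_variant")
  only_nontx <- purrr::map_lgl(entries, function(p) {
    terms <- so_terms(p[["Consequence"]])[[1]]
    length(terms) > 0 && all(terms %in% nontx)
  })
  if (all(only_nontx)) return(entries[[1]])
  NULL
}

csq_entry_row <- function(p, rec, chrom, pos, ref, alt, id, carriers, homozygotes) {
  where <- paste0("record ", rec)
  g <- function(f) if (f %in% names(p)) blank_to_na(p[[f]]) else NA_character_
  tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    variant_id = id,
    gene = g("SYMBOL"),
    gene_id = g("Gene"),
    consequence = paste(so_terms(p[["Consequence"]])[[1]], collapse = "&"),
    canonical = identical(p[["CANONICAL"]], "YES"),
    hgvs_c = g("HGVSc"),
    hgvs_p = g("HGVSp"),
    sift = parse_pred_score(g("SIFT"), "SIFT", where),
    polyphen = parse_pred_score(g("PolyPhen"), "PolyPhen", where),
    revel = parse_num_field(g("REVEL"), "REVEL", where),
    cadd_phred = parse_num_field(g("CADD_PHRED"), "CADD_PHRED", where),
    af_exome_global = parse_num_field(g("gnomADe_AF"), "gnomADe_AF", where),
    af_genome_global = parse_num_field(g("gnomADg_AF"), "gnomADg_AF", where),
    af_exome_fin = parse_num_field(g("gnomADe_FIN_AF"), "gnomADe_FIN_AF", where),
    af_genome_fin = parse_num_field(g("gnomADg_FIN_AF"), "gnomADg_FIN_AF", where),
    carriers = list(carriers),
    homozygotes = list(homozygotes)
  )
}

empty_variant_tbl <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    variant_id = character(), gene = character(), gene_id = character(),
    consequence = character(), canonical = logical(),
    hgvs_c = character(), hgvs_p = character(),
    sift = double(), polyphen = double(), revel = double(),
    cadd_phred = double(),
    af_exome_global = double(), af_genome_global = double(),
    af_exome_fin = double(), af_genome_fin = double(),
    carriers = list(), homozygotes = list(), key = character()
  )
}

#' Write an annotated cohort as a VCF file
#'
#' Serializes a variant tibble (and its carriers) to a VCF 4.2 file with a
#' single-transcript `INFO/CSQ` block per alternate allele and `GT` sample
#' columns (`0/1` for carriers, `1/1` for recorded homozygotes, `0/0`
#' otherwise). The output of [read_vcf_variants()] on the written file is
#' classification-equivalent to the input.
#'
#' @param variants Variant tibble (VCF-complete keys: ref/alt present).
#' @param path Output path; vcfR appends `.gz` compression, so use a
#'   `.vcf.gz` name.
#' @param samples Sample names for the genotype columns; defaults to the union
#'   of all carriers.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(variants, path, samples = NULL) {
  variants <- normalize_variant_keys(as_tibble(variants))
  if (any(is.na(variants$ref) | is.na(variants$alt))) {
    abort("write_cohort_vcf needs complete keys: ref/alt must be present")
  }
  if (!"carriers" %in% names(variants)) variants$carriers <- list(character(0))
  if (!"homozygotes" %in% names(variants)) variants$homozygotes <- list(character(0))
  if (is.null(samples)) {
    samples <- sort(unique(unlist(variants$carriers)))
  }
  variants <- arrange_keys(variants)
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  csq <- paste(
    vep_allele(variants$ref, variants$alt),
    fmt(variants$consequence), fmt(variants$gene), fmt(variants$gene_id),
    ifelse(isTRUE_vec(variants$canonical), "YES", ""),
    fmt(variants$hgvs_c), fmt(variants$hgvs_p),
    fmt(variants$sift), fmt(variants$polyphen), fmt(variants$revel),
    fmt(variants$cadd_phred),
    fmt(variants$af_exome_global), fmt(variants$af_genome_global),
    fmt(variants$af_exome_fin), fmt(variants$af_genome_fin),
    sep = "|"
  )
  meta <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh38",
    paste0(
      '##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence annotations. Format: ',
      paste(csq_supported_fields, collapse = "|"), '">'
    ),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  fix <- cbind(
    CHROM = paste0("chr", norm_chrom(variants$chrom)),
    POS = as.character(variants$pos),
    ID = ifelse(is.na(variants$variant_id), ".", variants$variant_id),
    REF = variants$ref,
    ALT = variants$alt,
    QUAL = ".",
    FILTER = "PASS",
    INFO = paste0("CSQ=", csq)
  )
  gt <- NULL
  if (length(samples) > 0) {
    gt_body <- vapply(seq_len(nrow(variants)), function(i) {
      g <- rep("0/0", length(samples))
      g[samples %in% variants$carriers[[i]]] <- "0/1"
      g[samples %in% variants$homozygotes[[i]]] <- "1/1"
      g
    }, character(length(samples)))
    gt_body <- matrix(gt_body, ncol = length(samples), byrow = TRUE,
                      dimnames = list(NULL, samples))
    gt <- cbind(FORMAT = rep("GT", nrow(variants)), gt_body)
  } else {
    gt <- matrix(character(0), nrow = nrow(variants), ncol = 0)
    gt <- cbind(FORMAT = rep("GT", nrow(variants)))
  }
  out <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x
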