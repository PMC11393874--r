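#' Load a DNA-repair gene panel
#'
#' The panel file lists one current gene symbol per line (`#` comments
#' allowed). An optional alias map (two tab-separated columns: old symbol,
#' current symbol) attaches outdated symbols as aliases, mirroring the
#' symbol-updating step a panel screen needs because published gene lists mix
#' nomenclature generations. If a panel line carries an *old* symbol that the
#' alias map updates, the entry is replaced by the current symbol with the
#' old one kept as an alias.
#'
#' @param panel_source Path to the symbol list.
#' @param alias_source Optional path to the old->current alias map.
#' @return A tibble with columns `symbol`, `aliases` (list column) and
#'   `gene_id` (stable identifier, `NA` when the file carries none).
#' @export
load_panel <- function(panel_source, alias_source = NULL) {
  lines <- readr::read_lines(panel_source, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  symbols <- lines[lines != ""]
  aliases <- tibble(old = character(0), current = character(0))
  if (!is.null(alias_source)) {
    aliases <- readr::read_tsv(alias_source, col_names = c("old", "current"),
                               col_types = "cc", progress = FALSE)
  }
  panel <- tibble(symbol = symbols, gene_id = NA_character_)
  panel <- panel[!duplicated(toupper(panel$symbol)), , drop = FALSE]
  panel$aliases <- rep(list(character(0)), nrow(panel))
  for (i in seq_len(nrow(aliases))) {
    old <- aliases$old[i]
    current <- aliases$current[i]
    hit_current <- match(toupper(current), toupper(panel$symbol))
    hit_old <- match(toupper(old), toupper(panel$symbol))
    if (!is.na(hit_current)) {
      panel$aliases[[hit_current]] <- unique(c(panel$aliases[[hit_current]], old))
      if (!is.na(hit_old) && hit_old != hit_current) {
        panel <- panel[-hit_old, , drop = FALSE]
      }
    } else if (!is.na(hit_old)) {
      # panel still lists the outdated symbol: update it in place
      panel$symbol[hit_old] <- current
      panel$aliases[[hit_old]] <- unique(c(panel$aliases[[hit_old]], old))
    }
  }
  panel$aliases <- map2(panel$aliases, panel$symbol,
                        function(al, sym) setdiff(al, sym))
  panel[, c("symbol", "aliases", "gene_id")]
}

#' Panel membership of variants
#'
#' A variant is on panel when its gene symbol matches a panel symbol or any
#' of its aliases (case-insensitive exact match; no fuzzy matching, which
#' would silently corrupt the panel restriction), or when its stable gene
#' identifier matches a panel gene identifier.
#'
#' @param variants A variant tibble (columns `gene`, optionally `gene_id`).
#' @param panel A panel tibble from [load_panel()].
#' @return Logical vector, one element per variant row.
#' @export
in_panel <- function(variants, panel) {
  if (nrow(panel) == 0) return(rep(FALSE, nrow(variants)))
  lookup <- toupper(unique(c(panel$symbol, unlist(panel$aliases))))
  hit <- toupper(variants$gene) %in% lookup
  ids <- panel$gene_id[!is.na(panel$gene_id)]
  if (length(ids) > 0 && "gene_id" %in% names(variants)) {
    hit <- hit | (!is.na(variants$gene_id) & variants$gene_id %in% ids)
  }
  hit[is.na(hit)] <- FALSE
  hit
}
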