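#' Quality and impact filter on labelled somatic variants
#'
#' Keeps (variant, gene) pairs whose site quality is strictly greater than
#' `min_qual` and whose annotated impact is `HIGH` or `MODERATE`. Somatic
#' calls without an annotation row are dropped and tallied.
#'
#' @param calls labelled site table (from [run_labelling()]`$calls` or
#'   [label_somatic()]); only rows with `label == "somatic"` are
#'   considered.
#' @param annotations data.frame `chrom,pos,ref,alt,gene_symbol,impact`
#'   with impact in `HIGH, MODERATE, LOW, MODIFIER`.
#' @param min_qual strict lower bound on site quality (default 20).
#' @return list with `pairs` (passing rows:
#'   `chrom,pos,ref,alt,qual,gene_symbol,impact`) and `n_unannotated`.
#' @export
filter_impact <- function(calls, annotations, min_qual = 20) {
  vocab <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  bad <- !annotations$impact %in% vocab
  if (any(bad)) {
    stop("input error: unknown impact '", annotations$impact[which(bad)[1]],
         "' in annotation row ", which(bad)[1], call. = FALSE)
  }
  som <- calls[calls$label == "somatic", , drop = FALSE]
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  idx <- match(key(som), key(annotations))
  n_unannotated <- sum(is.na(idx))
  som <- som[!is.na(idx), , drop = FALSE]
  ann <- annotations[idx[!is.na(idx)], , drop = FALSE]
  keep <- som$qual > min_qual & ann$impact %in% c("HIGH", "MODERATE")
  pairs <- data.frame(chrom = som$chrom, pos = som$pos, ref = som$ref,
                      alt = som$alt, qual = som$qual,
                      gene_symbol = ann$gene_symbol, impact = ann$impact,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, n_unannotated = n_unannotated)
}

#' Map gene symbols to their homologs
#'
#' Joins source (e.g. rat) symbols against a two-column homolog table and
#' reports which mapped symbols changed name (case-insensitive
#' comparison, so `Jak1 -> JAK1` does not count as renamed).
#'
#' @param gene_symbols character vector of source symbols.
#' @param homolog_table data.frame `source_symbol,target_symbol`; source
#'   symbols must be unique.
#' @return list with `mapped` (data.frame `source_symbol,target_symbol`),
#'   `unmapped` (character vector) and `n_renamed`.
#' @export
map_homologs <- function(gene_symbols, homolog_table) {
  if (anyDuplicated(homolog_table$source_symbol)) {
    dup <- homolog_table$source_symbol[
      duplicated(homolog_table$source_symbol)][1]
    stop("input error: duplicate source symbol in homolog table: ", dup,
         call. = FALSE)
  }
  symbols <- sort(unique(gene_symbols))
  idx <- match(symbols, homolog_table$source_symbol)
  mapped <- data.frame(source_symbol = symbols[!is.na(idx)],
                       target_symbol =
                         homolog_table$target_symbol[idx[!is.na(idx)]],
                       stringsAsFactors = FALSE)
  n_renamed <- sum(tolower(mapped$source_symbol) !=
                     tolower(mapped$target_symbol))
  list(mapped = mapped, unmapped = symbols[is.na(idx)],
       n_renamed = n_renamed)
}

#' Intersect mapped genes with a cancer gene census
#'
#' Builds the per-gene report: exactly the mapped genes whose human symbol
#' appears in the census table, with tier, passing-variant rollup and a
#' variant list, sorted by source symbol.
#'
#' @param mapped data.frame `source_symbol,target_symbol` from
#'   [map_homologs()].
#' @param cgc_table data.frame `human_symbol,tier` (tier 1 or 2).
#' @param pairs passing (variant, gene) pairs from [filter_impact()].
#' @return data.frame `gene_symbol,human_symbol,tier,n_passing_variants,
#'   variants` (variants as `chrom:pos:ref>alt` joined by `;`).
#' @export
intersect_cgc <- function(mapped, cgc_table, pairs) {
  hit <- mapped[mapped$target_symbol %in% cgc_table$human_symbol, ,
                drop = FALSE]
  hit <- hit[order(hit$source_symbol), , drop = FALSE]
  if (nrow(hit) == 0) {
    return(data.frame(gene_symbol = character(0),
                      human_symbol = character(0), tier = integer(0),
                      n_passing_variants = integer(0),
                      variants = character(0), stringsAsFactors = FALSE))
  }
  tier <- cgc_table$tier[match(hit$target_symbol, cgc_table$human_symbol)]
  rollup <- vapply(hit$source_symbol, function(g) {
    v <- pairs[pairs$gene_symbol == g, , drop = FALSE]
    v <- v[order(v$chrom, v$pos), , drop = FALSE]
    paste(sprintf("%s:%d:%s>%s", v$chrom, v$pos, v$ref, v$alt),
          collapse = ";")
  }, character(1))
  n_var <- vapply(hit$source_symbol,
                  function(g) sum(pairs$gene_symbol == g), integer(1))
  out <- data.frame(gene_symbol = hit$source_symbol,
                    human_symbol = hit$target_symbol,
                    tier = as.integer(tier),
                    n_passing_variants = n_var,
                    variants = rollup,
                    stringsAsFactors = FALSE)
  out <- out[out$n_passing_variants > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

gene_report_columns <- c("gene_symbol", "human_symbol", "tier",
                         "n_passing_variants", "variants", "wgs_detected",
                         "validated_cell_line", "validated_primary")

#' Render the gene report as TSV
#'
#' Output columns (in order): `gene_symbol`, `human_symbol`, `tier`,
#' `n_passing_variants`, `variants`, `wgs_detected`,
#' `validated_cell_line`, `validated_primary`. Genes in the report were
#' detected by sequencing, so `wgs_detected` is `yes`; validation columns
#' are filled from the optional validation table and rendered `unknown`
#' otherwise.
#'
#' @param report data.frame from [intersect_cgc()].
#' @param path optional output TSV path.
#' @param validation optional data.frame
#'   `gene_symbol,validated_cell_line,validated_primary` with `yes`/`no`
#'   entries.
#' @return The rendered data.frame (written to `path` when given),
#'   invisibly.
#' @export
render_report <- function(report, path = NULL, validation = NULL) {
  out <- report
  out$wgs_detected <- rep("yes", nrow(out))
  out$validated_cell_line <- rep("unknown", nrow(out))
  out$validated_primary <- rep("unknown", nrow(out))
  if (!is.null(validation) && nrow(out) > 0) {
    idx <- match(out$gene_symbol, validation$gene_symbol)
    hit <- !is.na(idx)
    out$validated_cell_line[hit] <-
      as.character(validation$validated_cell_line[idx[hit]])
    out$validated_primary[hit] <-
      as.character(validation$validated_primary[idx[hit]])
  }
  out <- out[, gene_report_columns, drop = FALSE]
  if (!is.null(path)) write_tsv_stable(out, path)
  invisible(out)
}

#' Read a gene report TSV written by [render_report()]
#' @param path TSV path.
#' @return The report data.frame.
#' @export
read_gene_report <- function(path) {
  df <- read_tsv_plain(path, colClasses = c(
    gene_symbol = "character", human_symbol = "character",
    tier = "integer", n_passing_variants = "integer",
    variants = "character", wgs_detected = "character",
    validated_cell_line = "character", validated_primary = "character"))
  df
}
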