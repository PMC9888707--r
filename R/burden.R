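# Per-gene and aggregate burden scores, carrier summaries and the
# case-carrier gene filters.

#' Individuals x genes burden matrix from qualified variants
#'
#' Burden(i, g) is the sum over qualifying variants in gene g of
#' individual i's alternate-allele count (a homozygote contributes 2
#' under the default allele-counting convention; `mode = "variant"`
#' counts a homozygote as 1). Missing genotypes contribute 0.
#'
#' @param genotypes Integer matrix, variants x individuals, `{0,1,2,NA}`,
#'   rownames = variant ids.
#' @param qualified Output of [qualify_variants()] (or any data frame
#'   with `variant_id` and `gene_id`).
#' @param mode `"allele"` (default) or `"variant"` counting.
#' @return Integer matrix, individuals x genes; genes with no qualifying
#'   variant are absent.
#' @export
gene_burden <- function(genotypes, qualified, mode = c("allele", "variant")) {
  mode <- match.arg(mode)
  idx <- match(qualified$variant_id, rownames(genotypes))
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " qualified variants absent from genotype ",
            "matrix; skipped")
    qualified <- qualified[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  g <- genotypes[idx, , drop = FALSE]
  g[is.na(g)] <- 0L
  if (mode == "variant") g <- pmin(g, 1L)
  genes <- factor(qualified$gene_id)
  # sum variant rows within gene: genes x individuals, then transpose
  agg <- rowsum(g, genes)
  out <- t(agg)
  storage.mode(out) <- "integer"
  out
}

#' Total burden over a gene subset
#'
#' Row sum of the burden matrix over the selected genes (all genes by
#' default). Genes absent from the matrix because they had no qualifying
#' variant contribute 0; gene ids never seen in the gene universe are an
#' error.
#'
#' @param burdens Individuals x genes matrix from [gene_burden()].
#' @param genes Character vector of gene ids, or NULL for all columns.
#' @param gene_universe Optional vector of all legal gene ids (defaults
#'   to the matrix columns).
#' @return Named integer vector of per-individual totals.
#' @export
total_burden <- function(burdens, genes = NULL, gene_universe = NULL) {
  if (is.null(genes)) return(rowSums(burdens))
  universe <- gene_universe %||% colnames(burdens)
  bad <- setdiff(genes, universe)
  if (length(bad))
    stop_input("unknown gene id: ", paste(head(bad, 5), collapse = ", "))
  cols <- intersect(genes, colnames(burdens))
  rowSums(burdens[, cols, drop = FALSE])
}

#' Carrier and case-carrier summary per gene
#'
#' A carrier has burden >= 1 in the gene; a case carrier is a carrier
#' labeled "case".
#'
#' @param burdens Individuals x genes burden matrix.
#' @param labels Character vector parallel to rows, `"case"`/`"control"`/
#'   `NA` as from [binarize_case_control()].
#' @return Data frame per gene: `gene_id`, `carriers`, `case_carriers`,
#'   `carrier_freq` (carriers / labeled n).
#' @export
carrier_summary <- function(burdens, labels) {
  if (length(labels) != nrow(burdens))
    stop_input("labels must be parallel to burden rows")
  lab <- !is.na(labels)
  carrier <- burdens[lab, , drop = FALSE] >= 1L
  is_case <- labels[lab] == "case"
  data.frame(gene_id = colnames(burdens),
             carriers = as.integer(colSums(carrier)),
             case_carriers = as.integer(colSums(carrier & is_case)),
             carrier_freq = colSums(carrier) / sum(lab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 2x2 carrier table (case/control x carrier/non-carrier)
#'
#' @param burden Per-individual burden vector (gene or total).
#' @param labels `"case"`/`"control"`/`NA` labels.
#' @return 2x2 integer matrix with rows case/control and columns
#'   carrier/non-carrier.
#' @export
carrier_table <- function(burden, labels) {
  keep <- !is.na(labels)
  t <- table(factor(labels[keep], c("case", "control")),
             factor(burden[keep] >= 1, c(TRUE, FALSE)))
  m <- matrix(as.integer(t), 2, 2,
              dimnames = list(c("case", "control"),
                              c("carrier", "non-carrier")))
  m
}

#' Filter genes by case-carrier count
#'
#' Retains genes with strictly more than `threshold` case carriers
#' (threshold 0 for the known hearing-loss gene scan, 25 for the
#' exome-wide scan).
#'
#' @param summary Output of [carrier_summary()].
#' @param threshold Nonnegative integer.
#' @return Character vector of retained gene ids.
#' @export
filter_genes_by_case_carriers <- function(summary, threshold) {
  if (threshold < 0) stop_input("'threshold' must be nonnegative")
  summary$gene_id[summary$case_carriers > threshold]
}

#' Load the packaged known hearing-loss gene set
#'
#' A synthetic stand-in gene list with the inheritance-class composition
#' of curated congenital hearing-loss panels: 173 autosomal genes, 66
#' autosomal-dominant (DFNA), 97 autosomal-recessive (DFNB) and 10 with
#' both inheritance patterns. Gene identifiers are synthetic
#' (`HLG0001`...); supply your own table for real analyses.
#'
#' @param path Optional path to a user gene set (`gene_id`,
#'   `inheritance`); defaults to the packaged synthetic list.
#' @return Data frame with columns `gene_id` and `inheritance`
#'   (`"DFNA"`, `"DFNB"`, `"DFNA+B"`).
#' @export
hl_gene_set <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hl_genes_synthetic.tsv",
                                package = "hlburden", mustWork = TRUE)
  gs <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "inheritance") %in% names(gs)))
    stop_input("gene set needs columns gene_id, inheritance")
  gs
}
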