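#' Rename expression-table columns to the package schema
#'
#' Expression tables from other pipelines rarely use this package's column
#' names; `header_map` maps them (e.g. `c(gene_id = "locus_tag", log2fc =
#' "log2FoldChange", padj = "padj")`, names being the schema names and
#' values the columns as found in the file).
#'
#' @param table data frame to rename.
#' @param header_map named character vector: schema name -> incoming name.
#' @return The renamed data frame.
#' @export
apply_header_map <- function(table, header_map) {
  missing <- setdiff(unname(header_map), names(table))
  if (length(missing)) {
    stop("column(s) not in table: ", paste(missing, collapse = ", "))
  }
  idx <- match(header_map, names(table))
  names(table)[idx] <- names(header_map)
  table
}

#' Transcripts per million
#'
#' Length-normalized within-sample expression: `tpm_i = (c_i / l_i) /
#' sum_j(c_j / l_j) * 1e6`. A nonzero vector always sums to exactly one
#' million (up to float tolerance).
#'
#' @param counts nonnegative read counts.
#' @param lengths positive feature lengths (nt), recycled against `counts`.
#' @return Numeric TPM vector.
#' @examples
#' tpm_from_counts(c(10, 10), c(100, 200))
#' @export
tpm_from_counts <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("feature lengths must be positive")
  if (any(counts < 0)) stop("counts must be nonnegative")
  rate <- counts / lengths
  tot <- sum(rate)
  if (tot == 0) {
    warning("all counts are zero; returning all-zero TPM")
    return(rep(0, length(rate)))
  }
  rate / tot * 1e6
}

#' Differential-gene filter
#'
#' Applies the published criterion with strict inequalities: a gene is
#' differentially expressed iff `|log2fc| > lfc_threshold` and `padj <
#' padj_threshold` (boundary values are excluded). Genes with higher
#' expression under the treatment condition (positive `log2fc`) are
#' upregulated.
#'
#' @param table data frame with columns `gene_id`, `log2fc`, `padj`.
#' @param lfc_threshold log2 fold-change threshold (default 1).
#' @param padj_threshold adjusted p-value threshold (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
deg_filter <- function(table, lfc_threshold = 1, padj_threshold = 0.05) {
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  ok <- !is.na(table$log2fc) & !is.na(table$padj) &
    table$padj < padj_threshold
  list(up = table$gene_id[ok & table$log2fc > lfc_threshold],
       down = table$gene_id[ok & table$log2fc < -lfc_threshold])
}

#' Hypergeometric COG enrichment
#'
#' For each COG category with more than `min_genes` members in the tested
#' gene universe, computes the upper-tail hypergeometric probability of
#' observing at least the number of differential genes seen in the category:
#' `P(X >= k)` with `K` category genes among `N` universe genes and a draw
#' of `n = |deg_set|`. No multiple-testing correction is applied by default
#' (significance is flagged at the 0.05 and 0.01 levels); set `bh = TRUE`
#' to add a Benjamini-Hochberg adjusted column for reuse.
#'
#' @param deg_set character vector of differential gene ids (subset of the
#'   universe).
#' @param genome_table data frame with columns `gene_id` and `cog`
#'   (single-letter category, `NA` for unannotated genes).
#' @param min_genes categories with at most this many genes in the universe
#'   are dropped (strictly-more-than semantics).
#' @param bh also report Benjamini-Hochberg adjusted p-values.
#' @return Data frame: `cog`, `K` (category size), `N` (universe size),
#'   `n` (differential set size), `k` (differential genes in category),
#'   `p`, `flag` (`"*"` p < 0.05, `"**"` p < 0.01), optionally `padj`.
#' @export
cog_enrichment <- function(deg_set, genome_table, min_genes = 5, bh = FALSE) {
  if (!all(c("gene_id", "cog") %in% names(genome_table))) {
    stop("genome_table must have columns gene_id and cog")
  }
  if (nrow(genome_table) == 0) stop("empty genome table")
  missing <- setdiff(deg_set, genome_table$gene_id)
  if (length(missing)) {
    stop("deg_set contains ids absent from the genome table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  N <- nrow(genome_table)
  n <- length(unique(deg_set))
  cats <- sort(unique(genome_table$cog[!is.na(genome_table$cog)]))
  rows <- lapply(cats, function(cc) {
    members <- genome_table$gene_id[!is.na(genome_table$cog) &
                                      genome_table$cog == cc]
    K <- length(members)
    if (K <= min_genes) return(NULL)
    k <- length(intersect(deg_set, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(cog = cc, K = K, N = N, n = n, k = k, p = p,
               flag = if (p < 0.01) "**" else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cog = character(), K = integer(), N = integer(),
               n = integer(), k = integer(), p = numeric(),
               flag = character(), stringsAsFactors = FALSE)
  if (bh && nrow(out)) out$padj <- stats::p.adjust(out$p, "BH")
  out[order(out$p), , drop = FALSE]
}

#' Fraction of total transcripts carried by a gene set
#'
#' Sums the TPM of the selected genes under one condition and expresses it
#' as a percentage of the million-TPM total (so the three lactate-utilization
#' genes with TPM 11,321, 16,133 and 35,189 carry 6.26% of transcripts).
#'
#' @param table data frame with `gene_id` and TPM columns.
#' @param gene_ids genes to sum.
#' @param condition condition name; the column used is `tpm_<condition>`
#'   (or `condition` itself if that column exists).
#' @return Percentage (numeric scalar).
#' @export
transcript_fraction <- function(table, gene_ids, condition) {
  col <- if (condition %in% names(table)) condition
         else paste0("tpm_", condition)
  if (!col %in% names(table)) {
    stop("no TPM column for condition '", condition, "'")
  }
  idx <- match(gene_ids, table$gene_id)
  if (anyNA(idx)) {
    stop("unknown gene id(s): ",
         paste(gene_ids[is.na(idx)], collapse = ", "))
  }
  sum(table[[col]][idx]) / 1e6 * 100
}

#' Relative expression by the 2^-ddCT method
#'
#' `2^-((ct_target - ct_reference) - (ct_target_control -
#' ct_reference_control))`, i.e. target CT normalized to a reference gene
#' (16S rRNA in the study) and to a control sample, whose own relative
#' expression is exactly 1.
#'
#' @param ct_target CT of the gene of interest in the test sample.
#' @param ct_reference CT of the reference gene in the test sample.
#' @param ct_target_control,ct_reference_control the same CTs in the
#'   control sample.
#' @return Fold change(s) relative to the control sample.
#' @examples
#' ddct_relative_expression(20, 10, 22, 10)  # 4-fold
#' @export
ddct_relative_expression <- function(ct_target, ct_reference,
                                     ct_target_control,
                                     ct_reference_control) {
  cts <- c(ct_target, ct_reference, ct_target_control, ct_reference_control)
  if (any(!is.finite(cts))) stop("CT values must be finite")
  ddct <- (ct_target - ct_reference) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' RNA-seq / qPCR fold-change concordance
#'
#' Pearson correlation of log2 fold changes measured by RNA-seq and by
#' qRT-PCR over the same genes.
#'
#' @param log2fc_rnaseq,log2fc_qpcr paired log2 fold changes (>= 3 pairs).
#' @return List with `r` (Pearson correlation) and `n`.
#' @export
fold_change_concordance <- function(log2fc_rnaseq, log2fc_qpcr) {
  if (length(log2fc_rnaseq) != length(log2fc_qpcr)) {
    stop("fold-change vectors must be paired")
  }
  ok <- is.finite(log2fc_rnaseq) & is.finite(log2fc_qpcr)
  x <- log2fc_rnaseq[ok] ; y <- log2fc_qpcr[ok]
  if (length(x) < 3) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one platform: correlation undefined")
  }
  list(r = stats::cor(x, y), n = length(x))
}
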