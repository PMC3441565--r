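#' SNPs falling in a gene's window
#'
#' The window runs from `upstream` bases upstream of the transcription
#' start site to the end of the transcribed region, on the gene's
#' chromosome.  Upstream is strand-aware: for a + strand gene the window is
#' `[max(1, tx_start - upstream), tx_end]`, for a - strand gene
#' `[tx_start, tx_end + upstream]`.
#'
#' @param gene one row of a gene annotation table (list/data.frame with
#'   gene_id, chrom, strand, tx_start, tx_end).
#' @param snps data.frame with snp_id, chrom, position (1-based).
#' @param upstream non-negative window extension in bases (default 1000).
#' @return character vector of snp ids (possibly empty), in `snps` order.
#' @export
snps_in_gene_window <- function(gene, snps, upstream = 1000L) {
  stopifnot(upstream >= 0)
  if (gene$strand == "+") {
    lo <- max(1L, gene$tx_start - upstream); hi <- gene$tx_end
  } else {
    lo <- gene$tx_start; hi <- gene$tx_end + upstream
  }
  hit <- snps$chrom == gene$chrom & snps$position >= lo & snps$position <= hi
  snps$snp_id[hit]
}

#' Pearson chi-square association of one SNP with phenotype
#'
#' Statistic of the 2 x k contingency table of class by genotype category,
#' where k is the number of genotype categories observed in the pooled
#' cohort; no continuity correction.  A SNP with a single observed category
#' is degenerate and scores 0.
#'
#' @param calls integer dosage vector for one SNP, aligned with `labels`.
#' @param labels a [phenotype_labels()] factor.
#' @return the chi-square statistic (>= 0).
#' @export
chi_square_association <- function(calls, labels) {
  stopifnot(length(calls) == length(labels))
  tab <- table(factor(labels), factor(calls))
  tab <- tab[, colSums(tab) > 0L, drop = FALSE]
  if (ncol(tab) < 2L || nrow(tab) < 2L) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

#' Minor allele frequency of a dosage vector
#'
#' `min(f, 1 - f)` with `f = sum(calls) / (2n)`; invariant to
#' complementary allele coding.
#'
#' @param calls integer dosage vector in \{0,1,2\}.
#' @return frequency in [0, 0.5].
#' @export
minor_allele_frequency <- function(calls) {
  stopifnot(length(calls) >= 1L)
  f <- sum(calls) / (2 * length(calls))
  min(f, 1 - f)
}

#' Select one representative SNP per gene
#'
#' Among the SNPs in each gene's window with minor allele frequency above
#' `maf_min`, picks the SNP with maximal chi-square association with
#' phenotype.  Ties are broken by smallest genomic position, then
#' lexicographic snp id.  Genes with no eligible SNP are omitted.
#'
#' @param genes gene annotation data.frame (see [read_gene_annotations()]).
#' @param snps SNP location data.frame (snp_id, chrom, position).
#' @param genotypes a [genotype_matrix()] (SNP x sample).
#' @param labels a [phenotype_labels()] aligned with `genotypes` columns.
#' @param upstream window extension in bases (default 1000).
#' @param maf_min MAF threshold in [0, 0.5); SNPs must exceed it (default 0.05).
#' @return data.frame gene_id/snp_id/chi_square/maf, one row per mapped
#'   gene, of class `"gene_snp_assignment"`.
#' @export
select_representative_snps <- function(genes, snps, genotypes, labels,
                                       upstream = 1000L, maf_min = 0.05) {
  stopifnot(maf_min >= 0, maf_min < 0.5)
  check_sample_alignment(genotypes, labels)
  # score every SNP once
  maf <- apply(unclass(genotypes), 1L, minor_allele_frequency)
  chi2 <- apply(unclass(genotypes), 1L, chi_square_association, labels = labels)
  names(maf) <- names(chi2) <- rownames(genotypes)
  pos <- snps$position[match(rownames(genotypes), snps$snp_id)]
  names(pos) <- rownames(genotypes)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    ids <- snps_in_gene_window(genes[i, ], snps, upstream)
    ids <- ids[ids %in% rownames(genotypes)]
    ids <- ids[maf[ids] > maf_min]
    if (length(ids) == 0L) return(NULL)
    o <- order(-chi2[ids], pos[ids], ids)
    best <- ids[o[1L]]
    data.frame(gene_id = genes$gene_id[i], snp_id = best,
               chi_square = unname(chi2[best]), maf = unname(maf[best]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), snp_id = character(),
                      chi_square = numeric(), maf = numeric())
  class(out) <- c("gene_snp_assignment", "data.frame")
  out
}

#' Collapse a SNP-level genotype matrix to the gene level
#'
#' Each assigned gene receives the dosage row of its representative SNP.
#'
#' @param genotypes a [genotype_matrix()] (SNP x sample).
#' @param assignment a `gene_snp_assignment` from
#'   [select_representative_snps()].
#' @return a [genotype_matrix()] with one row per assigned gene.
#' @export
collapse_to_gene_level <- function(genotypes, assignment) {
  missing <- setdiff(assignment$snp_id, rownames(genotypes))
  if (length(missing))
    stop("assigned SNP absent from genotype matrix: ",
         paste(missing, collapse = ", "))
  calls <- unclass(genotypes)[assignment$snp_id, , drop = FALSE]
  genotype_matrix(calls, assignment$gene_id, colnames(genotypes))
}
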