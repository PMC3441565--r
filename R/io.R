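#' Construct a validated expression matrix
#'
#' Expression data are stored as a plain numeric matrix with genes as rows
#' and samples as columns; row and column names carry the identifiers.
#'
#' @param values numeric matrix (genes x samples).
#' @param gene_ids,sample_ids optional identifier vectors; taken from
#'   `dimnames(values)` when missing.
#' @param description optional per-gene description vector (kept as an
#'   attribute, not used downstream).
#' @return the validated matrix with class `"expression_matrix"` prepended.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              description = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (ncol(values) < 2L)
    stop("at least 2 samples are required")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(description)) attr(values, "description") <- description
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Construct a validated genotype dosage matrix
#'
#' Genotypes are allele-dosage calls in \{0, 1, 2\} counting copies of the
#' designated minor/risk allele, stored SNP x sample.  After collapsing to
#' the gene level (see [collapse_to_gene_level()]) the rows are genes.
#'
#' @param calls integer matrix (SNPs x samples) with entries in \{0,1,2\}.
#' @param snp_ids,sample_ids optional identifier vectors.
#' @return validated integer matrix with class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(calls, snp_ids = rownames(calls),
                            sample_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(snp_ids) || is.null(sample_ids))
    stop("snp_ids and sample_ids are required")
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (length(snp_ids) != nrow(calls) || length(sample_ids) != ncol(calls))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(snp_ids))
    stop("duplicate snp/gene ids: ",
         paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!all(calls %in% c(0L, 1L, 2L)))
    stop("genotype calls must be 0, 1 or 2 (missing calls are not accepted)")
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(snp_ids, sample_ids)
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' Construct phenotype labels for a two-class cohort
#'
#' Labels are a two-level factor named by sample id.  The first level is
#' class C1 throughout the package (positive class, coded +1 in models).
#'
#' @param classes vector of class assignments (character/factor/0-1).
#' @param sample_ids sample identifiers, same length as `classes`.
#' @param class_levels optional explicit level order; first entry becomes C1.
#' @return named factor of class `"phenotype_labels"`.
#' @export
phenotype_labels <- function(classes, sample_ids, class_levels = NULL) {
  sample_ids <- as.character(sample_ids)
  if (length(classes) != length(sample_ids))
    stop("classes and sample_ids differ in length")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (is.null(class_levels)) {
    class_levels <- if (is.factor(classes)) levels(classes)
                    else unique(as.character(classes))
  }
  f <- factor(as.character(classes), levels = class_levels)
  if (nlevels(f) != 2L)
    stop("exactly two phenotype classes are required, got: ",
         paste(class_levels, collapse = ", "))
  if (anyNA(f)) stop("unlabeled samples present")
  if (any(table(f) < 2L))
    stop("each class needs at least 2 samples for class-conditional statistics")
  names(f) <- sample_ids
  class(f) <- c("phenotype_labels", "factor")
  f
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of member gene ids.
#'   Duplicate members within a set are collapsed (set semantics).
#' @param descriptions optional character vector parallel to `sets`.
#' @return named list of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("empty gene sets are not allowed")
  if (!is.null(descriptions)) {
    stopifnot(length(descriptions) == length(sets))
    attr(sets, "description") <- as.character(descriptions)
  }
  class(sets) <- "gene_set_collection"
  sets
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene set collection:", length(x), "sets, member counts",
      min(lengths(x)), "-", max(lengths(x)), "\n")
  invisible(x)
}

#' Read a GCT v1.2 expression file
#'
#' @param path path to a GCT file (two header lines, then a table with
#'   NAME and Description columns followed by one column per sample).
#' @return an [expression_matrix()].
#' @export
read_expression_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("GCT file too short: ", path)
  if (trimws(lines[1L]) != "#1.2")
    stop("expected GCT version line '#1.2', found: ", lines[1L])
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]]))
  if (length(dims) != 2L || anyNA(dims))
    stop("malformed GCT dimension line: ", lines[2L])
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(header) != dims[2L] + 2L)
    stop("GCT declares ", dims[2L], " samples but header has ",
         length(header) - 2L, " sample columns")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != dims[1L])
    stop("GCT declares ", dims[1L], " genes but contains ",
         length(body), " data rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != dims[2L] + 2L))
    stop("GCT data row with wrong number of fields (row ",
         which(nf != dims[2L] + 2L)[1L], ")")
  gene_ids <- vapply(fields, `[[`, "", 1L)
  descr <- vapply(fields, `[[`, "", 2L)
  vals <- matrix(as.numeric(unlist(lapply(fields, `[`, -(1:2)))),
                 nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
  expression_matrix(vals, gene_ids, header[-(1:2)], description = descr)
}

#' Write a GCT v1.2 expression file
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @export
write_expression_gct <- function(expr, path) {
  descr <- attr(expr, "description")
  if (is.null(descr)) descr <- rep("na", nrow(expr))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t"),
               paste(c("NAME", "Description", colnames(expr)),
                     collapse = "\t")), con)
  body <- apply(unclass(expr), 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(expr), descr, body, sep = "\t"), con)
  invisible(path)
}

#' Read a two-class CLS phenotype file
#'
#' Supports the categorical dialect (named classes on the `#` line) and the
#' numeric 0/1 dialect.  The first named class (or 0) becomes class C1.
#'
#' @param path path to a CLS file.
#' @param sample_ids optional sample ids (defaults to s1..sn).
#' @return a [phenotype_labels()] factor.
#' @export
read_labels_cls <- function(path, sample_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("CLS file needs 3 lines")
  hdr <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
  if (length(hdr) != 3L || anyNA(hdr))
    stop("malformed CLS count line: ", lines[1L])
  n <- hdr[1L]; k <- hdr[2L]
  if (k != 2L) stop("only two-class CLS files are supported, declared ", k)
  name_line <- strsplit(trimws(lines[2L]), "[ \t]+")[[1L]]
  if (name_line[1L] != "#") stop("CLS second line must start with '#'")
  class_names <- name_line[-1L]
  if (length(class_names) != 2L)
    stop("CLS declares 2 classes but names ", length(class_names))
  toks <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
  if (length(toks) != n)
    stop("CLS count line declares ", n, " samples but label line has ",
         length(toks))
  if (all(toks %in% c("0", "1"))) {
    cls <- class_names[as.integer(toks) + 1L]
  } else {
    if (!all(toks %in% class_names))
      stop("CLS label not among declared class names: ",
           paste(setdiff(toks, class_names), collapse = ", "))
    cls <- toks
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  phenotype_labels(cls, sample_ids, class_levels = class_names)
}

#' Write a two-class CLS phenotype file
#' @param labels a [phenotype_labels()] factor.
#' @param path output path.
#' @export
write_labels_cls <- function(labels, path) {
  writeLines(c(paste(length(labels), 2, 1),
               paste("#", paste(levels(labels), collapse = " ")),
               paste(as.character(labels), collapse = " ")), path)
  invisible(path)
}

#' Read a GMT gene set file
#'
#' Tab-separated lines: set name, description, then member gene ids.
#' Duplicate members within a line are collapsed; duplicate set names are
#' an error.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT line with fewer than 3 fields (line ",
         which(lengths(fields) < 3L)[1L], ")")
  nm <- vapply(fields, `[[`, "", 1L)
  descr <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, `[`, -(1:2))
  names(sets) <- nm
  gene_set_collection(sets, descriptions = descr)
}

#' Write a GMT gene set file
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  descr <- attr(sets, "description")
  if (is.null(descr)) descr <- rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descr[i], sets[[i]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Filter gene sets by mapped size
#'
#' Restricts each set to the genes present in `universe` and keeps only
#' sets whose mapped size lies in `[min_size, max_size]` (bounds
#' inclusive).  The canonical-pathway analyses use 15 to 100 mapped genes.
#'
#' @param sets a [gene_set_collection()].
#' @param universe character vector of measured gene ids.
#' @param min_size,max_size inclusive size bounds.
#' @return filtered [gene_set_collection()] with membership replaced by the
#'   intersection with `universe`.
#' @export
filter_gene_sets <- function(sets, universe, min_size = 15L, max_size = 100L) {
  stopifnot(min_size >= 1L, max_size >= min_size)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  descr <- attr(sets, "description")
  mapped <- lapply(sets, function(g) g[g %in% universe])
  keep <- lengths(mapped) >= min_size & lengths(mapped) <= max_size
  out <- mapped[keep]
  class(out) <- "gene_set_collection"
  if (!is.null(descr)) attr(out, "description") <- descr[keep]
  out
}

#' Read genotype calls from PLINK PED/MAP or a dosage TSV
#'
#' For PED/MAP input, each SNP must be biallelic with no missing calls; the
#' dosage counts the empirically rarer allele over the whole file, ties
#' broken by the lexicographically smaller allele.  TSV input has SNPs as
#' rows (first column snp id) and samples as columns, entries in \{0,1,2\}.
#'
#' @param path_ped path to a PED file (or a dosage TSV when `path_map` is
#'   NULL).
#' @param path_map path to the matching MAP file, or NULL for TSV input.
#' @return list with elements `genotypes` (a [genotype_matrix()]) and
#'   `locations` (data.frame snp_id/chrom/position; NULL for TSV input).
#' @export
read_genotypes <- function(path_ped, path_map = NULL) {
  if (is.null(path_map)) {
    tab <- utils::read.delim(path_ped, header = TRUE, check.names = FALSE,
                             colClasses = "character")
    calls <- as.matrix(tab[, -1L, drop = FALSE])
    mode(calls) <- "integer"
    return(list(genotypes = genotype_matrix(calls, tab[[1L]], colnames(tab)[-1L]),
                locations = NULL))
  }
  map <- utils::read.table(path_map, header = FALSE, col.names =
    c("chrom", "snp_id", "cm", "position"), colClasses =
    c("character", "character", "numeric", "integer"))
  ped <- strsplit(trimws(readLines(path_ped)), "[ \t]+")
  n_snp <- nrow(map)
  nf <- lengths(ped)
  if (any(nf != 6L + 2L * n_snp))
    stop("PED row ", which(nf != 6L + 2L * n_snp)[1L], " has ",
         nf[which(nf != 6L + 2L * n_snp)[1L]] - 6L,
         " allele fields, expected ", 2L * n_snp)
  sample_ids <- vapply(ped, `[[`, "", 2L)
  allele_mat <- do.call(rbind, lapply(ped, `[`, -(1:6)))  # samples x 2*snps
  calls <- matrix(0L, n_snp, length(ped))
  for (j in seq_len(n_snp)) {
    a <- allele_mat[, 2L * j - 1L]
    b <- allele_mat[, 2L * j]
    al <- c(a, b)
    if (any(al %in% c("0", "N", "-")))
      stop("missing genotype call at SNP ", map$snp_id[j],
           " (missing calls are not accepted)")
    tab <- table(al)
    if (length(tab) > 2L)
      stop("SNP ", map$snp_id[j], " is not biallelic: alleles ",
           paste(names(tab), collapse = "/"))
    # minor allele: rarer count, lexicographic tie-break
    minor <- if (length(tab) == 1L) names(tab) else {
      o <- order(as.integer(tab), names(tab))
      names(tab)[o[1L]]
    }
    calls[j, ] <- (a == minor) + (b == minor)
  }
  list(genotypes = genotype_matrix(calls, map$snp_id, sample_ids),
       locations = data.frame(snp_id = map$snp_id, chrom = map$chrom,
                              position = map$position,
                              stringsAsFactors = FALSE))
}

#' Read a gene annotation table
#'
#' Plain TSV with columns gene_id, chrom, strand, tx_start, tx_end
#' (1-based inclusive).  With `format = "bed"` the input is 0-based
#' half-open BED (chrom, start, end, gene_id, score, strand) and is shifted
#' to 1-based inclusive at parse time.
#'
#' @param path input path.
#' @param format `"tsv"` (default, 1-based) or `"bed"` (0-based half-open).
#' @return data.frame gene_id/chrom/strand/tx_start/tx_end.
#' @export
read_gene_annotations <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ann <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
    if (!all(need %in% names(ann)))
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
    ann <- ann[, need]
  } else {
    bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("BED input needs 6 columns incl. strand")
    ann <- data.frame(gene_id = bed[[4L]], chrom = bed[[1L]],
                      strand = bed[[6L]], tx_start = bed[[2L]] + 1L,
                      tx_end = bed[[3L]], stringsAsFactors = FALSE)
  }
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(ann$tx_start > ann$tx_end)) stop("tx_start > tx_end")
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids in annotation")
  ann
}

#' Check that datasets share an identical ordered sample list
#'
#' Downstream integration requires sample columns of every input to line up
#' exactly; silent intersection is never performed.
#'
#' @param ... matrices (genes/SNPs x samples) and/or [phenotype_labels()].
#' @return invisible TRUE, or an error naming the mismatch.
#' @export
check_sample_alignment <- function(...) {
  objs <- list(...)
  ids <- lapply(objs, function(o)
    if (inherits(o, "phenotype_labels")) names(o) else colnames(o))
  ref <- ids[[1L]]
  for (i in seq_along(ids)[-1L]) {
    if (!identical(ref, ids[[i]]))
      stop("sample ids misaligned between input 1 and input ", i,
           " (reorder explicitly; inputs are never silently intersected)")
  }
  invisible(TRUE)
}
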