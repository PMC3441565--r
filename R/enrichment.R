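#' Class-conditional expression profiles
#'
#' Per-gene mean/sd (and sufficient statistics) for each phenotype class of
#' a training cohort.  Used to score the cohort itself (optionally with
#' leave-self-out estimates) or new samples against the same profiles.
#'
#' @param expr an [expression_matrix()] (genes x samples).
#' @param labels a [phenotype_labels()] aligned with `expr` columns.
#' @return list of class `"expression_profiles"`.
#' @export
expression_profiles <- function(expr, labels) {
  check_sample_alignment(expr, labels)
  x <- unclass(expr)
  out <- list(gene_ids = rownames(expr), levels = levels(labels))
  for (k in 1:2) {
    idx <- which(as.integer(labels) == k)
    xk <- x[, idx, drop = FALSE]
    n <- length(idx)
    s1 <- rowSums(xk); s2 <- rowSums(xk^2)
    mu <- s1 / n
    v <- (s2 - n * mu^2) / (n - 1)
    out[[paste0("class", k)]] <- list(n = n, sum = s1, sumsq = s2, mean = mu,
                                      sd = sqrt(pmax(v, 0)))
  }
  class(out) <- "expression_profiles"
  out
}

# GSEA-style regularization: floors the class sd so constant genes cannot
# produce infinite statistics.
.floor_sd <- function(sd, mean) pmax(sd, 0.2 * abs(mean), 1e-8)

.gauss_logdiff <- function(x, mu1, sd1, mu2, sd2) {
  sd1 <- .floor_sd(sd1, mu1); sd2 <- .floor_sd(sd2, mu2)
  log(sd2) - log(sd1) - (x - mu1)^2 / (2 * sd1^2) + (x - mu2)^2 / (2 * sd2^2)
}

#' Per-sample, per-gene correlation statistics for expression data
#'
#' For sample i and gene j the statistic is the Gaussian log-likelihood
#' ratio `log f_C1(x_ij) - log f_C2(x_ij)`, where `f_Ck` has the class-k
#' mean and standard deviation of gene j.  With `leave_self_out = TRUE`
#' (default) a cohort sample's own class parameters are estimated without
#' that sample.  Larger values mean the sample looks more like class C1.
#'
#' @param expr an [expression_matrix()] (genes x samples) to score.
#' @param labels training-cohort labels (aligned with `expr` unless
#'   `profiles` is supplied).
#' @param profiles optional [expression_profiles()] of a training cohort;
#'   when given, `expr` may hold any samples (e.g. test samples) and no
#'   leave-self-out is applied.
#' @param leave_self_out drop the scored sample from its own class profile.
#' @return numeric matrix (genes x samples) of statistics.
#' @export
expression_correlation_stats <- function(expr, labels, profiles = NULL,
                                         leave_self_out = TRUE) {
  x <- unclass(expr)
  external <- !is.null(profiles)
  if (!external) profiles <- expression_profiles(expr, labels)
  if (!identical(rownames(expr), profiles$gene_ids))
    stop("gene ids of expr and profiles differ")
  p1 <- profiles$class1; p2 <- profiles$class2
  s <- .gauss_logdiff(x, p1$mean, p1$sd, p2$mean, p2$sd)
  if (!external && leave_self_out) {
    for (k in 1:2) {
      pk <- profiles[[paste0("class", k)]]
      po <- profiles[[paste0("class", 3L - k)]]
      idx <- which(as.integer(labels) == k)
      n <- pk$n
      xk <- x[, idx, drop = FALSE]
      loo_mean <- (pk$sum - xk) / (n - 1)
      if (n > 2) {
        loo_var <- (pk$sumsq - xk^2 - (n - 1) * loo_mean^2) / (n - 2)
      } else {
        loo_var <- matrix(0, nrow(xk), ncol(xk))
      }
      loo_sd <- sqrt(pmax(loo_var, 0))
      own <- .gauss_logdiff(xk, loo_mean, loo_sd, po$mean, po$sd)
      if (k == 2L) {
        # statistic is log f1 - log f2; for class-2 samples the LOO profile
        # replaces the class-2 (own) side
        own <- .gauss_logdiff(xk, po$mean, po$sd, loo_mean, loo_sd)
      }
      s[, idx] <- own
    }
  }
  dimnames(s) <- dimnames(x)
  s
}

#' Class-conditional genotype profiles
#'
#' Counts of each dosage category (0/1/2) per gene and class.
#'
#' @param gene_geno gene-level [genotype_matrix()] (genes x samples).
#' @param labels a [phenotype_labels()] aligned with `gene_geno` columns.
#' @return list of class `"genotype_profiles"`.
#' @export
genotype_profiles <- function(gene_geno, labels) {
  check_sample_alignment(gene_geno, labels)
  g <- unclass(gene_geno)
  out <- list(gene_ids = rownames(gene_geno), levels = levels(labels))
  for (k in 1:2) {
    ind <- as.numeric(as.integer(labels) == k)
    counts <- sapply(0:2, function(d) as.vector((g == d) %*% ind))
    out[[paste0("class", k)]] <- list(n = sum(ind),
                                      counts = matrix(counts, nrow(g), 3L))
  }
  class(out) <- "genotype_profiles"
  out
}

#' Per-sample, per-gene correlation statistics for genotype data
#'
#' `s_ij = log(p1 / p2)` where `pk` is the fraction of class-k samples
#' carrying sample i's genotype at gene j.  If either class has zero
#' carriers, both counts gain a pseudo-count of 1 and both denominators
#' gain 1 before forming the ratio.  With `leave_self_out = TRUE`
#' (default) a cohort sample is excluded from its own class's counts, so
#' cohort scores are exchangeable with scores of external samples computed
#' against the same profiles; self-inclusion otherwise inflates a sample's
#' own-genotype frequency in its own class at every gene.
#'
#' @param gene_geno gene-level [genotype_matrix()] to score.
#' @param labels training-cohort labels (aligned with `gene_geno` unless
#'   `profiles` is supplied).
#' @param profiles optional [genotype_profiles()] of a training cohort;
#'   when given, `gene_geno` may hold any samples and no leave-self-out is
#'   applied.
#' @param leave_self_out drop the scored sample from its own class counts.
#' @return numeric matrix (genes x samples) of statistics.
#' @export
genotype_correlation_stats <- function(gene_geno, labels, profiles = NULL,
                                       leave_self_out = TRUE) {
  g <- unclass(gene_geno)
  external <- !is.null(profiles)
  if (!external) profiles <- genotype_profiles(gene_geno, labels)
  if (!identical(rownames(gene_geno), profiles$gene_ids))
    stop("gene ids of genotypes and profiles differ")
  idx <- cbind(rep.int(seq_len(nrow(g)), ncol(g)), as.vector(g) + 1L)
  c1 <- matrix(profiles$class1$counts[idx], nrow(g), ncol(g))
  c2 <- matrix(profiles$class2$counts[idx], nrow(g), ncol(g))
  n1 <- matrix(profiles$class1$n, nrow(g), ncol(g))
  n2 <- matrix(profiles$class2$n, nrow(g), ncol(g))
  if (!external && leave_self_out) {
    in1 <- as.integer(labels) == 1L
    c1[, in1] <- c1[, in1] - 1L
    n1[, in1] <- n1[, in1] - 1L
    c2[, !in1] <- c2[, !in1] - 1L
    n2[, !in1] <- n2[, !in1] - 1L
  }
  zero <- c1 == 0 | c2 == 0
  s <- log((c1 / n1) / (c2 / n2))
  s[zero] <- log(((c1[zero] + 1) / (n1[zero] + 1)) /
                 ((c2[zero] + 1) / (n2[zero] + 1)))
  dimnames(s) <- dimnames(g)
  s
}

#' Sample-specific gene-set enrichment score
#'
#' Weighted Kolmogorov-Smirnov statistic of one sample's correlation
#' statistics for one gene set: genes are ranked by decreasing statistic;
#' the running sum gains `|s|^p / sum_set |s|^p` at member genes and loses
#' `1/(G - m)` at non-members; the score is the signed maximal deviation
#' from zero.  If every member statistic is exactly zero the member weights
#' fall back to uniform.
#'
#' @param stats named numeric vector of one sample's statistics (all genes).
#' @param set_members character vector of member gene ids.
#' @param p weight exponent (default 1; `p = 0` recovers the unweighted KS
#'   walk).
#' @return the enrichment score in [-1, 1].
#' @export
sample_enrichment_score <- function(stats, set_members, p = 1) {
  member_idx <- which(names(stats) %in% set_members)
  G <- length(stats)
  if (length(member_idx) == 0L)
    stop("gene set has no members among the statistic genes")
  if (length(member_idx) >= G)
    stop("gene set covers all genes; the non-member step mass vanishes")
  .es_matrix_cpp(matrix(as.numeric(stats), ncol = 1L),
                 list(member_idx), p)[1L, 1L]
}

#' Enrichment-score matrix for all samples and gene sets
#'
#' @param stats statistic matrix (genes x samples) from
#'   [expression_correlation_stats()] or [genotype_correlation_stats()].
#' @param sets a [gene_set_collection()]; every set must have at least one
#'   member among the statistic genes and must not cover all of them.
#' @param p weight exponent (default 1).
#' @return numeric matrix (samples x sets) of class `"enrichment_matrix"`
#'   with attribute `normalized = FALSE`.
#' @export
enrichment_matrix <- function(stats, sets, p = 1) {
  G <- nrow(stats)
  gene_ids <- rownames(stats)
  member_idx <- lapply(sets, function(g) which(gene_ids %in% g))
  bad <- lengths(member_idx) == 0L
  if (any(bad))
    stop("gene set(s) with no members among the statistic genes: ",
         paste(names(sets)[bad], collapse = ", "))
  full <- lengths(member_idx) >= G
  if (any(full))
    stop("gene set(s) covering all genes: ",
         paste(names(sets)[full], collapse = ", "))
  es <- .es_matrix_cpp(unclass(stats), member_idx, p)
  dimnames(es) <- list(colnames(stats), names(sets))
  attr(es, "normalized") <- FALSE
  class(es) <- c("enrichment_matrix", class(es))
  es
}

#' Normalize enrichment scores by label permutation
#'
#' Class labels are permuted `n_perm` times (preserving class sizes), the
#' statistics and enrichment scores are recomputed, and each original score
#' is divided by the mean of the same-sign background scores for that
#' (sample, set) cell: positive scores by the mean positive background,
#' negative scores by the absolute mean negative background.  Cells with no
#' same-sign background are left unchanged and counted in the
#' `n_unnormalized` attribute.
#'
#' @param scores an [enrichment_matrix()] (samples x sets).
#' @param stats_builder function(labels) returning a statistic matrix
#'   (genes x samples) for the permuted labels.
#' @param sets the [gene_set_collection()] used for `scores`.
#' @param labels the original [phenotype_labels()].
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @param p weight exponent passed to [enrichment_matrix()].
#' @return normalized enrichment matrix (`normalized = TRUE`).
#' @export
normalize_enrichment <- function(scores, stats_builder, sets, labels,
                                 n_perm = 1000L, seed = NULL, p = 1) {
  stopifnot(n_perm >= 1L)
  if (!is.null(seed)) set.seed(seed)
  pos_sum <- neg_sum <- matrix(0, nrow(scores), ncol(scores))
  pos_n <- neg_n <- matrix(0L, nrow(scores), ncol(scores))
  for (b in seq_len(n_perm)) {
    perm <- labels
    perm[] <- labels[sample.int(length(labels))]
    bg <- enrichment_matrix(stats_builder(perm), sets, p = p)
    up <- bg > 0; dn <- bg < 0
    pos_sum[up] <- pos_sum[up] + bg[up]
    neg_sum[dn] <- neg_sum[dn] + bg[dn]
    pos_n <- pos_n + up
    neg_n <- neg_n + dn
  }
  out <- unclass(scores)
  norm_pos <- out > 0 & pos_n > 0
  norm_neg <- out < 0 & neg_n > 0
  out[norm_pos] <- out[norm_pos] / (pos_sum[norm_pos] / pos_n[norm_pos])
  out[norm_neg] <- out[norm_neg] / abs(neg_sum[norm_neg] / neg_n[norm_neg])
  skipped <- sum((unclass(scores) > 0 & pos_n == 0) |
                 (unclass(scores) < 0 & neg_n == 0))
  if (skipped > 0)
    warning(skipped, " cell(s) had no same-sign background and were left ",
            "unnormalized")
  attr(out, "normalized") <- TRUE
  attr(out, "n_unnormalized") <- skipped
  class(out) <- c("enrichment_matrix", class(out))
  out
}
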