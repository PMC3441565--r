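#' Simulation parameters for matched genotype-expression data
#'
#' Defaults encode the generative model of the simulation studies: causal
#' SNPs in Hardy-Weinberg equilibrium with heterozygote odds ratios drawn
#' from U[1.1, 1.3] under an additive liability disease model (nominal
#' prevalence 0.02), multivariate-normal baseline expression per gene set
#' with an additive genotype effect of size U[1.0, 1.5], and random
#' background genes/SNPs (allele frequencies Beta(0.1, 0.1)).  Causal-SNP
#' allele frequencies and the baseline expression moments are configurable
#' substitutes for cohort-estimated values: frequencies U[0.05, 0.5],
#' mean-0/unit-variance baseline with exchangeable correlation 0.2, and
#' N(0, 1) background expression.
#'
#' @param n_per_class samples per phenotype class (used by callers that do
#'   not override it).
#' @param genes_per_set genes per simulated set (default 10).
#' @param or_range range of the heterozygote odds ratio (default c(1.1, 1.3)).
#' @param prevalence nominal disease prevalence of the additive model
#'   (default 0.02; recorded, the class-assignment intercept is calibrated
#'   for balanced case-control sampling).
#' @param causal_maf_sampler function(n) drawing causal/linked SNP minor
#'   allele frequencies (default U[0.05, 0.5]).
#' @param background_maf_sampler function(n) drawing background allele
#'   frequencies (default Beta(0.1, 0.1)).
#' @param effect_range range of the genotype-on-expression effect size
#'   (default c(1.0, 1.5)).
#' @param baseline_mean,baseline_var,baseline_cor moments of the per-set
#'   multivariate-normal expression baseline (exchangeable correlation).
#' @param background_mean,background_sd moments of background expression.
#' @param link liability link, `"logistic"` (default) or `"probit"`.
#' @param pool_factor oversampling factor of the rejection-sampling pool.
#' @param max_pool_factor budget cap before balancing fails with an error.
#' @return list of class `"sim_params"`.
#' @export
sim_params <- function(n_per_class = 25L, genes_per_set = 10L,
                       or_range = c(1.1, 1.3), prevalence = 0.02,
                       causal_maf_sampler = function(n) stats::runif(n, 0.05, 0.5),
                       background_maf_sampler = function(n) stats::rbeta(n, 0.1, 0.1),
                       effect_range = c(1.0, 1.5),
                       baseline_mean = 0, baseline_var = 1, baseline_cor = 0.2,
                       background_mean = 0, background_sd = 1,
                       link = c("logistic", "probit"),
                       pool_factor = 3, max_pool_factor = 48) {
  stopifnot(all(or_range > 1), prevalence > 0, prevalence < 1,
            baseline_var > 0, baseline_cor >= 0, baseline_cor < 1,
            genes_per_set >= 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 genes_per_set = as.integer(genes_per_set),
                 or_range = or_range, prevalence = prevalence,
                 causal_maf_sampler = causal_maf_sampler,
                 background_maf_sampler = background_maf_sampler,
                 effect_range = effect_range,
                 baseline_mean = baseline_mean, baseline_var = baseline_var,
                 baseline_cor = baseline_cor,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 link = match.arg(link),
                 pool_factor = pool_factor,
                 max_pool_factor = max_pool_factor),
            class = "sim_params")
}

#' Gene-set composition of a simulation scenario
#'
#' Four gene-set types: type 1 = differentially expressed and genetically
#' associated; type 2 = differentially expressed only; type 3 = genetically
#' associated only; type 4 = neither.
#'
#' @param n_type1,n_type2,n_type3,n_type4 non-negative set counts.
#' @return list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(n_type1, n_type2, n_type3, n_type4) {
  counts <- c(type1 = as.integer(n_type1), type2 = as.integer(n_type2),
              type3 = as.integer(n_type3), type4 = as.integer(n_type4))
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  structure(list(counts = counts), class = "scenario_spec")
}

#' The five task-similarity scenarios
#'
#' Scenario 1 has the most dissimilar enrichment between data types
#' (no shared type-1 sets), scenario 5 the most similar; each row has 100
#' sets in total.
#'
#' @param i scenario number 1..5.
#' @return a [scenario_spec()].
#' @export
similarity_scenario <- function(i) {
  stopifnot(i %in% 1:5)
  tab <- list(c(0L, 20L, 20L, 60L), c(5L, 15L, 15L, 65L),
              c(10L, 10L, 10L, 70L), c(15L, 5L, 5L, 75L),
              c(20L, 0L, 0L, 80L))
  do.call(scenario_spec, as.list(tab[[i]]))
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Per SNP with allele frequency f, dosages are Binomial(2, f), i.e.
#' genotype probabilities ((1-f)^2, 2f(1-f), f^2), independently per
#' sample.
#'
#' @param mafs allele frequencies, one per SNP.
#' @param n_samples number of samples.
#' @param snp_ids,sample_ids optional identifiers.
#' @return a [genotype_matrix()] (SNPs x samples).
#' @export
simulate_genotypes_hwe <- function(mafs, n_samples, snp_ids = NULL,
                                   sample_ids = NULL) {
  stopifnot(all(mafs >= 0), all(mafs <= 1), n_samples >= 1)
  S <- length(mafs)
  calls <- matrix(stats::rbinom(S * n_samples, 2L, rep(mafs, n_samples)),
                  nrow = S, ncol = n_samples)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%04d", seq_len(S))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(n_samples))
  genotype_matrix(calls, snp_ids, sample_ids)
}

#' Assign phenotype classes from an additive genetic liability
#'
#' Liability `eta_i = eta0 + sum_j beta_j g_ij + e_i` with standard-normal
#' error; `P(C1) = plogis(eta_i)` (or `pnorm` under the probit link).  The
#' intercept `eta0` is calibrated so the mean class-1 probability over the
#' supplied samples is 0.5, supporting balanced case-control sampling;
#' classes are then drawn Bernoulli.
#'
#' @param causal_dosages dosage matrix (causal SNPs x samples); may have
#'   zero rows (pure-noise labels).
#' @param betas log heterozygote odds ratio per causal SNP.
#' @param link `"logistic"` (default) or `"probit"`.
#' @return a [phenotype_labels()] factor with levels C1/C2 and attributes
#'   `eta0` and `prob`.
#' @export
assign_classes <- function(causal_dosages, betas, link = "logistic") {
  g <- unclass(causal_dosages)
  stopifnot(nrow(g) == length(betas))
  n <- ncol(g)
  lin <- if (nrow(g) > 0) drop(crossprod(g, betas)) else numeric(n)
  e <- stats::rnorm(n)
  cdf <- if (link == "probit") stats::pnorm else stats::plogis
  target <- function(eta0) mean(cdf(eta0 + lin + e)) - 0.5
  eta0 <- stats::uniroot(target, lower = -50 - max(abs(lin)),
                         upper = 50 + max(abs(lin)), tol = 1e-10)$root
  prob <- cdf(eta0 + lin + e)
  cls <- ifelse(stats::runif(n) < prob, "C1", "C2")
  # degenerate draws (all one class) are possible for tiny n; the factor
  # constructor enforces >= 2 per class where it matters
  f <- factor(cls, levels = c("C1", "C2"))
  names(f) <- colnames(g)
  if (is.null(names(f))) names(f) <- sprintf("s%04d", seq_len(n))
  attr(f, "eta0") <- eta0
  attr(f, "prob") <- prob
  class(f) <- c("phenotype_labels", "factor")
  f
}

# Cholesky factor of the exchangeable-correlation baseline covariance,
# var * ((1 - rho) I + rho J), for a block of m genes.
.baseline_chol <- function(m, var, rho) {
  sigma <- var * ((1 - rho) * diag(m) + rho * matrix(1, m, m))
  chol(sigma)
}

#' Simulate expression levels with additive genotype effects
#'
#' Genes of associated sets get a multivariate-normal baseline per set
#' (exchangeable correlation) plus `gamma_j * g_ij` for their linked SNP
#' dosage; background genes are i.i.d. normal.
#'
#' @param gene_info data.frame with columns gene_id, set_name, kind
#'   (`"linked"` = MVN baseline + genotype effect, `"mvn"` = MVN baseline
#'   only, `"background"`), gamma (effect size, 0 allowed) and snp_id (NA
#'   for background genes).
#' @param dosages dosage matrix (SNPs x samples) supplying the linked SNPs.
#' @param params a [sim_params()].
#' @param sample_ids sample identifiers (default from `dosages`).
#' @return an [expression_matrix()] (genes x samples).
#' @export
simulate_expression <- function(gene_info, dosages, params = sim_params(),
                                sample_ids = colnames(dosages)) {
  n <- length(sample_ids)
  G <- nrow(gene_info)
  x <- matrix(0, G, n)
  chol_cache <- list()
  for (sn in unique(gene_info$set_name)) {
    idx <- which(gene_info$set_name == sn)
    kind <- gene_info$kind[idx]
    if (all(kind == "background")) {
      x[idx, ] <- stats::rnorm(length(idx) * n, params$background_mean,
                               params$background_sd)
      next
    }
    m <- length(idx)
    key <- as.character(m)
    if (is.null(chol_cache[[key]]))
      chol_cache[[key]] <- .baseline_chol(m, params$baseline_var,
                                          params$baseline_cor)
    z <- matrix(stats::rnorm(m * n), m, n)
    x0 <- params$baseline_mean + crossprod(chol_cache[[key]], z)
    linked <- kind == "linked"
    if (any(linked)) {
      g <- unclass(dosages)[gene_info$snp_id[idx[linked]], , drop = FALSE]
      x0[linked, ] <- x0[linked, , drop = FALSE] +
        gene_info$gamma[idx[linked]] * g
    }
    x[idx, ] <- x0
  }
  expression_matrix(x, gene_info$gene_id, sample_ids)
}

# Lay out genes, sets and SNPs for a scenario: one SNP per gene, 10 genes
# per set.  Types 1-3 draw linked-SNP frequencies from the causal sampler;
# type-4 SNPs use the background Beta frequencies.  Liability SNPs are
# those of type-1 and type-3 genes.
.scenario_layout <- function(spec, params) {
  counts <- spec$counts
  n_sets <- sum(counts)
  gps <- params$genes_per_set
  set_type <- rep(names(counts), counts)
  set_name <- sprintf("set%03d", seq_len(n_sets))
  gene_id <- sprintf("g%04d", seq_len(n_sets * gps))
  snp_id <- sprintf("snp%04d", seq_len(n_sets * gps))
  gene_set <- rep(set_name, each = gps)
  gene_type <- rep(set_type, each = gps)
  kind <- c(type1 = "linked", type2 = "linked", type3 = "mvn",
            type4 = "background")[gene_type]
  gamma <- numeric(length(gene_id))
  de <- gene_type %in% c("type1", "type2")
  gamma[de] <- stats::runif(sum(de), params$effect_range[1L],
                            params$effect_range[2L])
  maf <- numeric(length(snp_id))
  causal_like <- gene_type %in% c("type1", "type2", "type3")
  maf[causal_like] <- params$causal_maf_sampler(sum(causal_like))
  maf[!causal_like] <- params$background_maf_sampler(sum(!causal_like))
  in_liability <- gene_type %in% c("type1", "type3")
  beta <- numeric(length(snp_id))
  beta[in_liability] <- log(stats::runif(sum(in_liability),
                                         params$or_range[1L],
                                         params$or_range[2L]))
  gene_info <- data.frame(gene_id = gene_id, set_name = gene_set,
                          set_type = gene_type, kind = kind, gamma = gamma,
                          snp_id = snp_id, maf = maf, beta = beta,
                          in_liability = in_liability,
                          stringsAsFactors = FALSE)
  sets <- gene_set_collection(split(gene_id, factor(gene_set,
                                                    levels = set_name)))
  attr(sets, "set_type") <- stats::setNames(set_type, set_name)
  list(gene_info = gene_info, sets = sets)
}

# Draw balanced samples: generate genotype pools and liability labels
# until each class reaches its quota, then keep the first `quota` samples
# of each class in draw order.
.balanced_draw <- function(gene_info, params, quota) {
  n_snp <- nrow(gene_info)
  causal <- which(gene_info$in_liability)
  pool <- ceiling(params$pool_factor * 2 * quota)
  budget <- ceiling(params$max_pool_factor * 2 * quota)
  repeat {
    geno <- simulate_genotypes_hwe(gene_info$maf, pool,
                                   snp_ids = gene_info$snp_id)
    labels <- assign_classes(unclass(geno)[causal, , drop = FALSE],
                             gene_info$beta[causal], link = params$link)
    names(labels) <- colnames(geno)
    if (sum(labels == "C1") >= quota && sum(labels == "C2") >= quota) {
      keep <- c(which(labels == "C1")[seq_len(quota)],
                which(labels == "C2")[seq_len(quota)])
      keep <- sort(keep)
      lab <- phenotype_labels(as.character(labels)[keep],
                              names(labels)[keep],
                              class_levels = c("C1", "C2"))
      return(list(genotypes = genotype_matrix(
                    unclass(geno)[, keep, drop = FALSE],
                    gene_info$snp_id, colnames(geno)[keep]),
                  labels = lab))
    }
    pool <- pool * 2
    if (pool > budget)
      stop("class quota unreachable within the sampling budget (", budget,
           " draws); check the liability calibration")
  }
}

#' Simulate a matched expression + genotype scenario
#'
#' Generates matched training and test cohorts under a scenario's gene-set
#' composition: type-1 genes are differentially expressed through SNPs
#' that also enter the liability model; type-2 genes are expressed through
#' private SNPs absent from the liability (their genotype rows are noise
#' with respect to phenotype); type-3 genes carry liability SNPs with no
#' expression effect; type-4 genes and SNPs are background.  Both cohorts
#' are balanced between the classes, and the identical dosage matrix feeds
#' the expression effects and the gene-level genotype task.
#'
#' @param spec a [scenario_spec()] (or integer 1..5 for the similarity
#'   scenarios).
#' @param params a [sim_params()].
#' @param n_train,n_test cohort sizes (evenly split into the 2 classes;
#'   `n_test = 0` skips the test cohort).
#' @param seed optional integer seed.
#' @return list of class `"matched_scenario"` with `train`/`test` (each
#'   `expression`, `genotype` at the gene level, `labels`), `sets`,
#'   `gene_info` and `target_sets` (names of type-1 sets).
#' @export
build_scenario <- function(spec, params = sim_params(), n_train = 50L,
                           n_test = 50L, seed = NULL) {
  if (is.numeric(spec) && length(spec) == 1L) spec <- similarity_scenario(spec)
  stopifnot(inherits(spec, "scenario_spec"),
            n_train %% 2L == 0L, n_test %% 2L == 0L)
  if (!is.null(seed)) set.seed(seed)
  layout <- .scenario_layout(spec, params)
  gi <- layout$gene_info
  quota <- (n_train + n_test) %/% 2L
  draw <- .balanced_draw(gi, params, quota)
  # split each class: first n_train/2 -> train, rest -> test
  split_idx <- function(lab) {
    tr <- c(which(lab == "C1")[seq_len(n_train %/% 2L)],
            which(lab == "C2")[seq_len(n_train %/% 2L)])
    sort(tr)
  }
  tr_idx <- split_idx(draw$labels)
  te_idx <- setdiff(seq_along(draw$labels), tr_idx)
  make_part <- function(idx) {
    if (length(idx) == 0L) return(NULL)
    g <- unclass(draw$genotypes)[, idx, drop = FALSE]
    ids <- colnames(draw$genotypes)[idx]
    geno <- genotype_matrix(g, gi$snp_id, ids)
    expr <- simulate_expression(gi, geno, params, sample_ids = ids)
    gene_geno <- genotype_matrix(g, gi$gene_id, ids)
    lab <- phenotype_labels(as.character(draw$labels)[idx], ids,
                            class_levels = c("C1", "C2"))
    list(expression = expr, genotype = gene_geno, labels = lab)
  }
  structure(list(train = make_part(tr_idx), test = make_part(te_idx),
                 sets = layout$sets, gene_info = gi,
                 target_sets = names(attr(layout$sets, "set_type"))[
                   attr(layout$sets, "set_type") == "type1"]),
            class = "matched_scenario")
}

#' Simulate a collection of related single-data-type tasks
#'
#' Each task has 100 gene sets of 10 genes: sets 1-30 are phenotype
#' associated and 31-50 background in every task; of sets 51-100 a
#' per-task random 30 are associated and 20 background.  The first 50 sets
#' therefore carry enrichment shared by all tasks and the last 50 sets
#' enrichment unique to each task.  For expression tasks, associated genes
#' are differentially expressed through liability SNPs; for genotype
#' tasks, associated genes carry liability SNPs directly.
#'
#' @param n_tasks number of tasks.
#' @param params a [sim_params()].
#' @param type `"expression"` or `"genotype"` data emitted per task.
#' @param n_train,n_test balanced cohort sizes per task (defaults 20/20).
#' @param n_sets,n_shared_assoc,n_shared_bg set layout (defaults 100/30/20).
#' @param seed optional integer seed.
#' @return list of tasks, each with `train`/`test` (`data`, `labels`) and
#'   `sets`; attribute `"associated"` marks each task's associated sets.
#' @export
build_task_collection <- function(n_tasks, params = sim_params(),
                                  type = c("expression", "genotype"),
                                  n_train = 20L, n_test = 20L,
                                  n_sets = 100L, n_shared_assoc = 30L,
                                  n_shared_bg = 20L, seed = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  n_rest <- n_sets - n_shared_assoc - n_shared_bg
  n_rest_assoc <- round(n_rest * n_shared_assoc /
                          (n_shared_assoc + n_shared_bg))
  lapply(seq_len(n_tasks), function(t) {
    assoc <- c(seq_len(n_shared_assoc),
               (n_shared_assoc + n_shared_bg) +
                 sort(sample.int(n_rest, n_rest_assoc)))
    is_assoc <- seq_len(n_sets) %in% assoc
    counts <- c(sum(is_assoc), 0L, 0L, sum(!is_assoc))
    spec <- if (type == "expression")
      scenario_spec(counts[1L], 0L, 0L, counts[4L])
    else scenario_spec(0L, 0L, counts[1L], counts[4L])
    # reorder set types to the required positions: .scenario_layout puts
    # associated sets first, so permute set labels afterwards
    layout <- .scenario_layout(spec, params)
    gi <- layout$gene_info
    # map: first counts[1] sets -> associated positions, rest -> background
    new_idx <- integer(n_sets)
    new_idx[which(is_assoc)] <- seq_len(counts[1L])
    new_idx[which(!is_assoc)] <- counts[1L] + seq_len(counts[4L])
    gps <- params$genes_per_set
    perm <- unlist(lapply(new_idx, function(k) (k - 1L) * gps + seq_len(gps)))
    gi <- gi[perm, , drop = FALSE]
    gi$set_name <- rep(sprintf("set%03d", seq_len(n_sets)),
                       each = params$genes_per_set)
    gi$gene_id <- sprintf("g%04d", seq_len(nrow(gi)))
    gi$snp_id <- sprintf("snp%04d", seq_len(nrow(gi)))
    sets <- gene_set_collection(split(gi$gene_id,
                                      factor(gi$set_name,
                                             levels = unique(gi$set_name))))
    quota <- (n_train + n_test) %/% 2L
    draw <- .balanced_draw(gi, params, quota)
    tr <- c(which(draw$labels == "C1")[seq_len(n_train %/% 2L)],
            which(draw$labels == "C2")[seq_len(n_train %/% 2L)])
    tr <- sort(tr)
    te <- setdiff(seq_along(draw$labels), tr)
    part <- function(idx) {
      ids <- colnames(draw$genotypes)[idx]
      lab <- phenotype_labels(as.character(draw$labels)[idx], ids,
                              class_levels = c("C1", "C2"))
      dat <- if (type == "expression") {
        simulate_expression(gi, genotype_matrix(
          unclass(draw$genotypes)[, idx, drop = FALSE], gi$snp_id, ids),
          params, sample_ids = ids)
      } else {
        genotype_matrix(unclass(draw$genotypes)[, idx, drop = FALSE],
                        gi$gene_id, ids)
      }
      list(data = dat, labels = lab)
    }
    structure(list(task_id = paste0("task", t), type = type,
                   train = part(tr), test = part(te), sets = sets),
              associated = sprintf("set%03d", which(is_assoc)))
  })
}
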