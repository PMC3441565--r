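#' Enrichment features for a matched scenario
#'
#' Computes correlation statistics and enrichment scores for the training
#' cohort (leave-self-out within the cohort) and, when present, for the
#' test cohort scored against the training class profiles (test labels
#' never touch the statistics).
#'
#' @param sc a `"matched_scenario"` from [build_scenario()].
#' @param p KS weight exponent.
#' @return list with `train` (named list of [task_dataset()]s for
#'   expression and genotype) and `test` (per-type enrichment matrices plus
#'   labels), or `test = NULL`.
#' @export
scenario_enrichment <- function(sc, p = 1) {
  tr <- sc$train
  expr_prof <- expression_profiles(tr$expression, tr$labels)
  geno_prof <- genotype_profiles(tr$genotype, tr$labels)
  es_tr_e <- enrichment_matrix(
    expression_correlation_stats(tr$expression, tr$labels), sc$sets, p)
  es_tr_g <- enrichment_matrix(
    genotype_correlation_stats(tr$genotype, tr$labels), sc$sets, p)
  train <- list(
    expression = task_dataset(es_tr_e, tr$labels, "expression"),
    genotype = task_dataset(es_tr_g, tr$labels, "genotype"))
  test <- NULL
  if (!is.null(sc$test)) {
    te <- sc$test
    es_te_e <- enrichment_matrix(
      expression_correlation_stats(te$expression, tr$labels,
                                   profiles = expr_prof), sc$sets, p)
    es_te_g <- enrichment_matrix(
      genotype_correlation_stats(te$genotype, tr$labels,
                                 profiles = geno_prof), sc$sets, p)
    test <- list(expression = es_te_e, genotype = es_te_g,
                 labels = te$labels)
  }
  list(train = train, test = test)
}

# accuracy of predicted vs true labels
.acc <- function(pred, truth) mean(as.character(pred) == as.character(truth))

#' Fit all six models on one matched scenario and score the test cohort
#'
#' @param sc a `"matched_scenario"` with a test cohort.
#' @param C,mu,p model and enrichment parameters.
#' @return named numeric vector of test accuracies: per data type for the
#'   single-task, multi-task and concatenated models, per matched sample
#'   for summed-prediction, summed-ES and merged.
#' @export
evaluate_scenario_models <- function(sc, C = 1, mu = 1, p = 1) {
  feats <- scenario_enrichment(sc, p)
  tr <- feats$train; te <- feats$test
  truth <- te$labels
  single_e <- fit_single_task(tr$expression, C)
  single_g <- fit_single_task(tr$genotype, C)
  multi <- fit_multitask(unname(tr), C, mu)
  conc <- fit_concatenated(unname(tr), C)
  sum_pred <- fit_summed_prediction(unname(tr), C)
  sum_es <- fit_summed_es(unname(tr), C)
  merged <- fit_merged(unname(tr), C)
  c(expression.single = .acc(predict(single_e, te$expression), truth),
    expression.multitask = .acc(predict(multi, te$expression,
                                        task = "expression"), truth),
    expression.concatenated = .acc(predict(conc, te$expression), truth),
    genotype.single = .acc(predict(single_g, te$genotype), truth),
    genotype.multitask = .acc(predict(multi, te$genotype,
                                      task = "genotype"), truth),
    genotype.concatenated = .acc(predict(conc, te$genotype), truth),
    matched.summed_prediction = .acc(
      predict(sum_pred, list(te$expression, te$genotype)), truth),
    matched.summed_es = .acc(
      predict(sum_es, list(te$expression, te$genotype)), truth),
    matched.merged = .acc(predict(merged, list(te$expression, te$genotype)),
                          truth))
}

.aggregate_reps <- function(mat, experiment, condition) {
  # mat: reps x metrics; standard error over replicate-level means
  data.frame(experiment = experiment, condition = condition,
             metric = colnames(mat),
             mean = colMeans(mat),
             se = apply(mat, 2L, stats::sd) / sqrt(nrow(mat)),
             reps = nrow(mat), row.names = NULL,
             stringsAsFactors = FALSE)
}

.as_experiment_result <- function(df) {
  class(df) <- c("experiment_result", "data.frame")
  df
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment results (", x$experiment[1L], "): mean +/- se over ",
      x$reps[1L], " replicates\n", sep = "")
  df <- data.frame(condition = x$condition, metric = x$metric,
                   value = sprintf("%.4f +/- %.4f", x$mean, x$se))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Task-similarity accuracy experiment
#'
#' For each scenario, repeatedly simulates matched train/test cohorts,
#' fits the six models and records test accuracy; accuracies are averaged
#' over replicates with their standard error.
#'
#' @param params a [sim_params()].
#' @param scenarios scenario numbers (default 1:5).
#' @param n_train,n_test cohort sizes (defaults 50/50).
#' @param reps replicates per scenario (default 50).
#' @param C,mu,p model and enrichment parameters.
#' @param seed optional integer seed.
#' @return an `"experiment_result"` data.frame.
#' @export
run_similarity_experiment <- function(params = sim_params(),
                                      scenarios = 1:5, n_train = 50L,
                                      n_test = 50L, reps = 50L, C = 1,
                                      mu = 1, p = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(scenarios, function(s) {
    mat <- t(vapply(seq_len(reps), function(r)
      evaluate_scenario_models(build_scenario(s, params, n_train, n_test),
                               C, mu, p),
      numeric(9L)))
    .aggregate_reps(mat, "similarity", paste0("scenario", s))
  })
  .as_experiment_result(do.call(rbind, out))
}

#' Sample-size accuracy experiment
#'
#' Scenario-3 composition with the training (and test) cohort size varied.
#'
#' @param params a [sim_params()].
#' @param scenario scenario number (default 3).
#' @param sizes training cohort sizes (default c(10, 20, 50, 100, 200)).
#' @param reps replicates per size.
#' @param C,mu,p model and enrichment parameters.
#' @param seed optional integer seed.
#' @return an `"experiment_result"` data.frame.
#' @export
run_sample_size_experiment <- function(params = sim_params(), scenario = 3L,
                                       sizes = c(10L, 20L, 50L, 100L, 200L),
                                       reps = 50L, C = 1, mu = 1, p = 1,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(sizes, function(n) {
    mat <- t(vapply(seq_len(reps), function(r)
      evaluate_scenario_models(build_scenario(scenario, params, n, n),
                               C, mu, p),
      numeric(9L)))
    .aggregate_reps(mat, "sample_size", paste0("n", n))
  })
  .as_experiment_result(do.call(rbind, out))
}

# enrichment features for one single-data-type task of a collection
.collection_task_features <- function(task, p = 1) {
  tr <- task$train; te <- task$test
  if (task$type == "expression") {
    prof <- expression_profiles(tr$data, tr$labels)
    st_tr <- expression_correlation_stats(tr$data, tr$labels)
    st_te <- expression_correlation_stats(te$data, tr$labels,
                                          profiles = prof)
  } else {
    prof <- genotype_profiles(tr$data, tr$labels)
    st_tr <- genotype_correlation_stats(tr$data, tr$labels)
    st_te <- genotype_correlation_stats(te$data, tr$labels, profiles = prof)
  }
  list(train = task_dataset(enrichment_matrix(st_tr, task$sets, p),
                            tr$labels, task$task_id),
       test_es = enrichment_matrix(st_te, task$sets, p),
       test_labels = te$labels)
}

#' Task-count experiment for the multi-task model
#'
#' For each number of tasks T, simulates a collection of related tasks,
#' fits one multi-task model over all T tasks and a single-task model per
#' task, and records test accuracy pooled over every task's test samples.
#'
#' @param params a [sim_params()].
#' @param T_values numbers of tasks (default c(1, 2, 5, 10, 20, 50, 100)).
#' @param type `"expression"` or `"genotype"` tasks.
#' @param reps replicates per T.
#' @param C,mu,p model and enrichment parameters.
#' @param seed optional integer seed.
#' @return an `"experiment_result"` with metrics `multitask` and `single`.
#' @export
run_task_count_experiment <- function(params = sim_params(),
                                      T_values = c(1L, 2L, 5L, 10L, 20L,
                                                   50L, 100L),
                                      type = "expression", reps = 10L,
                                      C = 1, mu = 1, p = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(T_values, function(Tn) {
    mat <- t(vapply(seq_len(reps), function(r) {
      coll <- build_task_collection(Tn, params, type = type)
      feats <- lapply(coll, .collection_task_features, p = p)
      multi <- fit_multitask(lapply(feats, `[[`, "train"), C, mu)
      acc_m <- acc_s <- matrix(NA_real_, 2L, length(feats))
      for (i in seq_along(feats)) {
        f <- feats[[i]]
        acc_m[1L, i] <- .acc(predict(multi, f$test_es,
                                     task = f$train$task_id),
                             f$test_labels)
        acc_m[2L, i] <- length(f$test_labels)
        single <- fit_single_task(f$train, C)
        acc_s[1L, i] <- .acc(predict(single, f$test_es), f$test_labels)
        acc_s[2L, i] <- length(f$test_labels)
      }
      c(multitask = sum(acc_m[1L, ] * acc_m[2L, ]) / sum(acc_m[2L, ]),
        single = sum(acc_s[1L, ] * acc_s[2L, ]) / sum(acc_s[2L, ]))
    }, numeric(2L)))
    .aggregate_reps(mat, "task_count", paste0("T", Tn))
  })
  .as_experiment_result(do.call(rbind, out))
}

#' Target-set rank-recovery experiment
#'
#' Simulates matched data with a single target gene set that is both
#' differentially expressed and genetically associated (composition
#' 1/5/5/89), fits all models, and records the rank of the target set
#' under each weight type: expression and genotype single-task weights,
#' their sum, the multi-task common weight, the concatenated weight, the
#' summed-enrichment-score weight and the merged block-summed weight.
#'
#' @param params a [sim_params()].
#' @param spec target scenario composition (default
#'   `scenario_spec(1, 5, 5, 89)`).
#' @param n cohort size (default 400, evenly split).
#' @param reps replicates (default 100).
#' @param C,mu,p model and enrichment parameters.
#' @param seed optional integer seed.
#' @return an `"experiment_result"` with the mean rank (and se) of the
#'   target set per weight type.
#' @export
run_rank_experiment <- function(params = sim_params(),
                                spec = scenario_spec(1L, 5L, 5L, 89L),
                                n = 400L, reps = 100L, C = 1, mu = 1,
                                p = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one_rep <- function(r) {
    sc <- build_scenario(spec, params, n_train = n, n_test = 0L)
    target <- sc$target_sets[1L]
    feats <- scenario_enrichment(sc, p)
    tr <- feats$train
    w_e <- coef(fit_single_task(tr$expression, C))
    w_g <- coef(fit_single_task(tr$genotype, C))
    w0 <- coef(fit_multitask(unname(tr), C, mu))
    w_c <- coef(fit_concatenated(unname(tr), C))
    w_s <- coef(fit_summed_es(unname(tr), C))
    w_m <- coef(fit_merged(unname(tr), C))
    rk <- function(w) {
      r <- rank_gene_sets(w)
      r$rank[match(target, r$set_name)]
    }
    c(expression_single = rk(w_e), genotype_single = rk(w_g),
      single_summed = rk(w_e + w_g), multitask_common = rk(w0),
      concatenated = rk(w_c), summed_es = rk(w_s), merged_summed = rk(w_m))
  }
  mat <- t(vapply(seq_len(reps), one_rep, numeric(7L)))
  .as_experiment_result(.aggregate_reps(mat, "rank_recovery",
                                        paste0("n", n)))
}

#' Tabulate experiment results
#'
#' Combines one or more `"experiment_result"` objects into a single table
#' and optionally writes it as TSV.
#'
#' @param ... `"experiment_result"` objects (or a single list of them).
#' @param path optional output TSV path.
#' @return the combined `"experiment_result"` data.frame (invisibly when
#'   `path` is given).
#' @export
summarize_experiments <- function(..., path = NULL) {
  args <- list(...)
  if (length(args) == 1L && !inherits(args[[1L]], "data.frame"))
    args <- args[[1L]]
  out <- .as_experiment_result(do.call(rbind, lapply(args, as.data.frame)))
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
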