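#' Bundle enrichment features and labels as one learning task
#'
#' @param es enrichment matrix (samples x gene sets) for one data type.
#' @param labels a [phenotype_labels()] for the same samples (matched by
#'   sample id, same order).
#' @param task_id identifier for the task (e.g. `"expression"`).
#' @return list of class `"task_dataset"` with features, labels and the
#'   +1/-1 encoding (class C1, the first level, is +1).
#' @export
task_dataset <- function(es, labels, task_id) {
  es <- as.matrix(unclass(es))
  if (!identical(rownames(es), names(labels)))
    stop("task '", task_id, "': feature rows and labels are misaligned")
  structure(list(task_id = as.character(task_id), features = es,
                 labels = labels,
                 y = ifelse(as.integer(labels) == 1L, 1, -1)),
            class = "task_dataset")
}

#' Linear kernel (Gram) matrix
#' @param X feature matrix (samples x features).
#' @return symmetric PSD matrix of inner products.
#' @export
linear_gram <- function(X) {
  if (!all(is.finite(X))) stop("non-finite features")
  G <- tcrossprod(X)
  (G + t(G)) / 2
}

#' Multi-task coupling kernel matrix
#'
#' `K[s, t] = (1/mu + [task_s == task_t]) * <x_s, x_t>`: a shared linear
#' part scaled by `1/mu` plus a within-task linear part.  Small `mu` ties
#' the tasks together; as `mu` grows the kernel approaches the
#' block-diagonal single-task Gram.
#'
#' @param X stacked feature matrix (samples x features) over all tasks.
#' @param task_of task id per row of `X`.
#' @param mu positive coupling parameter.
#' @return symmetric PSD matrix.
#' @export
multitask_gram <- function(X, task_of, mu) {
  if (mu <= 0) stop("mu must be positive")
  stopifnot(length(task_of) == nrow(X))
  G <- linear_gram(X)
  same <- outer(task_of, task_of, "==")
  (1 / mu + same) * G
}

#' Solve the soft-margin SVM dual for a precomputed kernel
#'
#' Sequential minimal optimization with maximal-violating-pair selection;
#' deterministic given inputs.  The decision function is
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b`.
#'
#' @param gram kernel matrix (symmetrized defensively).
#' @param y labels in \{+1, -1\}.
#' @param C box constraint (> 0).
#' @param tol KKT stopping tolerance (default 1e-6).
#' @param max_iter iteration cap.
#' @return list with `alphas`, `bias`, `iterations` and the achieved KKT
#'   `violation`.
#' @details The solver targets `tol`; on ill-conditioned Gram matrices SMO
#'   can cycle in double precision slightly above a very tight target, in
#'   which case it stops at the best achievable KKT gap.  A fit whose gap
#'   is not small relative to the kernel scale is an error.
#' @export
train_svm <- function(gram, y, C = 1, tol = 1e-6, max_iter = 10000000L) {
  stopifnot(C > 0, all(y %in% c(-1, 1)))
  gram <- (gram + t(gram)) / 2
  fit <- .smo_solve(gram, as.numeric(y), C, tol, as.integer(max_iter))
  scale_tol <- 1e-3 * max(1, mean(diag(gram)) * C)
  if (!fit$converged || fit$violation > max(tol, scale_tol))
    stop("SVM solver did not converge after ", fit$iterations,
         " iterations (KKT violation ", signif(fit$violation, 3), ")")
  list(alphas = fit$alpha, bias = fit$b, iterations = fit$iterations,
       violation = fit$violation)
}

#' Primal weight vector of a linear-kernel SVM
#'
#' `w = sum_i alpha_i y_i x_i`; any constant factor in the published weight
#' expressions only rescales `w` and cannot change gene-set rankings.
#'
#' @param alphas dual coefficients.
#' @param y labels in \{+1, -1\}.
#' @param X training features (samples x gene sets).
#' @return named weight vector over gene sets.
#' @export
weights_single <- function(alphas, y, X) {
  w <- as.vector(crossprod(X, alphas * y))
  names(w) <- colnames(X)
  w
}

.check_shared_sets <- function(tasks) {
  sn <- colnames(tasks[[1L]]$features)
  for (t in tasks[-1L])
    if (!identical(colnames(t$features), sn))
      stop("tasks do not share an identical gene-set feature space")
  sn
}

.check_matched <- function(tasks) {
  ids <- rownames(tasks[[1L]]$features)
  for (t in tasks[-1L]) {
    if (!identical(rownames(t$features), ids))
      stop("matched-data models require identical samples across tasks")
    if (!identical(as.character(t$labels), as.character(tasks[[1L]]$labels)))
      stop("matched-data models require identical labels across tasks")
  }
  ids
}

.new_pathway_model <- function(model, w, tasks_levels, C, extra = list()) {
  structure(c(list(model = model, w = w, C = C, levels = tasks_levels),
              extra),
            class = c(paste0(gsub("-", "_", model), "_model"),
                      "pathway_model"))
}

#' Fit a single-task SVM on one data type's enrichment scores
#'
#' @param task a [task_dataset()].
#' @param C regularization parameter (default 1).
#' @param tol solver tolerance.
#' @return a `"pathway_model"` object with per-gene-set weights.
#' @export
fit_single_task <- function(task, C = 1, tol = 1e-6) {
  X <- task$features
  fit <- train_svm(linear_gram(X), task$y, C, tol)
  .new_pathway_model("single", weights_single(fit$alphas, task$y, X),
                     levels(task$labels), C,
                     list(bias = fit$bias, alphas = fit$alphas, y = task$y,
                          iterations = fit$iterations,
                          task_id = task$task_id,
                          set_names = colnames(X), n_train = nrow(X)))
}

#' Fit a concatenated-data SVM
#'
#' Stacks all tasks' samples in the shared gene-set feature space and
#' trains one standard SVM; predictions remain per sample and data type.
#'
#' @param tasks list of [task_dataset()] with identical gene sets.
#' @param C regularization parameter.
#' @param tol solver tolerance.
#' @return a `"pathway_model"` object.
#' @export
fit_concatenated <- function(tasks, C = 1, tol = 1e-6) {
  if (inherits(tasks, "task_dataset")) tasks <- list(tasks)
  sn <- .check_shared_sets(tasks)
  X <- do.call(rbind, lapply(tasks, `[[`, "features"))
  y <- unlist(lapply(tasks, `[[`, "y"), use.names = FALSE)
  fit <- train_svm(linear_gram(X), y, C, tol)
  .new_pathway_model("concatenated", weights_single(fit$alphas, y, X),
                     levels(tasks[[1L]]$labels), C,
                     list(bias = fit$bias, alphas = fit$alphas, y = y,
                          iterations = fit$iterations, set_names = sn,
                          n_train = nrow(X)))
}

#' Fit a regularized multi-task SVM
#'
#' Trains one SVM over the stacked samples with the task-coupling kernel
#' of [multitask_gram()].  Task-specific effects are
#' `v_t = sum_{i in t} alpha_i y_i x_i`, the common effect is
#' `w0 = (1/(mu T)) sum_t v_t`, and the final per-task weights are
#' `w_t = w0 + v_t`.  Prediction for a sample of task t uses the kernel
#' expansion restricted to the fitted duals.
#'
#' @param tasks list of [task_dataset()] with identical gene sets.
#' @param C regularization parameter.
#' @param mu positive coupling parameter (small = strongly tied tasks).
#' @param tol solver tolerance.
#' @return a `"pathway_model"` object carrying `w0`, `v` (sets x tasks) and
#'   `w_task = w0 + v_t`; `coef()` returns the common weight `w0`.
#' @export
fit_multitask <- function(tasks, C = 1, mu = 1, tol = 1e-6) {
  if (inherits(tasks, "task_dataset")) tasks <- list(tasks)
  if (mu <= 0) stop("mu must be positive")
  sn <- .check_shared_sets(tasks)
  task_ids <- vapply(tasks, `[[`, "", "task_id")
  if (anyDuplicated(task_ids)) stop("duplicate task ids")
  X <- do.call(rbind, lapply(tasks, `[[`, "features"))
  y <- unlist(lapply(tasks, `[[`, "y"), use.names = FALSE)
  task_of <- rep(task_ids, vapply(tasks, function(t) nrow(t$features), 0L))
  fit <- train_svm(multitask_gram(X, task_of, mu), y, C, tol)
  ay <- fit$alphas * y
  Tn <- length(tasks)
  v <- sapply(task_ids, function(tid) {
    idx <- task_of == tid
    as.vector(crossprod(X[idx, , drop = FALSE], ay[idx]))
  })
  v <- matrix(v, ncol = Tn, dimnames = list(sn, task_ids))
  w0 <- rowSums(v) / (mu * Tn)
  w_task <- w0 + v
  .new_pathway_model("multitask", w0, levels(tasks[[1L]]$labels), C,
                     list(bias = fit$bias, alphas = fit$alphas, y = y,
                          iterations = fit$iterations, set_names = sn,
                          mu = mu, task_ids = task_ids, v = v, w0 = w0,
                          w_task = w_task, n_train = nrow(X)))
}

#' Fit per-task models whose real-valued predictions are summed
#'
#' For matched samples, one single-task SVM is trained per data type and a
#' sample's class is the sign of the summed decision values (ties go to
#' class C1).
#'
#' @param tasks list of matched [task_dataset()] (identical samples).
#' @param C regularization parameter.
#' @param tol solver tolerance.
#' @return a `"pathway_model"` holding the per-task submodels; `coef()`
#'   returns the sum of the single-task weight vectors.
#' @export
fit_summed_prediction <- function(tasks, C = 1, tol = 1e-6) {
  if (inherits(tasks, "task_dataset")) tasks <- list(tasks)
  .check_shared_sets(tasks)
  .check_matched(tasks)
  submodels <- lapply(tasks, fit_single_task, C = C, tol = tol)
  w <- Reduce(`+`, lapply(submodels, `[[`, "w"))
  .new_pathway_model("summed_prediction", w, levels(tasks[[1L]]$labels), C,
                     list(submodels = submodels,
                          task_ids = vapply(tasks, `[[`, "", "task_id"),
                          set_names = colnames(tasks[[1L]]$features)))
}

#' Fit a single SVM on summed enrichment scores
#'
#' For matched samples, the per-set enrichment scores of all data types are
#' summed into one feature matrix before an ordinary single-task fit.
#'
#' @param tasks list of matched [task_dataset()].
#' @param C regularization parameter.
#' @param tol solver tolerance.
#' @return a `"pathway_model"` object.
#' @export
fit_summed_es <- function(tasks, C = 1, tol = 1e-6) {
  if (inherits(tasks, "task_dataset")) tasks <- list(tasks)
  .check_shared_sets(tasks)
  .check_matched(tasks)
  X <- Reduce(`+`, lapply(tasks, `[[`, "features"))
  if (all(abs(X) < 1e-12))
    stop("summed enrichment scores are identically zero; cannot train")
  y <- tasks[[1L]]$y
  fit <- train_svm(linear_gram(X), y, C, tol)
  .new_pathway_model("summed_es", weights_single(fit$alphas, y, X),
                     levels(tasks[[1L]]$labels), C,
                     list(bias = fit$bias, alphas = fit$alphas, y = y,
                          iterations = fit$iterations,
                          set_names = colnames(X),
                          task_ids = vapply(tasks, `[[`, "", "task_id"),
                          n_train = nrow(X)))
}

#' Fit a merged-feature SVM
#'
#' For matched samples, the per-task enrichment scores are concatenated
#' along gene sets into one feature vector of length (tasks x sets).  The
#' fitted weight vector splits back into per-task blocks; the combined
#' per-set weight used for ranking is the sum over blocks.
#'
#' @param tasks list of matched [task_dataset()].
#' @param C regularization parameter.
#' @param tol solver tolerance.
#' @return a `"pathway_model"` with `blocks` (sets x tasks) and combined
#'   per-set weights.
#' @export
fit_merged <- function(tasks, C = 1, tol = 1e-6) {
  if (inherits(tasks, "task_dataset")) tasks <- list(tasks)
  sn <- .check_shared_sets(tasks)
  .check_matched(tasks)
  task_ids <- vapply(tasks, `[[`, "", "task_id")
  Xs <- lapply(tasks, `[[`, "features")
  X <- do.call(cbind, Xs)
  colnames(X) <- unlist(lapply(task_ids, function(tid) paste(tid, sn, sep = ":")))
  y <- tasks[[1L]]$y
  fit <- train_svm(linear_gram(X), y, C, tol)
  w_full <- weights_single(fit$alphas, y, X)
  blocks <- matrix(w_full, nrow = length(sn), ncol = length(tasks),
                   dimnames = list(sn, task_ids))
  .new_pathway_model("merged", rowSums(blocks), levels(tasks[[1L]]$labels), C,
                     list(bias = fit$bias, alphas = fit$alphas, y = y,
                          iterations = fit$iterations, set_names = sn,
                          task_ids = task_ids, blocks = blocks,
                          w_full = w_full, n_train = nrow(X)))
}

#' Fit any of the six pathway-level predictive models
#'
#' Umbrella fitting function over enrichment-score features.  `"single"`
#' expects one task; `"concatenated"` and `"multitask"` accept unmatched
#' tasks; `"summed_prediction"`, `"summed_es"` and `"merged"` require
#' matched samples across tasks.
#'
#' @param tasks a [task_dataset()] or list of them.
#' @param model one of `"single"`, `"concatenated"`, `"multitask"`,
#'   `"summed_prediction"`, `"summed_es"`, `"merged"`.
#' @param C regularization parameter (default 1).
#' @param mu multi-task coupling parameter (default 1).
#' @param tol solver tolerance.
#' @return a classed `"pathway_model"` object with `print`, `summary`,
#'   `coef` and `predict` methods.
#' @export
fit_pathway_model <- function(tasks,
                              model = c("single", "concatenated", "multitask",
                                        "summed_prediction", "summed_es",
                                        "merged"),
                              C = 1, mu = 1, tol = 1e-6) {
  model <- match.arg(model)
  switch(model,
         single = {
           if (!inherits(tasks, "task_dataset")) {
             if (length(tasks) != 1L)
               stop("model 'single' takes exactly one task")
             tasks <- tasks[[1L]]
           }
           fit_single_task(tasks, C, tol)
         },
         concatenated = fit_concatenated(tasks, C, tol),
         multitask = fit_multitask(tasks, C, mu, tol),
         summed_prediction = fit_summed_prediction(tasks, C, tol),
         summed_es = fit_summed_es(tasks, C, tol),
         merged = fit_merged(tasks, C, tol))
}

.as_features <- function(newdata, set_names) {
  X <- as.matrix(unclass(newdata))
  if (!is.null(colnames(X)) && !identical(colnames(X), set_names)) {
    if (!all(set_names %in% colnames(X)))
      stop("newdata lacks gene-set feature(s): ",
           paste(setdiff(set_names, colnames(X))[1:5], collapse = ", "))
    X <- X[, set_names, drop = FALSE]
  }
  X
}

.class_from_decision <- function(decision, levels) {
  # tie at 0 goes to class C1 (the first level)
  factor(ifelse(decision >= 0, levels[1L], levels[2L]), levels = levels)
}

#' Predict phenotype class from a fitted pathway model
#'
#' @param object a `"pathway_model"`.
#' @param newdata enrichment matrix (samples x sets) for single-task,
#'   concatenated and multitask models; a list of matched per-task
#'   enrichment matrices for summed-prediction, summed-ES and merged
#'   models.
#' @param task task id of `newdata` (required for multitask models).
#' @param type `"class"` (default) or `"decision"` for the real-valued
#'   decision function.
#' @param ... unused.
#' @return factor of predicted classes, or named numeric decision values.
#' @export
predict.pathway_model <- function(object, newdata, task = NULL,
                                  type = c("class", "decision"), ...) {
  type <- match.arg(type)
  dec <- switch(object$model,
    single = ,
    concatenated = ,
    summed_es = {
      if (object$model == "summed_es" && is.list(newdata) &&
          !is.matrix(newdata))
        newdata <- Reduce(`+`, lapply(newdata, function(m)
          .as_features(m, object$set_names)))
      X <- .as_features(newdata, object$set_names)
      drop(X %*% object$w) + object$bias
    },
    multitask = {
      if (is.null(task)) stop("multitask prediction needs a task id")
      if (!task %in% object$task_ids)
        stop("unknown task at predict time: ", task)
      X <- .as_features(newdata, object$set_names)
      w_eff <- length(object$task_ids) * object$w0 + object$v[, task]
      drop(X %*% w_eff) + object$bias
    },
    summed_prediction = {
      stopifnot(is.list(newdata), length(newdata) == length(object$submodels))
      decs <- mapply(function(m, nd)
        predict(m, nd, type = "decision"), object$submodels, newdata,
        SIMPLIFY = FALSE)
      Reduce(`+`, decs)
    },
    merged = {
      stopifnot(is.list(newdata), length(newdata) == length(object$task_ids))
      X <- do.call(cbind, lapply(newdata, function(m)
        .as_features(m, object$set_names)))
      drop(X %*% object$w_full) + object$bias
    })
  if (type == "decision") dec else .class_from_decision(dec, object$levels)
}

#' Gene-set weights of a fitted pathway model
#'
#' Returns the per-gene-set weight vector used for ranking: the primal
#' weights for single/concatenated/summed-ES fits, the common weight `w0`
#' for multitask fits, the summed single-task weights for
#' summed-prediction fits and the across-task block sum for merged fits.
#'
#' @param object a `"pathway_model"`.
#' @param ... unused.
#' @export
coef.pathway_model <- function(object, ...) object$w

#' @export
print.pathway_model <- function(x, ...) {
  cat("Pathway-level SVM model ('", x$model, "'), C = ", x$C,
      if (!is.null(x$mu)) paste0(", mu = ", x$mu), "\n", sep = "")
  cat("  gene sets:", length(x$w),
      " classes:", paste(x$levels, collapse = " vs "), "\n")
  if (!is.null(x$task_ids))
    cat("  tasks:", paste(x$task_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pathway_model <- function(object, ...) {
  print(object)
  if (!is.null(object$alphas)) {
    sv <- sum(object$alphas > 1e-8)
    cat("  support vectors:", sv, "of", length(object$alphas),
        " solver iterations:", object$iterations, "\n")
  }
  top <- utils::head(rank_gene_sets(object$w), 5L)
  cat("  top gene sets by |weight|:\n")
  print(top, row.names = FALSE)
  invisible(object)
}

#' Rank gene sets by predictive weight
#'
#' Sets are ordered by decreasing absolute weight (sign only encodes class
#' direction); ties are broken by set name.  Rank 1 is the largest.
#'
#' @param w named weight vector over gene sets (e.g. from
#'   [coef.pathway_model()]).
#' @param signed rank by the signed weight instead of its magnitude.
#' @return data.frame set_name/weight/rank ordered by rank, of class
#'   `"gene_set_ranking"`.
#' @export
rank_gene_sets <- function(w, signed = FALSE) {
  key <- if (signed) w else abs(w)
  o <- order(-key, names(w))
  out <- data.frame(set_name = names(w)[o], weight = unname(w[o]),
                    rank = seq_along(w), stringsAsFactors = FALSE)
  class(out) <- c("gene_set_ranking", "data.frame")
  out
}

#' Leave-one-out cross-validation with predictive-value metrics
#'
#' Generic LOO harness: for each sample, `fit_fn` is called with the
#' training indices and the held-out index and must return the predicted
#' class label for the held-out sample.  Class C1 (the first factor level)
#' is the positive class for PPV/NPV.
#'
#' @param fit_fn function(train_idx, test_idx) -> predicted label
#'   (character or factor, one element).
#' @param labels true [phenotype_labels()] for all samples.
#' @return list of class `"loo_result"` with `predictions`, `confusion`
#'   (TP/FP/TN/FN), `overall`, `ppv`, `npv` (NA when undefined).
#' @export
loo_cross_validate <- function(fit_fn, labels) {
  n <- length(labels)
  preds <- character(n)
  for (i in seq_len(n))
    preds[i] <- as.character(fit_fn(setdiff(seq_len(n), i), i))
  pos <- levels(labels)[1L]
  truth_pos <- as.character(labels) == pos
  pred_pos <- preds == pos
  tp <- sum(pred_pos & truth_pos); fp <- sum(pred_pos & !truth_pos)
  tn <- sum(!pred_pos & !truth_pos); fn <- sum(!pred_pos & truth_pos)
  structure(list(
    predictions = factor(preds, levels = levels(labels)),
    confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
    overall = (tp + tn) / n,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_),
    class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat("LOO cross-validation:",
      sprintf("overall %.2f%%", 100 * x$overall),
      sprintf("PPV %s", ifelse(is.na(x$ppv), "n/a",
                               sprintf("%.2f%%", 100 * x$ppv))),
      sprintf("NPV %s", ifelse(is.na(x$npv), "n/a",
                               sprintf("%.2f%%", 100 * x$npv))), "\n")
  cat("  counts:", paste(names(x$confusion), x$confusion, collapse = ", "),
      "\n")
  invisible(x)
}

#' Leave-one-out evaluation of a matched expression + genotype dataset
#'
#' Concrete LOO pipeline for matched data: per fold, class profiles and
#' enrichment scores are recomputed from the training samples only (the
#' held-out sample never touches the class profiles - strict mode), a
#' model is fitted and the held-out sample is predicted from its own
#' enrichment scores against the training profiles.  Fast mode reuses
#' full-cohort enrichment scores; its statistics leak the held-out label
#' and it is provided for exploration only.
#'
#' @param expr an [expression_matrix()] or NULL.
#' @param gene_geno gene-level [genotype_matrix()] or NULL.
#' @param sets a [gene_set_collection()].
#' @param labels a [phenotype_labels()].
#' @param model model name as in [fit_pathway_model()]; for `"single"`,
#'   supply exactly one data matrix.
#' @param C,mu,tol model parameters.
#' @param p KS weight exponent.
#' @param mode `"strict"` (default) or `"fast"`.
#' @return a `"loo_result"`.
#' @export
loo_matched <- function(expr = NULL, gene_geno = NULL, sets, labels,
                        model = "merged", C = 1, mu = 1, tol = 1e-6,
                        p = 1, mode = c("strict", "fast")) {
  mode <- match.arg(mode)
  data_list <- list()
  if (!is.null(expr)) data_list$expression <- expr
  if (!is.null(gene_geno)) data_list$genotype <- gene_geno
  if (length(data_list) == 0L) stop("no data supplied")
  for (d in data_list) check_sample_alignment(d, labels)

  make_tasks <- function(train_idx, test_idx) {
    tr_lab <- phenotype_labels(as.character(labels)[train_idx],
                               names(labels)[train_idx],
                               class_levels = levels(labels))
    train <- list(); test <- list()
    for (nm in names(data_list)) {
      dat <- unclass(data_list[[nm]])
      dtr <- dat[, train_idx, drop = FALSE]
      dte <- dat[, test_idx, drop = FALSE]
      if (nm == "expression") {
        prof <- expression_profiles(
          expression_matrix(dtr, rownames(dat), colnames(dat)[train_idx]), tr_lab)
        str_ <- expression_correlation_stats(dtr, tr_lab)
        ste <- expression_correlation_stats(dte, tr_lab, profiles = prof)
      } else {
        gtr <- genotype_matrix(dtr, rownames(dat), colnames(dat)[train_idx])
        prof <- genotype_profiles(gtr, tr_lab)
        str_ <- genotype_correlation_stats(gtr, tr_lab)
        ste <- genotype_correlation_stats(
          genotype_matrix(dte, rownames(dat), colnames(dat)[test_idx]),
          tr_lab, profiles = prof)
      }
      train[[nm]] <- task_dataset(enrichment_matrix(str_, sets, p), tr_lab, nm)
      test[[nm]] <- enrichment_matrix(ste, sets, p)
    }
    list(train = train, test = test)
  }

  full_es <- NULL
  if (mode == "fast") {
    full_es <- lapply(names(data_list), function(nm) {
      st <- if (nm == "expression")
        expression_correlation_stats(unclass(data_list[[nm]]), labels)
      else genotype_correlation_stats(data_list[[nm]], labels)
      enrichment_matrix(st, sets, p)
    })
    names(full_es) <- names(data_list)
  }

  fit_fn <- function(train_idx, test_idx) {
    if (mode == "strict") {
      parts <- make_tasks(train_idx, test_idx)
      train_tasks <- parts$train
      test_feats <- parts$test
    } else {
      tr_lab <- phenotype_labels(as.character(labels)[train_idx],
                                 names(labels)[train_idx],
                                 class_levels = levels(labels))
      train_tasks <- lapply(names(data_list), function(nm)
        task_dataset(full_es[[nm]][train_idx, , drop = FALSE], tr_lab, nm))
      names(train_tasks) <- names(data_list)
      test_feats <- lapply(full_es, function(m) m[test_idx, , drop = FALSE])
    }
    fitted <- fit_pathway_model(unname(train_tasks), model = model,
                                C = C, mu = mu, tol = tol)
    pred <- if (model %in% c("summed_prediction", "summed_es", "merged")) {
      predict(fitted, unname(test_feats))
    } else if (model == "multitask") {
      # matched sample: sum the per-task decisions, tie to C1
      dec <- Reduce(`+`, lapply(names(test_feats), function(nm)
        predict(fitted, test_feats[[nm]], task = nm, type = "decision")))
      .class_from_decision(dec, fitted$levels)
    } else if (model == "concatenated") {
      dec <- Reduce(`+`, lapply(test_feats, function(m)
        predict(fitted, m, type = "decision")))
      .class_from_decision(dec, fitted$levels)
    } else {
      predict(fitted, test_feats[[1L]])
    }
    as.character(pred)[1L]
  }
  loo_cross_validate(fit_fn, labels)
}
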