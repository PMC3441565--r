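test_that("gram matrices match their definitions", {
  # orthonormal rows give the identity
  X <- diag(3)
  expect_equal(linear_gram(X), diag(3))
  # duplicated row gives a rank-1 block
  X2 <- rbind(c(1, 2), c(1, 2))
  expect_equal(linear_gram(X2), matrix(5, 2, 2))
  # random instance equals the double loop
  set.seed(51)
  X3 <- matrix(rnorm(40), 8, 5)
  G <- linear_gram(X3)
  for (i in 1:8) for (j in 1:8)
    expect_equal(G[i, j], sum(X3[i, ] * X3[j, ]), tolerance = 1e-12)
})

test_that("multi-task kernel couples tasks through 1/mu", {
  x <- c(1, 2); z <- c(2, 1)
  X <- rbind(x, x, z)
  # same task, mu = 1: (1/1 + 1) * <x, x>
  K <- multitask_gram(X, c("a", "a", "b"), mu = 1)
  expect_equal(K[1, 2], 2 * sum(x * x))
  # different tasks, mu = 2, <x, z> = 4 -> 2
  expect_equal(multitask_gram(rbind(x, z), c("a", "b"), mu = 2)[1, 2],
               0.5 * 4)
  # mu -> infinity approaches the block-diagonal single-task Gram
  Kinf <- multitask_gram(X, c("a", "a", "b"), mu = 1e12)
  expect_equal(Kinf[1, 3], 0, tolerance = 1e-9)
  expect_equal(Kinf[1, 2], sum(x * x), tolerance = 1e-9)
  expect_error(multitask_gram(X, c("a", "a", "b"), mu = 0), "positive")

  # PSD for any mu > 0 (eigenvalue check on random instances)
  set.seed(52)
  for (r in 1:10) {
    Xr <- matrix(rnorm(60), 12, 5)
    task <- sample(c("t1", "t2", "t3"), 12, TRUE)
    mu <- stats::runif(1, 0.01, 10)
    ev <- eigen(multitask_gram(Xr, task, mu), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("the dual solver reproduces the hand-solved two-point problem", {
  X <- matrix(c(-1, 1), 2, 1)
  y <- c(-1, 1)
  fit <- train_svm(linear_gram(X), y, C = 10)
  expect_equal(fit$alphas, c(0.5, 0.5), tolerance = 1e-6)
  w <- weights_single(fit$alphas, y, X)
  expect_equal(unname(w), 1, tolerance = 1e-6)
  expect_equal(fit$bias, 0, tolerance = 1e-6)
  # decision function f(x) = x
  for (x0 in c(-2, 0.3, 1.7))
    expect_equal(sum(w * x0) + fit$bias, x0, tolerance = 1e-5)
})

test_that("dual feasibility holds after every fit", {
  set.seed(53)
  for (r in 1:10) {
    n <- sample(10:40, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    y <- sample(c(-1, 1), n, TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
    C <- stats::runif(1, 0.1, 5)
    fit <- train_svm(linear_gram(X), y, C)
    expect_true(all(fit$alphas >= -1e-9))
    expect_true(all(fit$alphas <= C + 1e-9))
    expect_lt(abs(sum(fit$alphas * y)), 1e-6)
  }
})

test_that("duplicating a separable training set leaves the decision unchanged", {
  # in the hard-margin regime the solution is unique, so duplicating every
  # point must reproduce the same decision function
  set.seed(54)
  X <- rbind(matrix(rnorm(24, mean = 2), 12, 2),
             matrix(rnorm(24, mean = -2), 12, 2))
  y <- rep(c(1, -1), each = 12)
  f1 <- train_svm(linear_gram(X), y, C = 100)
  f2 <- train_svm(linear_gram(rbind(X, X)), c(y, y), C = 100)
  w1 <- weights_single(f1$alphas, y, X)
  w2 <- weights_single(f2$alphas, c(y, y), rbind(X, X))
  expect_equal(unname(w1), unname(w2), tolerance = 1e-4)
  expect_equal(f1$bias, f2$bias, tolerance = 1e-4)
})

test_that("a separable problem is fit to zero training error at large C", {
  set.seed(55)
  X <- rbind(matrix(rnorm(30, mean = 3), 15, 2),
             matrix(rnorm(30, mean = -3), 15, 2))
  y <- rep(c(1, -1), each = 15)
  fit <- train_svm(linear_gram(X), y, C = 100)
  w <- weights_single(fit$alphas, y, X)
  expect_true(all(sign(drop(X %*% w) + fit$bias) == y))
})

test_that("dual coefficients agree with an independent SVM implementation", {
  skip_if_not_installed("kernlab")
  set.seed(56)
  X <- rbind(matrix(rnorm(40, 1), 20, 2), matrix(rnorm(40, -1), 20, 2))
  y <- rep(c(1, -1), each = 20)
  fit <- train_svm(linear_gram(X), y, C = 1)
  w <- weights_single(fit$alphas, y, X)
  ref <- kernlab::ksvm(X, factor(y), kernel = "vanilladot",
                       kpar = list(), C = 1, scaled = FALSE, tol = 1e-7)
  # kernlab's decision orientation may flip; compare up to sign
  w_ref <- colSums(kernlab::coef(ref)[[1]] *
                     X[kernlab::alphaindex(ref)[[1]], , drop = FALSE])
  flip <- sign(sum(w * w_ref))
  expect_equal(unname(w), flip * unname(w_ref), tolerance = 1e-3)
  expect_equal(fit$bias, flip * -kernlab::b(ref), tolerance = 1e-3)
})

test_that("primal weights reproduce kernel-expansion decisions", {
  set.seed(57)
  X <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("s", 1:20), paste0("f", 1:3)))
  y <- rep(c(1, -1), 10)
  fit <- train_svm(linear_gram(X), y, C = 0.7)
  expect_equal(unname(weights_single(rep(0, 20), y, X)), c(0, 0, 0))
  w <- weights_single(fit$alphas, y, X)
  Xt <- matrix(rnorm(15), 5, 3)
  dec_primal <- drop(Xt %*% w) + fit$bias
  dec_kernel <- drop(Xt %*% t(X) %*% (fit$alphas * y)) + fit$bias
  expect_lt(max(abs(dec_primal - dec_kernel)), 1e-8)
})

test_that("concatenated fits stack tasks and degenerate to single-task", {
  tasks <- make_strong_tasks()
  single <- fit_single_task(tasks$expr, C = 1)
  conc1 <- fit_concatenated(list(tasks$expr), C = 1)
  expect_equal(coef(conc1), coef(single), tolerance = 1e-6)
  # two identical tasks: same decision function as one task
  conc2 <- fit_concatenated(list(tasks$expr, tasks$expr), C = 1)
  newx <- tasks$expr$features + 0.1
  expect_equal(as.character(predict(conc2, newx)),
               as.character(predict(single, newx)))
  # disjoint informative sets: weight support spans both blocks
  t_a <- make_strong_tasks(informative = 1, seed = 7)
  t_b <- make_strong_tasks(informative = 5, seed = 8)
  conc <- fit_concatenated(list(t_a$expr, t_b$geno), C = 1)
  w <- abs(coef(conc))
  expect_gt(w[1], max(w[-c(1, 5)]))
  expect_gt(w[5], max(w[-c(1, 5)]))
  # feature mismatch errors
  bad <- t_b$geno
  colnames(bad$features)[1] <- "other"
  expect_error(fit_concatenated(list(t_a$expr, bad)), "feature space")
})

test_that("multi-task fits obey the coupling-kernel algebra", {
  tasks <- make_strong_tasks(seed = 9)
  tlist <- list(tasks$expr, tasks$geno)

  # T = 1: decision equals a single-task SVM on the kernel scaled by
  # (1/mu + 1)
  mu <- 1.7
  m1 <- fit_multitask(list(tasks$expr), C = 1, mu = mu)
  X <- tasks$expr$features
  ref <- train_svm(linear_gram(X) * (1 / mu + 1), tasks$expr$y, C = 1)
  dec_ref <- drop((1 / mu + 1) * (X + 0.05) %*%
                    t(X) %*% (ref$alphas * tasks$expr$y)) + ref$bias
  dec_mt <- predict(m1, X + 0.05, task = "expression", type = "decision")
  expect_equal(unname(dec_mt), unname(dec_ref), tolerance = 1e-5)

  # large mu: the cross-task kernel vanishes, leaving single-task blocks
  # coupled only through the shared sum(alpha*y) = 0 constraint and bias;
  # predicted classes match the single-task models and decision functions
  # agree up to that residual coupling
  mbig <- fit_multitask(tlist, C = 1, mu = 1e6)
  for (tk in tlist) {
    s <- fit_single_task(tk, C = 1)
    d_mt <- predict(mbig, tk$features, task = tk$task_id, type = "decision")
    d_st <- predict(s, tk$features, type = "decision")
    expect_identical(as.character(predict(mbig, tk$features,
                                          task = tk$task_id)),
                     as.character(predict(s, tk$features)))
    expect_gt(stats::cor(d_mt, d_st), 0.99)
  }
  # symmetric case: two copies of one task make the shared intercept
  # allocation neutral, so the limit matches single-task exactly
  tcopy <- tasks$expr
  tcopy$task_id <- "copy"
  msym <- fit_multitask(list(tasks$expr, tcopy), C = 1, mu = 1e6)
  ssym <- fit_single_task(tasks$expr, C = 1)
  expect_equal(unname(predict(msym, tasks$expr$features, task = "expression",
                              type = "decision")),
               unname(predict(ssym, tasks$expr$features, type = "decision")),
               tolerance = 1e-3)

  # identical tasks: v_t identical across tasks and w0 = v_1 / mu
  t2 <- tasks$expr
  t2$task_id <- "copy"
  mid <- fit_multitask(list(tasks$expr, t2), C = 1, mu = 2)
  expect_equal(mid$v[, 1], mid$v[, 2], tolerance = 1e-5)
  expect_equal(mid$w0, mid$v[, 1] / 2, tolerance = 1e-5)

  # w_t - v_t equals w0 exactly for every task (algebraic identity)
  mfit <- fit_multitask(tlist, C = 1, mu = 0.8)
  for (k in 1:2)
    expect_equal(mfit$w_task[, k] - mfit$v[, k], mfit$w0, tolerance = 1e-12)
  expect_error(predict(mfit, X, task = "nope"), "unknown task")
})

test_that("matched-data models combine tasks as documented", {
  tasks <- make_strong_tasks(seed = 10)
  tlist <- list(tasks$expr, tasks$geno)
  newdata <- list(tasks$expr$features + 0.02, tasks$geno$features - 0.02)

  # summed prediction: sign of the summed decisions, ties to C1
  sp <- fit_summed_prediction(tlist, C = 1)
  decs <- predict(sp, newdata, type = "decision")
  d1 <- predict(sp$submodels[[1]], newdata[[1]], type = "decision")
  d2 <- predict(sp$submodels[[2]], newdata[[2]], type = "decision")
  expect_equal(decs, d1 + d2, tolerance = 1e-12)
  expect_identical(
    as.character(predict(sp, newdata)),
    unname(ifelse(d1 + d2 >= 0, "C1", "C2")))
  sp1 <- fit_summed_prediction(list(tasks$expr), C = 1)
  expect_identical(as.character(predict(sp1, newdata[1])),
                   as.character(predict(sp$submodels[[1]], newdata[[1]])))

  # summed enrichment scores: doubled features keep the predicted classes
  se2 <- fit_summed_es(list(tasks$expr, tasks$expr), C = 1)
  s1 <- fit_single_task(tasks$expr, C = 1)
  expect_identical(as.character(predict(se2, list(newdata[[1]], newdata[[1]]))),
                   as.character(predict(s1, newdata[[1]])))
  # opposite scores cancel: degenerate training rejected
  neg <- tasks$expr
  neg$features <- -tasks$expr$features
  expect_error(fit_summed_es(list(tasks$expr, neg)), "identically zero")

  # merged: T = 1 equals single-task; block permutation flips blocks but
  # not predictions
  mg1 <- fit_merged(list(tasks$expr), C = 1)
  expect_equal(unname(coef(mg1)), unname(coef(s1)), tolerance = 1e-6)
  mg <- fit_merged(tlist, C = 1)
  mg_sw <- fit_merged(rev(tlist), C = 1)
  expect_equal(mg$blocks[, "expression"], mg_sw$blocks[, "expression"],
               tolerance = 1e-5)
  expect_identical(as.character(predict(mg, newdata)),
                   as.character(predict(mg_sw, rev(newdata))))
  # only task 2 informative: task-1 block near zero
  quiet <- make_strong_tasks(seed = 11, shift = 0)$expr
  loud <- make_strong_tasks(seed = 11, shift = 3)$geno
  mg2 <- fit_merged(list(quiet, loud), C = 1)
  expect_lt(max(abs(mg2$blocks[, 1])), max(abs(mg2$blocks[, 2])) / 3)
})

test_that("fit_pathway_model dispatches and methods print cleanly", {
  tasks <- make_strong_tasks(seed = 12)
  m <- fit_pathway_model(list(tasks$expr, tasks$geno), "multitask",
                         C = 1, mu = 1)
  expect_s3_class(m, "pathway_model")
  expect_named(coef(m), colnames(tasks$expr$features))
  expect_output(print(m), "multitask")
  expect_output(summary(m), "support vectors")
  expect_error(fit_pathway_model(list(tasks$expr, tasks$geno), "single"),
               "exactly one task")
})

test_that("gene-set ranking uses |weight| with name tie-breaks", {
  w <- c(set1 = 0.5, set2 = -0.9, set3 = 0.1)
  r <- rank_gene_sets(w)
  expect_identical(r$set_name, c("set2", "set1", "set3"))
  expect_identical(r$rank, 1:3)
  # equal weights rank in name order
  w_eq <- c(b = 0.2, a = 0.2, c = 0.2)
  expect_identical(rank_gene_sets(w_eq)$set_name, c("a", "b", "c"))
  # random weights agree with a sort oracle and rescaling invariance
  set.seed(58)
  w_r <- stats::setNames(rnorm(20), paste0("s", sprintf("%02d", 1:20)))
  r_r <- rank_gene_sets(w_r)
  o <- order(-abs(w_r), names(w_r))
  expect_identical(r_r$set_name, names(w_r)[o])
  expect_identical(rank_gene_sets(3.7 * w_r)$set_name, r_r$set_name)
  # signed option ranks by the signed value
  expect_identical(rank_gene_sets(w, signed = TRUE)$set_name,
                   c("set1", "set3", "set2"))
})

test_that("LOO cross-validation computes overall accuracy, PPV and NPV", {
  lab <- make_labels(8)
  # perfect classifier
  perfect <- loo_cross_validate(function(tr, te) as.character(lab)[te], lab)
  expect_equal(perfect$overall, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)

  # confusion counts mirroring a published breakdown:
  # TP = 194, FP = 11, TN = 50, FN = 9 -> PPV = 194/205 = 94.63%
  truth <- phenotype_labels(c(rep("C1", 203), rep("C2", 61)),
                            paste0("s", 1:264))
  preds <- c(rep("C1", 194), rep("C2", 9), rep("C1", 11), rep("C2", 50))
  res <- loo_cross_validate(function(tr, te) preds[te], truth)
  expect_equal(res$confusion[["TP"]], 194)
  expect_equal(res$confusion[["FP"]], 11)
  expect_equal(round(100 * res$ppv, 2), 94.63)
  expect_equal(res$overall, 244 / 264)
  expect_equal(res$npv, 50 / 59)

  # all-one-class predictor on balanced data: accuracy 0.5, NPV undefined
  allpos <- loo_cross_validate(function(tr, te) "C1", lab)
  expect_equal(allpos$overall, 0.5)
  expect_true(is.na(allpos$npv))
  expect_output(print(allpos), "n/a")
})

test_that("matched LOO pipeline recovers a strongly separated cohort", {
  set.seed(59)
  n <- 16
  lab <- make_labels(n)
  G <- 30
  shift <- ifelse(as.integer(lab) == 1L, 2.5, -2.5)
  expr <- expression_matrix(
    matrix(rnorm(G * n), G, n) + rbind(matrix(rep(shift, each = 10),
                                              10, n), matrix(0, 20, n)),
    paste0("g", 1:G), names(lab))
  geno <- genotype_matrix(
    matrix(rbinom(G * n, 2, 0.5), G, n), paste0("g", 1:G), names(lab))
  sets <- gene_set_collection(list(up = paste0("g", 1:10),
                                   null = paste0("g", 21:30)))
  res <- loo_matched(expr, geno, sets, lab, model = "merged", C = 1)
  expect_gt(res$overall, 0.85)
  # fast mode runs and reports the same structure
  res_fast <- loo_matched(expr = expr, sets = sets, labels = lab,
                          model = "single", mode = "fast")
  expect_s3_class(res_fast, "loo_result")
})
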