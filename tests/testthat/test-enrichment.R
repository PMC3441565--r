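test_that("expression statistic is the class-conditional Gaussian log-ratio", {
  # score external samples against hand-built profiles so the parameters
  # are exact: gene with class means +/-1, both sds 1
  prof <- structure(list(
    gene_ids = "g1",
    levels = c("C1", "C2"),
    class1 = list(n = 10, mean = 1, sd = 1),
    class2 = list(n = 10, mean = -1, sd = 1)), class = "expression_profiles")
  score <- function(x) {
    m <- matrix(x, 1, length(x),
                dimnames = list("g1", paste0("t", seq_along(x))))
    expression_correlation_stats(m, labels = NULL, profiles = prof)[1, ]
  }
  expect_equal(unname(score(0)), 0)          # symmetric point
  expect_equal(unname(score(1)), 2)          # [-(x-mu1)^2 + (x-mu2)^2] / 2
  expect_equal(unname(score(-1)), -2)
  # equal class parameters give identically zero statistics
  prof$class2 <- prof$class1
  expect_equal(unname(score(c(-2, 0, 3))), c(0, 0, 0))
})

test_that("swapping class labels negates both correlation statistics", {
  expr <- make_expr(10, 12, seed = 5)
  lab <- make_labels(12)
  lab_sw <- phenotype_labels(as.character(lab), names(lab),
                             class_levels = c("C2", "C1"))
  for (loo in c(TRUE, FALSE)) {
    s1 <- expression_correlation_stats(expr, lab, leave_self_out = loo)
    s2 <- expression_correlation_stats(expr, lab_sw, leave_self_out = loo)
    expect_equal(s2, -s1, tolerance = 1e-12)
  }
  set.seed(6)
  geno <- genotype_matrix(matrix(rbinom(10 * 12, 2, 0.4), 10, 12),
                          paste0("g", 1:10), names(lab))
  for (loo in c(TRUE, FALSE)) {
    g1 <- genotype_correlation_stats(geno, lab, leave_self_out = loo)
    g2 <- genotype_correlation_stats(geno, lab_sw, leave_self_out = loo)
    expect_equal(g2, -g1, tolerance = 1e-12)
  }
})

test_that("genotype statistic reproduces the hand-computed ratios", {
  # cohort: 40 samples; gene where 10/20 in class 1 and 5/20 in class 2
  # carry genotype 1 (scored sample carries 1)
  lab <- phenotype_labels(rep(c("C1", "C2"), each = 20), paste0("s", 1:40))
  g_row <- c(rep(1L, 10), rep(0L, 10), rep(1L, 5), rep(0L, 15))
  geno <- genotype_matrix(matrix(g_row, 1, 40), "gA", names(lab))
  prof <- genotype_profiles(geno, lab)
  ext <- genotype_matrix(matrix(1L, 1, 1), "gA", "new1")
  s <- genotype_correlation_stats(ext, lab, profiles = prof)
  expect_equal(s[1, 1], log(0.50 / 0.25), tolerance = 1e-12)  # log 2

  # pseudo-count rule: class1 5/10 carriers, class2 0/10
  lab2 <- phenotype_labels(rep(c("C1", "C2"), each = 10), paste0("s", 1:20))
  g2 <- c(rep(1L, 5), rep(0L, 5), rep(0L, 10))
  geno2 <- genotype_matrix(matrix(g2, 1, 20), "gA", names(lab2))
  prof2 <- genotype_profiles(geno2, lab2)
  s2 <- genotype_correlation_stats(genotype_matrix(matrix(1L, 1, 1), "gA", "n1"),
                                   lab2, profiles = prof2)
  expect_equal(s2[1, 1], log(6), tolerance = 1e-12)  # log((6/11)/(1/11))

  # identical class frequencies give zero
  g3 <- rep(c(1L, 0L), 20)
  geno3 <- genotype_matrix(matrix(g3, 1, 40), "gA", names(lab))
  s3 <- genotype_correlation_stats(geno3, lab, leave_self_out = FALSE)
  expect_true(all(s3 == 0))

  # leave-self-out removes the scored sample from its own class counts:
  # a class-1 carrier sees (10-1)/(20-1) vs 5/20
  s_loo <- genotype_correlation_stats(geno, lab, leave_self_out = TRUE)
  expect_equal(s_loo[1, 1], log((9 / 19) / (5 / 20)), tolerance = 1e-12)
})

test_that("the worked 5-gene enrichment walk gives 0.75", {
  s <- c(gene1 = 3, gene2 = 2, gene3 = 1, gene4 = 0.5, gene5 = 0.1)
  expect_equal(sample_enrichment_score(s, c("gene1", "gene3")), 0.75)
  # full running sum checked against the independent walk
  expect_equal(es_oracle(s, c("gene1", "gene3")), 0.75)
})

test_that("enrichment scores have the KS structure and symmetry", {
  # top-half set with equal |s| is positively enriched; complement negative
  s <- c(a = 2, b = 2, c = 2, d = -2, e = -2, f = -2)
  top <- sample_enrichment_score(s, c("a", "b", "c"))
  bot <- sample_enrichment_score(s, c("d", "e", "f"))
  expect_gt(top, 0)
  expect_equal(bot, -top, tolerance = 1e-12)

  # all s equal at p = 0: |ES| equals the classical unweighted KS distance
  # of the membership indicator (ties resolved by stable gene order)
  s_eq <- stats::setNames(rep(1, 6), letters[1:6])
  memb <- c("a", "b", "e")
  got <- sample_enrichment_score(s_eq, memb, p = 0)
  # closed form: ranking is the stable gene order a..f; running sum of
  # +1/3 at members, -1/3 at non-members
  rs <- cumsum(ifelse(letters[1:6] %in% memb, 1 / 3, -1 / 3))
  expect_equal(got, rs[which.max(abs(rs))], tolerance = 1e-12)

  # degenerate member weights (all zero stats) fall back to uniform
  s0 <- c(a = 0, b = 0, c = 1, d = 2)
  expect_equal(sample_enrichment_score(s0, c("a", "b")),
               sample_enrichment_score(s0, c("a", "b"), p = 0),
               tolerance = 1e-12)

  expect_error(sample_enrichment_score(s, c("zz")), "no members")
  expect_error(sample_enrichment_score(s, names(s)), "covers all genes")
})

test_that("enrichment matrix equals the brute-force walk on random instances", {
  set.seed(31)
  for (r in 1:50) {
    G <- sample(6:20, 1)
    n <- sample(2:5, 1)
    st <- matrix(rnorm(G * n), G, n,
                 dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
    if (r %% 3 == 0) st[sample(length(st), G)] <- 0  # ties and zeros
    K <- sample(2:4, 1)
    sets <- gene_set_collection(stats::setNames(lapply(seq_len(K), function(k)
      paste0("g", sample(G, sample(seq_len(G - 1), 1)))), paste0("S", 1:K)))
    em <- enrichment_matrix(st, sets)
    for (i in seq_len(n)) for (k in seq_len(K))
      expect_es_match(unname(em[i, k]), st[, i], sets[[k]])
    expect_true(all(abs(em) <= 1 + 1e-12))
  }
})

test_that("enrichment matrix is invariant to gene input order", {
  set.seed(32)
  st <- matrix(rnorm(30 * 4), 30, 4,
               dimnames = list(paste0("g", 1:30), paste0("s", 1:4)))
  sets <- gene_set_collection(list(A = paste0("g", 1:7),
                                   B = paste0("g", c(2, 9, 20))))
  perm <- sample(30)
  expect_equal(unclass(enrichment_matrix(st, sets)),
               unclass(enrichment_matrix(st[perm, ], sets)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(enrichment_matrix(st, gene_set_collection(list(X = "zz"))),
               "X")
})

test_that("running-sum bookkeeping conserves the step masses", {
  set.seed(33)
  s <- stats::setNames(rnorm(25), paste0("g", 1:25))
  memb <- paste0("g", sample(25, 6))
  ord <- order(s, decreasing = TRUE)
  is_m <- names(s)[ord] %in% memb
  w <- abs(s[ord]); w <- w / sum(w[is_m])
  expect_equal(sum(w[is_m]), 1, tolerance = 1e-12)
  expect_equal(sum(ifelse(is_m, 0, 1 / (25 - 6))), 1, tolerance = 1e-12)
  # hence the full walk ends at zero
  inc <- ifelse(is_m, w, 0); dec <- ifelse(is_m, 0, 1 / 19)
  expect_equal(sum(inc - dec), 0, tolerance = 1e-12)
})

test_that("improving a member gene's rank never decreases an unweighted ES", {
  # with p = 1 the member weights are renormalized by the total member
  # |s| mass, so raising one member's statistic can dilute an earlier
  # member's peak; the clean monotonicity holds for the unweighted walk
  # (p = 0), where raising a member only moves its hit earlier
  set.seed(34)
  for (r in 1:20) {
    s <- stats::setNames(rnorm(15), paste0("g", 1:15))
    memb <- paste0("g", sample(15, 4))
    base <- sample_enrichment_score(s, memb, p = 0)
    if (base <= 0) next
    j <- sample(memb, 1)
    s2 <- s
    s2[j] <- max(s) + 1        # promote the member to the top rank
    expect_gte(sample_enrichment_score(s2, memb, p = 0) + 1e-12, base)
  }

  # documented p = 1 counterexample: raising the trailing member's
  # statistic dilutes the leading member's peak
  s <- c(g1 = 10, g2 = 1, g3 = 0.9, g4 = 0.8, g5 = 0.7)
  memb <- c("g1", "g5")
  hi <- sample_enrichment_score(s, memb)
  s["g5"] <- 0.75
  expect_lt(hi, 10 / 10.7 + 1e-12)
  expect_lt(sample_enrichment_score(s, memb), hi)
})

test_that("permutation normalization divides by same-sign background means", {
  lab <- make_labels(4)

  # background equal to the original scores: every cell becomes +/-1
  set.seed(40)
  st <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("g", 1:6),
                                                paste0("s", 1:4)))
  sets <- gene_set_collection(list(A = c("g1", "g2"), B = c("g4", "g6")))
  orig <- enrichment_matrix(st, sets)
  norm <- normalize_enrichment(orig, function(perm_labels) st, sets, lab,
                               n_perm = 5, seed = 1)
  expect_equal(unclass(norm), sign(unclass(orig)), ignore_attr = TRUE,
               tolerance = 1e-12)

  # explicit division rule: single-member set over 5 genes, member rank
  # position fixes the ES exactly (pos 1 -> 1, pos 2 -> 0.75); original
  # ES 1 over a constant positive background 0.75 normalizes to 4/3.
  sets1 <- gene_set_collection(list(A = "g1"))
  stat_with_g1_at <- function(pos) {
    vals <- c(5, 4, 3, 2, 1)
    s <- matrix(0, 5, 1, dimnames = list(paste0("g", 1:5), "s1"))
    s["g1", 1] <- vals[pos]
    s[paste0("g", 2:5), 1] <- vals[setdiff(1:5, pos)]
    s
  }
  orig1 <- enrichment_matrix(stat_with_g1_at(1), sets1)
  expect_equal(unclass(orig1)[1, 1], 1)
  norm1 <- normalize_enrichment(orig1,
                                function(perm_labels) stat_with_g1_at(2),
                                sets1, lab, n_perm = 2, seed = 2)
  expect_equal(unclass(norm1)[1, 1], 1 / 0.75, tolerance = 1e-12)

  # sign preservation on a random instance with noisy backgrounds
  set.seed(41)
  st2 <- matrix(rnorm(40), 10, 4,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  sets2 <- gene_set_collection(list(A = paste0("g", 1:3),
                                    B = paste0("g", 5:8)))
  orig2 <- enrichment_matrix(st2, sets2)
  norm2 <- normalize_enrichment(orig2,
                                function(perm_labels) st2 + rnorm(40, sd = 0.3),
                                sets2, lab, n_perm = 20, seed = 2)
  expect_true(all(sign(unclass(norm2)) == sign(unclass(orig2))))
  expect_true(attr(norm2, "normalized"))

  # zero original scores stay zero
  orig0 <- orig1
  orig0[1, 1] <- 0
  norm0 <- normalize_enrichment(orig0,
                                function(perm_labels) stat_with_g1_at(3),
                                sets1, lab, n_perm = 2, seed = 3)
  expect_equal(unclass(norm0)[1, 1], 0)
})
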