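# Shared fixture builders and independent oracles, all generated in code.

# small expression matrix with named genes/samples
make_expr <- function(G = 6, n = 8, seed = 1) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(G * n), G, n),
                    paste0("g", seq_len(G)), paste0("s", seq_len(n)))
}

make_labels <- function(n = 8, levels = c("C1", "C2")) {
  phenotype_labels(rep(levels, length.out = n), paste0("s", seq_len(n)),
                   class_levels = levels)
}

# brute-force full-walk enrichment oracle: explicit running sum over every
# gene, value at the first position of maximal absolute deviation
es_oracle <- function(s, members, p = 1) {
  G <- length(s)
  ord <- order(s, decreasing = TRUE, method = "radix")
  is_m <- names(s)[ord] %in% members
  m <- sum(is_m)
  w <- abs(s[ord])^p
  W <- sum(w[is_m])
  inc <- ifelse(is_m, if (W > 0) w / W else 1 / m, 0)
  inc[!is_m] <- 0
  dec <- ifelse(is_m, 0, 1 / (G - m))
  rs <- cumsum(inc - dec)
  rs[which.max(abs(rs))]
}

# full running sum of the oracle walk
es_oracle_walk <- function(s, members, p = 1) {
  G <- length(s)
  ord <- order(s, decreasing = TRUE, method = "radix")
  is_m <- names(s)[ord] %in% members
  m <- sum(is_m)
  w <- abs(s[ord])^p
  W <- sum(w[is_m])
  inc <- ifelse(is_m, if (W > 0) w / W else 1 / m, 0)
  inc[!is_m] <- 0
  dec <- ifelse(is_m, 0, 1 / (G - m))
  cumsum(inc - dec)
}

# assert that an enrichment score matches the brute-force walk; when the
# positive and negative extremes tie exactly (up to roundoff) either is an
# admissible maximal deviation, so the value must match one of them
expect_es_match <- function(value, s, members, p = 1) {
  rs <- es_oracle_walk(s, members, p)
  top <- which(abs(rs) >= max(abs(rs)) - 1e-9)
  testthat::expect_true(any(abs(value - rs[top]) < 1e-12),
                        label = sprintf("ES %.8f among walk extrema {%s}",
                                        value,
                                        paste(sprintf("%.8f", unique(rs[top])),
                                              collapse = ", ")))
}

# write a GCT file for an expression matrix (independent of the package
# writer; used to cross-check the reader)
write_gct_by_hand <- function(expr, path) {
  lines <- c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t"),
             paste(c("NAME", "Description", colnames(expr)), collapse = "\t"))
  for (i in seq_len(nrow(expr)))
    lines <- c(lines, paste(c(rownames(expr)[i], "na",
                              format(unclass(expr)[i, ], digits = 15)),
                            collapse = "\t"))
  writeLines(lines, path)
}

# PED/MAP pair for a genotype matrix given per-SNP ref/alt alleles where
# alt is the dosage-counted allele
write_ped_map_by_hand <- function(calls, ref, alt, positions, path_prefix) {
  n <- ncol(calls)
  ped <- character(n)
  for (i in seq_len(n)) {
    al <- character(0)
    for (j in seq_len(nrow(calls))) {
      g <- calls[j, i]
      al <- c(al, switch(g + 1L, c(ref[j], ref[j]), c(ref[j], alt[j]),
                         c(alt[j], alt[j])))
    }
    ped[i] <- paste(c(paste0("F", i), colnames(calls)[i], "0", "0", "1",
                      "0", al), collapse = " ")
  }
  writeLines(ped, paste0(path_prefix, ".ped"))
  writeLines(paste("1", rownames(calls), "0", positions, sep = "\t"),
             paste0(path_prefix, ".map"))
  invisible(path_prefix)
}

# matched strong-signal dataset where class separation is planted directly
# in the features feeding the models (bypasses the generative simulator)
make_strong_tasks <- function(n = 20, K = 8, informative = c(1, 2),
                              seed = 3, shift = 2) {
  set.seed(seed)
  lab <- make_labels(n)
  mk <- function() {
    es <- matrix(rnorm(n * K, sd = 0.3), n, K,
                 dimnames = list(paste0("s", seq_len(n)),
                                 paste0("set", seq_len(K))))
    es[, informative] <- es[, informative] +
      ifelse(as.integer(lab) == 1L, shift, -shift)
    es
  }
  list(expr = task_dataset(mk(), lab, "expression"),
       geno = task_dataset(mk(), lab, "genotype"), labels = lab)
}
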