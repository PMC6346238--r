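test_that("median-of-ratios size factors: closed forms and oracles", {
  # exact proportionality: second sample at 2x depth
  counts <- matrix(c(10, 30, 50, 20, 60, 100), ncol = 2,
                   dimnames = list(paste0("g", 1:3), c("A", "B")))
  sf <- normalize_counts(counts)$size_factors
  expect_equal(unname(sf["B"] / sf["A"]), 2)

  # identical samples -> all size factors exactly 1
  counts2 <- matrix(rep(c(5, 80, 300), 4), ncol = 4,
                    dimnames = list(paste0("g", 1:3), paste0("S", 1:4)))
  expect_equal(unname(normalize_counts(counts2)$size_factors),
               rep(1, 4))

  # random NB matrix vs an independently coded oracle (odd gene count so
  # the median is a single ratio and ratio-scale = log-scale median)
  set.seed(71)
  m <- matrix(rnbinom(301 * 8, mu = 50, size = 5), ncol = 8,
              dimnames = list(sprintf("g%03d", 1:301), paste0("S", 1:8)))
  keep <- apply(m > 0, 1, all)
  if (sum(keep) %% 2 == 0) keep[which(keep)[1]] <- FALSE  # force odd count
  m <- m[keep, , drop = FALSE]
  sf3 <- normalize_counts(m)$size_factors
  gm <- apply(m, 1, function(x) prod(x)^(1 / length(x)))
  oracle <- apply(m, 2, function(x) stats::median(x / gm))
  expect_equal(sf3, oracle, tolerance = 1e-9)

  # normalized log values follow the definition
  nrm <- normalize_counts(counts)
  expect_equal(nrm$log_norm, log2(sweep(counts, 2, nrm$size_factors,
                                        "/") + 1))

  zeroy <- matrix(c(0, 5, 3, 0), 2,
                  dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(normalize_counts(zeroy), "no gene has nonzero")
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(72)
  m <- matrix(rnbinom(200 * 6, mu = 40, size = 3), ncol = 6,
              dimnames = list(sprintf("g%03d", 1:200), paste0("S", 1:6)))
  sf <- normalize_counts(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(sf, ref, tolerance = 1e-10)
})

test_that("differential expression gates on LFC and significance", {
  set.seed(81)
  n <- 6
  up <- c(rnorm(n, 2, 0.05), rnorm(n, 6, 0.05))    # LFC 4 -> cluster B
  small <- c(rnorm(n, 5, 0.05), rnorm(n, 5.5, 0.05))  # LFC 0.5 -> none
  flat <- matrix(rnorm(30 * 2 * n, 5, 0.3), nrow = 30)
  m <- rbind(up, small, flat)
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("S%d", seq_len(2 * n))
  labels <- stats::setNames(rep(c("CIMP_NEG", "CIMP_POS"), each = n),
                            colnames(m))
  res <- differential_expression(m, labels)
  expect_identical(res$cluster[1], "B")
  expect_equal(res$lfc[1], mean(up[-(1:n)]) - mean(up[1:n]))
  expect_identical(res$cluster[2], "none")
  expect_lt(res$q_value[2], 0.05)                  # LFC gate did the work

  # Welch p equals the t.test oracle
  oracle <- apply(m[1:5, ], 1, function(x) {
    stats::t.test(x[labels == "CIMP_POS"], x[labels == "CIMP_NEG"])$p.value
  })
  expect_equal(res$p_value[1:5], unname(oracle), tolerance = 1e-12)

  expect_error(differential_expression(m, labels[c(1:2, 7:12)]),
               ">= 3 samples")
})

test_that("label swap negates LFC and swaps clusters A and B", {
  co <- generate_cohort(small_spec(seed = 23))
  labels <- cohort_labels(co)
  swapped <- labels
  swapped[labels == "CIMP_POS"] <- "CIMP_NEG"
  swapped[labels == "CIMP_NEG"] <- "CIMP_POS"
  ln <- normalize_counts(co$counts)$log_norm
  a <- differential_expression(ln, labels)
  b <- differential_expression(ln, swapped)
  expect_equal(b$lfc, -a$lfc)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  expect_identical(b$cluster == "A", a$cluster == "B")
  expect_identical(b$cluster == "B", a$cluster == "A")
})

test_that("promoter-expression correlation: exact linear and null cases", {
  sites <- sprintf("cg%03d", 1:4)
  samples <- sprintf("S%d", 1:10)
  set.seed(91)
  pb <- runif(10, 0.1, 0.9)
  m <- rbind(matrix(rep(pb, each = 2), nrow = 2), matrix(runif(20), 2))
  dimnames(m) <- list(sites, samples)
  ann <- toy_annotation(sites, gene = c("G1", "G1", "", ""),
                        region = c("TSS200", "5'UTR", "Body", "Body"))
  expr <- rbind(G1 = 8 - 3 * pb, G2 = runif(10, 4, 6))
  colnames(expr) <- samples
  res <- correlate_promoter_expression(BetaMatrix(m), ann, expr,
                                       genes = c("G1", "G2"))
  expect_equal(res$r[res$gene_id == "G1"], -1, tolerance = 1e-12)
  expect_identical(res$direction[res$gene_id == "G1"], "negative")
  # G2 has no promoter probes: reported missing, not dropped
  expect_identical(res$n_probes[res$gene_id == "G2"], 0L)
  expect_true(is.na(res$r[res$gene_id == "G2"]))

  # permutation null: independent expression is rarely called
  hits <- vapply(1:100, function(i) {
    expr2 <- rbind(G1 = sample(expr["G1", ]))
    colnames(expr2) <- samples
    r <- correlate_promoter_expression(BetaMatrix(m), ann, expr2,
                                       genes = "G1")
    r$direction == "ns"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  expect_error(correlate_promoter_expression(
    BetaMatrix(m[, 1:3]), ann, expr[, 1:3, drop = FALSE], genes = "G1"),
    ">= 5 samples")
})

test_that("coupled genes are detected as negatively correlated", {
  co <- generate_cohort(small_spec(seed = 29))
  ln <- normalize_counts(co$counts)$log_norm
  res <- correlate_promoter_expression(co$beta, co$annotation, ln,
                                       genes = co$truth$coupled_genes)
  expect_gte(mean(res$direction == "negative"), 0.9)
})

test_that("hypergeometric overlap matches brute-force enumeration", {
  universe <- sprintf("g%03d", 1:100)
  # complete overlap: smallest attainable p = 1 / C(100, 10)
  cluster <- universe[1:10]
  sigs <- list(full = universe[1:10], half = universe[c(1:5, 51:95)])
  res <- geneset_overlap(cluster, sigs, universe)
  expect_equal(res$p_value[res$signature == "full"], 1 / choose(100, 10),
               tolerance = 1e-12)

  # overlap at expectation (cluster 10, signature 50, overlap 5): p ~ 0.5-0.7
  p_half <- res$p_value[res$signature == "half"]
  expect_gt(p_half, 0.5)
  expect_lt(p_half, 0.7)

  # brute-force pmf summation oracle, universe <= 200
  hyper_oracle <- function(k, K, n, N) {
    sum(vapply(k:min(K, n), function(i) {
      choose(K, i) * choose(N - K, n - i) / choose(N, n)
    }, numeric(1)))
  }
  for (case in list(c(5, 50, 10, 100), c(10, 10, 10, 100),
                    c(2, 30, 15, 200), c(0, 8, 12, 60))) {
    k <- case[1]; K <- case[2]; n <- case[3]; N <- case[4]
    expect_equal(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 hyper_oracle(k, K, n, N), tolerance = 1e-10)
  }

  expect_error(geneset_overlap(cluster, list(bad = c("zzz")), universe),
               "disjoint")
  expect_error(geneset_overlap(c("zzz"), sigs, universe), "subset")
})
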