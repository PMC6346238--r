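test_that("promoter methylation is a gene-level, then sample-level mean", {
  # one gene, two promoter probes
  b <- toy_beta(matrix(c(0.2, 0.6), ncol = 1))
  ann <- toy_annotation(rownames(b), gene = "G1",
                        region = c("TSS1500", "TSS200"))
  res <- mean_promoter_methylation(b, ann)
  expect_equal(unname(res$sample_mean), 0.4)

  # two genes with unequal probe counts: gene-level averaging, the
  # 3-probe gene does not dominate
  b2 <- toy_beta(matrix(c(0.2, 0.6, 0.6, 0.6), ncol = 1))
  ann2 <- toy_annotation(rownames(b2), gene = c("G1", "G2", "G2", "G2"),
                         region = "TSS200")
  expect_equal(unname(mean_promoter_methylation(b2, ann2)$sample_mean), 0.4)

  # multi-gene probes count once per gene
  b3 <- toy_beta(matrix(c(0.1, 0.7), ncol = 1))
  ann3 <- toy_annotation(rownames(b3), gene = c("G1;G2", "G2"),
                         region = "TSS1500")
  gm <- mean_promoter_methylation(b3, ann3)$gene_means
  expect_equal(gm["G1", 1], 0.1)
  expect_equal(gm["G2", 1], 0.4)

  # non-promoter probes are excluded; empty selection errors
  ann4 <- toy_annotation(rownames(b), gene = "G1", region = "Body")
  expect_error(mean_promoter_methylation(b, ann4), "no gene has")
  expect_error(mean_promoter_methylation(b, ann, regions = character(0)),
               "empty region")
})

test_that("hyper/hypo calls compare against the reference mean", {
  m <- cbind(S = c(0.9, 0.3, 0.5), R1 = c(0.1, 0.5, 0.5),
             R2 = c(0.1, 0.5, 0.5))
  b <- toy_beta(m)
  calls <- call_hyper_hypo(b, c("R1", "R2"))
  expect_identical(calls$hyper$S, "cg001")        # 0.9 - 0.1 = 0.8 >= 0.4
  expect_identical(calls$hypo$S, character(0))    # |0.3 - 0.5| < 0.4
  expect_identical(calls$counts$n_hyper, 1L)

  # boundary: the threshold itself calls (>= / <=)
  m2 <- cbind(S = c(0.5, 0.1), R = c(0.1, 0.5))
  calls2 <- call_hyper_hypo(toy_beta(m2), "R")
  expect_identical(calls2$hyper$S, "cg001")
  expect_identical(calls2$hypo$S, "cg002")

  expect_error(call_hyper_hypo(b, "nope"), "reference sample set")
})

test_that("category enrichment matches the closed-form ratio", {
  # array: 10 sites, 4 Island; hyper: 5 sites of which 4 Island -> 2.0
  sites <- sprintf("cg%03d", 1:10)
  ann <- toy_annotation(sites,
                        island = rep(c("Island", "OpenSea"), c(4, 6)))
  calls <- structure(list(hyper = list(S1 = sites[c(1:4, 10)])),
                     class = "hyper_hypo_calls")
  enr <- category_enrichment(calls, ann, scheme = "island")
  expect_equal(enr$ratio[enr$category == "Island"], (4 / 5) / (4 / 10))
  expect_equal(enr$ratio[enr$category == "OpenSea"], (1 / 5) / (6 / 10))
  # absent category -> missing ratio
  expect_true(is.na(enr$ratio[enr$category == "Shore"]))

  # hyper distribution proportional to the array -> all present ratios 1
  calls2 <- structure(list(hyper = list(S1 = sites[c(1, 2, 5, 6, 7)])),
                      class = "hyper_hypo_calls")
  enr2 <- category_enrichment(calls2, ann, scheme = "island")
  expect_equal(enr2$ratio[enr2$category %in% c("Island", "OpenSea")],
               c(1, 1))
})

test_that("category counts partition the hyper calls", {
  co <- generate_cohort(small_spec(seed = 4))
  refs <- co$samples$sample_id[co$samples$group == "REFERENCE"]
  calls <- call_hyper_hypo(co$beta, refs)
  for (scheme in c("island", "region")) {
    enr <- category_enrichment(calls, co$annotation, scheme)
    tot <- tapply(enr$n_calls, enr$sample_id, sum)
    expect_identical(as.integer(tot[calls$counts$sample_id]),
                     calls$counts$n_hyper)
  }
})

test_that("rank-sum p-values equal the wilcox.test oracle", {
  set.seed(202)
  m <- rbind(matrix(runif(15 * 12), nrow = 15),
             matrix(sample(seq(0, 1, 0.1), 10 * 12, TRUE), nrow = 10))
  rownames(m) <- sprintf("cg%03d", 1:25)
  colnames(m) <- sprintf("S%d", 1:12)
  idx1 <- 1:5
  idx2 <- 6:12
  mine <- methcimp:::ranksum_rows(m, idx1, idx2)
  oracle <- apply(m, 1, function(x) {
    suppressWarnings(stats::wilcox.test(x[idx1], x[idx2], exact = FALSE,
                                        correct = TRUE)$p.value)
  })
  expect_equal(mine, unname(oracle), tolerance = 1e-12)
})

test_that("dm_cpgs applies both the delta and the FDR gate", {
  set.seed(7)
  n <- 10  # rank-sum + BH needs this many to clear q < 0.05
  dm_site <- c(rnorm(n, 0.9, 0.01), rnorm(n, 0.2, 0.01))
  small_site <- c(rnorm(n, 0.50, 0.005), rnorm(n, 0.45, 0.005))
  flat <- matrix(runif(40 * 2 * n), nrow = 40)
  m <- rbind(dm_site, small_site, flat)
  rownames(m) <- sprintf("cg%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("S%d", seq_len(2 * n))
  labels <- stats::setNames(rep(c("CIMP_POS", "CIMP_NEG"), each = n),
                            colnames(m))
  res <- dm_cpgs(BetaMatrix(m), labels)
  expect_true(res$dm[1])                       # |delta| = 0.7 and tiny p
  expect_false(res$dm[2])                      # delta gate fails despite p
  expect_lt(res$q_value[2], 0.05)
  expect_equal(res$delta_beta[1], mean(dm_site[1:n]) - mean(dm_site[-(1:n)]))
  expect_true(all(res$q_value >= res$p_value, na.rm = TRUE))

  expect_error(dm_cpgs(BetaMatrix(m), labels[c(1, 2, 6)]), ">= 2 samples")
})

test_that("dm_cpgs is antisymmetric under label swap", {
  co <- generate_cohort(small_spec(seed = 9, n_sites = 500, n_panel = 30,
                                   n_coupled_genes = 0))
  labels <- cohort_labels(co)
  swapped <- labels
  swapped[labels == "CIMP_POS"] <- "CIMP_NEG"
  swapped[labels == "CIMP_NEG"] <- "CIMP_POS"
  a <- dm_cpgs(co$beta, labels)
  b <- dm_cpgs(co$beta, swapped)
  expect_equal(b$delta_beta, -a$delta_beta)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  expect_identical(b$dm, a$dm)
})

test_that("hyper-call counts track the CIMP score across samples", {
  co <- generate_cohort(small_spec(seed = 13))
  refs <- co$samples$sample_id[co$samples$group == "REFERENCE"]
  calls <- call_hyper_hypo(co$beta, refs)
  sc <- cimp_score(co$beta, co$panel)
  merged <- merge(calls$counts, sc, by = "sample_id")
  expect_gt(stats::cor(merged$n_hyper, merged$score), 0.9)
})
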