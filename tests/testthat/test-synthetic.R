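test_that("generated bundle has the declared shape and bookkeeping", {
  co <- generate_cohort(synthetic_spec(n_sites = 5000, n_panel = 200,
                                       n_neg = 8, n_pos = 12, seed = 1,
                                       n_genes = 300, n_deg = 30,
                                       n_coupled_genes = 10,
                                       sites_per_coupled_gene = 2))
  expect_identical(dim(co$beta), c(5000L, 23L))  # incl. 3 reference samples
  expect_identical(sum(co$truth$labels == "CIMP_POS"), 12L)
  expect_identical(length(co$panel), 200L)
  expect_identical(nrow(co$annotation), 5000L)
  expect_setequal(co$samples$sample_id, colnames(co$beta))
  # every truth id exists in the generated objects
  expect_true(all(co$truth$dm_sites %in% rownames(co$beta)))
  expect_true(all(co$truth$deg_genes %in% rownames(co$counts)))
  expect_true(all(unlist(co$truth$coupled_sites) %in% co$panel))
  expect_identical(length(co$truth$deg_genes), 30L)
})

test_that("betas are in [0,1] and counts are non-negative integers", {
  co <- generate_cohort(small_spec(seed = 7))
  expect_true(all(co$beta >= 0 & co$beta <= 1, na.rm = TRUE))
  expect_true(all(co$counts >= 0))
  expect_true(all(co$counts == round(co$counts)))
  expect_true(all(co$qpcr$ct > 0))
})

test_that("identical spec and seed give an identical bundle", {
  a <- generate_cohort(small_spec(seed = 11))
  b <- generate_cohort(small_spec(seed = 11))
  expect_identical(unclass(a$beta), unclass(b$beta))
  expect_identical(a$counts, b$counts)
  expect_identical(a$qpcr, b$qpcr)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_spec(seed = 12))
  expect_false(identical(unclass(a$beta), unclass(c$beta)))
})

test_that("POS panel methylation is monotone in frac_panel_meth_pos", {
  mean_pos_beta <- vapply(c(0.3, 0.5, 0.8), function(f) {
    co <- generate_cohort(small_spec(seed = 3, frac_panel_meth_pos = f,
                                     n_coupled_genes = 0))
    pos <- names(co$truth$labels)[co$truth$labels == "CIMP_POS"]
    mean(unclass(co$beta)[co$panel, pos])
  }, numeric(1))
  expect_true(all(diff(mean_pos_beta) > 0))
})

test_that("POS score means recover frac_panel_meth_pos within 0.05", {
  scores <- vapply(1:20, function(s) {
    co <- generate_cohort(small_spec(seed = s))
    sc <- cimp_score(co$beta, co$panel)
    pos <- names(co$truth$labels)[co$truth$labels == "CIMP_POS"]
    mean(sc$score[sc$sample_id %in% pos])
  }, numeric(1))
  expect_lt(abs(mean(scores) - 0.70), 0.05)
})

test_that("no panel separation means chance-level classification", {
  acc <- vapply(1:10, function(s) {
    co <- generate_cohort(small_spec(seed = s, frac_panel_meth_neg = 0.4,
                                     frac_panel_meth_pos = 0.4,
                                     n_coupled_genes = 0))
    res <- cimp_classify_samples(co$beta, co$panel)
    truth <- co$truth$labels[res$sample_id]
    mean(res$label[truth != "REFERENCE"] == truth[truth != "REFERENCE"])
  }, numeric(1))
  expect_lt(abs(mean(acc) - 0.5), 0.15)
})

test_that("infeasible placements raise generation errors", {
  # panel too large a fraction of the array for a 3x island enrichment
  expect_error(generate_cohort(small_spec(seed = 1, n_sites = 600,
                                          n_panel = 300)),
               "infeasible placement")
  # more coupled-gene promoter sites than strongly de novo panel sites
  expect_error(generate_cohort(small_spec(seed = 1, n_coupled_genes = 60,
                                          sites_per_coupled_gene = 5,
                                          n_genes = 300)),
               "infeasible placement")
})

test_that("missing_rate pokes holes that downstream operations tolerate", {
  co <- generate_cohort(small_spec(seed = 5, missing_rate = 0.05))
  expect_gt(mean(is.na(co$beta)), 0.03)
  sc <- cimp_score(co$beta, co$panel)
  expect_true(all(sc$n_panel_used < length(co$panel)))
  expect_true(all(sc$score >= 0 & sc$score <= 1))
})

test_that("write_cohort writes a complete readable bundle", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_spec(seed = 2))
  write_cohort(co, dir)
  files <- c("beta.tsv", "annotation.tsv", "samples.tsv", "counts.tsv",
             "qpcr.tsv", "panel.txt", "clock.tsv", "mitotic_panel.txt",
             "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  b <- read_beta_matrix(file.path(dir, "beta.tsv"))
  expect_lt(max(abs(b - co$beta), na.rm = TRUE), 1e-12)
  expect_identical(read_cimp_panel(file.path(dir, "panel.txt")), co$panel)
})
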