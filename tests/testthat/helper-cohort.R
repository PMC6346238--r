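# shared fixtures: scaled-down cohort specs (panel fraction kept near the
# default 6.5% so the island-enrichment placement stays feasible)

small_spec <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_sites = 2000, n_panel = 130, n_neg = 8, n_pos = 12, n_ref = 3,
         n_clock_sites = 40, n_mitotic_sites = 40,
         n_genes = 300, n_deg = 30, n_coupled_genes = 10,
         sites_per_coupled_gene = 2, seed = seed),
    list(...))
  do.call(synthetic_spec, args)
}

toy_beta <- function(values, sites = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- sites %||% rownames(m) %||%
    sprintf("cg%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||%
    sprintf("S%d", seq_len(ncol(m)))
  BetaMatrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_annotation <- function(site_ids, gene = "", region = "Body",
                           island = "OpenSea") {
  data.frame(site_id = site_ids, chromosome = "chr1",
             position = seq_along(site_ids), gene = gene,
             region_category = region, island_category = island,
             stringsAsFactors = FALSE)
}

cohort_labels <- function(cohort) {
  stats::setNames(cohort$samples$group, cohort$samples$sample_id)
}
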