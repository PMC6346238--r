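#' Synthetic cohort specification
#'
#' Declares the stated world the generator emulates: two T-ALL-like sample
#' groups differing in the fraction of methylated CIMP-panel CpGs (defaults
#' 0.20 vs 0.70), de novo hypermethylation enriched in CpG-island / TSS200
#' categories for the positive group, age-correlated clock CpGs, mitotic-clock
#' CpGs with group-shifted means (0.27 vs 0.64), negative-binomial counts with
#' promoter-methylation-coupled expression for a designated gene subset, and
#' qPCR Ct values derived from known true relative telomere lengths (group
#' medians 1.13 vs 0.85). Sample counts default to the study scale: 25
#' CIMP-negative, 40 CIMP-positive, 3 CD34+-like reference samples.
#'
#' Panel methylation is nested: every sample methylates the lowest-ranked
#' panel sites up to a per-sample `Binomial(n_panel, frac_group)` count, so a
#' high-CIMP sample's methylated set contains a low-CIMP sample's. This
#' mirrors the coordinated, ratchet-like accumulation of CIMP
#' hypermethylation and gives every panel site a closed-form true group
#' difference (recorded in the ground truth).
#'
#' @param n_sites total CpG sites on the synthetic array.
#' @param n_panel CIMP panel size (study panel: 1293).
#' @param n_neg,n_pos,n_ref samples per group (reference = sorted CD34+-like).
#' @param frac_panel_meth_neg,frac_panel_meth_pos expected fraction of
#'   methylated panel sites per group.
#' @param beta_lo,beta_hi Beta-distribution shape pairs for the unmethylated
#'   (mean 0.10) and methylated (mean 0.85) states.
#' @param island_enrichment multiplier by which panel (de novo-methylatable)
#'   sites are enriched in Island and TSS200 categories relative to the array.
#' @param n_clock_sites,clock_slope,clock_noise_sd age-clock CpGs follow
#'   `beta = clip(base + clock_slope * age + noise, 0, 1)`.
#' @param n_mitotic_sites,mitotic_mean_neg,mitotic_mean_pos,mitotic_sample_sd,mitotic_concentration
#'   mitotic-clock CpGs: per-sample mean = group mean + Normal(0, sample sd),
#'   per-site betas Beta-distributed around it with the given concentration.
#' @param n_genes,n_deg,lfc_effect,nb_dispersion expression model: log2
#'   baseline per gene, designated DEG genes shifted by `lfc_effect` (signed)
#'   in the positive group, negative-binomial counts.
#' @param n_coupled_genes,coupling_strength,sites_per_coupled_gene genes whose
#'   log2 expression decreases by `coupling_strength` x mean promoter beta.
#' @param rtl_neg_median,rtl_pos_median,rtl_sdlog true relative telomere
#'   length is log-normal around the group median.
#' @param qpcr_replicates,qpcr_noise_sd,qpcr_efficiency_t,qpcr_efficiency_s
#'   qPCR model: `Ct = base - log(quantity)/log(E) + Normal(0, noise)`.
#' @param age_range chronological age range in years (uniform).
#' @param background_meth_rate fraction of non-panel sites constitutively
#'   methylated (same state in all samples).
#' @param missing_rate fraction of beta cells set missing at random.
#' @param dm_delta_truth delta-beta magnitude above which a panel site's true
#'   group difference puts it in the ground-truth DM set.
#' @param seed integer random seed.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_sites = 20000, n_panel = 1293,
                           n_neg = 25, n_pos = 40, n_ref = 3,
                           frac_panel_meth_neg = 0.20,
                           frac_panel_meth_pos = 0.70,
                           beta_lo = c(2, 18), beta_hi = c(17, 3),
                           island_enrichment = 3.0,
                           n_clock_sites = 100, clock_slope = 0.02,
                           clock_noise_sd = 0.01,
                           n_mitotic_sites = 100,
                           mitotic_mean_neg = 0.27, mitotic_mean_pos = 0.64,
                           mitotic_sample_sd = 0.09,
                           mitotic_concentration = 30,
                           n_genes = 2000, n_deg = 100, lfc_effect = 2.0,
                           nb_dispersion = 0.1,
                           n_coupled_genes = 50, coupling_strength = 3.0,
                           sites_per_coupled_gene = 3,
                           rtl_neg_median = 1.13, rtl_pos_median = 0.85,
                           rtl_sdlog = 0.4,
                           qpcr_replicates = 3, qpcr_noise_sd = 0.05,
                           qpcr_efficiency_t = 2.0, qpcr_efficiency_s = 2.0,
                           age_range = c(1, 16),
                           background_meth_rate = 0.35,
                           missing_rate = 0,
                           dm_delta_truth = 0.4,
                           seed = 1) {
  spec <- as.list(environment())
  validate_synthetic_spec(spec)
  class(spec) <- "synthetic_spec"
  spec
}

validate_synthetic_spec <- function(spec) {
  counts <- c("n_sites", "n_panel", "n_neg", "n_pos", "n_clock_sites",
              "n_mitotic_sites", "n_genes", "qpcr_replicates")
  for (f in counts) {
    if (spec[[f]] < 1L) stop("spec: '", f, "' must be positive",
                             call. = FALSE)
  }
  if (spec$n_ref < 0L || spec$n_deg < 0L || spec$n_coupled_genes < 0L) {
    stop("spec: counts must be non-negative", call. = FALSE)
  }
  for (f in c("frac_panel_meth_neg", "frac_panel_meth_pos",
              "mitotic_mean_neg", "mitotic_mean_pos",
              "background_meth_rate", "missing_rate")) {
    assert_fraction(spec[[f]], f)
  }
  if (spec$n_panel > spec$n_sites) {
    stop("spec: n_panel must be <= n_sites", call. = FALSE)
  }
  if (spec$n_panel + spec$n_clock_sites + spec$n_mitotic_sites >
      spec$n_sites) {
    stop("spec: panel + clock + mitotic sites exceed n_sites", call. = FALSE)
  }
  if (any(c(spec$beta_lo, spec$beta_hi) <= 0)) {
    stop("spec: Beta shape parameters must be > 0", call. = FALSE)
  }
  if (spec$n_deg + spec$n_coupled_genes > spec$n_genes) {
    stop("spec: n_deg + n_coupled_genes exceed n_genes", call. = FALSE)
  }
  invisible(spec)
}

# base array category frequencies for sites outside the CIMP panel; island
# base of 0.25 (vs ~0.31 on the real platform) keeps a 3x island enrichment
# of the panel feasible at the default panel fraction
BASE_ISLAND_PROBS <- c(Island = 0.25, Shore = 0.23, Shelf = 0.12,
                       OpenSea = 0.40)
BASE_REGION_PROBS <- c(TSS1500 = 0.13, TSS200 = 0.10, "5'UTR" = 0.12,
                       "1stExon" = 0.07, Body = 0.34, "3'UTR" = 0.04,
                       Intergenic = 0.20)

# probability of the boosted category among panel sites such that the
# realized array-wide enrichment ratio equals `enrich`:
#   p_panel / (f * p_panel + (1 - f) * p0) = enrich
solve_panel_prob <- function(p0, enrich, panel_frac) {
  denom <- 1 - enrich * panel_frac
  if (denom <= 0) {
    stop("infeasible placement: panel fraction too large for requested ",
         "enrichment", call. = FALSE)
  }
  p <- enrich * (1 - panel_frac) * p0 / denom
  if (p > 1) {
    stop(sprintf(
      "infeasible placement: enrichment %.2f requires category probability %.3f > 1 among panel sites",
      enrich, p), call. = FALSE)
  }
  p
}

rbeta_state <- function(state, lo, hi) {
  n <- length(state)
  stats::rbeta(n, ifelse(state, hi[1], lo[1]), ifelse(state, hi[2], lo[2]))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws a full analysis bundle from a [synthetic_spec()]: beta matrix, CpG
#' annotation, sample sheet, gene count matrix (diagnostic samples only),
#' qPCR Ct table, CIMP panel, a matched synthetic age clock and mitotic
#' panel, and a `truth` list recording everything the generator knows
#' (labels, true per-site group deltas and the DM set, ages, per-sample
#' mitotic means, signed DEG effects, coupled genes, true relative telomere
#' lengths). Identical spec (including seed) gives an identical bundle.
#'
#' @param spec a [synthetic_spec()].
#' @return a list of class `cimp_cohort` with elements `beta`, `annotation`,
#'   `samples`, `counts`, `qpcr`, `panel`, `clock`, `mitotic_panel`, `truth`,
#'   `spec`.
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_sites = 2000, n_panel = 200,
#'   n_neg = 6, n_pos = 8, n_genes = 300, n_deg = 20, n_coupled_genes = 10,
#'   seed = 1))
#' dim(cohort$beta)
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  validate_synthetic_spec(spec)
  set.seed(spec$seed)

  n_samp <- spec$n_neg + spec$n_pos + spec$n_ref
  sample_ids <- c(sprintf("NEG%02d", seq_len(spec$n_neg)),
                  sprintf("POS%02d", seq_len(spec$n_pos)),
                  if (spec$n_ref > 0) sprintf("REF%d", seq_len(spec$n_ref)))
  group <- c(rep("CIMP_NEG", spec$n_neg), rep("CIMP_POS", spec$n_pos),
             rep("REFERENCE", spec$n_ref))
  names(group) <- sample_ids
  diag_ids <- sample_ids[group != "REFERENCE"]

  site_ids <- sprintf("cg%07d", seq_len(spec$n_sites))
  idx <- sample.int(spec$n_sites)
  panel_sites <- site_ids[idx[seq_len(spec$n_panel)]]
  clock_sites <- site_ids[idx[spec$n_panel + seq_len(spec$n_clock_sites)]]
  mitotic_sites <- site_ids[idx[spec$n_panel + spec$n_clock_sites +
                                seq_len(spec$n_mitotic_sites)]]
  bg_sites <- setdiff(site_ids, c(panel_sites, clock_sites, mitotic_sites))

  ## ---- sample-level covariates ------------------------------------------
  age <- round(stats::runif(n_samp, spec$age_range[1], spec$age_range[2]), 1)
  names(age) <- sample_ids
  sex <- sample(c("F", "M"), n_samp, replace = TRUE)

  ## ---- panel betas: nested binomial methylation -------------------------
  rank_of <- sample.int(spec$n_panel)          # site -> methylation rank
  names(rank_of) <- panel_sites
  frac <- c(CIMP_NEG = spec$frac_panel_meth_neg,
            CIMP_POS = spec$frac_panel_meth_pos, REFERENCE = 0)
  k <- vapply(group, function(g) {
    if (g == "REFERENCE") 0L else stats::rbinom(1L, spec$n_panel, frac[[g]])
  }, integer(1))
  panel_state <- outer(rank_of, k, `<=`)       # n_panel x n_samp logical
  panel_beta <- matrix(
    rbeta_state(panel_state, spec$beta_lo, spec$beta_hi),
    nrow = spec$n_panel, dimnames = list(panel_sites, sample_ids))

  ## ---- background betas: fixed per-site state ---------------------------
  bg_state <- stats::rbinom(length(bg_sites), 1L,
                            spec$background_meth_rate) == 1L
  bg_beta <- matrix(
    rbeta_state(rep(bg_state, times = n_samp), spec$beta_lo, spec$beta_hi),
    nrow = length(bg_sites), dimnames = list(bg_sites, sample_ids))

  ## ---- age-clock betas --------------------------------------------------
  clock_base <- stats::runif(spec$n_clock_sites, 0.1, 0.5)
  clock_beta <- outer(clock_base, rep(1, n_samp)) +
    outer(rep(spec$clock_slope, spec$n_clock_sites), age) +
    matrix(stats::rnorm(spec$n_clock_sites * n_samp, 0, spec$clock_noise_sd),
           nrow = spec$n_clock_sites)
  clock_beta <- pmin(pmax(clock_beta, 0), 1)
  dimnames(clock_beta) <- list(clock_sites, sample_ids)

  ## ---- mitotic betas ----------------------------------------------------
  mit_group_mean <- c(CIMP_NEG = spec$mitotic_mean_neg,
                      CIMP_POS = spec$mitotic_mean_pos, REFERENCE = 0.10)
  mit_mu <- pmin(pmax(mit_group_mean[group] +
                      stats::rnorm(n_samp, 0, spec$mitotic_sample_sd),
                      0.02), 0.98)
  names(mit_mu) <- sample_ids
  kappa <- spec$mitotic_concentration
  mit_beta <- matrix(
    stats::rbeta(spec$n_mitotic_sites * n_samp,
                 rep(mit_mu, each = spec$n_mitotic_sites) * kappa,
                 rep(1 - mit_mu, each = spec$n_mitotic_sites) * kappa),
    nrow = spec$n_mitotic_sites, dimnames = list(mitotic_sites, sample_ids))

  beta <- rbind(panel_beta, bg_beta, clock_beta, mit_beta)[site_ids, ,
                                                           drop = FALSE]
  if (spec$missing_rate > 0) {
    nav <- stats::runif(length(beta)) < spec$missing_rate
    beta[nav] <- NA_real_
  }
  beta <- BetaMatrix(beta)

  ## ---- annotation -------------------------------------------------------
  panel_frac <- spec$n_panel / spec$n_sites
  p_isl_panel <- solve_panel_prob(BASE_ISLAND_PROBS[["Island"]],
                                  spec$island_enrichment, panel_frac)
  isl_panel_probs <- c(Island = p_isl_panel,
                       BASE_ISLAND_PROBS[-1] /
                         sum(BASE_ISLAND_PROBS[-1]) * (1 - p_isl_panel))
  p_tss_panel <- solve_panel_prob(BASE_REGION_PROBS[["TSS200"]],
                                  spec$island_enrichment, panel_frac)
  reg_rest <- BASE_REGION_PROBS[names(BASE_REGION_PROBS) != "TSS200"]
  reg_panel_probs <- c(TSS200 = p_tss_panel,
                       reg_rest / sum(reg_rest) * (1 - p_tss_panel))

  island_cat <- character(spec$n_sites)
  names(island_cat) <- site_ids
  region_cat <- island_cat
  is_panel <- site_ids %in% panel_sites
  island_cat[is_panel] <- sample(names(isl_panel_probs), sum(is_panel),
                                 replace = TRUE, prob = isl_panel_probs)
  island_cat[!is_panel] <- sample(names(BASE_ISLAND_PROBS), sum(!is_panel),
                                  replace = TRUE, prob = BASE_ISLAND_PROBS)
  region_cat[is_panel] <- sample(names(reg_panel_probs), sum(is_panel),
                                 replace = TRUE, prob = reg_panel_probs)
  region_cat[!is_panel] <- sample(names(BASE_REGION_PROBS), sum(!is_panel),
                                  replace = TRUE, prob = BASE_REGION_PROBS)

  ## ---- truth: closed-form per-site group deltas -------------------------
  mu_lo <- spec$beta_lo[1] / sum(spec$beta_lo)
  mu_hi <- spec$beta_hi[1] / sum(spec$beta_hi)
  p_meth <- function(f) stats::pbinom(rank_of - 1L, spec$n_panel, f,
                                      lower.tail = FALSE)
  true_delta <- (p_meth(spec$frac_panel_meth_pos) -
                 p_meth(spec$frac_panel_meth_neg)) * (mu_hi - mu_lo)
  dm_sites <- panel_sites[abs(true_delta) > spec$dm_delta_truth]

  ## ---- gene assignment --------------------------------------------------
  gene_ids <- sprintf("GENE%04d", seq_len(spec$n_genes))
  coupled_genes <- if (spec$n_coupled_genes > 0) {
    sample(gene_ids, spec$n_coupled_genes)
  } else character(0)
  # strongly de novo panel sites carry the coupled genes' promoters
  strong <- panel_sites[p_meth(spec$frac_panel_meth_pos) >= 0.95 &
                        p_meth(spec$frac_panel_meth_neg) <= 0.05]
  need <- spec$n_coupled_genes * spec$sites_per_coupled_gene
  if (need > length(strong)) {
    stop(sprintf(
      "infeasible placement: %d promoter sites needed for coupled genes but only %d strongly de novo panel sites available",
      need, length(strong)), call. = FALSE)
  }
  gene_of <- stats::setNames(rep("", spec$n_sites), site_ids)
  coupled_site_list <- list()
  if (need > 0) {
    picked <- sample(strong, need)
    coupled_site_list <- split(picked,
                               rep(coupled_genes,
                                   each = spec$sites_per_coupled_gene))
    gene_of[picked] <- rep(coupled_genes,
                           each = spec$sites_per_coupled_gene)
    region_cat[picked] <- "TSS200"
  }
  other_genic <- site_ids[region_cat != "Intergenic" & gene_of == ""]
  pool <- setdiff(gene_ids, coupled_genes)
  gene_of[other_genic] <- sample(pool, length(other_genic), replace = TRUE)
  region_cat[gene_of == "" & region_cat != "Intergenic"] <- "Intergenic"

  annotation <- validate_annotation(data.frame(
    site_id = site_ids,
    chromosome = paste0("chr", sample(1:22, spec$n_sites, replace = TRUE)),
    position = sample.int(1e8L, spec$n_sites, replace = TRUE),
    gene = unname(gene_of),
    region_category = unname(region_cat),
    island_category = unname(island_cat),
    stringsAsFactors = FALSE))

  ## ---- expression -------------------------------------------------------
  base_log2 <- stats::setNames(stats::runif(spec$n_genes, 3, 9), gene_ids)
  deg_genes <- if (spec$n_deg > 0) {
    sample(setdiff(gene_ids, coupled_genes), spec$n_deg)
  } else character(0)
  deg_sign <- stats::setNames(
    sample(c(-1, 1), length(deg_genes), replace = TRUE), deg_genes)
  log2mu <- matrix(rep(base_log2, times = length(diag_ids)),
                   nrow = spec$n_genes,
                   dimnames = list(gene_ids, diag_ids))
  pos_diag <- group[diag_ids] == "CIMP_POS"
  if (length(deg_genes)) {
    log2mu[deg_genes, pos_diag] <- log2mu[deg_genes, pos_diag] +
      deg_sign * spec$lfc_effect
  }
  for (g in names(coupled_site_list)) {
    prom <- colMeans(unclass(beta)[coupled_site_list[[g]], diag_ids,
                                   drop = FALSE], na.rm = TRUE)
    prom[!is.finite(prom)] <- 0.5  # all promoter probes missing
    log2mu[g, ] <- base_log2[[g]] + spec$coupling_strength * 0.5 -
      spec$coupling_strength * prom
  }
  depth <- stats::setNames(stats::runif(length(diag_ids), 0.5, 1.5),
                           diag_ids)
  counts <- matrix(
    stats::rnbinom(spec$n_genes * length(diag_ids),
                   mu = 2^log2mu * rep(depth, each = spec$n_genes),
                   size = 1 / spec$nb_dispersion),
    nrow = spec$n_genes, dimnames = list(gene_ids, diag_ids))

  ## ---- telomere qPCR ----------------------------------------------------
  rtl_med <- c(CIMP_NEG = spec$rtl_neg_median, CIMP_POS = spec$rtl_pos_median,
               REFERENCE = 1.0)
  rtl_true <- stats::setNames(
    stats::rlnorm(n_samp, log(rtl_med[group]), spec$rtl_sdlog), sample_ids)
  calibrator <- if (spec$n_ref > 0) "REF1" else sample_ids[1]
  rtl_true[calibrator] <- 1.0
  qpcr_ids <- unique(c(diag_ids, calibrator))
  amount <- stats::setNames(stats::rlnorm(length(qpcr_ids), 0, 0.3),
                            qpcr_ids)
  reps <- spec$qpcr_replicates
  mk_ct <- function(base, quantity, eff) {
    rep(base - log(quantity) / log(eff), each = reps) +
      stats::rnorm(length(quantity) * reps, 0, spec$qpcr_noise_sd)
  }
  qpcr <- rbind(
    data.frame(sample_id = rep(qpcr_ids, each = reps), assay = "T",
               replicate = rep(seq_len(reps), length(qpcr_ids)),
               ct = mk_ct(20, amount * rtl_true[qpcr_ids],
                          spec$qpcr_efficiency_t)),
    data.frame(sample_id = rep(qpcr_ids, each = reps), assay = "S",
               replicate = rep(seq_len(reps), length(qpcr_ids)),
               ct = mk_ct(22, amount, spec$qpcr_efficiency_s)))

  ## ---- matched synthetic age clock --------------------------------------
  w <- 1 / (spec$n_clock_sites * spec$clock_slope)
  clock <- clock_model(name = "synthetic_linear_clock",
                       intercept = -sum(clock_base) * w,
                       coefficients = stats::setNames(
                         rep(w, spec$n_clock_sites), clock_sites),
                       transform = "identity")

  samples <- data.frame(sample_id = sample_ids, group = unname(group),
                        chronological_age = unname(age), sex = sex,
                        stringsAsFactors = FALSE)

  truth <- list(labels = group,
                dm_sites = dm_sites,
                denovo_sites = dm_sites,
                true_delta = stats::setNames(true_delta, panel_sites),
                ages = age,
                mitotic_mean = mit_mu,
                deg_genes = deg_genes,
                deg_sign = deg_sign,
                coupled_genes = coupled_genes,
                coupled_sites = coupled_site_list,
                rtl = rtl_true,
                calibrator_sample = calibrator)

  structure(list(beta = beta, annotation = annotation, samples = samples,
                 counts = counts, qpcr = qpcr, panel = panel_sites,
                 clock = clock, mitotic_panel = mitotic_sites,
                 truth = truth, spec = spec),
            class = "cimp_cohort")
}

#' @export
print.cimp_cohort <- function(x, ...) {
  cat(sprintf(
    "cimp_cohort: %d CpG sites x %d samples (%d NEG / %d POS / %d REF), %d genes, panel %d\n",
    nrow(x$beta), ncol(x$beta), x$spec$n_neg, x$spec$n_pos, x$spec$n_ref,
    nrow(x$counts), length(x$panel)))
  invisible(x)
}

#' Write a synthetic cohort bundle as plain-text tables
#'
#' Writes `beta.tsv`, `annotation.tsv`, `samples.tsv`, `counts.tsv`,
#' `qpcr.tsv`, `panel.txt`, `clock.tsv`, `mitotic_panel.txt` and
#' `truth.json` under `dir`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @param delimiter field delimiter for the tables.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, delimiter = "\t") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_beta_matrix(cohort$beta, fp("beta.tsv"), delimiter)
  write_annotation(cohort$annotation, fp("annotation.tsv"), delimiter)
  write_sample_sheet(cohort$samples, fp("samples.tsv"), delimiter)
  write_tsv(data.frame(gene_id = rownames(cohort$counts),
                       as.data.frame(cohort$counts, check.names = FALSE),
                       check.names = FALSE), fp("counts.tsv"), delimiter)
  write_tsv(cohort$qpcr, fp("qpcr.tsv"), delimiter)
  write_cimp_panel(cohort$panel, fp("panel.txt"))
  write_clock_model(cohort$clock, fp("clock.tsv"))
  write_cimp_panel(cohort$mitotic_panel, fp("mitotic_panel.txt"))
  truth <- cohort$truth
  truth$true_delta <- as.list(truth$true_delta)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
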