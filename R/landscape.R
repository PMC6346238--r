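#' Mean promoter methylation per sample
#'
#' Two-stage mean: for every gene, the mean beta over its promoter-region
#' CpGs (default regions `TSS1500` and `TSS200`, i.e. up to 1500 bp upstream
#' of the transcription start site); the per-sample value is the unweighted
#' mean over all genes with data, so genes with many probes do not dominate.
#' Sites annotated to several genes contribute once per gene.
#'
#' @param beta a [BetaMatrix].
#' @param ann CpG annotation (see [validate_annotation()]).
#' @param regions region categories counted as promoter.
#' @return list with `sample_mean` (named numeric vector) and `gene_means`
#'   (genes x samples matrix).
#' @export
mean_promoter_methylation <- function(beta, ann,
                                      regions = c("TSS1500", "TSS200")) {
  if (!length(regions)) stop("empty region selection", call. = FALSE)
  stopifnot(all(regions %in% REGION_CATEGORIES))
  ann <- validate_annotation(ann)
  long <- expand_gene_annotation(ann[ann$region_category %in% regions, ,
                                     drop = FALSE])
  long <- long[long$site_id %in% rownames(beta), , drop = FALSE]
  if (!nrow(long)) {
    stop("no gene has a promoter CpG in the selected regions", call. = FALSE)
  }
  m <- unclass(beta)[long$site_id, , drop = FALSE]
  gene_means <- rowsum_mean(m, long$gene)
  list(sample_mean = colMeans(gene_means, na.rm = TRUE),
       gene_means = gene_means)
}

# group-wise column means of a matrix by a row grouping factor, NA-aware
rowsum_mean <- function(m, f) {
  f <- as.factor(f)
  sums <- rowsum(ifelse(is.na(m), 0, m), f)
  ns <- rowsum((!is.na(m)) + 0, f)
  out <- sums / ns
  out[ns == 0] <- NA_real_
  out
}

#' Hyper- and hypomethylation calls against a reference
#'
#' A site is hypermethylated in a sample when its beta exceeds the mean
#' reference beta by at least `delta_threshold`, hypomethylated when it falls
#' below by at least the same margin. The reference is typically a set of
#' sorted normal CD34+ samples.
#'
#' @param beta a [BetaMatrix] containing both test and reference samples (or
#'   at least the reference sites).
#' @param reference_samples character vector of reference sample ids.
#' @param delta_threshold beta difference threshold (default 0.4).
#' @param samples samples to call; defaults to all non-reference samples.
#' @return object of class `hyper_hypo_calls`: list with `hyper` and `hypo`
#'   (named lists of site-id vectors per sample), `counts` data.frame and the
#'   threshold used.
#' @export
call_hyper_hypo <- function(beta, reference_samples, delta_threshold = 0.4,
                            samples = NULL) {
  assert_fraction(delta_threshold, "delta_threshold")
  refs <- intersect(reference_samples, colnames(beta))
  if (!length(refs)) {
    stop("reference sample set is empty or disjoint from the matrix",
         call. = FALSE)
  }
  if (is.null(samples)) samples <- setdiff(colnames(beta), refs)
  stopifnot(all(samples %in% colnames(beta)))
  m <- unclass(beta)
  ref_mean <- rowMeans(m[, refs, drop = FALSE], na.rm = TRUE)
  delta <- m[, samples, drop = FALSE] - ref_mean
  hyper <- apply(delta, 2, function(d) {
    rownames(m)[!is.na(d) & d >= delta_threshold]
  }, simplify = FALSE)
  hypo <- apply(delta, 2, function(d) {
    rownames(m)[!is.na(d) & d <= -delta_threshold]
  }, simplify = FALSE)
  structure(list(hyper = hyper, hypo = hypo,
                 counts = data.frame(sample_id = samples,
                                     n_hyper = lengths(hyper),
                                     n_hypo = lengths(hypo),
                                     row.names = NULL),
                 delta_threshold = delta_threshold,
                 reference_samples = refs),
            class = "hyper_hypo_calls")
}

#' Category enrichment of hypermethylated CpGs
#'
#' For each sample and category c:
#' `ratio(c) = (#hyper in c / #hyper) / (#array sites in c / #array sites)`,
#' i.e. the representation of the category among a sample's hypermethylated
#' sites relative to its representation on the array. A uniform draw from
#' the array gives ratio 1 in every category. Categories absent from the
#' array are reported as missing.
#'
#' @param calls a [call_hyper_hypo()] result.
#' @param ann CpG annotation.
#' @param scheme `"region"` or `"island"`.
#' @param which use `"hyper"` (default) or `"hypo"` calls.
#' @return data.frame `sample_id`, `category`, `n_calls`, `ratio`.
#' @export
category_enrichment <- function(calls, ann, scheme = c("island", "region"),
                                which = c("hyper", "hypo")) {
  scheme <- match.arg(scheme)
  which <- match.arg(which)
  sets <- calls[[which]]
  if (!length(sets)) stop("no calls to summarize", call. = FALSE)
  ann <- validate_annotation(ann)
  col <- if (scheme == "island") "island_category" else "region_category"
  cats <- if (scheme == "island") ISLAND_CATEGORIES else REGION_CATEGORIES
  site_cat <- stats::setNames(ann[[col]], ann$site_id)
  array_tab <- table(factor(site_cat, levels = cats))
  array_frac <- as.numeric(array_tab) / sum(array_tab)
  names(array_frac) <- cats
  res <- lapply(names(sets), function(s) {
    sites <- intersect(sets[[s]], names(site_cat))
    tab <- table(factor(site_cat[sites], levels = cats))
    frac <- if (length(sites)) as.numeric(tab) / length(sites) else
      rep(NA_real_, length(cats))
    ratio <- ifelse(array_frac > 0, frac / array_frac, NA_real_)
    data.frame(sample_id = s, category = cats,
               n_calls = as.integer(tab), ratio = as.numeric(ratio),
               row.names = NULL)
  })
  do.call(rbind, res)
}

#' Group summary of enrichment ratios (median and SD)
#'
#' @param enrichment a [category_enrichment()] table.
#' @param labels named character vector mapping sample id to group.
#' @return data.frame `group`, `category`, `median_ratio`, `sd_ratio`.
#' @export
summarize_enrichment <- function(enrichment, labels) {
  enrichment$group <- labels[enrichment$sample_id]
  agg <- stats::aggregate(ratio ~ group + category, data = enrichment,
                          FUN = function(x) c(median = stats::median(x),
                                              sd = stats::sd(x)),
                          na.action = stats::na.omit)
  data.frame(group = agg$group, category = agg$category,
             median_ratio = agg$ratio[, "median"],
             sd_ratio = agg$ratio[, "sd"], row.names = NULL)
}

# vectorized two-sided Wilcoxon rank-sum p-values (normal approximation with
# tie correction and continuity correction), one test per matrix row;
# equivalent to stats::wilcox.test(exact = FALSE, correct = TRUE)
ranksum_rows <- function(m, idx1, idx2) {
  vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, idx1]
    y <- m[i, idx2]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    n1 <- length(x)
    n2 <- length(y)
    if (n1 < 1L || n2 < 1L) return(NA_real_)
    r <- rank(c(x, y))
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    nt <- n1 + n2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sig2 <= 0) return(1)
    z <- w - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sig2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }, numeric(1))
}

#' Differentially methylated CpG identification
#'
#' Per site: group mean betas, `delta_beta = mean(CIMP_POS) - mean(CIMP_NEG)`,
#' a two-sided Wilcoxon rank-sum p-value, Benjamini-Hochberg q, and a DM flag
#' requiring both `|delta_beta| > dm_delta` (default 0.4) and `q < fdr_alpha`
#' (default 0.05). Missing betas are excluded pairwise.
#'
#' @param beta a [BetaMatrix].
#' @param labels named character vector (or factor) assigning each sample id
#'   to `CIMP_POS` / `CIMP_NEG`; other labels are ignored.
#' @param dm_delta delta-beta magnitude gate.
#' @param fdr_alpha FDR significance gate.
#' @return data.frame `site_id`, `mean_neg`, `mean_pos`, `delta_beta`,
#'   `p_value`, `q_value`, `dm`.
#' @export
dm_cpgs <- function(beta, labels, dm_delta = 0.4, fdr_alpha = 0.05) {
  assert_fraction(dm_delta, "dm_delta")
  assert_fraction(fdr_alpha, "fdr_alpha")
  labels <- labels[intersect(names(labels), colnames(beta))]
  neg <- names(labels)[labels == "CIMP_NEG"]
  pos <- names(labels)[labels == "CIMP_POS"]
  if (length(neg) < 2L || length(pos) < 2L) {
    stop("each CIMP group needs >= 2 samples", call. = FALSE)
  }
  m <- unclass(beta)
  mean_neg <- rowMeans(m[, neg, drop = FALSE], na.rm = TRUE)
  mean_pos <- rowMeans(m[, pos, drop = FALSE], na.rm = TRUE)
  p <- ranksum_rows(m, match(pos, colnames(m)), match(neg, colnames(m)))
  q <- bh_adjust(p)
  delta <- mean_pos - mean_neg
  data.frame(site_id = rownames(m),
             mean_neg = mean_neg, mean_pos = mean_pos,
             delta_beta = delta, p_value = p, q_value = q,
             dm = !is.na(q) & abs(delta) > dm_delta & q < fdr_alpha,
             row.names = NULL)
}
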