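#' Read a gene count matrix
#'
#' First column gene ids, header row sample ids, non-negative integer body.
#'
#' @param path file path; @param delimiter field delimiter.
#' @return integer matrix, genes x samples.
#' @export
read_count_matrix <- function(path, delimiter = "\t") {
  df <- read_tsv(path, delimiter)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  m
}

#' Median-of-ratios normalization
#'
#' Size factor of a sample: the median across genes of its counts divided by
#' the per-gene geometric mean, using only genes with nonzero counts in
#' every sample (the standard median-of-ratios estimator). Normalized
#' log values are `log2(count / size_factor + 1)`.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @return list with `size_factors` (named, geometric mean 1-scaled as
#'   estimated), `log_norm` (matrix of normalized log2 values) and
#'   `norm_counts`.
#' @export
normalize_counts <- function(counts) {
  if (ncol(counts) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  all_nz <- rowSums(counts == 0) == 0L
  if (!any(all_nz)) {
    stop("no gene has nonzero counts in all samples; consider a ",
         "pseudo-reference fallback on filtered data", call. = FALSE)
  }
  logc <- log(counts[all_nz, , drop = FALSE])
  log_gm <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(stats::median(x - log_gm)))
  norm <- sweep(counts, 2, sf, "/")
  list(size_factors = sf,
       log_norm = log2(norm + 1),
       norm_counts = norm)
}

#' Differential expression between CIMP groups
#'
#' Per gene: log2 fold change `LFC = mean log2 normalized (CIMP_POS) -
#' mean (CIMP_NEG)` (the CIMP-negative group is the reference), a Welch
#' two-sample t-test on the normalized log values, Benjamini-Hochberg q.
#' Cluster A: `LFC < -lfc_threshold` and `q < fdr_alpha` (higher in
#' CIMP-negative); cluster B: `LFC > lfc_threshold` and `q < fdr_alpha`.
#'
#' @param log_norm matrix of normalized log2 expression (genes x samples),
#'   e.g. `normalize_counts(...)$log_norm`.
#' @param labels named vector assigning sample ids to `CIMP_POS` /
#'   `CIMP_NEG`; other labels ignored.
#' @param lfc_threshold absolute LFC gate (default 1).
#' @param fdr_alpha FDR gate (default 0.05).
#' @return data.frame `gene_id`, `mean_neg`, `mean_pos`, `lfc`, `p_value`,
#'   `q_value`, `cluster` (`A`/`B`/`none`).
#' @export
differential_expression <- function(log_norm, labels, lfc_threshold = 1.0,
                                    fdr_alpha = 0.05) {
  labels <- labels[intersect(names(labels), colnames(log_norm))]
  neg <- names(labels)[labels == "CIMP_NEG"]
  pos <- names(labels)[labels == "CIMP_POS"]
  if (length(neg) < 3L || length(pos) < 3L) {
    stop("each CIMP group needs >= 3 samples", call. = FALSE)
  }
  xn <- log_norm[, neg, drop = FALSE]
  xp <- log_norm[, pos, drop = FALSE]
  mn <- rowMeans(xn)
  mp <- rowMeans(xp)
  vn <- apply(xn, 1, stats::var)
  vp <- apply(xp, 1, stats::var)
  se2 <- vn / length(neg) + vp / length(pos)
  tstat <- (mp - mn) / sqrt(se2)
  df <- se2^2 / ((vn / length(neg))^2 / (length(neg) - 1) +
                 (vp / length(pos))^2 / (length(pos) - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(mp[se2 == 0] == mn[se2 == 0], 1, 0)
  q <- bh_adjust(p)
  lfc <- mp - mn
  cluster <- rep("none", nrow(log_norm))
  sig <- !is.na(q) & q < fdr_alpha
  cluster[sig & lfc < -lfc_threshold] <- "A"
  cluster[sig & lfc > lfc_threshold] <- "B"
  data.frame(gene_id = rownames(log_norm),
             mean_neg = mn, mean_pos = mp, lfc = lfc,
             p_value = p, q_value = q, cluster = cluster,
             row.names = NULL)
}

#' Promoter methylation vs expression correlation
#'
#' For each gene: the mean promoter beta per sample over its `TSS1500`,
#' `TSS200` and `5'UTR` probes is correlated (Pearson, two-sided) with the
#' gene's normalized log2 expression across the samples shared by both
#' matrices; q-values are Benjamini-Hochberg across the tested genes.
#' Direction is `negative` (`r < 0`, `q < fdr_alpha`), `positive`, or `ns`.
#' Genes without promoter probes are reported with missing statistics, not
#' dropped.
#'
#' @param beta a [BetaMatrix].
#' @param ann CpG annotation.
#' @param log_norm normalized log2 expression matrix.
#' @param genes genes to test (default: all rows of `log_norm`).
#' @param regions promoter region categories.
#' @param fdr_alpha significance gate for the direction call.
#' @return data.frame `gene_id`, `n_probes`, `n_samples`, `r`, `r_squared`,
#'   `p_value`, `q_value`, `direction`.
#' @export
correlate_promoter_expression <- function(beta, ann, log_norm,
                                          genes = rownames(log_norm),
                                          regions = c("TSS1500", "TSS200",
                                                      "5'UTR"),
                                          fdr_alpha = 0.05) {
  shared <- intersect(colnames(beta), colnames(log_norm))
  if (length(shared) < 5L) {
    stop("need >= 5 samples shared between beta and expression matrices",
         call. = FALSE)
  }
  ann <- validate_annotation(ann)
  long <- expand_gene_annotation(ann[ann$region_category %in% regions, ,
                                     drop = FALSE])
  long <- long[long$site_id %in% rownames(beta) & long$gene %in% genes, ,
               drop = FALSE]
  probes <- split(long$site_id, long$gene)
  m <- unclass(beta)[, shared, drop = FALSE]
  rows <- lapply(genes, function(g) {
    pr <- probes[[g]]
    if (is.null(pr) || !length(pr)) {
      return(data.frame(gene_id = g, n_probes = 0L,
                        n_samples = length(shared), r = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_))
    }
    pb <- colMeans(m[pr, , drop = FALSE], na.rm = TRUE)
    ex <- log_norm[g, shared]
    ok <- !is.na(pb) & !is.na(ex)
    if (sum(ok) < 5L || stats::sd(pb[ok]) == 0 || stats::sd(ex[ok]) == 0) {
      return(data.frame(gene_id = g, n_probes = length(pr),
                        n_samples = sum(ok), r = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(pb[ok], ex[ok], method = "pearson")
    data.frame(gene_id = g, n_probes = length(pr), n_samples = sum(ok),
               r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
               p_value = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$direction <- "ns"
  sig <- !is.na(out$q_value) & out$q_value < fdr_alpha
  out$direction[sig & out$r < 0] <- "negative"
  out$direction[sig & out$r > 0] <- "positive"
  rownames(out) <- NULL
  out
}

#' Gene-set overlap by hypergeometric test
#'
#' Upper-tail hypergeometric p-value for the overlap between a DEG cluster
#' and each named signature, within a stated gene universe (signatures are
#' intersected with the universe first); Benjamini-Hochberg q across
#' signatures.
#'
#' @param cluster_genes character vector, must be a subset of `universe`.
#' @param signatures named list of character vectors.
#' @param universe character vector of all testable genes.
#' @return data.frame `signature`, `overlap`, `cluster_size`,
#'   `signature_size`, `universe_size`, `p_value`, `q_value`.
#' @export
geneset_overlap <- function(cluster_genes, signatures, universe) {
  universe <- unique(universe)
  if (!all(cluster_genes %in% universe)) {
    stop("cluster genes must be a subset of the universe", call. = FALSE)
  }
  if (!length(signatures) || is.null(names(signatures))) {
    stop("signatures must be a named list", call. = FALSE)
  }
  n_univ <- length(universe)
  n_clus <- length(unique(cluster_genes))
  rows <- lapply(names(signatures), function(nm) {
    sig <- intersect(unique(signatures[[nm]]), universe)
    if (!length(sig)) {
      stop("signature '", nm, "' is disjoint from the universe",
           call. = FALSE)
    }
    k <- length(intersect(cluster_genes, sig))
    p <- stats::phyper(k - 1, length(sig), n_univ - length(sig), n_clus,
                       lower.tail = FALSE)
    data.frame(signature = nm, overlap = k, cluster_size = n_clus,
               signature_size = length(sig), universe_size = n_univ,
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Read a signature file
#'
#' Two-column table `signature_name`, `gene`; one row per membership.
#'
#' @param path file path; @param delimiter field delimiter.
#' @return named list of gene vectors.
#' @export
read_signatures <- function(path, delimiter = "\t") {
  df <- read_tsv(path, delimiter)
  stopifnot(all(c("signature_name", "gene") %in% names(df)))
  split(df$gene, df$signature_name)
}
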