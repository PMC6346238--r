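#' Read / write a CIMP panel
#'
#' A CIMP panel is a plain list of CpG site identifiers, one per line
#' (comment lines starting with `#` ignored). The study-scale panel holds
#' 1293 promoter-enriched CpG sites; any non-empty unique list is accepted.
#'
#' @param path file path.
#' @return character vector of unique site ids.
#' @export
read_cimp_panel <- function(path) {
  stopifnot(file.exists(path))
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("empty CIMP panel file", call. = FALSE)
  if (anyDuplicated(x)) stop("CIMP panel contains duplicate ids",
                             call. = FALSE)
  x
}

#' @rdname read_cimp_panel
#' @param panel character vector of site ids.
#' @export
write_cimp_panel <- function(panel, path) {
  stopifnot(length(panel) > 0L, !anyDuplicated(panel))
  writeLines(panel, path)
  invisible(path)
}

#' CIMP panel score
#'
#' The CIMP score of a sample is the fraction of panel CpG sites that are
#' methylated, a site counting as methylated when its beta value is strictly
#' greater than `beta_threshold` (default 0.4). Missing panel betas are
#' excluded from the denominator (`n_panel_used` is reported per sample), so
#' probe dropout does not bias scores downward.
#'
#' @param beta a [BetaMatrix].
#' @param panel character vector of panel CpG site ids.
#' @param beta_threshold beta value above which a site is called methylated
#'   (strict `>`, default 0.4).
#' @param min_panel_coverage minimum fraction of the panel that must be
#'   present in the matrix (default 0.5); below this, an error.
#' @return data.frame with `sample_id`, `score`, `n_panel_used`.
#' @examples
#' b <- BetaMatrix(matrix(c(rep(0.9, 5), rep(0.1, 5)), ncol = 1,
#'                 dimnames = list(paste0("cg", 1:10), "S1")))
#' cimp_score(b, paste0("cg", 1:10))$score  # 0.5
#' @export
cimp_score <- function(beta, panel, beta_threshold = 0.4,
                       min_panel_coverage = 0.5) {
  stopifnot(length(panel) > 0L, !anyDuplicated(panel))
  assert_fraction(beta_threshold, "beta_threshold")
  present <- intersect(panel, rownames(beta))
  if (!length(present)) {
    stop("no panel sites present in the beta matrix", call. = FALSE)
  }
  cov <- length(present) / length(panel)
  if (cov < min_panel_coverage) {
    stop(sprintf(
      "only %.1f%% of panel sites present (< %.0f%% required)",
      100 * cov, 100 * min_panel_coverage), call. = FALSE)
  }
  sub <- beta[present, , drop = FALSE]
  n_used <- colSums(!is.na(sub))
  if (any(n_used == 0L)) {
    stop("sample(s) with no non-missing panel betas: ",
         paste(colnames(sub)[n_used == 0L], collapse = ", "), call. = FALSE)
  }
  meth <- colSums(sub > beta_threshold, na.rm = TRUE)
  data.frame(sample_id = colnames(sub),
             score = as.numeric(meth / n_used),
             n_panel_used = as.integer(n_used),
             row.names = NULL)
}

#' CIMP classification from panel scores
#'
#' A sample is CIMP-positive when strictly more than `cutoff` (default 40%)
#' of its panel sites are methylated, CIMP-negative otherwise. A score
#' exactly at the cutoff is classified CIMP-negative: the positive class is
#' defined by "more than" the cutoff, which leaves equality to the negative
#' side.
#'
#' @param score numeric vector of panel scores in \[0, 1\].
#' @param cutoff classification cutoff (default 0.40).
#' @return character vector of labels, `"CIMP_POS"` / `"CIMP_NEG"`.
#' @export
classify_cimp <- function(score, cutoff = 0.40) {
  assert_fraction(score, "score")
  assert_fraction(cutoff, "cutoff")
  ifelse(score > cutoff, "CIMP_POS", "CIMP_NEG")
}

#' Score and classify all samples of a beta matrix
#'
#' Convenience wrapper combining [cimp_score()] and [classify_cimp()].
#'
#' @inheritParams cimp_score
#' @inheritParams classify_cimp
#' @return data.frame `sample_id`, `score`, `n_panel_used`, `label`.
#' @export
cimp_classify_samples <- function(beta, panel, beta_threshold = 0.4,
                                  cutoff = 0.40, min_panel_coverage = 0.5) {
  res <- cimp_score(beta, panel, beta_threshold, min_panel_coverage)
  res$label <- classify_cimp(res$score, cutoff)
  res
}
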