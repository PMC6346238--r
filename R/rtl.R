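#' Read a qPCR Ct table
#'
#' Long-format table with columns `sample_id`, `assay` (`T` telomere / `S`
#' single-copy gene), `replicate`, `ct` (cycles, finite and > 0).
#'
#' @param path file path; @param delimiter field delimiter.
#' @return validated data.frame.
#' @export
read_qpcr_table <- function(path, delimiter = "\t") {
  validate_qpcr_table(read_tsv(path, delimiter))
}

#' @rdname read_qpcr_table
#' @param table a data.frame to validate.
#' @export
validate_qpcr_table <- function(table) {
  req <- c("sample_id", "assay", "replicate", "ct")
  miss <- setdiff(req, names(table))
  if (length(miss)) {
    stop("qPCR table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(table$assay), c("T", "S"))
  if (length(bad)) {
    stop("unknown assay token(s): ", paste(bad, collapse = ", "),
         "; accepted: T, S", call. = FALSE)
  }
  if (any(!is.finite(table$ct) | table$ct <= 0)) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  table
}

#' Relative telomere length from qPCR Ct values
#'
#' Cawthon-style delta-delta-Ct: replicate Ct values are averaged per
#' (sample, assay) and the telomere-to-single-copy ratio relative to the
#' reference sample is
#' `rtl = E_T^(CtT_ref - CtT_s) / E_S^(CtS_ref - CtS_s)`,
#' with per-assay amplification efficiencies `E` (fold amplification per
#' cycle; 2 = ideal doubling). The reference sample has rtl 1 by
#' construction. Samples missing either assay are skipped with a warning.
#' Replicate scatter is summarized as the coefficient of variation of the
#' replicate Cts, averaged over the two assays.
#'
#' @param table a qPCR table (see [read_qpcr_table()]).
#' @param reference_sample sample id all ratios are normalized to.
#' @param efficiency named list/vector with per-assay efficiencies `T` and
#'   `S`, each in (1, 2\].
#' @return data.frame `sample_id`, `rtl`, `cv`.
#' @examples
#' tab <- data.frame(sample_id = rep(c("REF", "A"), each = 2),
#'                   assay = rep(c("T", "S"), 2), replicate = 1L,
#'                   ct = c(20, 22, 19, 22))
#' compute_rtl(tab, "REF")  # A: one T cycle earlier at E = 2 -> rtl 2
#' @export
compute_rtl <- function(table, reference_sample,
                        efficiency = c(T = 2.0, S = 2.0)) {
  table <- validate_qpcr_table(table)
  eff <- unlist(efficiency)
  if (!all(c("T", "S") %in% names(eff))) {
    stop("efficiency must provide values for assays T and S", call. = FALSE)
  }
  if (any(eff <= 1)) {
    stop("amplification efficiency must be > 1 fold per cycle",
         call. = FALSE)
  }
  agg <- stats::aggregate(ct ~ sample_id + assay, data = table, FUN = mean)
  cv <- stats::aggregate(ct ~ sample_id + assay, data = table,
                         FUN = function(x) {
                           if (length(x) > 1L) stats::sd(x) / mean(x) else 0
                         })
  ctm <- function(sample, assay) {
    v <- agg$ct[agg$sample_id == sample & agg$assay == assay]
    if (length(v)) v else NA_real_
  }
  if (is.na(ctm(reference_sample, "T")) ||
      is.na(ctm(reference_sample, "S"))) {
    stop("reference sample '", reference_sample,
         "' lacks T and/or S assay", call. = FALSE)
  }
  samples <- unique(table$sample_id)
  rows <- lapply(samples, function(s) {
    ct_t <- ctm(s, "T")
    ct_s <- ctm(s, "S")
    if (is.na(ct_t) || is.na(ct_s)) {
      warning("sample '", s, "' skipped: missing T or S assay",
              call. = FALSE)
      return(NULL)
    }
    rtl <- eff[["T"]]^(ctm(reference_sample, "T") - ct_t) /
      eff[["S"]]^(ctm(reference_sample, "S") - ct_s)
    cvs <- cv$ct[cv$sample_id == s]
    data.frame(sample_id = s, rtl = rtl, cv = mean(cvs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
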