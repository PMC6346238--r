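# shared helpers; not exported

# deterministic plain-text table writer: no quoting, no row names, fixed "NA"
write_tsv <- function(df, path, delimiter = "\t") {
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, delimiter = "\t", ...) {
  stopifnot(file.exists(path))
  utils::read.delim(path, sep = delimiter, header = TRUE,
                    check.names = FALSE, na.strings = c("NA", ""),
                    stringsAsFactors = FALSE, ...)
}

# Benjamini-Hochberg adjusted p-values; NA-safe
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# split multi-gene annotations ("A;B") into one row per (site, gene)
expand_gene_annotation <- function(ann) {
  if (!nrow(ann)) {
    out <- ann
    out$gene <- character(0)
    return(out)
  }
  genes <- strsplit(ifelse(is.na(ann$gene), "", as.character(ann$gene)),
                    ";", fixed = TRUE)
  n <- lengths(genes)
  keep <- n > 0L
  out <- ann[rep(which(keep), n[keep]), , drop = FALSE]
  out$gene <- unlist(genes[keep], use.names = FALSE)
  out <- out[out$gene != "", , drop = FALSE]
  rownames(out) <- NULL
  out
}
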