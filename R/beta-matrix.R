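#' Beta-value matrix container
#'
#' A `BetaMatrix` is a numeric matrix of methylation beta values (CpG sites in
#' rows, samples in columns) validated against the platform contract: all
#' values in \[0, 1\] (within a small numeric tolerance) or `NA`, unique row
#' and column identifiers, and at least one site and one sample. Missing
#' values are preserved, never imputed silently; every downstream operation
#' states its own missing-data policy.
#'
#' @param values numeric matrix of beta values with `rownames` (CpG site ids)
#'   and `colnames` (sample ids), or a matrix plus explicit `site_ids` /
#'   `sample_ids`.
#' @param site_ids,sample_ids optional character vectors overriding dimnames.
#' @param tol numeric tolerance for the \[0, 1\] bound check (default `1e-9`).
#'
#' @return an object of class `BetaMatrix` (a plain numeric matrix with
#'   dimnames; all matrix operations apply).
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.5, 0.2, 0.8, 0.4), nrow = 3,
#'             dimnames = list(paste0("cg", 1:3), c("S1", "S2")))
#' b <- BetaMatrix(m)
#' dim(b)
#' @export
BetaMatrix <- function(values, site_ids = NULL, sample_ids = NULL,
                       tol = 1e-9) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("BetaMatrix: 'values' must be a numeric matrix", call. = FALSE)
  }
  if (!is.null(site_ids)) rownames(values) <- site_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  validate_beta_matrix(values, tol = tol)
  structure(values, class = c("BetaMatrix", "matrix", "array"))
}

validate_beta_matrix <- function(values, tol = 1e-9) {
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("BetaMatrix must have at least 1 site and 1 sample", call. = FALSE)
  }
  sid <- rownames(values)
  cid <- colnames(values)
  if (is.null(sid) || is.null(cid)) {
    stop("BetaMatrix requires site ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate site ids: ", paste(unique(sid[duplicated(sid)]),
         collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cid)) {
    stop("duplicate sample ids: ", paste(unique(cid[duplicated(cid)]),
         collapse = ", "), call. = FALSE)
  }
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -tol || max(v) > 1 + tol)) {
    bad <- which(values < -tol | values > 1 + tol, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "beta value out of [0,1]: %.6g at site '%s', sample '%s'",
      values[bad[1L], bad[2L]], sid[bad[1L]], cid[bad[2L]]), call. = FALSE)
  }
  invisible(values)
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d CpG sites x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read / write a beta-value matrix
#'
#' Tabular layout: first column CpG site ids, header row sample ids, numeric
#' body. Empty cells and `NA` are kept as missing. Values outside \[0, 1\]
#' beyond a `1e-9` tolerance, malformed numeric cells, and duplicated ids are
#' rejected with errors naming the offending row/column.
#'
#' @param path file path.
#' @param delimiter field delimiter (default tab).
#' @return `read_beta_matrix`: a [BetaMatrix]. `write_beta_matrix`: `path`,
#'   invisibly. Round-tripping preserves values to better than `1e-12`.
#' @export
read_beta_matrix <- function(path, delimiter = "\t") {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("beta matrix file needs >= 2 columns", call. = FALSE)
  site_ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(site_ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    raw <- body[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad)) {
      stop(sprintf(
        "malformed numeric cell '%s' at row '%s', column '%s'",
        raw[bad[1L]], site_ids[bad[1L]], colnames(body)[j]), call. = FALSE)
    }
    vals[, j] <- num
  }
  BetaMatrix(vals)
}

#' @rdname read_beta_matrix
#' @param beta a [BetaMatrix] (or compatible numeric matrix).
#' @export
write_beta_matrix <- function(beta, path, delimiter = "\t") {
  df <- data.frame(site_id = rownames(beta),
                   as.data.frame(unclass(beta), check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path, delimiter)
  invisible(path)
}
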