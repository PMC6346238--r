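#' Manifest category vocabularies
#'
#' Closed vocabularies for the two probe-context classifications used on
#' 450K-style arrays: gene-relative region (`TSS1500`, `TSS200`, `5'UTR`,
#' `1stExon`, `Body`, `3'UTR`, `Intergenic`) and CpG-density context
#' (`Island`, `Shore`, `Shelf`, `OpenSea`). Any other token is rejected at
#' read time.
#'
#' @format character vectors.
#' @export
REGION_CATEGORIES <- c("TSS1500", "TSS200", "5'UTR", "1stExon",
                       "Body", "3'UTR", "Intergenic")

#' @rdname REGION_CATEGORIES
#' @export
ISLAND_CATEGORIES <- c("Island", "Shore", "Shelf", "OpenSea")

# region categories counted as "promoter" for gene-level promoter methylation
PROMOTER_REGIONS <- c("TSS1500", "TSS200")
PROMOTER_REGIONS_EXT <- c("TSS1500", "TSS200", "5'UTR")

#' Validate a CpG annotation table
#'
#' Required columns: `site_id`, `chromosome`, `position` (1-based, >= 1),
#' `gene` (zero or more `;`-separated symbols; empty for intergenic probes),
#' `region_category`, `island_category`. Site ids must be unique and category
#' tokens must come from the closed vocabularies ([REGION_CATEGORIES],
#' [ISLAND_CATEGORIES]).
#'
#' @param ann a data.frame.
#' @return the validated data.frame (gene `NA` normalized to `""`).
#' @export
validate_annotation <- function(ann) {
  req <- c("site_id", "chromosome", "position", "gene",
           "region_category", "island_category")
  miss <- setdiff(req, names(ann))
  if (length(miss)) {
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$site_id)) {
    stop("annotation has duplicated site_id: ",
         paste(unique(ann$site_id[duplicated(ann$site_id)])[1:3],
               collapse = ", "), call. = FALSE)
  }
  ann$position <- as.integer(ann$position)
  if (any(!is.finite(ann$position)) || any(ann$position < 1L)) {
    stop("annotation positions must be integers >= 1", call. = FALSE)
  }
  badr <- setdiff(unique(ann$region_category), REGION_CATEGORIES)
  if (length(badr)) {
    stop("unknown region_category token(s): ",
         paste(badr, collapse = ", "), "; accepted: ",
         paste(REGION_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  badi <- setdiff(unique(ann$island_category), ISLAND_CATEGORIES)
  if (length(badi)) {
    stop("unknown island_category token(s): ",
         paste(badi, collapse = ", "), "; accepted: ",
         paste(ISLAND_CATEGORIES, collapse = ", "), call. = FALSE)
  }
  ann$gene[is.na(ann$gene)] <- ""
  ann
}

#' Read / write a CpG annotation table
#'
#' @param path file path to a delimited table with the columns documented in
#'   [validate_annotation()].
#' @param delimiter field delimiter (default tab).
#' @return `read_annotation`: validated annotation data.frame.
#' @export
read_annotation <- function(path, delimiter = "\t") {
  ann <- read_tsv(path, delimiter,
                  colClasses = c(position = "integer"))
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param ann annotation data.frame.
#' @export
write_annotation <- function(ann, path, delimiter = "\t") {
  write_tsv(validate_annotation(ann), path, delimiter)
  invisible(path)
}

#' Read / validate a sample sheet
#'
#' Columns: `sample_id`, `group` (one of `CIMP_NEG`, `CIMP_POS`, `REFERENCE`,
#' `UNKNOWN`), optional `chronological_age` (years, finite and >= 0 when
#' present) and `sex`.
#'
#' @param path file path; @param delimiter field delimiter.
#' @param sheet a data.frame to validate.
#' @param beta optional [BetaMatrix] whose sample ids the sheet must match.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path, delimiter = "\t") {
  validate_sample_sheet(read_tsv(path, delimiter))
}

#' @rdname read_sample_sheet
#' @export
validate_sample_sheet <- function(sheet, beta = NULL) {
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  groups <- c("CIMP_NEG", "CIMP_POS", "REFERENCE", "UNKNOWN")
  bad <- setdiff(unique(sheet$group), groups)
  if (length(bad)) {
    stop("unknown group token(s): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(groups, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("sample sheet has duplicated sample_id", call. = FALSE)
  }
  if ("chronological_age" %in% names(sheet)) {
    a <- sheet$chronological_age
    if (any(!is.na(a) & (!is.finite(a) | a < 0))) {
      stop("chronological_age must be finite and >= 0", call. = FALSE)
    }
  }
  if (!is.null(beta)) {
    extra <- setdiff(sheet$sample_id, colnames(beta))
    if (length(extra)) {
      stop("sample sheet ids absent from beta matrix: ",
           paste(extra[1:3], collapse = ", "), call. = FALSE)
    }
  }
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path, delimiter = "\t") {
  write_tsv(validate_sample_sheet(sheet), path, delimiter)
  invisible(path)
}
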