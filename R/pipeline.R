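#' Default analysis thresholds
#'
#' Beta value above which a CpG counts as methylated (0.4), CIMP score
#' cutoff (0.40), per-sample hyper/hypo and group DM delta-beta thresholds
#' (0.4), absolute LFC gate (1.0) and FDR alpha (0.05).
#'
#' @return named list.
#' @export
default_thresholds <- function() {
  list(beta_methylated = 0.4, cimp_cutoff = 0.40, hyper_delta = 0.4,
       dm_delta = 0.4, lfc = 1.0, fdr = 0.05)
}

#' Read a pipeline configuration
#'
#' JSON file with optional blocks `synthetic` (a [synthetic_spec()] field
#' subset), `inputs` (paths: `beta`, `annotation`, `samples`, `panel`,
#' `counts`, `qpcr`, `clock`, `mitotic_panel`, `signatures`), `thresholds`
#' (overriding [default_thresholds()]), `seed`, `outdir`,
#' `reference_sample`, `delimiter`.
#'
#' @param path JSON file path.
#' @return config list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

load_pipeline_inputs <- function(config) {
  delim <- config$delimiter %||% "\t"
  if (!is.null(config$synthetic)) {
    spec_args <- config$synthetic
    if (!is.null(config$seed)) spec_args$seed <- config$seed
    spec <- do.call(synthetic_spec, spec_args)
    return(generate_cohort(spec))
  }
  inputs <- config$inputs
  if (is.null(inputs)) {
    stop("configuration error: neither 'synthetic' nor 'inputs' given",
         call. = FALSE)
  }
  required <- c("beta", "annotation", "samples", "panel")
  for (req in required) {
    if (is.null(inputs[[req]])) {
      stop("configuration error: required input '", req, "' missing",
           call. = FALSE)
    }
  }
  for (req in required) {
    if (!file.exists(inputs[[req]])) {
      stop("configuration error: input file not found: ", inputs[[req]],
           call. = FALSE)
    }
  }
  list(beta = read_beta_matrix(inputs$beta, delim),
       annotation = read_annotation(inputs$annotation, delim),
       samples = read_sample_sheet(inputs$samples, delim),
       panel = read_cimp_panel(inputs$panel),
       counts = if (!is.null(inputs$counts))
         read_count_matrix(inputs$counts, delim),
       qpcr = if (!is.null(inputs$qpcr))
         read_qpcr_table(inputs$qpcr, delim),
       clock = if (!is.null(inputs$clock)) read_clock_model(inputs$clock),
       mitotic_panel = if (!is.null(inputs$mitotic_panel))
         read_cimp_panel(inputs$mitotic_panel),
       signatures = if (!is.null(inputs$signatures))
         read_signatures(inputs$signatures, delim))
}

#' Run the full CIMP methylome pipeline
#'
#' Executes the stages in order — CIMP score and classification, methylome
#' landscape (promoter means, hyper/hypo calls against the reference group,
#' category enrichment, DM-CpGs), clocks (DNAm age, mitotic age, age
#' correlation), relative telomere length, expression (normalization, DEG),
#' and methylation-expression integration — writing one TSV per result
#' table plus `run_log.json` (seed, thresholds, versions) to the output
#' directory. Stages whose inputs are absent are skipped. With the same
#' config and seed the result tables are byte-identical across runs.
#'
#' @param config a config list (see [read_config()]) or path to a JSON file.
#' @param outdir output directory (overrides `config$outdir`).
#' @return invisibly, a list of all result tables plus `paths`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  outdir <- outdir %||% config$outdir %||%
    stop("configuration error: no output directory given", call. = FALSE)
  thresholds <- utils::modifyList(default_thresholds(),
                                  config$thresholds %||% list())
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  delim <- config$delimiter %||% "\t"
  if (!is.null(config$seed)) set.seed(config$seed)

  inp <- load_pipeline_inputs(config)
  results <- list()
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, paste0(name, ".tsv"))
    write_tsv(df, p, delim)
    paths[[name]] <<- p
    results[[name]] <<- df
  }

  ## stage: score + classify
  cimp <- cimp_classify_samples(inp$beta, inp$panel,
                                beta_threshold = thresholds$beta_methylated,
                                cutoff = thresholds$cimp_cutoff)
  emit(cimp, "cimp_scores")
  labels <- stats::setNames(cimp$label, cimp$sample_id)
  sheet_groups <- stats::setNames(inp$samples$group, inp$samples$sample_id)
  refs <- names(sheet_groups)[sheet_groups == "REFERENCE"]
  labels[names(labels) %in% refs] <- "REFERENCE"

  ## stage: landscape
  prom <- mean_promoter_methylation(inp$beta, inp$annotation)
  emit(data.frame(sample_id = names(prom$sample_mean),
                  mean_promoter_beta = unname(prom$sample_mean)),
       "promoter_methylation")
  if (length(refs)) {
    calls <- call_hyper_hypo(inp$beta, refs,
                             delta_threshold = thresholds$hyper_delta)
    emit(calls$counts, "hyper_hypo_counts")
    for (scheme in c("region", "island")) {
      enr <- category_enrichment(calls, inp$annotation, scheme)
      emit(enr, paste0("enrichment_", scheme))
      emit(summarize_enrichment(enr, labels),
           paste0("enrichment_", scheme, "_summary"))
    }
  }
  dm <- dm_cpgs(inp$beta, labels, dm_delta = thresholds$dm_delta,
                fdr_alpha = thresholds$fdr)
  emit(dm, "dm_cpgs")

  ## stage: clocks
  if (!is.null(inp$clock)) {
    clk <- apply_clock(inp$beta, inp$clock)
    emit(clk, "dnam_age")
    emit(age_correlation(clk, inp$samples), "age_correlation")
  }
  if (!is.null(inp$mitotic_panel)) {
    emit(mitotic_age(inp$beta, inp$mitotic_panel), "mitotic_age")
  }

  ## stage: telomere
  if (!is.null(inp$qpcr)) {
    ref_sample <- config$reference_sample %||%
      intersect(refs, unique(inp$qpcr$sample_id))[1]
    if (is.null(ref_sample) || is.na(ref_sample)) {
      stop("configuration error: no qPCR reference sample available",
           call. = FALSE)
    }
    emit(compute_rtl(inp$qpcr, ref_sample), "rtl")
  }

  ## stage: expression + integration
  if (!is.null(inp$counts)) {
    norm <- normalize_counts(inp$counts)
    emit(data.frame(sample_id = names(norm$size_factors),
                    size_factor = unname(norm$size_factors)),
         "size_factors")
    deg <- differential_expression(norm$log_norm, labels,
                                   lfc_threshold = thresholds$lfc,
                                   fdr_alpha = thresholds$fdr)
    emit(deg, "deg")
    deg_genes <- deg$gene_id[deg$cluster != "none"]
    if (length(deg_genes)) {
      corr <- correlate_promoter_expression(inp$beta, inp$annotation,
                                            norm$log_norm,
                                            genes = deg_genes,
                                            fdr_alpha = thresholds$fdr)
      emit(corr, "meth_expr_correlation")
      if (!is.null(inp$signatures)) {
        universe <- rownames(inp$counts)
        for (cl in c("A", "B")) {
          cg <- deg$gene_id[deg$cluster == cl]
          if (length(cg)) {
            emit(geneset_overlap(cg, inp$signatures, universe),
                 paste0("geneset_overlap_", cl))
          }
        }
      }
    }
  }

  log <- list(package = "methcimp",
              version = as.character(utils::packageVersion("methcimp")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = config$seed %||% NA,
              thresholds = thresholds,
              synthetic = config$synthetic %||% NULL,
              inputs = config$inputs %||% NULL,
              tables = names(paths))
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(paths = paths)))
}
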