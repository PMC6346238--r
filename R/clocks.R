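#' Linear methylation clock model
#'
#' A clock is an intercept plus a sparse linear combination of CpG betas,
#' followed by an inverse age transform. `transform = "identity"` returns
#' the linear predictor; `transform = "horvath_age"` applies the adult-age
#' anchored piecewise log-linear inverse (see [horvath_inverse()]), the form
#' used by the classical 353-CpG DNAm age clock.
#'
#' @param name clock name.
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector, site id -> weight.
#' @param transform `"identity"` or `"horvath_age"`.
#' @param adult_age anchor age in years for `horvath_age` (default 20).
#' @return object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coefficients,
                        transform = c("identity", "horvath_age"),
                        adult_age = 20) {
  transform <- match.arg(transform)
  if (!length(coefficients) || is.null(names(coefficients)) ||
      any(!nzchar(names(coefficients)))) {
    stop("clock needs >= 1 named coefficient", call. = FALSE)
  }
  if (any(!is.finite(coefficients)) || !is.finite(intercept)) {
    stop("clock weights and intercept must be finite", call. = FALSE)
  }
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, transform = transform,
                 adult_age = adult_age),
            class = "clock_model")
}

#' Adult-age anchored age transform and its inverse
#'
#' Forward transform of an age `a` (used when training such clocks):
#' `log(a + 1) - log(adult_age + 1)` for `a <= adult_age`, else
#' `(a - adult_age) / (adult_age + 1)`. The inverse maps a linear predictor
#' `m` back to years: `exp(m + log(adult_age + 1)) - 1` for `m < 0`, else
#' `m * (adult_age + 1) + adult_age`. Both are continuous and strictly
#' increasing, and `horvath_inverse(0) == adult_age`.
#'
#' @param a age in years (forward) / @param m linear predictor (inverse).
#' @param adult_age anchor age (default 20).
#' @return numeric vector.
#' @export
horvath_transform <- function(a, adult_age = 20) {
  ifelse(a <= adult_age,
         log(a + 1) - log(adult_age + 1),
         (a - adult_age) / (adult_age + 1))
}

#' @rdname horvath_transform
#' @export
horvath_inverse <- function(m, adult_age = 20) {
  ifelse(m < 0,
         exp(m + log(adult_age + 1)) - 1,
         m * (adult_age + 1) + adult_age)
}

#' Apply a methylation clock to a beta matrix
#'
#' Computes the linear predictor `intercept + sum(w_i * beta_i)` per sample
#' and passes it through the model's inverse transform. Missing cells at a
#' model site present in the matrix are imputed by that site's cohort mean
#' beta (standard clock practice); model sites entirely absent from the
#' matrix are dropped. If fewer than `min_coverage` (default 80%) of model
#' sites are present, the call errors, naming the missing fraction.
#'
#' @param beta a [BetaMatrix].
#' @param model a [clock_model()].
#' @param min_coverage minimum fraction of model sites that must be present.
#' @return data.frame `sample_id`, `linear_predictor`, `predicted_value`,
#'   `n_sites_used`, `frac_imputed`.
#' @export
apply_clock <- function(beta, model, min_coverage = 0.8) {
  stopifnot(inherits(model, "clock_model"))
  sites <- names(model$coefficients)
  present <- intersect(sites, rownames(beta))
  cov <- length(present) / length(sites)
  if (cov < min_coverage) {
    stop(sprintf(
      "clock coverage too low: %.1f%% of model sites missing (max allowed %.1f%%)",
      100 * (1 - cov), 100 * (1 - min_coverage)), call. = FALSE)
  }
  m <- unclass(beta)[present, , drop = FALSE]
  site_mean <- rowMeans(m, na.rm = TRUE)
  imputed <- is.na(m)
  if (any(imputed)) m[imputed] <- site_mean[row(m)[imputed]]
  w <- model$coefficients[present]
  lp <- model$intercept + as.numeric(crossprod(m, w))
  pred <- switch(model$transform,
                 identity = lp,
                 horvath_age = horvath_inverse(lp, model$adult_age))
  data.frame(sample_id = colnames(m),
             linear_predictor = lp,
             predicted_value = pred,
             n_sites_used = length(present),
             frac_imputed = colMeans(imputed),
             row.names = NULL)
}

#' Mitotic age score
#'
#' The mitotic age of a sample is the plain mean beta over a mitotic-clock
#' CpG panel (a \[0, 1\] score; higher values indicate a longer replicative
#' history). Missing betas are excluded per sample.
#'
#' @param beta a [BetaMatrix].
#' @param panel character vector of mitotic-clock site ids.
#' @return data.frame `sample_id`, `score`, `n_sites_used`.
#' @export
mitotic_age <- function(beta, panel) {
  present <- intersect(panel, rownames(beta))
  if (!length(present)) {
    stop("no mitotic panel sites present in the matrix", call. = FALSE)
  }
  m <- unclass(beta)[present, , drop = FALSE]
  data.frame(sample_id = colnames(m),
             score = colMeans(m, na.rm = TRUE),
             n_sites_used = colSums(!is.na(m)),
             row.names = NULL)
}

#' Correlation of predicted and chronological age per group
#'
#' Pearson correlation (r, R-squared, two-sided p) between a clock's
#' predictions and chronological age, computed separately per sample group.
#' Groups with fewer than 3 aged samples, or zero variance in either
#' variable, are reported as missing.
#'
#' @param results an [apply_clock()] result (or any data.frame with
#'   `sample_id` and `predicted_value`).
#' @param sheet sample sheet with `sample_id`, `group`, `chronological_age`.
#' @return data.frame `group`, `n`, `r`, `r_squared`, `p_value`.
#' @export
age_correlation <- function(results, sheet) {
  sheet <- validate_sample_sheet(sheet)
  if (!"chronological_age" %in% names(sheet)) {
    stop("sample sheet lacks chronological_age", call. = FALSE)
  }
  df <- merge(results, sheet, by = "sample_id")
  df <- df[!is.na(df$chronological_age) & !is.na(df$predicted_value), ,
           drop = FALSE]
  out <- lapply(split(df, df$group), function(d) {
    g <- d$group[1]
    if (nrow(d) < 3L || stats::sd(d$chronological_age) == 0 ||
        stats::sd(d$predicted_value) == 0) {
      return(data.frame(group = g, n = nrow(d), r = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(d$predicted_value, d$chronological_age,
                          method = "pearson")
    data.frame(group = g, n = nrow(d), r = unname(ct$estimate),
               r_squared = unname(ct$estimate)^2, p_value = ct$p.value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read / write a clock model file
#'
#' Plain TSV of `site_id`, `weight`, preceded by `#`-prefixed metadata lines
#' `# name:`, `# intercept:`, `# transform:`, `# adult_age:`.
#'
#' @param path file path.
#' @return `read_clock_model`: a [clock_model()].
#' @export
read_clock_model <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                            stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "weight") %in% names(body)))
  clock_model(name = meta$name %||% "unnamed_clock",
              intercept = as.numeric(meta$intercept %||% "0"),
              coefficients = stats::setNames(as.numeric(body$weight),
                                             body$site_id),
              transform = meta$transform %||% "identity",
              adult_age = as.numeric(meta$adult_age %||% "20"))
}

#' @rdname read_clock_model
#' @param model a [clock_model()].
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name: %s", model$name),
               sprintf("# intercept: %.17g", model$intercept),
               sprintf("# transform: %s", model$transform),
               sprintf("# adult_age: %.17g", model$adult_age),
               "site_id\tweight",
               sprintf("%s\t%.17g", names(model$coefficients),
                       model$coefficients)), con)
  invisible(path)
}
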