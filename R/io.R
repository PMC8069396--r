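# Data input, fixture generation and the command-line front end.

#' Read a univariate positive series
#'
#' Accepts either a plain text file (one value per line, blank lines and
#' `#` comments skipped) or a CSV with a header, in which case `column`
#' selects the variable. Values must all be strictly positive.
#'
#' @param path input file.
#' @param column column name for CSV input; ignored for plain series.
#' @return numeric vector in file order.
#' @export
read_series <- function(path, column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("empty input file: ", path, call. = FALSE)
  header_like <- grepl("[,;\t]", lines[1]) ||
    is.na(suppressWarnings(as.numeric(lines[1])))
  if (header_like) {
    df <- utils::read.csv(text = paste(lines, collapse = "\n"))
    if (is.null(column)) {
      num <- vapply(df, is.numeric, logical(1))
      if (!any(num)) stop("no numeric column found in ", path, call. = FALSE)
      column <- names(df)[which(num)[1]]
    }
    if (!column %in% names(df))
      stop("column '", column, "' not present in ", path, call. = FALSE)
    x <- df[[column]]
  } else {
    x <- suppressWarnings(as.numeric(lines))
    bad <- which(is.na(x))
    if (length(bad))
      stop("non-numeric value at row ", bad[1], " of ", path, call. = FALSE)
  }
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop("non-positive value at row ", bad[1], " of ", path, call. = FALSE)
  as.numeric(x)
}

#' Generate a self-describing synthetic fixture
#'
#' Draws `n` values from the chosen sub-model by inverse transform and
#' writes them one per line, together with a JSON manifest
#' (`<path>.manifest.json`) recording the model, parameters, size and
#' seed so the fixture is fully reproducible. The intended use is to
#' emulate the two classic application datasets from their printed
#' fitted parameters when the originals are not at hand.
#'
#' @param model `"exponential"` or `"frechet"` (any baseline name works).
#' @param params parameter vector `(lambda, beta, phi...)`.
#' @param n sample size.
#' @param seed integer seed.
#' @param path output file path.
#' @return invisibly, the sample.
#' @export
generate_fixture <- function(model, params, n, seed, path) {
  p <- theta_to_hlow(model, as.numeric(params))
  x <- rhlow(n, p, seed = seed)
  writeLines(format(x, digits = 15, scientific = FALSE, trim = TRUE), path)
  manifest <- list(model = model, params = as.numeric(params),
                   param_names = c("lambda", "beta", p$baseline$param_names),
                   n = n, seed = seed)
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' Serialize a fit report to JSON
#'
#' Writes estimates, standard errors, objective value and the
#' goodness-of-fit block of a fitted model, plus dataset metadata and
#' the baseline parameterization note (Frechet: `G(x) = exp(-(a/x)^b)`,
#' `a` scale, `b` shape).
#'
#' @param fit an object from [hlow_fit()].
#' @param x the data the fit used.
#' @param path output JSON path.
#' @param data_path optional provenance string recorded in the report.
#' @export
write_fit_report <- function(fit, x, path, data_path = NA_character_) {
  gof <- hlow_gof(fit$model, x, df = length(fit$estimates))
  report <- list(
    dataset = list(path = data_path, n = length(x),
                   checksum = sum(x) + sum(x^2)),
    convention = "Frechet baseline G(x) = exp(-(a/x)^b), a scale, b shape; parameter order (lambda, beta, phi)",
    method = fit$method,
    estimates = as.list(fit$estimates),
    standard_errors = as.list(fit$standard_errors),
    objective_value = fit$objective_value,
    converged = fit$converged,
    gof = unclass(gof),
    version = as.character(utils::packageVersion("hlowg")),
    seed = if (is.null(fit$seed)) NA else fit$seed)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(report)
}

#' Read back a fit report
#'
#' @param path JSON path written by [write_fit_report()].
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
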