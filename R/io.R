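# Config-file round trips: JSON/YAML for full objects, CSV for the tabular
# pieces (tariffs, category tables). Validation is delegated to the
# constructors so a loaded object is exactly as trustworthy as a programmatic
# one.

params_to_list <- function(x) {
  if (inherits(x, "cost_table")) {
    out <- list(schema = "cost", currency = x$currency,
                entries = as.list(x$entries))
    if (!is.null(x$codes)) out$codes <- as.list(x$codes)
    out
  } else if (inherits(x, "model_parameters")) {
    list(schema = "model",
         model_id = x$model_id,
         currency = x$currency,
         category_dist = as.list(x$category_dist),
         rom = as.list(x$rom),
         site_mix = x$site_mix,
         iva_surgery_rate = x$iva_surgery_rate,
         second_fnac_dist = as.list(x$second_fnac_dist),
         upfront_malignancy_rate = x$upfront_malignancy_rate)
  } else {
    stop("cannot serialize object of class ", paste(class(x), collapse = "/"),
         call. = FALSE)
  }
}

list_to_params <- function(lst, schema = c("auto", "model", "cost")) {
  schema <- match.arg(schema)
  if (schema == "auto") {
    schema <- lst$schema %||%
      (if (!is.null(lst$entries)) "cost" else "model")
  }
  num <- function(x) vapply(x, as.numeric, numeric(1))
  if (schema == "cost") {
    codes <- if (!is.null(lst$codes)) {
      vapply(lst$codes, as.character, character(1))
    }
    cost_table(lst$currency, num(lst$entries), codes)
  } else {
    model_parameters(model_id = lst$model_id,
                     currency = lst$currency,
                     category_dist = num(lst$category_dist),
                     rom = num(lst$rom),
                     site_mix = as.numeric(lst$site_mix),
                     iva_surgery_rate = as.numeric(lst$iva_surgery_rate),
                     second_fnac_dist =
                       if (!is.null(lst$second_fnac_dist)) {
                         num(lst$second_fnac_dist)
                       },
                     upfront_malignancy_rate =
                       as.numeric(lst$upfront_malignancy_rate %||% 0.25))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a parameter set or cost table to a config file
#'
#' Serializes to JSON or YAML at full numeric precision. The written file
#' round-trips through [load_parameters()] to an object equal to the input.
#'
#' @param x A [model_parameters()] or [cost_table()] object.
#' @param path Output file; format inferred from the extension
#'   (`.json`, `.yaml`/`.yml`) unless `format` is given.
#' @param format `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(x, path, format = NULL) {
  format <- format %||%
    switch(tolower(tools::file_ext(path)),
           json = "json", yaml = "yaml", yml = "yaml",
           stop("cannot infer format from '", path,
                "'; pass format = 'json' or 'yaml'", call. = FALSE))
  lst <- params_to_list(x)
  if (format == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(yaml::as.yaml(lst, precision = 15), path)
  }
  invisible(path)
}

#' Load a parameter set or cost table from a config file
#'
#' Accepts the JSON and YAML dialects written by [write_parameters()] (or
#' hand-written equivalents). The loaded values pass through the same
#' validation as programmatic construction, so schema violations (a missing
#' category, a probability outside `[0, 1]`, a distribution that does not sum
#' to 1) are rejected with the offending field named.
#'
#' @param path Config file (`.json`, `.yaml`, `.yml`).
#' @param schema `"auto"` (default, uses the file's `schema` field or its
#'   shape), `"model"`, or `"cost"`.
#' @return A [model_parameters()] or [cost_table()] object.
#' @export
load_parameters <- function(path, schema = c("auto", "model", "cost")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
                json = jsonlite::read_json(path),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("unsupported config extension '.", ext, "'",
                     call. = FALSE))
  list_to_params(lst, schema)
}

#' CSV export/import of cost tables and category tables
#'
#' `write_cost_csv()`/`read_cost_csv()` round-trip a [cost_table()] through a
#' CSV with columns `procedure, code, cost, currency`.
#' `write_category_csv()` writes the category-level slice of a
#' [model_parameters()] object (columns `category, frequency, rom`), and
#' `read_category_csv()` reads such a table back as a data frame for use in
#' [model_parameters()].
#'
#' @param x A [cost_table()] or [model_parameters()] object.
#' @param path CSV file path.
#' @return The readers return a [cost_table()] or a data frame; the writers
#'   return `path` invisibly.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
write_cost_csv <- function(x, path) {
  stopifnot(inherits(x, "cost_table"))
  df <- data.frame(procedure = names(x$entries),
                   code = if (is.null(x$codes)) "" else
                     unname(x$codes[names(x$entries)]),
                   cost = unname(x$entries),
                   currency = x$currency)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_cost_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("procedure", "cost", "currency")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("cost CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  currency <- unique(df$currency)
  if (length(currency) != 1) {
    stop("cost CSV mixes currencies: ", paste(currency, collapse = ", "),
         call. = FALSE)
  }
  entries <- stats::setNames(df$cost, df$procedure)
  codes <- if ("code" %in% names(df)) {
    stats::setNames(as.character(df$code), df$procedure)
  }
  cost_table(currency, entries, codes)
}

#' @rdname csv_io
#' @export
write_category_csv <- function(x, path) {
  stopifnot(inherits(x, "model_parameters"))
  df <- data.frame(category = milan_categories(),
                   frequency = unname(x$category_dist),
                   rom = unname(x$rom))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_category_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "frequency", "rom")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("category CSV missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}
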