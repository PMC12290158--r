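#' Dataset schema for CSV import
#'
#' Names the class column and its favorable value, and the protected columns
#' with their unprivileged values, so arbitrary user CSVs can be mapped onto
#' the package's 0/1 coding. Serializable to a sidecar YAML file.
#'
#' @param class_column name of the class column.
#' @param favorable_value value mapped to the favorable label 1.
#' @param protected named list: attribute name -> value mapped to the
#'   unprivileged group 0.
#' @return A `tabular_schema`.
#' @export
tabular_schema <- function(class_column = "y", favorable_value = 1,
                           protected = list(A = 0)) {
  stopifnot(is.character(class_column), length(protected) >= 1,
            !is.null(names(protected)))
  structure(list(class_column = class_column, favorable_value = favorable_value,
                 protected = protected),
            class = "tabular_schema")
}

#' @rdname tabular_schema
#' @param path YAML file to read or write.
#' @export
read_schema <- function(path) {
  obj <- yaml::read_yaml(path)
  tabular_schema(obj$class_column, obj$favorable_value, obj$protected)
}

#' @rdname tabular_schema
#' @param schema a `tabular_schema`.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(unclass(schema), path)
  invisible(path)
}

#' Load a tabular dataset from CSV under a schema
#'
#' Feature columns are all columns not named by the schema, in file order.
#' Protected columns must be binary after mapping (unprivileged value -> 0,
#' the single other value -> 1); offending values are reported.
#'
#' @param path CSV file with a header row.
#' @param schema a [tabular_schema()] or path to its YAML file.
#' @return A [tabular_dataset()].
#' @export
load_tabular <- function(path, schema) {
  if (is.character(schema)) schema <- read_schema(schema)
  stopifnot(inherits(schema, "tabular_schema"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c(schema$class_column, names(schema$protected))
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_fairpost(paste("missing columns:", paste(missing, collapse = ", ")),
                  "fairpost_schema_error")
  yraw <- df[[schema$class_column]]
  if (length(unique(yraw)) > 2L)
    stop_fairpost(sprintf("class column '%s' has more than two values",
                          schema$class_column), "fairpost_encoding_error")
  labels <- as.integer(yraw == schema$favorable_value)
  prot <- lapply(names(schema$protected), function(nm) {
    vals <- df[[nm]]
    uniq <- unique(vals)
    if (length(uniq) > 2L)
      stop_fairpost(sprintf("protected column '%s' is not binary; values: %s",
                            nm, paste(utils::head(sort(uniq), 5), collapse = ", ")),
                    "fairpost_encoding_error")
    as.integer(vals != schema$protected[[nm]])
  })
  names(prot) <- names(schema$protected)
  feats <- df[, setdiff(names(df), needed), drop = FALSE]
  tabular_dataset(feats, labels, as.data.frame(prot))
}

#' Write a tabular dataset to CSV (plus optional YAML schema)
#'
#' @param dataset a [tabular_dataset()].
#' @param path CSV output path.
#' @param schema_path optional YAML sidecar describing the written columns.
#' @export
write_tabular <- function(dataset, path, schema_path = NULL) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  if (!is.null(schema_path)) {
    prot <- as.list(stats::setNames(rep(0, ncol(dataset$protected)),
                                    names(dataset$protected)))
    write_schema(tabular_schema("y", 1, prot), schema_path)
  }
  invisible(path)
}

FIXTURE_NAMES <- c("toy-scores", "two-attr-correlated", "planted-bias",
                   "synthetic-balanced")

#' Generate a registered test fixture on disk
#'
#' Deterministic small datasets used by the test suite and vignette:
#' \describe{
#'   \item{toy-scores}{48 scored instances with group and label columns.}
#'   \item{two-attr-correlated}{synthetic dataset with two negatively
#'     correlated protected attributes (target Spearman rho = -0.5).}
#'   \item{planted-bias}{one-feature scores with a planted subgroup
#'     miscalibration of -0.3 on x > 0.}
#'   \item{synthetic-balanced}{the 2000-row class-balanced s = 0 synthetic
#'     dataset (1000 favorable, 1000 unfavorable).}
#' }
#' Repeated calls with the same name and seed produce byte-identical files.
#'
#' @param name one of the registered fixture names.
#' @param dir output directory.
#' @param seed master seed (default 1).
#' @return Invisibly, the paths written.
#' @export
generate_fixture <- function(name, dir, seed = 1L) {
  if (!name %in% FIXTURE_NAMES)
    stop_fairpost(paste0("unknown fixture '", name, "'; registered: ",
                         paste(FIXTURE_NAMES, collapse = ", ")),
                  "fairpost_invalid_argument")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sseed <- substream_seed(seed, paste0("fixture-", name))
  paths <- switch(name,
    "toy-scores" = {
      df <- withr::with_seed(sseed, {
        n <- 48
        g <- rep(0:1, each = n / 2)
        y <- rep(rep(0:1, each = n / 4), 2)
        s <- round(clamp(0.35 + 0.3 * y + 0.1 * g + stats::runif(n, -0.25, 0.25), 0.01, 0.99), 3)
        data.frame(score = s, y = y, group = g)
      })
      p <- file.path(dir, "toy-scores.csv")
      utils::write.csv(df, p, row.names = FALSE)
      p
    },
    "two-attr-correlated" = {
      ds <- simulate_dataset(synth_config(s = 0, n_per_class = 500, seed = sseed))
      B <- withr::with_seed(substream_seed(sseed, "attr-b"), {
        flip <- stats::runif(dataset_n(ds)) < 0.75
        ifelse(flip, 1L - ds$protected$A, ds$protected$A)
      })
      ds$protected$B <- as.integer(B)
      p <- file.path(dir, "two-attr-correlated.csv")
      sp <- file.path(dir, "two-attr-correlated.yaml")
      write_tabular(ds, p, sp)
      c(p, sp)
    },
    "planted-bias" = {
      df <- withr::with_seed(sseed, {
        n <- 400
        x <- stats::runif(n, -1, 1)
        ptrue <- stats::plogis(2 * x)
        y <- as.integer(stats::runif(n) < ptrue)
        score <- round(clamp(ptrue - 0.3 * (x > 0), 0.01, 0.99), 4)
        data.frame(x = round(x, 4), y = y, score = score)
      })
      p <- file.path(dir, "planted-bias.csv")
      utils::write.csv(df, p, row.names = FALSE)
      p
    },
    "synthetic-balanced" = {
      ds <- simulate_dataset(synth_config(s = 0, n_per_class = 1000, seed = sseed))
      p <- file.path(dir, "synthetic-balanced.csv")
      sp <- file.path(dir, "synthetic-balanced.yaml")
      write_tabular(ds, p, sp)
      c(p, sp)
    })
  invisible(paths)
}

#' Benchmark run configuration
#'
#' Validated container tying a whole run together; unknown keys are
#' rejected. Datasets are either synthetic specs
#' (`list(type = "synthetic", s =, n_per_class =)`) or CSV paths with a
#' schema (`list(type = "csv", path =, schema =)`).
#'
#' @param datasets named list of dataset specs (see Details).
#' @param methods methods to benchmark (default all of [debias_methods()]).
#' @param adapters adapter names, subset of c("logistic", "xgboost").
#' @param k folds.
#' @param seed master seed.
#' @param train_ugr optional training unprivileged-group rate.
#' @param healthcare_factor performance-retention line (default 0.9).
#' @param settings fit settings overrides.
#' @return A `run_config`.
#' @export
run_config <- function(datasets, methods = debias_methods(),
                       adapters = "logistic", k = 5L, seed = 1L,
                       train_ugr = NULL, healthcare_factor = 0.9,
                       settings = list()) {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  for (nm in names(datasets)) {
    spec <- datasets[[nm]]
    if (!is.list(spec) || is.null(spec$type) ||
        !spec$type %in% c("synthetic", "csv"))
      stop_fairpost(sprintf("dataset spec '%s' must have type 'synthetic' or 'csv'", nm),
                    "fairpost_invalid_argument")
    known <- if (spec$type == "synthetic") c("type", "s", "n_per_class")
             else c("type", "path", "schema")
    extra <- setdiff(names(spec), known)
    if (length(extra))
      stop_fairpost(sprintf("unknown keys in dataset spec '%s': %s", nm,
                            paste(extra, collapse = ", ")),
                    "fairpost_invalid_argument")
  }
  methods <- vapply(methods, function(m) match.arg(m, debias_methods()), character(1))
  adapters <- vapply(adapters, function(a) match.arg(a, c("logistic", "xgboost")), character(1))
  structure(list(datasets = datasets, methods = unname(methods),
                 adapters = unname(adapters), k = as.integer(k),
                 seed = as.integer(seed), train_ugr = train_ugr,
                 healthcare_factor = healthcare_factor, settings = settings),
            class = "run_config")
}

#' Execute a configured benchmark run and write its outputs
#'
#' Materializes the configured datasets, runs [run_benchmark()], and writes
#' `results.csv`, `policies.csv` and a `manifest.json` (config, seed,
#' package version) to `out_dir`, enabling exact replay.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return The `bench_store`, invisibly.
#' @export
run_from_config <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  datasets <- lapply(names(config$datasets), function(nm) {
    spec <- config$datasets[[nm]]
    if (spec$type == "synthetic") {
      simulate_dataset(synth_config(s = spec$s %||% 0,
                                    n_per_class = spec$n_per_class %||% 1000L,
                                    seed = substream_seed(config$seed, paste0("data-", nm))))
    } else {
      load_tabular(spec$path, spec$schema)
    }
  })
  names(datasets) <- names(config$datasets)
  adapters <- lapply(config$adapters, function(a)
    switch(a, logistic = adapter_logistic(), xgboost = adapter_xgboost()))
  names(adapters) <- config$adapters
  store <- run_benchmark(datasets, adapters, config$methods, k = config$k,
                         seed = config$seed, train_ugr = config$train_ugr,
                         settings = config$settings)
  utils::write.csv(store$results, file.path(out_dir, "results.csv"), row.names = FALSE)
  utils::write.csv(store$policies, file.path(out_dir, "policies.csv"), row.names = FALSE)
  jsonlite::write_json(list(config = unclass(config),
                            package_version = as.character(utils::packageVersion("fairpost"))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(store)
}
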