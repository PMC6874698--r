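#' Load and validate a model specification document
#'
#' Reads a JSON model spec, rejects unknown keys, checks types and
#' ranges, resolves defaults, and builds the corresponding model
#' object.  The validated document (with defaults filled in) is attached
#' so a run can echo its exact configuration.
#'
#' Top-level keys: `schema_version` (1), `kind` (one of `"replicator"`,
#' `"nonlocal_logistic"`, `"stage"`, `"delay"`, `"foerster"`), `grid`
#' (`lower`, `upper`, `nodes`), `coefficients` (kind-specific), `initial`,
#' `solver` (`horizon`, `rtol`, `atol`, `seed`), `output` (`dir`).
#'
#' @param path path to a JSON file.
#' @return an object of class `model_spec`: list with `kind`, `model`
#'   (the built model object, or the initial state for replicator
#'   specs), `solver`, `output` and `document` (the resolved spec).
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) stop("model spec not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  spec_validate(doc)
  doc <- spec_defaults(doc)
  grid <- if (!is.null(doc$grid))
    strategy_grid(as.integer(doc$grid$nodes),
                  interval = c(doc$grid$lower, doc$grid$upper))
  co <- doc$coefficients
  model <- switch(doc$kind,
    replicator = as.numeric(doc$initial$mu),
    nonlocal_logistic = {
      if (!is.null(co$family)) {
        fam <- tradeoff_family(co$family, grid)
        nonlocal_logistic_model(grid, k = fam$k, r = fam$r,
                                rho0 = spec_rho0(doc, grid),
                                coupling = "total")
      } else if (identical(co$k, "transient")) {
        transient_logistic_model(grid)
      } else {
        nonlocal_logistic_model(grid, k = as.numeric(co$k),
                                r = if (is.null(co$r)) 1 else
                                  as.numeric(co$r),
                                rho0 = spec_rho0(doc, grid),
                                coupling = if (is.null(co$coupling))
                                  "total" else co$coupling)
      }
    },
    stage = stage_model(n = length(co$a), b = as.numeric(co$b),
                        a = as.numeric(co$a), p = as.numeric(co$p),
                        R = if (is.null(co$R)) 1 else as.numeric(co$R),
                        grid = grid),
    delay = delay_model(n = as.integer(co$n), tau = as.numeric(co$tau),
                        q = array(as.numeric(unlist(co$q)),
                                  dim = c(co$n, co$n, length(co$tau))),
                        r = matrix(as.numeric(unlist(co$r)), co$n, co$n),
                        R = if (is.null(co$R)) 1 else as.numeric(co$R),
                        grid = grid),
    foerster = foerster_to_delay(tau = as.numeric(co$tau),
                                 a = as.numeric(co$a),
                                 b = as.numeric(co$b),
                                 R = if (is.null(co$R)) 1 else
                                   as.numeric(co$R),
                                 grid = grid))
  structure(list(kind = doc$kind, model = model, solver = doc$solver,
                 output = doc$output, document = doc),
            class = "model_spec")
}

spec_validate <- function(doc) {
  allowed_top <- c("schema_version", "kind", "grid", "coefficients",
                   "initial", "solver", "output")
  extra <- setdiff(names(doc), allowed_top)
  if (length(extra))
    stop("unknown key(s) in model spec: ", paste(extra, collapse = ", "))
  if (is.null(doc$kind)) stop("model spec must declare 'kind' (string)")
  kinds <- c("replicator", "nonlocal_logistic", "stage", "delay",
             "foerster")
  if (!doc$kind %in% kinds)
    stop("'kind' must be one of: ", paste(kinds, collapse = ", "))
  if (!is.null(doc$schema_version) && doc$schema_version != 1)
    stop("'schema_version' must be 1")
  if (!is.null(doc$grid)) {
    ge <- setdiff(names(doc$grid), c("lower", "upper", "nodes"))
    if (length(ge)) stop("unknown key(s) in grid: ",
                         paste(ge, collapse = ", "))
    if (!is.numeric(doc$grid$nodes) || doc$grid$nodes < 3)
      stop("grid 'nodes' must be a number >= 3")
  }
  co <- doc$coefficients
  if (!is.null(co$tau) && any(as.numeric(co$tau) <= 0))
    stop("'tau' must be positive (delays / age thresholds)")
  if (!is.null(doc$solver)) {
    se <- setdiff(names(doc$solver), c("horizon", "rtol", "atol", "seed"))
    if (length(se)) stop("unknown key(s) in solver: ",
                         paste(se, collapse = ", "))
    if (!is.null(doc$solver$horizon) &&
        (!is.numeric(doc$solver$horizon) || doc$solver$horizon <= 0))
      stop("solver 'horizon' must be a positive number")
  }
  invisible(TRUE)
}

spec_defaults <- function(doc) {
  if (is.null(doc$schema_version)) doc$schema_version <- 1
  if (is.null(doc$solver)) doc$solver <- list()
  if (is.null(doc$solver$horizon)) doc$solver$horizon <- 100
  if (is.null(doc$solver$rtol)) doc$solver$rtol <- 1e-8
  if (is.null(doc$solver$atol)) doc$solver$atol <- 1e-10
  if (is.null(doc$output)) doc$output <- list(dir = ".")
  if (doc$kind %in% c("nonlocal_logistic", "stage") && is.null(doc$grid))
    doc$grid <- list(lower = 0, upper = 1, nodes = 101)
  if (!is.null(doc$grid)) {
    if (is.null(doc$grid$lower)) doc$grid$lower <- 0
    if (is.null(doc$grid$upper)) doc$grid$upper <- 1
  }
  if (doc$kind == "replicator" && is.null(doc$initial))
    doc$initial <- list(mu = c(0.2, 0.3, 0.5))
  doc
}

spec_rho0 <- function(doc, grid) {
  if (is.null(doc$initial) || is.null(doc$initial$rho0)) return(1)
  as.numeric(doc$initial$rho0)
}

#' Write a model spec document to JSON
#'
#' Round-trips with [load_model_spec()]: writing a loaded document and
#' loading it again yields an identical resolved document.
#'
#' @param doc a `model_spec` (its resolved document is written) or a
#'   plain list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(doc, path) {
  if (inherits(doc, "model_spec")) doc <- doc$document
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write run outputs with a manifest
#'
#' Serialises a named list of results into an output directory:
#' [density_field()]s as long CSV (`t`, `v`, `eta`), landscapes as CSV
#' (`v`, `J`, `converged`; failed nodes kept with `NA`, not dropped),
#' `root_set`s as CSV (`v`, `re_lambda`, `im_lambda`, `residual`),
#' ranking reports and other lists as JSON.  A `manifest.json` records
#' the files written, the spec (echoed when supplied), the seed and the
#' package version.  The output path is checked to be writable before
#' anything is computed from the results.
#'
#' @param results named list of result objects.
#' @param out_dir output directory (created if needed).
#' @param spec optional `model_spec` to echo alongside the results.
#' @param seed optional seed to record.
#' @return the manifest, invisibly.
#' @export
write_results <- function(results, out_dir, spec = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); file.remove(probe); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("output directory is not writable: ", out_dir)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "density_field")) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      write_field_csv(x, f)
    } else if (inherits(x, "fitness_landscape") ||
               inherits(x, "analytic_landscape")) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(x), f, row.names = FALSE, na = "NA")
    } else if (inherits(x, "root_set")) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      df <- data.frame(re_lambda = x$re, im_lambda = x$im,
                       residual = x$residual)
      utils::write.csv(df, f, row.names = FALSE, na = "NA")
    } else if (inherits(x, "ranking_report")) {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(list(pair = as.list(x$pair),
                                verdict = x$verdict, radius = x$radius,
                                tolerance = x$tolerance,
                                initial_measures =
                                  as.list(x$initial_measures)),
                           f, auto_unbox = TRUE, digits = NA)
    } else if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE, na = "NA")
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    }
    files <- c(files, f)
  }
  manifest <- list(
    files = basename(files),
    seed = seed,
    package = "evofit",
    version = as.character(utils::packageVersion("evofit")))
  if (!is.null(spec)) {
    spec_path <- file.path(out_dir, "spec_echo.json")
    write_model_spec(spec, spec_path)
    manifest$spec <- "spec_echo.json"
    manifest$spec_sha <- unname(tools::md5sum(spec_path))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
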