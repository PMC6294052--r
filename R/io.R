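## ------------------------------------------------------------------------
## Configuration files, experiment presets mirroring the published figure
## scenarios at desk scale, and tidy CSV output.
## ------------------------------------------------------------------------

config_keys <- c("F", "M", "gamma", "lambda", "y", "tau", "r", "K", "m",
                 "sr", "e", "n", "s", "delta", "c", "bank", "replicates",
                 "seed")

parse_config_value <- function(key, value) {
  if (key == "bank") {
    v <- tolower(value)
    if (v %in% c("true", "1", "on", "yes")) return(TRUE)
    if (v %in% c("false", "0", "off", "no")) return(FALSE)
    stop("config: cannot parse bank = '", value, "'")
  }
  x <- suppressWarnings(as.numeric(value))
  if (is.na(x)) stop("config: cannot parse ", key, " = '", value, "'")
  x
}

#' Load simulation parameters from a flat config file and overrides
#'
#' Reads a flat `key = value` text file whose keys are the model's
#' parameter symbols (`F`, `M`, `gamma`, `lambda`, `y`, `tau`, `r`, `K`,
#' `m`, `sr`, `e`, `n`, `s`, `delta`, `c`, `bank`, `replicates`, `seed`);
#' `#` starts a comment.  Values in `overrides` (e.g. command-line flags)
#' take precedence over the file.  Missing keys fall back to the package
#' defaults of [sim_params()].
#'
#' @param path Path to the config file, or `NULL` for defaults only.
#' @param overrides Named list of symbol-keyed overrides.
#' @return A list with `params` (a validated [sim_params()]) and `seed`
#'   (or `NULL` if none was given).
#' @export
#' @examples
#' cfg <- tempfile()
#' writeLines(c("K = 2e4", "M = 100  # migrant eggs"), cfg)
#' load_config(cfg, overrides = list(K = 2e5))$params$K  # flag wins
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    bad_lines <- !grepl("=", lines, fixed = TRUE)
    if (any(bad_lines)) {
      stop("config: lines without 'key = value': ",
           paste(lines[bad_lines], collapse = "; "))
    }
    keys <- trimws(sub("=.*$", "", lines))
    strs <- trimws(sub("^[^=]*=", "", lines))
    unknown <- setdiff(keys, config_keys)
    if (length(unknown)) {
      stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
    }
    for (i in seq_along(keys)) {
      vals[[keys[i]]] <- parse_config_value(keys[i], strs[i])
    }
  }
  unknown <- setdiff(names(overrides), config_keys)
  if (length(unknown)) {
    stop("config: unknown override key(s): ",
         paste(unknown, collapse = ", "))
  }
  vals <- modifyList(vals, overrides)
  seed <- vals$seed
  vals$seed <- NULL
  params <- if (length(vals)) {
    params_with(sim_params(), vals)
  } else {
    sim_params()
  }
  list(params = params, seed = if (is.null(seed)) NULL else as.integer(seed))
}

results_columns <- c("preset", "replicate", "seed", "y", "K", "r", "M",
                     "F", "delta", "c", "bank", "fst", "fstq", "h_t",
                     "h_s", "census_1", "census_2", "extinct_flag")

#' Write experiment results to a tidy CSV file
#'
#' Writes the fixed-header tidy table (one row per combination, replicate
#' and recorded generation) produced by [run_experiment()].  Numbers are
#' written at full precision so a read-back reproduces the in-memory
#' values.
#'
#' @param results Tibble from [run_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(nrow(results) >= 1)
  missing_cols <- setdiff(results_columns, names(results))
  if (length(missing_cols)) {
    stop("results table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  readr::write_csv(results[, results_columns], path, progress = FALSE)
  invisible(path)
}

#' Experiment presets mirroring the published figure scenarios
#'
#' Parameter grids for the simulation experiments behind each results
#' figure, at a desk-scale default of 10 replicates; `full = TRUE`
#' restores the full replicate counts (50, or 100 for the selection and
#' recombination scenarios).  Fixed parameters follow the figure
#' captions; the migration grid of `fig2` is a reconstruction spanning
#' the stated 0 to 1e5 range, as the caption does not enumerate its tick
#' values.
#'
#' @param name One of `"fig2"` (FST vs migration), `"fig3"` (FST vs
#'   carrying capacity), `"fig4"` (4,000-generation time course),
#'   `"fig5"` (growth rate x carrying capacity), `"fig6"` (number of
#'   founders) or `"fig7"` (selection x recombination).
#' @param full Use the full replicate counts?
#' @return List of class `"experiment_preset"` with `name`, `grid`,
#'   `replicates` and `record_every`.
#' @export
#' @examples
#' preset("fig3")$grid
preset <- function(name, full = FALSE) {
  K_all <- 2 * 10^(2:7)
  grids <- list(
    fig2 = expand.grid(M = c(0, 1, 2, 10, 100, 1000, 1e4, 1e5),
                       K = c(2e2, 2e7), bank = c(TRUE, FALSE),
                       r = 0.3, s = 0, F = 1, y = 1000),
    fig3 = expand.grid(K = K_all, bank = c(TRUE, FALSE), M = 2, r = 0.3,
                       s = 0, F = 1, y = 1000),
    fig4 = expand.grid(K = K_all, bank = c(TRUE, FALSE), M = 2, r = 0.3,
                       s = 0, F = 1, y = 4000),
    fig5 = expand.grid(r = c(0.05, 0.1, 0.2, 0.3, 0.5, 1), K = K_all,
                       bank = c(TRUE, FALSE), M = 2, s = 0, F = 1,
                       y = 1000),
    fig6 = expand.grid(F = c(1, 2, 5, 50), K = c(2e4, 2e7),
                       bank = c(TRUE, FALSE), M = 2, r = 0.3, s = 0,
                       y = 4000),
    fig7 = expand.grid(c = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                       delta = c(1e-4, 1e-2), K = c(2e4, 2e7),
                       bank = TRUE, M = 2, r = 0.3, n = 5, s = 5, F = 1,
                       y = 1000)
  )
  if (!name %in% names(grids)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(grids), collapse = ", "))
  }
  replicates <- if (!full) 10L else if (name == "fig7") 100L else 50L
  record_every <- if (name %in% c("fig4", "fig6")) 10L else 1L
  structure(list(name = name, grid = tibble::as_tibble(grids[[name]]),
                 replicates = replicates, record_every = record_every),
            class = "experiment_preset")
}

#' Run an experiment preset
#'
#' @param x An [preset()] object or preset name.
#' @param seed Master seed.
#' @param ... Passed to [run_experiment()].
#' @return Tidy results tibble (see [run_experiment()]).
#' @export
run_preset <- function(x, seed = 1, ...) {
  if (is.character(x)) x <- preset(x)
  stopifnot(inherits(x, "experiment_preset"))
  run_experiment(x$grid, replicates = x$replicates, seed = seed,
                 record_every = x$record_every, label = x$name, ...)
}
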