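#' Load a run configuration from YAML or JSON
#'
#' A configuration supplies a `mode` (one of `simulate`, `analytic`,
#' `higuchi`, `constant-rate`, `deviation`, `sweep`), exactly one of a
#' `physical:` block (fields `D`, `k`, `A0`, `r0`, `Cs`, `Ca0`, `n`) or a
#' `dimensionless:` block (fields `K`, `G`, `n`), and optional `mesh`
#' (node count) and `solver` (fields of [solver_options()]) blocks.
#' Defaults: 2000 mesh nodes, relative integration tolerance 1e-3,
#' quadrature tolerance 1e-6. Unknown keys are an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `run_config`: list with `mode`, `params`
#'   (a [dimensionless_params()]; physical blocks are converted via
#'   [nondimensionalize()]), `physical` (the original [physical_params()]
#'   or `NULL`), `mesh` and `solver`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("mode", "physical", "dimensionless", "mesh", "solver", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  modes <- c("simulate", "analytic", "higuchi", "constant-rate",
             "deviation", "sweep")
  mode <- cfg$mode %||% "simulate"
  if (!mode %in% modes) {
    stop("'mode' must be one of: ", paste(modes, collapse = ", "),
         call. = FALSE)
  }
  has_phys <- !is.null(cfg$physical)
  has_dim <- !is.null(cfg$dimensionless)
  if (has_phys == has_dim) {
    stop("supply exactly one of a 'physical' or a 'dimensionless' block",
         call. = FALSE)
  }
  physical <- NULL
  if (has_phys) {
    b <- cfg$physical
    check_block_keys(b, c("D", "k", "A0", "r0", "Cs", "Ca0", "n"), "physical")
    physical <- physical_params(D = b$D, k = b$k, A0 = b$A0, r0 = b$r0,
                                Cs = b$Cs, Ca0 = b$Ca0, n = b$n %||% 0)
    params <- nondimensionalize(physical)
  } else {
    b <- cfg$dimensionless
    check_block_keys(b, c("K", "G", "n"), "dimensionless")
    params <- dimensionless_params(K = b$K, G = b$G, n = b$n %||% 0)
  }
  mesh_n <- cfg$mesh %||% 2000L
  solver_args <- cfg$solver %||% list()
  check_block_keys(solver_args,
                   c("rel_tol", "abs_tol", "quad_rel_tol", "front_epsilon",
                     "output_tau", "n_out", "max_steps"), "solver")
  solver <- do.call(solver_options, solver_args)
  structure(list(mode = mode, params = params, physical = physical,
                 mesh = release_mesh(mesh_n), solver = solver,
                 output = cfg$output %||% NULL),
            class = "run_config")
}

check_block_keys <- function(block, known, name) {
  unknown <- setdiff(names(block), known)
  if (length(unknown)) {
    stop(sprintf("unknown keys in '%s' block: %s", name,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  invisible(block)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis result to CSV with a JSON sidecar
#'
#' Writes the tabular part of a result (a [release_curve()], a
#' [higuchi_solution()], a `constant_rate_region`, a `deviation_summary`,
#' or a [release_sweep()] data frame) as CSV with full double precision
#' (15 significant digits), plus a `<path>.json` sidecar carrying the
#' parameters, options, package version and a timestamp, from which the run
#' can be reproduced exactly (the pipeline is deterministic).
#'
#' @param x the result object.
#' @param path output CSV path.
#' @param params optional [dimensionless_params()] recorded in the sidecar
#'   (taken from the result itself where it carries one).
#' @param extra optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, params = NULL, extra = NULL) {
  df <- result_as_data_frame(x)
  if (is.null(params)) params <- result_params(x)
  dfx <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.15g", col) else col
  }), stringsAsFactors = FALSE)
  names(dfx) <- names(df)
  utils::write.csv(dfx, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    class = class(x)[1],
    params = if (is.null(params)) NULL else
      list(K = params$K, G = params$G, n = params$n),
    package = "matrixrelease",
    version = as.character(utils::packageVersion("matrixrelease")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(extra)) sidecar <- c(sidecar, extra)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

result_as_data_frame <- function(x) {
  if (inherits(x, "release_solution")) return(as.data.frame(release_curve(x)))
  if (inherits(x, "constant_rate_region")) {
    return(data.frame(K = x$K, G = x$G, n = x$n, tau_s = x$tau_s,
                      tau_c = x$tau_c, rate_start = x$rate_start,
                      rate_end = x$rate_end, rate_middle = x$rate_middle,
                      coverage_percent = x$coverage_percent,
                      negligible = x$negligible))
  }
  if (inherits(x, "deviation_summary")) {
    return(data.frame(tau = x$tau, fraction_present = x$fraction_present,
                      fraction_higuchi = x$fraction_higuchi,
                      deviation = x$deviation))
  }
  if (is.data.frame(x)) return(as.data.frame(x))
  stop("no CSV representation for objects of class ", class(x)[1],
       call. = FALSE)
}

result_params <- function(x) {
  if (inherits(x, "release_solution")) return(x$params)
  if (inherits(x, "deviation_summary")) return(x$params)
  if (inherits(x, "constant_rate_region")) {
    return(dimensionless_params(x$K, x$G, x$n))
  }
  NULL
}

#' Named parameterizations of the studied release systems
#'
#' Returns the exact `(K, G, n)` triple of a documented study case, for use
#' in scripted reproductions. Cases follow the naming scheme
#' `table1_K<1/K>_G<G>_n<0|12|23>` (the zero-order-window study over
#' `K` in \{1/2, 1/101\}, `G` in \{0.1, 1, 10\} and the three shapes),
#' `table2_K<1/K>_G<G>` (the Higuchi-deviation study, spherical particles,
#' `K` in \{1/2, 1/11, 1/101\}, `G` in \{1, 10, 1e3, 1e5\}),
#' `fig2a_K<1/K>` (planar validation at `G = 1e3`) and `fig2b_G<G>`
#' (planar validation at `K = 1/101`).
#'
#' @param case_id a fixture name, e.g. `"table1_K101_G0.1_n0"`; call
#'   `make_fixture()` without arguments to list all names.
#' @return A [dimensionless_params()] object, or (with no `case_id`) a
#'   character vector of valid names.
#' @examples
#' make_fixture("table2_K2_G1")
#' head(make_fixture())
#' @export
make_fixture <- function(case_id) {
  reg <- fixture_registry()
  if (missing(case_id)) return(names(reg))
  if (!case_id %in% names(reg)) {
    stop("unknown case '", case_id, "'; valid cases:\n  ",
         paste(names(reg), collapse = "\n  "), call. = FALSE)
  }
  p <- reg[[case_id]]
  dimensionless_params(K = p[1], G = p[2], n = p[3])
}

fixture_registry <- function() {
  reg <- list()
  k_code <- c("K2" = 1 / 2, "K11" = 1 / 11, "K101" = 1 / 101)
  n_code <- c("n0" = 0, "n12" = 1 / 2, "n23" = 2 / 3)
  for (kc in c("K2", "K101")) for (G in c(0.1, 1, 10)) for (nc in names(n_code)) {
    reg[[sprintf("table1_%s_G%g_%s", kc, G, nc)]] <-
      c(k_code[[kc]], G, n_code[[nc]])
  }
  for (kc in c("K2", "K11", "K101")) for (G in c(1, 10, 1e3, 1e5)) {
    reg[[sprintf("table2_%s_G%g", kc, G)]] <- c(k_code[[kc]], G, 2 / 3)
  }
  for (kc in names(k_code)) {
    reg[[sprintf("fig2a_%s", kc)]] <- c(k_code[[kc]], 1e3, 0)
  }
  for (G in c(10, 100, 1000)) {
    reg[[sprintf("fig2b_G%g", G)]] <- c(1 / 101, G, 0)
  }
  reg
}
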