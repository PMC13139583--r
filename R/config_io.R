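#' Run configuration
#'
#' A run configuration is a JSON file with optional sections `model`,
#' `gate`, `geometry`, `solver`, `noise`, `synth`, plus a global `seed` and
#' an `out_dir`. Missing fields are filled with the package defaults (the
#' default parameter sets of the models); unknown keys are rejected with
#' their paths.
#'
#' @param path Path to a JSON run-config file.
#' @return A validated list of class `evseq_config` with constructed
#'   component objects (`$geometry`, `$solver`, `$noise`, and the raw
#'   `$model`, `$gate`, `$synth` sections).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (file.size(path) == 0) list() else
    jsonlite::read_json(path, simplifyVector = TRUE)
  build_config(raw)
}

build_config <- function(raw) {
  known <- c("model", "gate", "geometry", "solver", "noise", "synth",
             "seed", "out_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  section <- function(name, formals_of) {
    sec <- raw[[name]]
    if (is.null(sec)) sec <- list()
    extra <- setdiff(names(sec), names(formals(formals_of)))
    if (length(extra))
      stop("unknown keys in section '", name, "': ",
           paste(extra, collapse = ", "))
    sec
  }
  geometry <- do.call(maze_geometry, section("geometry", maze_geometry))
  solver <- do.call(solver_config, section("solver", solver_config))
  noise <- do.call(noise_config, section("noise", noise_config))
  model_sec <- raw$model
  if (is.null(model_sec)) model_sec <- list(name = "mutual")
  model_name <- if (is.null(model_sec$name)) "mutual" else model_sec$name
  margs <- model_sec[setdiff(names(model_sec), "name")]
  params <- if (model_name %in% c("mutual", "uncoupled", "unstable")) {
    do.call(chain_params, c(margs, list(variant = model_name)))
  } else if (model_name %in% c("bump", "trad_bump")) {
    do.call(bump_params, margs)
  } else if (model_name == "trad_accum") NULL
  else stop("unknown model name: ", model_name)
  gate_sec <- raw$gate
  gate <- if (is.null(gate_sec)) NULL else {
    gname <- if (is.null(gate_sec$name)) "square" else gate_sec$name
    gargs <- gate_sec[setdiff(names(gate_sec), "name")]
    switch(gname,
           square = do.call(square_gate, c(gargs, list(geometry = geometry))),
           gaussian = do.call(gaussian_gate,
                              c(gargs, list(geometry = geometry))),
           heterogeneous = do.call(draw_heterogeneous_gates,
                                   c(gargs, list(geometry = geometry))),
           stop("unknown gate name: ", gname))
  }
  synth <- raw$synth
  structure(list(model = model_name, params = params, gate = gate,
                 geometry = geometry, solver = solver, noise = noise,
                 synth = synth,
                 seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
                 out_dir = raw$out_dir),
            class = "evseq_config")
}

#' @rdname load_config
#' @param config An `evseq_config` (or plain list of sections).
#' @export
save_config <- function(config, path) {
  raw <- attr(config, "raw")
  out <- if (!is.null(raw)) raw else config
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write / read analysis outputs
#'
#' Writes a named list of results to a directory (created if missing):
#' data frames and matrices as CSV (`<name>.csv`; matrices keep row
#' names), everything else as JSON. `read_outputs()` restores the same
#' structure; integers and identifiers round-trip losslessly, rates at
#' full double precision.
#'
#' @param results Named list of data frames / matrices / lists.
#' @param dir Output directory.
#' @return `write_outputs` returns `dir` invisibly; `read_outputs` the
#'   restored list.
#' @export
write_outputs <- function(results, dir) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kinds <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.matrix(x)) {
      utils::write.csv(as.data.frame(x), file.path(dir, paste0(nm, ".csv")),
                       row.names = TRUE)
      kinds[[nm]] <- "matrix"
    } else if (is.data.frame(x)) {
      utils::write.csv(x, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
      kinds[[nm]] <- "data.frame"
    } else {
      jsonlite::write_json(x, file.path(dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
      kinds[[nm]] <- "json"
    }
  }
  jsonlite::write_json(kinds, file.path(dir, "_manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_outputs
#' @export
read_outputs <- function(dir) {
  man_path <- file.path(dir, "_manifest.json")
  if (!file.exists(man_path)) stop("not an outputs directory (no manifest): ",
                                   dir)
  kinds <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  out <- list()
  for (nm in names(kinds)) {
    out[[nm]] <- switch(kinds[[nm]],
      matrix = {
        df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                              row.names = 1, check.names = FALSE)
        as.matrix(df)
      },
      data.frame = utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                   stringsAsFactors = FALSE),
      json = jsonlite::read_json(file.path(dir, paste0(nm, ".json")),
                                 simplifyVector = TRUE))
  }
  out
}
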