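#' Load and validate a run configuration
#'
#' Configurations are JSON or YAML mappings with fields
#' `potential` (`{"name": ..., "params": {...}}`), `eps`, `dt`, `n_steps`,
#' and optionally `n_paths` (default 100), `seed` (default 1), `x0`
#' (default 0). Defaults are filled in and echoed in the returned object.
#'
#' @param file Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
  ext <- tolower(tools::file_ext(file))
  raw <- switch(ext,
    json = jsonlite::fromJSON(file, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(file),
    stop("config must be .json, .yaml or .yml", call. = FALSE))
  validate_config(raw)
}

#' @rdname load_config
#' @param config A configuration list (possibly partial).
#' @export
validate_config <- function(config) {
  num <- function(field, default = NULL, positive = FALSE) {
    v <- config[[field]] %||% default
    if (is.null(v))
      stop("config field '", field, "' is required", call. = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("config field '", field, "' must be a finite number", call. = FALSE)
    if (positive && v <= 0)
      stop("config field '", field, "' must be positive", call. = FALSE)
    as.numeric(v)  # JSON/YAML may deliver integers; normalise to double
  }
  pot <- config$potential
  if (is.null(pot$name))
    stop("config field 'potential' needs a 'name'", call. = FALSE)
  par <- lapply(as.list(pot$params),
                function(v) if (is.numeric(v)) as.numeric(v) else v)
  # constructing the potential performs its own parameter validation
  make_potential(pot$name, par)
  cfg <- list(
    potential = list(name = pot$name, params = par),
    eps = num("eps", positive = TRUE),
    dt = num("dt", positive = TRUE),
    n_steps = as.integer(num("n_steps", positive = TRUE)),
    n_paths = as.integer(num("n_paths", default = 100, positive = TRUE)),
    seed = as.integer(num("seed", default = 1)),
    x0 = num("x0", default = 0)
  )
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config A `run_config`.
#' @param file Destination path (`.json`, `.yaml`, `.yml`).
#' @export
save_config <- function(config, file) {
  stopifnot(inherits(config, "run_config"))
  ext <- tolower(tools::file_ext(file))
  x <- unclass(config)
  switch(ext,
    json = jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(x, file),
    stop("config must be .json, .yaml or .yml", call. = FALSE))
  invisible(file)
}

config_process <- function(config) {
  process_spec(make_potential(config$potential$name, config$potential$params),
               config$eps)
}

#' Write and read path ensembles as annotated TSV
#'
#' One column per path, positions printed with 17 significant digits so the
#' text round-trip reproduces every double exactly. A commented header
#' carries the grid, temperature, potential spec (JSON) and seed; on read
#' the header is parsed back and, when `process` is supplied, checked
#' against it.
#'
#' @param paths A [as_paths()] ensemble.
#' @param file Destination / source path.
#' @param process Optional [process_spec()] whose metadata is stored
#'   (written) or checked against the header (read).
#' @return `write_paths` invisibly returns `file`; `read_paths` returns a
#'   [as_paths()] ensemble.
#' @export
write_paths <- function(paths, file, process = attr(paths, "process")) {
  stopifnot(inherits(paths, "bd_paths"))
  if (ncol(paths) < 1L) stop("empty ensemble", call. = FALSE)
  grid <- path_grid(paths)
  prov <- attr(paths, "provenance")
  hdr <- c(
    sprintf("# dt=%.17g", grid$dt),
    sprintf("# n_steps=%d", grid$n_steps),
    if (!is.null(process)) sprintf("# eps=%.17g", process$temperature),
    if (!is.null(process))
      sprintf("# potential=%s", jsonlite::toJSON(
        list(name = process$potential$name, params = process$potential$params),
        auto_unbox = TRUE, digits = NA)),
    if (!is.null(prov$seed)) sprintf("# seed=%d", as.integer(prov$seed))
  )
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste0("path", seq_len(ncol(paths)), collapse = "\t"), con)
  x <- unclass(paths)
  fmt <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_paths
#' @export
read_paths <- function(file, process = NULL) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  if (is.null(meta$dt) || is.null(meta$n_steps))
    stop("path file header must carry dt and n_steps", call. = FALSE)
  grid <- time_grid(as.numeric(meta$dt), as.integer(meta$n_steps))
  if (!is.null(process)) {
    if (!is.null(meta$eps) &&
        !isTRUE(all.equal(as.numeric(meta$eps), process$temperature)))
      stop(sprintf(
        "file was written at eps = %s but the requested process has eps = %g",
        meta$eps, process$temperature), call. = FALSE)
    if (!is.null(meta$potential)) {
      stored <- jsonlite::fromJSON(meta$potential)
      if (!identical(stored$name, process$potential$name))
        stop(sprintf("file potential '%s' does not match requested '%s'",
                     stored$name, process$potential$name), call. = FALSE)
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)][-1L]  # drop column header row
  if (length(body) == 0L) stop("no path data in file", call. = FALSE)
  x <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  file_proc <- process
  if (is.null(file_proc) && !is.null(meta$potential) && !is.null(meta$eps)) {
    stored <- jsonlite::fromJSON(meta$potential)
    file_proc <- process_spec(make_potential(stored$name, as.list(stored$params)),
                              as.numeric(meta$eps))
  }
  as_paths(x, grid, process = file_proc,
           provenance = list(seed = if (!is.null(meta$seed))
             as.integer(meta$seed), generator = "file"))
}
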