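# On-disk format for series sets: one CSV per series with header t,x1..xN and
# values at 17 significant digits (lossless double round trip), plus a JSON
# sidecar carrying the step size, parameters and seeds. Human-inspectable and
# sufficient at desk-scale data volumes.

#' Write a series set to a directory
#'
#' Writes `series_001.csv`, `series_002.csv`, ... (columns `t,x1..xN`) and a
#' sidecar `seriesset.json` with the parameters, simulation settings and
#' per-series seeds. [read_series] restores the set bit-identically.
#'
#' @param series an `"lca_series"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  stopifnot(inherits(series, "lca_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- series$params$n
  for (s in seq_len(series$n_series)) {
    m <- series_matrix(series, s)
    df <- cbind(t = series$times, m)
    txt <- apply(df, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
    writeLines(c(paste(c("t", colnames(m)), collapse = ","), txt),
               file.path(dir, sprintf("series_%03d.csv", s)))
  }
  sidecar <- list(
    n_alternatives = n, dt = series$dt, n_steps = series$n_steps,
    n_series = series$n_series, x0 = series$x0, scheme = series$scheme,
    seed = series$seed, series_seeds = series$series_seeds,
    params = list(kappa = series$params$kappa, beta = series$params$beta,
                  inputs = series$params$inputs, xi = series$params$xi))
  jsonlite::write_json(sidecar, file.path(dir, "seriesset.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a series set written by [write_series]
#'
#' @param dir directory containing `series_*.csv` and `seriesset.json`.
#' @return An `"lca_series"` object.
#' @export
read_series <- function(dir) {
  sidecar_path <- file.path(dir, "seriesset.json")
  if (!file.exists(sidecar_path))
    stop("missing sidecar 'seriesset.json' in ", dir,
         " (it carries the step size required for likelihood work)")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^series_[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no series_*.csv files in ", dir)
  n <- as.integer(meta$n_alternatives)
  n_steps <- as.integer(meta$n_steps)
  states <- array(NA_real_, dim = c(length(files), n_steps, n))
  times <- NULL
  for (k in seq_along(files)) {
    lines <- readLines(files[k])
    hdr <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
    if (length(hdr) != n + 1L || hdr[1L] != "t" ||
        !identical(hdr[-1L], paste0("x", seq_len(n))))
      stop(sprintf("%s: header does not match the sidecar (expected t,x1..x%d)",
                   basename(files[k]), n))
    body <- strsplit(lines[-1L], ",", fixed = TRUE)
    bad <- which(lengths(body) != n + 1L)
    if (length(bad))
      stop(sprintf("%s: ragged row at line %d", basename(files[k]), bad[1L] + 1L))
    m <- matrix(as.numeric(unlist(body)), ncol = n + 1L, byrow = TRUE)
    if (nrow(m) != n_steps)
      stop(sprintf("%s: %d rows, sidecar says %d", basename(files[k]),
                   nrow(m), n_steps))
    tt <- m[, 1L]
    steps <- diff(tt)
    if (any(steps <= 0) ||
        max(abs(steps - meta$dt)) > 1e-9 * max(1, abs(meta$dt)))
      stop(sprintf("%s: time column is not a uniform grid with dt = %g",
                   basename(files[k]), meta$dt))
    if (is.null(times)) times <- tt
    states[k, , ] <- m[, -1L, drop = FALSE]
  }
  params <- lca_params(meta$params$kappa, meta$params$beta,
                       as.numeric(meta$params$inputs), meta$params$xi)
  structure(
    list(times = times, states = states, params = params, dt = meta$dt,
         n_steps = n_steps, n_series = length(files),
         x0 = as.numeric(meta$x0), scheme = meta$scheme,
         seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed),
         series_seeds = as.integer(meta$series_seeds)),
    class = "lca_series"
  )
}
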