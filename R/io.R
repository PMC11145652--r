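# Trace sets on disk: one two-column plain-text file per trace
# (time in us, amplitude) plus a YAML manifest carrying mixing times and
# roles. Times are always us, concentrations mol/L, sigma MHz, end to end.

#' Write a trace set to a directory
#'
#' Each trace becomes a two-column text file (`time_us amplitude`, full
#' double precision) and a YAML manifest (`manifest.yml`) records file
#' names, mixing times and roles (`main`/`reference`), plus the
#' deconvolution state of the set.
#'
#' @param set A [trace_set()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix for main traces. Default `"trace"`.
#' @return Invisibly, the manifest path.
#' @export
write_traceset <- function(set, dir, prefix = "trace") {
  stopifnot(is_trace_set(set))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  write_one <- function(tr, file) {
    con <- file.path(dir, file)
    header <- c("# ih-RIDME decay trace",
                "# columns: time_us amplitude",
                sprintf("# t_mix_us: %.17g", tr$t_mix))
    body <- sprintf("%.17g %.17g", tr$t, tr$v)
    writeLines(c(header, body), con)
  }
  for (i in seq_along(set$main)) {
    file <- sprintf("%s_%02d.dat", prefix, i)
    write_one(set$main[[i]], file)
    entries[[length(entries) + 1L]] <-
      list(file = file, t_mix_us = set$main[[i]]$t_mix, role = "main")
  }
  if (!is.null(set$reference)) {
    write_one(set$reference, "reference.dat")
    entries[[length(entries) + 1L]] <-
      list(file = "reference.dat", t_mix_us = set$reference$t_mix,
           role = "reference")
  }
  manifest <- list(format = "ihridme-traceset-1",
                   units = list(time = "us", amplitude = "dimensionless"),
                   deconvolved = set$deconvolved,
                   traces = entries)
  if (set$deconvolved) manifest$ref_t_mix_us <- set$ref_t_mix
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, path, precision = 17)
  invisible(path)
}

read_trace_file <- function(path, t_mix) {
  lines <- readLines(path)
  data_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(data_idx)) stop("no data rows in ", path)
  fields <- strsplit(trimws(lines[data_idx]), "\\s+|,")
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s", data_idx[bad[1]], path))
  }
  m <- vapply(fields, function(f) suppressWarnings(as.numeric(f)), numeric(2))
  if (any(!is.finite(m))) {
    j <- which(colSums(!is.finite(m)) > 0)[1]
    stop(sprintf("non-finite value at line %d of %s", data_idx[j], path))
  }
  t <- m[1, ]; v <- m[2, ]
  if (any(diff(t) <= 0)) {
    j <- which(diff(t) <= 0)[1] + 1L
    stop(sprintf("time not strictly increasing at line %d of %s",
                 data_idx[j], path))
  }
  trace(t, v, t_mix)
}

#' Read a trace set from a manifest
#'
#' Reads the YAML manifest written by [write_traceset()] (or assembled by
#' hand), validates every trace file (strictly increasing times, finite
#' values — NaN/Inf are rejected with the offending line number), and
#' returns the set ordered by mixing time. A non-deconvolved manifest must
#' name exactly one reference trace.
#'
#' @param manifest Path to `manifest.yml`.
#' @return A [trace_set()].
#' @export
read_traceset <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  cfg <- yaml::read_yaml(manifest)
  if (is.null(cfg$traces) || length(cfg$traces) < 2L) {
    stop("manifest must list at least two traces")
  }
  dir <- dirname(manifest)
  roles <- vapply(cfg$traces, function(e) e$role %||% "main", character(1))
  deconvolved <- isTRUE(cfg$deconvolved)
  if (!deconvolved && sum(roles == "reference") != 1L) {
    stop("manifest must designate exactly one reference trace")
  }
  if (deconvolved && any(roles == "reference")) {
    stop("a deconvolved manifest cannot contain a reference trace")
  }
  traces <- lapply(cfg$traces, function(e) {
    if (is.null(e$file) || is.null(e$t_mix_us)) {
      stop("each manifest entry needs 'file' and 't_mix_us'")
    }
    read_trace_file(file.path(dir, e$file), as.numeric(e$t_mix_us))
  })
  main <- traces[roles == "main"]
  t_mixes <- vapply(main, function(tr) tr$t_mix, numeric(1))
  if (anyDuplicated(t_mixes)) stop("duplicate t_mix among main traces")
  reference <- if (any(roles == "reference")) traces[[which(roles == "reference")]]
               else NULL
  trace_set(main, reference = reference, deconvolved = deconvolved,
            ref_t_mix = if (deconvolved) as.numeric(cfg$ref_t_mix_us) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a global-fit result to CSV plus a JSON sidecar
#'
#' CSV columns: `c_grid`, `p`, `lower`, `upper` (the band columns are `NA`
#' if no [uncertainty_band()] was computed). The sidecar records λ, k₃,
#' per-trace residual norms and weights.
#'
#' @param result A `ridme_fit` from [global_fit()].
#' @param csv_path Output CSV path.
#' @param json_path Output JSON path; default replaces the CSV extension.
#' @return Invisibly, `csv_path`.
#' @export
write_fit_result <- function(result, csv_path,
                             json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(result, "ridme_fit"))
  band <- result$uncertainty_band
  df <- data.frame(c_grid = result$density$c_grid,
                   p = result$density$p,
                   lower = if (is.null(band)) NA_real_ else band$lower,
                   upper = if (is.null(band)) NA_real_ else band$upper)
  utils::write.csv(df, csv_path, row.names = FALSE)
  side <- list(lambda_reg = result$lambda_reg,
               k3 = result$constants$k3,
               k3_fitted = !is.null(result$k3_fitted),
               residual_norms = result$residual_norms,
               weights = result$weights,
               objective = result$objective)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Read a fitted density from the CSV written by [write_fit_result()]
#' @param csv_path CSV path.
#' @return A [density_distribution].
#' @export
read_density_csv <- function(csv_path) {
  df <- utils::read.csv(csv_path)
  density_distribution(df$c_grid, df$p)
}

#' Write / read a Gaussian mixture as JSON
#' @param mixture A [gaussian_mixture].
#' @param path JSON file path.
#' @return `write_mixture_json`: invisibly, `path`;
#'   `read_mixture_json`: a [gaussian_mixture].
#' @export
write_mixture_json <- function(mixture, path) {
  stopifnot(is_mixture(mixture))
  jsonlite::write_json(list(means = mixture$means, widths = mixture$widths,
                            fractions = mixture$fractions),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_mixture_json
#' @export
read_mixture_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  gaussian_mixture(m$means, m$widths, m$fractions, normalize = TRUE)
}

#' Export a mixture as a table (Mean, Width, Fraction)
#' @param mixture A [gaussian_mixture].
#' @param path CSV file path.
#' @return Invisibly, `path`.
#' @export
write_mixture_csv <- function(mixture, path) {
  stopifnot(is_mixture(mixture))
  utils::write.csv(data.frame(Mean = mixture$means, Width = mixture$widths,
                              Fraction = mixture$fractions),
                   path, row.names = FALSE)
  invisible(path)
}
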