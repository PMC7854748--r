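#' Read and write plain-text trace files
#'
#' Traces are stored as comma-separated text with `# key: value`
#' metadata header lines followed by a `time_s,potential_V,current`
#' column header.  Numeric values survive a write/read round trip to
#' better than 1e-12 (they are written with 17 significant digits) and
#' metadata exactly.  Potentials are always stored vs SHE.
#'
#' @param path file path.
#' @return `read_trace` returns a [pfe_trace()]; `write_trace` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  header_at <- which(!is_meta)[1]
  if (is.na(header_at)) stop_parse("no column header found")
  meta <- list()
  for (i in seq_len(header_at - 1)) {
    m <- regmatches(lines[i], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3)
      stop_parse(sprintf("line %d: malformed metadata line '%s'", i, lines[i]))
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (!is.na(num)) num else val
  }
  cols <- strsplit(lines[header_at], ",")[[1]]
  need <- c("time_s", "potential_V", "current")
  if (!identical(trimws(cols), need))
    stop_parse(sprintf("line %d: expected columns %s", header_at,
                       paste(need, collapse = ",")))
  body <- lines[-seq_len(header_at)]
  body <- body[nzchar(body)]
  if (length(body) == 0) stop_parse("no data rows")
  parts <- strsplit(body, ",")
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0)
    stop_parse(sprintf("line %d: expected 3 comma-separated values",
                       header_at + bad[1]))
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop_parse(sprintf("line %d: non-numeric value", header_at + bad))
  }
  tryCatch(
    pfe_trace(vals[, 1], vals[, 2], vals[, 3], metadata = meta),
    capkin_invalid_parameter = function(e)
      stop_parse(sprintf("invalid trace data: %s", conditionMessage(e))))
}

#' @rdname read_trace
#' @param trace a [pfe_trace()] object.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pfe_trace"))
  meta <- trace_metadata(trace)
  fmt <- function(x) if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
  header <- vapply(names(meta), function(k)
    sprintf("# %s: %s", k, fmt(meta[[k]])), character(1))
  rows <- sprintf("%.17g,%.17g,%.17g", trace$time_s, trace$potential_V,
                  trace$current)
  writeLines(c(header, "time_s,potential_V,current", rows), path)
  invisible(path)
}

#' Reference-electrode potential conversions
#'
#' Convert potentials measured against common reference electrodes to
#' the SHE scale used throughout: `E_SHE = E_calomel + 0.244 V` and
#' `E_SHE = E_AgAgCl + 0.205 V` (at 20 degrees C).
#'
#' @param E potential(s) in volts vs the named reference.
#' @return Potential(s) in volts vs SHE.
#' @export
she_from_calomel <- function(E) E + 0.244

#' @rdname she_from_calomel
#' @export
she_from_agagcl <- function(E) E + 0.205

#' Write and read a structured fit report
#'
#' Serialises a `capkin_fit` (optionally together with a model
#' comparison) to JSON: shared rates with standard errors, the
#' per-potential `k_react` table, amplitudes, `alpha2`, `ssr`, point
#' and parameter counts.  `read_fit_report` validates the schema on
#' read-back.
#'
#' @param fit a `capkin_fit` object.
#' @param path output path.
#' @param comparison optional `capkin_model_comparison`.
#' @return `write_fit_report` returns `path` invisibly;
#'   `read_fit_report` returns the report as a validated list.
#' @export
write_fit_report <- function(fit, path, comparison = NULL) {
  stopifnot(inherits(fit, "capkin_fit"))
  rates <- lapply(seq_along(fit$shared), function(i)
    list(name = names(fit$shared)[i], value = fit$shared[[i]],
         se = fit$shared_se[[i]]))
  kr <- lapply(seq_len(nrow(fit$kreact_table)), function(i)
    list(name = "k_react", potential = fit$kreact_table$potential[i],
         value = fit$kreact_table$k_react[i],
         se = fit$kreact_table$se[i]))
  doc <- list(
    schema = "capkin-fit-report/1",
    model_kind = fit$model_kind,
    rates = c(rates, kr),
    amplitudes = as.data.frame(fit$amplitudes),
    alpha2 = fit$alpha2,
    ssr = fit$ssr, n_points = fit$n_points, n_params = fit$n_params,
    pH = fit$pH
  )
  if (!is.null(comparison))
    doc$comparison <- list(f_statistic = comparison$f_statistic,
                           p_value = comparison$p_value,
                           aic_delta = comparison$aic_delta,
                           preferred = comparison$preferred)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_parse(sprintf("not valid JSON: %s",
                                       conditionMessage(e))))
  need <- c("schema", "model_kind", "rates", "ssr", "n_points", "n_params")
  missing <- setdiff(need, names(doc))
  if (length(missing) > 0)
    stop_parse(sprintf("fit report missing field(s): %s",
                       paste(missing, collapse = ", ")))
  if (!identical(doc$schema, "capkin-fit-report/1"))
    stop_parse(sprintf("unknown report schema: %s", doc$schema))
  if (doc$ssr < 0 || doc$n_params >= doc$n_points)
    stop_parse("fit report violates invariants (ssr >= 0, n_params < n_points)")
  doc
}

# Known run-configuration keys (flat key = value text document used by
# the command-line interface).
config_keys <- function() c(
  "k1", "k_neg1", "k_inact", "k_react",
  "alpha2", "fit_alpha2",
  "low_E", "high_E", "n_cycles", "step_duration",
  "pH", "temperature_K", "rotation_rpm",
  "relative_sd", "capacitive_peak", "capacitive_tau", "film_loss_tau",
  "sample_hz", "mask_after_step", "multistart",
  "E_start", "E_vertex", "scan_rate",
  "E_eq", "steepness", "i_lim", "kreact_k0", "kreact_E_ref",
  "kreact_slope",
  "o2_molar", "damage_rate", "o2_washout_tau", "plateau_window",
  "reducing_E", "oxidising_E",
  "red_k1", "red_k_neg1", "red_k_inact", "red_k_react",
  "oxi_k1", "oxi_k_neg1", "oxi_k_inact", "oxi_k_react",
  "amp_low", "amp_high", "amp_reducing", "amp_oxidising",
  "chain", "cys_residue", "fe_serial", "twofe_resname", "fourfe_resname"
)

#' Read a flat key-value run configuration
#'
#' Parses a TOML-like plain-text configuration of `key = value` lines
#' (`#` starts a comment).  Unknown keys are rejected; values that
#' parse as numbers become numeric.
#'
#' @param path file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*?)\\s*$",
                                  line))[[1]]
    if (length(m) != 3)
      stop_parse(sprintf("line %d: expected 'key = value', got '%s'",
                         i, trimws(lines[i])))
    key <- m[2]
    if (!(key %in% config_keys()))
      stop_parse(sprintf("line %d: unknown configuration key '%s'", i, key))
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    else if (val %in% c("true", "false")) val <- identical(val, "true")
    out[[key]] <- val
  }
  out
}
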