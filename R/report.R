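.report_schema_version <- "1.0"

#' Write an analysis report as structured JSON
#'
#' Wraps arbitrary analysis results (fits, events, assignments) with a
#' schema version, a config echo and provenance (input file checksums,
#' seed) so every run is reproducible from its report.
#'
#' @param results A named list of result objects.
#' @param path Output path (.json).
#' @param config Named list of the parameters used (echoed verbatim).
#' @param inputs Character vector of input file paths; MD5 checksums are
#'   recorded.
#' @param seed The seed used, if any.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, config = list(), inputs = character(0),
                         seed = NULL) {
  report <- list(
    schema_version = .report_schema_version,
    package = "gatingspring",
    version = as.character(utils::packageVersion("gatingspring")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else NULL,
    results = results)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Read an analysis report
#'
#' @param path A JSON file written by [write_report()].
#' @return The parsed report list; a schema-version mismatch raises an
#'   error.
#' @export
read_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(report$schema_version) ||
      report$schema_version != .report_schema_version) {
    stop("read_report: schema version mismatch (file: ",
         report$schema_version %||% "<none>", ", supported: ",
         .report_schema_version, ")")
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default run configuration
#'
#' All pipeline and model defaults in one documented table: the boxcar
#' window, force-binning and stiffness-fit ranges, rip-detection
#' thresholds, refolding criterion, clamp-analysis settings, gating-model
#' parameters and physical constants.
#'
#' @return A named list (flat keys).
#' @export
default_config <- function() {
  list(
    kBT_pNnm = 4.1, aa_rise_nm = 0.365, bp_rise_nm = 0.338,
    residues_per_AR = 33,
    boxcar_window_s = 0.1,
    bin_width_pN = 0.2, bin_lo_pN = 0.5, bin_hi_pN = 20,
    stiffness_fit_lo_pN = 1, stiffness_fit_hi_pN = 7,
    rip_jump_threshold_nm = 3, rip_max_dwell_s = 0.02,
    refold_tol_nm = 2, refold_lo_pN = 2, refold_hi_pN = 6,
    clamp_density_bin_nm = 0.25,
    P_dna_nm = 40, P_chain_nm = 0.6, L_dna_nm = 1527.8, nanodisc_nm = 5,
    k_fold_pN_per_nm = 1.4, x0_folded_nm = 20, x0_partial_nm = 14.5,
    gating_swing_nm = 4.6, V_open_kBT = 8,
    disordered_folded = 123, disordered_partial = 442, n_tethered = 4,
    pull_speed_nm_s = 10, trap_stiffness_pN_nm = 0.3,
    sampling_rate_hz = 100,
    sim_noise_ext_nm = 2, sim_noise_force_pN = 0.2)
}

#' Write a flat key/value configuration file
#'
#' Plain-text `key = value` lines (strings quoted, booleans true/false);
#' round-trips through [read_config()] identically.
#'
#' @param config Named list of scalars.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15, scientific = FALSE)
  }
  lines <- vapply(names(config),
                  function(k) paste(k, "=", fmt(config[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key/value configuration file
#'
#' @param path File written by [write_config()] (or hand-edited in the
#'   same dialect; `#` starts a comment line).
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("read_config: malformed line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    out[[key]] <- if (grepl('^".*"$', val)) {
      substr(val, 2, nchar(val) - 1)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else {
      as.numeric(val)
    }
  }
  out
}
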