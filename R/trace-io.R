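#' Force-extension trace from a pulling (or relaxation) ramp
#'
#' @param time_s,trap_sep_nm,force_pN,extension_nm Numeric vectors of equal
#'   length; `time_s` strictly increasing and uniformly sampled within 1%.
#' @param label Free-text identifier (molecule/construct).
#' @param phase `"pull"` or `"relax"`.
#' @param sampling_rate Samples per second, Hz.
#' @return An object of class `fec_trace` wrapping a data frame with the
#'   four trajectory columns.
#' @export
fec_trace <- function(time_s, trap_sep_nm, force_pN, extension_nm,
                      label = "", phase = c("pull", "relax"),
                      sampling_rate = NULL) {
  phase <- match.arg(phase)
  n <- length(time_s)
  stopifnot(n >= 2, length(trap_sep_nm) == n, length(force_pN) == n,
            length(extension_nm) == n)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("fec_trace: time must be strictly increasing")
  if ((max(dt) - min(dt)) > 0.01 * stats::median(dt)) {
    stop("fec_trace: sampling must be uniform within 1%")
  }
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(dt)
  structure(list(
    data = data.frame(time_s = time_s, trap_sep_nm = trap_sep_nm,
                      force_pN = force_pN, extension_nm = extension_nm),
    label = label, phase = phase, sampling_rate = sampling_rate
  ), class = "fec_trace")
}

#' @export
print.fec_trace <- function(x, ...) {
  cat("fec_trace '", x$label, "' (", x$phase, "): ",
      nrow(x$data), " samples @ ", round(x$sampling_rate), " Hz, force ",
      round(min(x$data$force_pN), 2), "-", round(max(x$data$force_pN), 2),
      " pN\n", sep = "")
  invisible(x)
}

#' Constant-force (force-clamp) extension trace
#'
#' @param time_s,extension_nm Numeric vectors, equal length.
#' @param mean_force Clamp force, pN (> 0).
#' @param sampling_rate Hz; inferred from time if omitted.
#' @return An object of class `clamp_trace`.
#' @export
clamp_trace <- function(time_s, extension_nm, mean_force,
                        sampling_rate = NULL) {
  n <- length(time_s)
  stopifnot(n >= 2, length(extension_nm) == n, mean_force > 0)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("clamp_trace: time must be strictly increasing")
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(dt)
  structure(list(
    data = data.frame(time_s = time_s, extension_nm = extension_nm),
    mean_force = mean_force, sampling_rate = sampling_rate
  ), class = "clamp_trace")
}

#' @export
print.clamp_trace <- function(x, ...) {
  cat("clamp_trace: ", nrow(x$data), " samples, ",
      round(max(x$data$time_s) - min(x$data$time_s), 2), " s at ",
      x$mean_force, " pN\n", sep = "")
  invisible(x)
}

.trace_cols <- c("time_s", "trap_sep_nm", "force_pN", "extension_nm")
.clamp_cols <- c("time_s", "extension_nm")

#' Read a trajectory TSV
#'
#' Reads the tab-separated trajectory dialect (header line required;
#' UTF-8, '.' decimal; gzip transparently accepted). Full ramp files carry
#' columns `time_s trap_sep_nm force_pN extension_nm` (any order); clamp
#' files carry `time_s extension_nm` and need `mean_force`.
#'
#' @param path File path (.tsv or .tsv.gz).
#' @param mean_force Clamp force in pN, required for the two-column
#'   clamp variant.
#' @param label,phase Passed to [fec_trace()] for ramp files.
#' @return A [fec_trace()] or [clamp_trace()].
#' @export
read_trace <- function(path, mean_force = NULL, label = basename(path),
                       phase = "pull") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  nm <- names(df)
  if (all(.trace_cols %in% nm)) {
    vals <- lapply(df[.trace_cols],
                   function(col) suppressWarnings(as.numeric(col)))
    bad <- which(Reduce(`|`, lapply(vals, function(v) !is.finite(v))))
    if (length(bad)) {
      stop("read_trace: malformed rows (line ",
           paste(utils::head(bad + 1, 5), collapse = ", "), ") in ", path)
    }
    fec_trace(vals$time_s, vals$trap_sep_nm, vals$force_pN,
              vals$extension_nm, label = label, phase = phase)
  } else if (all(.clamp_cols %in% nm)) {
    if (is.null(mean_force)) {
      stop("read_trace: clamp trace requires mean_force (pN)")
    }
    clamp_trace(df$time_s, df$extension_nm, mean_force = mean_force)
  } else {
    stop("read_trace: header must contain columns ",
         paste(.trace_cols, collapse = " "), " (ramp) or ",
         paste(.clamp_cols, collapse = " "), " (clamp); found: ",
         paste(nm, collapse = " "))
  }
}

#' Write a trace to a trajectory TSV
#'
#' @param trace A [fec_trace()] or [clamp_trace()].
#' @param path Output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format(trace$data, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a binned force-extension curve as TSV
#'
#' Columns `force_pN mean_ext_nm sd_nm n`.
#'
#' @param fec A [binned_fec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binned_fec <- function(fec, path) {
  stopifnot(inherits(fec, "binned_fec"))
  df <- data.frame(force_pN = fec$bins$force_pN,
                   mean_ext_nm = fec$bins$mean_ext_nm,
                   sd_nm = fec$bins$sd_nm, n = fec$bins$n)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binned force-extension curve TSV
#'
#' @param path File written by [write_binned_fec()].
#' @return A [binned_fec()].
#' @export
read_binned_fec <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  binned_fec(df$force_pN, df$mean_ext_nm, df$sd_nm, df$n)
}
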