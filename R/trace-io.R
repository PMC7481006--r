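#' @include AllClasses.R
NULL

## CSV trace container: '# key=value' header lines (sampling_rate_hz, units,
## kind, t0_s) followed by one sample per line. Samples are written with 17
## significant digits so that the write/read round trip is bit exact.

.parseHeader <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Read a recorded trace from a file
#'
#' Reads the package's plain-text trace container: comment-style header
#' lines `# sampling_rate_hz=...`, `# units=...`, `# kind=...` (and
#' optionally `# t0_s=...`), then one sample per line. A file missing a
#' required header raises a schema error naming the missing field.
#'
#' @param path file path.
#' @param format container format; only `"csv"` is supported.
#' @return A [Trace-class].
#' @seealso [writeTrace()]
#' @export
readTrace <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("HDF5 containers are not supported by this build; ",
         "use the CSV trace format", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kv <- .parseHeader(lines)
  for (field in c("sampling_rate_hz", "units", "kind"))
    if (is.null(kv[[field]]))
      stop(sprintf("trace file '%s' is missing required header field '%s'",
                   path, field), call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  Trace(as.numeric(body),
        samplingRate = as.numeric(kv$sampling_rate_hz),
        units = kv$units, kind = kv$kind,
        t0 = if (is.null(kv$t0_s)) 0 else as.numeric(kv$t0_s))
}

#' Write a trace to the CSV container
#'
#' @param trace a [Trace-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readTrace()]
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "Trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate_hz=%.17g", trace@samplingRate),
    sprintf("# units=%s", trace@units),
    sprintf("# kind=%s", trace@kind),
    sprintf("# t0_s=%.17g", trace@t0),
    sprintf("%.17g", trace@samples)), con)
  invisible(path)
}

#' Read spike times from a file
#'
#' Plain-text spike container: a `# duration_s=...` header followed by one
#' spike time (s) per line.
#'
#' @param path file path.
#' @return A [SpikeTrain-class].
#' @export
readSpikeTrain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kv <- .parseHeader(lines)
  if (is.null(kv$duration_s))
    stop(sprintf("spike file '%s' is missing required header field '%s'",
                 path, "duration_s"), call. = FALSE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  SpikeTrain(as.numeric(body), duration = as.numeric(kv$duration_s))
}

#' Write spike times to a file
#'
#' @param spikes a [SpikeTrain-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpikeTrain <- function(spikes, path) {
  stopifnot(is(spikes, "SpikeTrain"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# duration_s=%.17g", spikes@duration),
               sprintf("%.17g", spikes@times)), con)
  invisible(path)
}

#' Write a state segmentation as a BED-like interval file
#'
#' Three tab-separated columns: start (s), end (s), label.
#'
#' @param seg a [StateSegmentation-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSegmentation <- function(seg, path) {
  stopifnot(is(seg, "StateSegmentation"))
  iv <- seg@intervals
  utils::write.table(
    data.frame(start_s = sprintf("%.6f", iv$start),
               end_s = sprintf("%.6f", iv$end), label = iv$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
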