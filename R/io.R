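#' Write traces to TSV with a JSON metadata sidecar
#'
#' Writes a demodulated (or raw) trace set as tab-separated text --
#' `time_s` followed by one labeled column per channel -- plus a
#' `<path>.json` sidecar carrying the metadata (channel map, lock-in
#' settings, seed, artifact windows). Values are written with 17
#' significant digits so a round trip preserves every sample.
#'
#' @param x A `"demod_traces"` or `"raw_traces"` object, or a data frame
#'   whose first column is `time_s`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(x, path) {
  if (inherits(x, "demod_traces")) {
    d <- data.frame(time_s = x$time_s, x$x, check.names = FALSE)
    meta <- list(type = "demod_traces",
                 channels = x$channels,
                 lockin = unclass(x$lockin),
                 meta = x$meta)
  } else if (inherits(x, "raw_traces")) {
    d <- data.frame(time_s = x$time_s, x$y, check.names = FALSE)
    meta <- list(type = "raw_traces", dt = x$dt, meta = x$meta)
  } else if (is.data.frame(x)) {
    d <- x
    meta <- list(type = "data.frame")
  } else stop("cannot serialize object of class ", class(x)[1], call. = FALSE)
  if (anyDuplicated(names(d))) {
    stop("channel label collision: ",
         paste(unique(names(d)[duplicated(names(d))]), collapse = ", "),
         call. = FALSE)
  }
  fmt <- as.data.frame(lapply(d, function(col) sprintf("%.17g", col)),
                       check.names = FALSE)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read traces written by [write_traces()]
#'
#' Reconstructs the trace object from the TSV and its JSON sidecar. A
#' missing sidecar degrades gracefully: the traces load as a plain data
#' frame with a warning and empty metadata.
#'
#' @param path TSV path.
#' @return A `"demod_traces"` / `"raw_traces"` object, or a data frame.
#' @export
read_traces <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header)) {
    stop("channel label collision in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = rep("numeric", length(header)))
  if (!identical(names(d)[1], "time_s")) {
    stop("malformed header: first column must be time_s (line 1)", call. = FALSE)
  }
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    warning("metadata sidecar not found (", side, "); returning plain traces")
    return(d)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (identical(meta$type, "demod_traces")) {
    lk <- meta$lockin
    cfg <- lockin_config(lk$time_constant_s, order = lk$order,
                         output_interval_s = lk$output_interval_s,
                         phase_mode = if (identical(lk$phase_mode, "auto"))
                           "auto" else as.numeric(lk$phase_mode),
                         output_mode = lk$output_mode,
                         settle_factor = lk$settle_factor)
    x <- as.matrix(d[, -1, drop = FALSE])
    structure(list(time_s = d$time_s, x = x,
                   settled = !settle_mask(cfg, d$time_s),
                   channels = as.data.frame(meta$channels),
                   lockin = cfg, meta = meta$meta),
              class = "demod_traces")
  } else if (identical(meta$type, "raw_traces")) {
    structure(list(time_s = d$time_s,
                   y = as.matrix(d[, -1, drop = FALSE]),
                   dt = meta$dt, meta = meta$meta),
              class = "raw_traces")
  } else d
}
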