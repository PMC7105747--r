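#' Write a recording to disk
#'
#' One tab-separated file per cell (`<id>.tsv`: first column `time_ms`,
#' one column per step level, values in pA) plus a JSON sidecar
#' (`<id>.json`) carrying capacitance, group, measured resting potential
#' and the protocol.
#'
#' @param rec an `fls_recording`.
#' @param dir output directory (created if absent).
#' @return path of the sweep file, invisibly.
#' @export
write_recording <- function(rec, dir) {
  if (!inherits(rec, "fls_recording")) stopf("rec must be an fls_recording")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(rec$id, ".tsv"))
  df <- data.frame(time_ms = rec$time_ms, rec$sweeps, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(id = rec$id, group = rec$group,
               capacitance_pF = rec$capacitance_pF,
               rmp_mV = rec$rmp_mV,
               protocol = unclass(rec$protocol))
  jsonlite::write_json(meta, file.path(dir, paste0(rec$id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(tsv)
}

#' Read a recording written by [write_recording()]
#'
#' @param tsv_path path of the sweep `.tsv`; the `.json` sidecar is
#'   expected next to it.
#' @return an `fls_recording` (with `truth = NULL`).
#' @export
read_recording <- function(tsv_path) {
  json_path <- sub("\\.tsv$", ".json", tsv_path)
  if (!file.exists(json_path)) stopf("sidecar %s not found", json_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  df <- utils::read.delim(tsv_path, check.names = FALSE)
  sweeps <- as.matrix(df[, -1, drop = FALSE])
  pr <- meta$protocol
  protocol <- step_protocol(holding_mV = pr$holding_mV,
                            steps_mV = pr$steps_mV, step_ms = pr$step_ms,
                            pre_ms = pr$pre_ms, post_ms = pr$post_ms,
                            dt_ms = pr$dt_ms)
  structure(
    list(id = meta$id, group = meta$group,
         capacitance_pF = meta$capacitance_pF,
         rmp_mV = meta$rmp_mV, time_ms = df$time_ms, sweeps = sweeps,
         protocol = protocol, truth = NULL),
    class = "fls_recording")
}

#' Write / read a whole cohort
#'
#' `write_cohort` stores every recording of a list in `dir`;
#' `read_cohort` loads all `.tsv`/`.json` pairs found there.
#'
#' @param recs list of `fls_recording` objects.
#' @param dir directory.
#' @return `write_cohort`: `dir` invisibly; `read_cohort`: list of
#'   recordings ordered by file name.
#' @export
write_cohort <- function(recs, dir) {
  for (r in recs) write_recording(r, dir)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) stopf("no recordings found in %s", dir)
  lapply(files, read_recording)
}
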