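#' Read and write SICM topography grids as TSV
#'
#' The on-disk dialect is a plain tab-separated height grid (nm) preceded by
#' a one-line header `# pixel_size_um=<value>`.
#'
#' @param scan A [topography_scan()] (for writing).
#' @param path File path.
#' @return `read_topography_tsv` returns a [topography_scan()];
#'   `write_topography_tsv` returns the path invisibly.
#' @export
write_topography_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "topography_scan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_um=%.10g", scan$pixel_size_um), con)
  utils::write.table(scan$height_nm, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_topography_tsv
#' @export
read_topography_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("pixel_size_um=([0-9.eE+-]+)", header))[[1]]
  if (length(m) < 2L) {
    stop("missing 'pixel_size_um=' header in ", path, call. = FALSE)
  }
  grid <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(grid) <- NULL
  topography_scan(grid, as.numeric(m[2L]))
}

#' Write / read a patch recording as CSV plus JSON sidecar
#'
#' Sweeps go to `<path>` as CSV columns `time_s, sweep1, sweep2, ...`;
#' protocol voltages, sampling rate and labels go to `<path>.json`.
#'
#' @param rec A [patch_recording()] (for writing).
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `read_patch_csv` returns a [patch_recording()];
#'   `write_patch_csv` returns the path invisibly.
#' @export
write_patch_csv <- function(rec, path) {
  stopifnot(inherits(rec, "patch_recording"))
  n <- length(rec$sweeps[[1L]])
  df <- data.frame(time_s = (seq_len(n) - 0.5) / rec$sampling_rate_hz)
  for (i in seq_along(rec$sweeps)) {
    df[[paste0("sweep", i)]] <- rec$sweeps[[i]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(sampling_rate_hz = rec$sampling_rate_hz,
               protocol = unclass(rec$protocol),
               labels = rec$labels)
  if (!is.null(rec$pipette)) {
    meta$pipette <- list(R_pipette = rec$pipette$R_pipette,
                         phi_deg = rec$pipette$phi_deg,
                         conductivity_S_per_m =
                           rec$pipette$conductivity_S_per_m)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_patch_csv
#' @export
read_patch_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  sweep_cols <- grep("^sweep", names(df), value = TRUE)
  proto <- voltage_protocol(holding_mV = meta$protocol$holding_mV,
                            step_mV = meta$protocol$step_mV,
                            step_start_s = meta$protocol$step_start_s,
                            step_duration_s = meta$protocol$step_duration_s)
  pip <- if (!is.null(meta$pipette)) {
    pipette_geometry(meta$pipette$R_pipette, meta$pipette$phi_deg,
                     meta$pipette$conductivity_S_per_m)
  } else NULL
  patch_recording(lapply(df[sweep_cols], identity),
                  meta$sampling_rate_hz, proto,
                  labels = as.list(meta$labels), pipette = pip)
}
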