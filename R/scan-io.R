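#' Read and write stimulation-scan containers
#'
#' Scans are stored as a single HDF5 file with datasets `/voltages` (5-D,
#' dims stimulating electrode x amplitude x repeat x recording electrode x
#' sample, chunked along the stimulating-electrode axis so one stimulating
#' electrode can stream independently) and `/amplitudes`, plus root
#' attributes `sampling_rate`, `stim_electrodes`, `geometry` (a JSON
#' descriptor with `n_rows`, `n_cols`, `pitch`) and `format_version`.
#' Electrode indices are 1-based row-major. The round trip is bit-exact on
#' the voltage tensor and preserves all metadata.
#'
#' @param scan a [ScanRecording-class].
#' @param path file path of the container.
#' @return `readScan` returns a [ScanRecording-class]; `writeScan` returns
#'   `path` invisibly.
#' @examples
#' arr <- ElectrodeArray(2, 2)
#' g <- AmplitudeGrid(c(0.1, 0.2, 0.3))
#' v <- array(rnorm(1 * 3 * 2 * 4 * 41), c(1, 3, 2, 4, 41))
#' sc <- ScanRecording(v, 20000, g, arr)
#' f <- tempfile(fileext = ".h5")
#' writeScan(sc, f)
#' stopifnot(identical(voltages(readScan(f)), v))
#' @export
writeScan <- function(scan, path) {
  stopifnot(is(scan, "ScanRecording"))
  validObject(scan)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  d <- dim(scan@voltages)
  rhdf5::h5createDataset(path, "voltages", dims = d,
                         chunk = c(1L, d[2L], d[3L], d[4L], d[5L]),
                         storage.mode = "double", level = 1L)
  rhdf5::h5write(scan@voltages, path, "voltages")
  rhdf5::h5write(scan@grid@amplitudes, path, "amplitudes")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  geom <- jsonlite::toJSON(list(n_rows = scan@array@nRows,
                                n_cols = scan@array@nCols,
                                pitch = scan@array@pitch),
                           auto_unbox = TRUE)
  rhdf5::h5writeAttribute(as.character(geom), fid, "geometry")
  rhdf5::h5writeAttribute(scan@samplingRate, fid, "sampling_rate")
  rhdf5::h5writeAttribute(scan@stimElectrodes, fid, "stim_electrodes")
  rhdf5::h5writeAttribute("bundleScan-1", fid, "format_version")
  invisible(path)
}

#' @rdname writeScan
#' @export
readScan <- function(path) {
  if (!file.exists(path)) stop("scan container not found: ", path)
  ls <- rhdf5::h5ls(path)
  for (ds in c("voltages", "amplitudes"))
    if (!ds %in% ls$name) stop("container is missing dataset '", ds, "'")
  att <- rhdf5::h5readAttributes(path, "/")
  for (a in c("geometry", "sampling_rate", "stim_electrodes"))
    if (is.null(att[[a]])) stop("container is missing attribute '", a, "'")
  geom <- jsonlite::fromJSON(att$geometry)
  arr <- ElectrodeArray(geom$n_rows, geom$n_cols, geom$pitch)
  v <- rhdf5::h5read(path, "voltages")
  amps <- as.numeric(rhdf5::h5read(path, "amplitudes"))
  d <- dim(v)
  if (length(d) != 5L)
    stop("voltages dataset must be 5-D, got ", length(d), " dimensions")
  if (d[3L] < 1L) stop("empty repeats axis")
  if (d[4L] != geom$n_rows * geom$n_cols)
    stop(sprintf(paste0("geometry descriptor (%d x %d = %d electrodes) disagrees ",
                        "with the recording axis of the tensor (%d)"),
                 geom$n_rows, geom$n_cols, geom$n_rows * geom$n_cols, d[4L]))
  if (d[2L] != length(amps))
    stop(sprintf("amplitude axis (%d) disagrees with the amplitude grid (%d levels)",
                 d[2L], length(amps)))
  if (anyNA(v) || any(!is.finite(v)))
    stop("voltages contain non-finite values")
  ScanRecording(v, samplingRate = as.numeric(att$sampling_rate),
                grid = AmplitudeGrid(amps), array = arr,
                stimElectrodes = as.integer(att$stim_electrodes))
}

#' Write and read bundle-threshold tables
#'
#' `writeThresholds` writes one CSV row per stimulating electrode
#' (`stim_electrode`, `threshold_uA`, `threshold_index`, `status`), with
#' empty numeric cells and status `not_found` for electrodes where no
#' tested amplitude met the border rule, plus a JSON run summary
#' (`<path>.json`: detection counts, amplitude grid, optional
#' configuration echo, package version). `readThresholds` reconstructs the
#' [BundleThresholds-class] from the pair of files.
#'
#' @param thresholds a [BundleThresholds-class].
#' @param path CSV output path; the JSON summary is written to
#'   `paste0(path, ".json")`.
#' @param config optional [DetectionConfig-class] echoed into the summary.
#' @param extra optional named list merged into the JSON summary.
#' @return `writeThresholds` returns `path` invisibly; `readThresholds`
#'   returns a [BundleThresholds-class].
#' @export
writeThresholds <- function(thresholds, path, config = NULL, extra = list()) {
  stopifnot(is(thresholds, "BundleThresholds"))
  df <- as.data.frame(thresholds)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  summ <- list(
    n_electrodes = length(thresholds@electrode),
    n_detected = sum(!is.na(thresholds@index)),
    n_not_found = sum(is.na(thresholds@index)),
    amplitude_grid_uA = thresholds@grid@amplitudes,
    package = "bundleScan",
    version = as.character(utils::packageVersion("bundleScan"))
  )
  if (!is.null(config))
    summ$config <- list(p_value = config@pValue,
                        window_start_ms = config@windowStartMs,
                        window_end_ms = config@windowEndMs,
                        min_borders = config@minBorders,
                        exclude_recording = config@excludeRecording,
                        corner_rule = config@cornerRule)
  summ <- c(summ, extra)
  jsonlite::write_json(summ, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stim_electrode", "threshold_uA", "threshold_index", "status")
  if (!all(need %in% names(df)))
    stop("threshold table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  summ <- jsonlite::fromJSON(paste0(path, ".json"))
  grid <- AmplitudeGrid(summ$amplitude_grid_uA)
  BundleThresholds(df$stim_electrode, df$threshold_index, grid)
}
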