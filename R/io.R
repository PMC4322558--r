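#' @include AllClasses.R AllGenerics.R
NULL

#' Convert A01-style well labels to 0-based grid indices and back
#'
#' File-boundary convention: letter row plus two-digit column ("A01");
#' internal convention: 0-based integer row and column.
#'
#' @param well character vector of well labels
#' @return data.frame with columns row, col (0-based)
#' @examples
#' wellToIndices("B03")  # row 1, col 2
#' @export
wellToIndices <- function(well) {
  ok <- grepl("^[A-Z][0-9]{2}$", well)
  if (!all(ok))
    stop("malformed well label(s): ",
         paste(unique(well[!ok]), collapse = ", "))
  data.frame(row = match(substr(well, 1, 1), LETTERS) - 1L,
             col = as.integer(substr(well, 2, 3)) - 1L)
}

#' @rdname wellToIndices
#' @param row,col 0-based grid indices
#' @export
indicesToWell <- function(row, col) {
  sprintf("%s%02d", LETTERS[row + 1L], col + 1L)
}

checkColumns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
}

#' Read a per-well plate count table
#'
#' Expected CSV schema: \code{plate_id}, \code{processing_order},
#' \code{well} (A01 style), \code{condition}, \code{count}.  Counts must
#' be nonnegative integers; duplicate (plate, well) keys are an error
#' reporting the offending file rows.
#'
#' @param path CSV file path
#' @return a \linkS4class{ScreenExperiment} (empty truth table)
#' @export
readWellTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  checkColumns(df, c("plate_id", "processing_order", "well", "condition",
                     "count"), path)
  if (!is.numeric(df$count) || any(df$count %% 1 != 0, na.rm = TRUE))
    stop("non-numeric or non-integer counts in '", path, "'")
  if (any(df$count < 0, na.rm = TRUE))
    stop("negative counts in '", path, "'")
  rc <- wellToIndices(df$well)
  key <- paste(df$plate_id, df$well)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    rows <- which(key == d)
    stop("duplicate (plate, well) key '", d, "' at file rows ",
         paste(rows + 1L, collapse = " and "))
  }
  wells <- data.frame(plate_id = df$plate_id,
                      processing_order = df$processing_order,
                      row = rc$row, col = rc$col,
                      condition = df$condition,
                      count = df$count, stringsAsFactors = FALSE)
  new("ScreenExperiment", wells = wells,
      truth = data.frame(pool_id = character(), true_effect = numeric()))
}

#' Read a clinical outcome table
#'
#' Expected CSV schema: \code{id}, \code{time}, \code{event},
#' \code{subtype} and optionally \code{centre}.
#'
#' @param path CSV file path
#' @return validated data.frame
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  checkColumns(df, c("id", "time", "event", "subtype"), path)
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0L, 1L)))
    stop("event indicator must be 0 or 1")
  if (anyDuplicated(df$id)) stop("duplicate subject ids in '", path, "'")
  df
}

#' Write a results table deterministically
#'
#' Columns keep their given order; rows are written as supplied, so the
#' same records always produce identical bytes.  The MD5 checksum of the
#' written file is returned for manifest recording.
#'
#' @param records data.frame
#' @param path output CSV path
#' @return invisibly, the file's MD5 checksum
#' @export
writeResultsTable <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(unname(tools::md5sum(path)))
}

#' Run manifest for reproducible pipeline invocations
#'
#' Records the command, parameter set, seed, input-file checksums and
#' package version; rerunning with the same manifest (same seed, same
#' inputs) reproduces stochastic outputs exactly.
#'
#' @param command character label of the pipeline stage
#' @param params named list of parameters
#' @param seed integer seed driving all randomness of the run
#' @param inputs character vector of input file paths (checksummed)
#' @return list; write it with \code{\link{writeManifest}}
#' @export
runManifest <- function(command, params = list(), seed = NA_integer_,
                        inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(command = command, params = params, seed = seed,
       input_checksums = sums,
       package_version = as.character(packageVersion("GrowthScreen")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @rdname runManifest
#' @param manifest a manifest list
#' @param path output JSON path
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
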