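#' Read a Bonn-style plain-text record
#'
#' The Bonn EEG distribution stores each record as ASCII text, one sample
#' value per line, with no header; the sampling rate is supplied by the
#' caller (default 173.61 Hz). Blank lines, surrounding whitespace and
#' CRLF line endings are tolerated.
#'
#' @param path Path to the record file.
#' @param fs Sampling rate in Hz to attach to the parsed record.
#' @param label Optional class tag.
#' @return An [ts_signal()].
#' @examples
#' f <- tempfile()
#' writeLines(c("1.5", "2.5", "-3"), f)
#' read_record(f, fs = 100)$samples
#' @export
read_record <- function(path, fs = 173.61, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vals <- trimws(lines)
  keep <- nzchar(vals)
  parsed <- suppressWarnings(as.numeric(vals[keep]))
  if (anyNA(parsed)) {
    bad <- which(keep)[which(is.na(parsed))[1]]
    stop(sprintf("cannot parse line %d of %s: '%s'", bad, path, lines[bad]))
  }
  if (length(parsed) < 2L)
    stop("file ", path, " yields fewer than 2 samples")
  ts_signal(parsed, fs = fs, label = label)
}

#' Write a record as Bonn-style plain text
#'
#' One sample per line, printed with 17 significant digits so that reading
#' the file back reproduces the doubles exactly.
#'
#' @param signal An [ts_signal()] or numeric vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record <- function(signal, path) {
  signal <- as_ts_signal(signal)
  writeLines(sprintf("%.17g", signal$samples), path)
  invisible(path)
}

#' Read / write a five-set dataset directory
#'
#' `read_dataset()` expects five subdirectories `A`–`E` under `root_dir`,
#' each containing one text record per file (any extension; files are read
#' in sorted order). `write_dataset()` creates that layout from a
#' [labeled_dataset()], naming records `A001.txt`, `A002.txt`, ...
#'
#' @param root_dir Dataset root directory.
#' @param fs Sampling rate attached to every record.
#' @return `read_dataset()`: a [labeled_dataset()]; `write_dataset()`:
#'   `root_dir`, invisibly.
#' @examples
#' dir <- tempfile()
#' write_dataset(make_bonn_like(seed = 1, records_per_set = 2), dir)
#' ds <- read_dataset(dir)
#' @export
read_dataset <- function(root_dir, fs = 173.61) {
  ids <- c("A", "B", "C", "D", "E")
  present <- ids[dir.exists(file.path(root_dir, ids))]
  missing <- setdiff(ids, present)
  if (length(missing) > 0)
    stop("missing set director", if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "),
         " (found: ", paste(present, collapse = ", "), ") under ", root_dir)
  sets <- lapply(ids, function(id) {
    files <- sort(list.files(file.path(root_dir, id), full.names = TRUE))
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) stop("set directory ", id, " contains no files")
    lapply(files, read_record, fs = fs)
  })
  names(sets) <- ids
  labeled_dataset(sets)
}

#' @rdname read_dataset
#' @param data A [labeled_dataset()].
#' @export
write_dataset <- function(data, root_dir) {
  stopifnot(inherits(data, "labeled_dataset"))
  for (id in names(data$sets)) {
    dir.create(file.path(root_dir, id), recursive = TRUE,
               showWarnings = FALSE)
    for (ri in seq_along(data$sets[[id]])) {
      write_record(data$sets[[id]][[ri]],
                   file.path(root_dir, id, sprintf("%s%03d.txt", id, ri)))
    }
  }
  invisible(root_dir)
}
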