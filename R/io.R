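# Readers/writers for the two interchange formats the pipeline touches:
# 16-bit EDF and a delimited numeric matrix (one channel per row) with a
# JSON sidecar {fs, labels}. The internal unit is microvolts throughout;
# EDF physical dimensions are taken at face value (no unit conversion
# beyond the physical/digital scaling the header declares).

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width)
    stop("EDF header field too long: '", x, "' (max ", width, " chars)")
  formatC(x, width = -width, flag = "-")
}

edfNum <- function(x, width = 8L) {
  for (digits in 7:1) {
    s <- formatC(x, format = "g", digits = digits, width = -1)
    if (nchar(s) <= width) return(s)
  }
  stop("cannot represent ", x, " in an ", width, "-char EDF field")
}

#' Write a Recording to disk
#'
#' EDF output uses 16-bit samples with a symmetric physical range chosen to
#' cover the data, so the write/read round trip is exact up to one
#' quantization step \code{(physMax - physMin) / 65535}. Delimited output
#' is full-precision text (one channel per row) plus a JSON sidecar
#' \code{<path>.json} holding \code{fs} and \code{labels}, and round-trips
#' losslessly.
#'
#' @param rec a [Recording-class].
#' @param path output file path.
#' @param format \code{"edf"} or \code{"delimited"}; \code{"auto"} picks by
#'   file extension (\code{.edf} -> EDF).
#' @param delimiter column separator for delimited output.
#' @return \code{path}, invisibly.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(rec, path, format = c("auto", "edf", "delimited"),
                           delimiter = "\t") {
  stopifnot(is(rec, "Recording"))
  validObject(rec)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  if (format == "edf") writeEDF(rec, path) else {
    utils::write.table(rec@data, path, sep = delimiter,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(fs = rec@fs, labels = rec@labels),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a Recording from disk
#'
#' @param path input file path.
#' @param format \code{"edf"}, \code{"delimited"}, or \code{"auto"} (by
#'   extension).
#' @param delimiter separator for delimited input.
#' @param fs,labels sampling rate / channel labels for delimited input
#'   without a sidecar. A delimited matrix with neither a sidecar nor an
#'   explicit \code{fs} is an error: the rate is never defaulted.
#' @return A [Recording-class] with channels in file order, values in
#'   microvolts.
#' @export
readRecording <- function(path, format = c("auto", "edf", "delimited"),
                          delimiter = "\t", fs = NULL, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "delimited"
  if (format == "edf") return(readEDF(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(lines, delimiter, fixed = TRUE),
                 function(r) as.numeric(r))
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("inconsistent row lengths in delimited matrix: ",
         paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, rows)
  if (anyNA(mat)) stop("non-numeric entries in delimited matrix")
  sidecar <- paste0(path, ".json")
  if (is.null(fs)) {
    if (!file.exists(sidecar))
      stop("no sampling rate available for ", path,
           ": supply fs= or provide the JSON sidecar ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs))
      stop("sidecar ", sidecar, " lacks an 'fs' entry")
    fs <- meta$fs
    if (is.null(labels)) labels <- meta$labels
  }
  Recording(mat, fs = fs, labels = labels,
            meta = list(source = path, format = "delimited"))
}

writeEDF <- function(rec, path) {
  ns <- nrow(rec@data); n <- ncol(rec@data); fs <- rec@fs
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0) {
    spr <- as.integer(round(fs)); nrec <- n %/% spr; dur <- 1
  } else {
    spr <- n; nrec <- 1L; dur <- n / fs
  }
  # choose a physical range that is exactly representable in the 8-char
  # header fields (including the minus sign), then quantize against the
  # same rounded value the reader will parse back
  pminStr <- vapply(seq_len(ns), function(i) {
    m <- max(abs(rec@data[i, ]))
    edfNum(if (m == 0) -1 else -m * 1.0005)
  }, character(1))
  pmax <- -as.numeric(pminStr)
  pmaxStr <- sub("^-", "", pminStr)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edfPad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (ns + 1L)), 8); wr("", 44)
  wr(as.character(nrec), 8); wr(edfNum(dur), 8); wr(as.character(ns), 4)
  for (i in seq_len(ns)) wr(rec@labels[i], 16)
  for (i in seq_len(ns)) wr("", 80)               # transducer
  for (i in seq_len(ns)) wr("uV", 8)              # physical dimension
  for (i in seq_len(ns)) wr(pminStr[i], 8)        # physical min
  for (i in seq_len(ns)) wr(pmaxStr[i], 8)        # physical max
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)               # prefiltering
  for (i in seq_len(ns)) wr(as.character(spr), 8)
  for (i in seq_len(ns)) wr("", 32)
  dmin <- -32768; dmax <- 32767
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      x <- rec@data[i, idx]
      d <- round((x + pmax[i]) / (2 * pmax[i]) * (dmax - dmin) + dmin)
      if (any(d < dmin) || any(d > dmax))
        stop("channel ", rec@labels[i],
             " exceeds the representable EDF range; refusing to clip")
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version field '", version, "')")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes (recomputed below)
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("EDF header: bad signal count")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing sampling rates are not supported")
  spr1 <- spr[1L]
  n <- nrec * spr1
  data <- matrix(0, ns, n)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr1 + 1L):(r * spr1)
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr1, size = 2L, endian = "little")
      if (length(d) != spr1) stop("EDF file truncated in record ", r)
      data[i, idx] <- (d - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax[i] - pmin[i]) + pmin[i]
    }
  }
  if (!is.finite(dur) || dur <= 0) stop("EDF header: bad record duration")
  Recording(data, fs = spr1 / dur, labels = labels,
            meta = list(source = path, format = "edf"))
}

#' Resolve a frontal montage against a Recording
#'
#' Matches the requested frontal labels to the recording's channels by
#' exact string comparison after whitespace trimming, case-insensitively.
#' The identification step needs at least two forehead channels.
#'
#' @param rec a [Recording-class].
#' @param frontal character vector of frontal channel names.
#' @return Integer channel indices of the frontal channels, named by label.
#' @export
resolveMontage <- function(rec, frontal) {
  if (length(frontal) < 2L)
    stop("the montage must name at least two frontal channels")
  want <- tolower(trimws(frontal))
  have <- tolower(trimws(rec@labels))
  idx <- match(want, have)
  if (anyNA(idx))
    stop("frontal channel(s) not present in recording: ",
         paste(frontal[is.na(idx)], collapse = ", "))
  stats::setNames(idx, rec@labels[idx])
}
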