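#' Construct a Sanger trace object
#'
#' A trace is the four-channel chromatogram (A, C, G, T fluorescence intensity
#' per scan) plus the basecall positions the sequencer assigned. Scan indices
#' are 0-based, matching chromatogram viewers.
#'
#' @param channels Numeric matrix (scans x 4) with columns `A`, `C`, `G`, `T`.
#' @param basecalls Data frame with columns `scan` (0-based, strictly
#'   increasing, within the trace) and `base`.
#' @return An object of class `sanger_trace`.
#' @export
sanger_trace <- function(channels, basecalls) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 4) stop("channels must have 4 columns", call. = FALSE)
  colnames(channels) <- c("A", "C", "G", "T")
  basecalls <- tibble::as_tibble(basecalls)
  stopifnot(all(c("scan", "base") %in% names(basecalls)))
  basecalls$scan <- as.integer(basecalls$scan)
  if (nrow(basecalls) > 0) {
    if (any(diff(basecalls$scan) <= 0)) {
      stop("basecall scan positions must be strictly increasing", call. = FALSE)
    }
    if (basecalls$scan[1] < 0 || basecalls$scan[nrow(basecalls)] >= nrow(channels)) {
      stop("basecall scan positions must lie within the trace", call. = FALSE)
    }
  }
  structure(list(channels = channels, basecalls = basecalls,
                 length = nrow(channels)),
            class = "sanger_trace")
}

#' @export
print.sanger_trace <- function(x, ...) {
  cat("<sanger_trace> ", x$length, " scans, ", nrow(x$basecalls),
      " basecalls\n", sep = "")
  invisible(x)
}

#' @export
length.sanger_trace <- function(x) x$length

#' Read a chromatogram trace
#'
#' Dispatches on the file extension: `.ab1` is parsed as an ABIF binary
#' (processed channels `DATA` 9-12, base order `FWO_`, peak locations `PLOC`,
#' basecalls `PBAS`); anything else is parsed as the plain-text trace dialect
#' written by [write_trace()]: a header line `scan A C G T`, one row of channel
#' intensities per scan, and a block of `#basecall <scan> <base>` comment
#' lines.
#'
#' @param path Path to an `.ab1` or trace-TSV file.
#' @return A [sanger_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  if (grepl("\\.ab1$", path, ignore.case = TRUE)) {
    read_abif_trace(path)
  } else {
    read_trace_tsv(path)
  }
}

read_trace_tsv <- function(path) {
  lines <- readLines(path)
  bc_lines <- grep("^#basecall\\b", lines, value = TRUE)
  data_lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(data_lines) < 1) stop("trace file has no data: ", path, call. = FALSE)
  header <- strsplit(data_lines[1], "\t| +")[[1]]
  if (!identical(header, c("scan", "A", "C", "G", "T"))) {
    stop("trace header must be 'scan A C G T': ", path, call. = FALSE)
  }
  fields <- strsplit(data_lines[-1], "\t| +")
  n_fields <- lengths(fields)
  if (any(n_fields != 5)) {
    stop("malformed trace row (expected 5 columns) at data line ",
         which(n_fields != 5)[1], call. = FALSE)
  }
  mat <- matrix(as.numeric(unlist(fields)), ncol = 5, byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric value in trace channels", call. = FALSE)
  if (!identical(as.integer(mat[, 1]), seq_len(nrow(mat)) - 1L)) {
    stop("scan column must run 0..n-1 without gaps", call. = FALSE)
  }
  bc <- tibble::tibble(scan = integer(), base = character())
  if (length(bc_lines) > 0) {
    parts <- strsplit(bc_lines, "\t| +")
    bc <- tibble::tibble(
      scan = as.integer(vapply(parts, `[`, "", 2)),
      base = vapply(parts, `[`, "", 3)
    )
  }
  sanger_trace(mat[, 2:5, drop = FALSE], bc)
}

#' Write a trace in the plain-text dialect
#'
#' Round-trips exactly through [read_trace()] when intensities are integral.
#'
#' @param trace A [sanger_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#basecall", trace$basecalls$scan, trace$basecalls$base), con)
  writeLines("scan\tA\tC\tG\tT", con)
  body <- cbind(seq_len(trace$length) - 1L, trace$channels)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

# --- minimal ABIF (ab1) support ------------------------------------------
# ABIF is a big-endian tagged container: a 128-byte header whose directory
# pointer leads to 28-byte entries (name, tag number, element type/size,
# count, data size, offset; data <= 4 bytes is stored inline in the offset
# field). Only the tags needed for peak-area work are read.

abif_read_entry_data <- function(con, entry) {
  if (entry$size <= 4) {
    raw <- entry$inline[seq_len(entry$size)]
  } else {
    seek(con, entry$offset)
    raw <- readBin(con, "raw", n = entry$size)
  }
  switch(as.character(entry$type),
    "2" = rawToChar(raw),                                        # char
    "4" = readBin(raw, "integer", n = entry$n, size = 2,
                  endian = "big", signed = TRUE),                # short
    "5" = readBin(raw, "integer", n = entry$n, size = 4,
                  endian = "big"),                               # long
    "18" = rawToChar(raw[-1]),                                   # pString
    raw
  )
}

read_abif <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, "ABIF")) stop("not an ABIF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 2, endian = "big")  # version
  # the header's own directory entry
  readBin(con, "raw", 4); readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 2, size = 2, endian = "big")
  n_entries <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 1, size = 4, endian = "big")  # dir size
  dir_offset <- readBin(con, "integer", 1, size = 4, endian = "big")
  entries <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    seek(con, dir_offset + (i - 1) * 28)
    name <- rawToChar(readBin(con, "raw", 4))
    number <- readBin(con, "integer", 1, size = 4, endian = "big")
    type <- readBin(con, "integer", 1, size = 2, endian = "big")
    el_size <- readBin(con, "integer", 1, size = 2, endian = "big")
    n <- readBin(con, "integer", 1, size = 4, endian = "big")
    size <- readBin(con, "integer", 1, size = 4, endian = "big")
    inline <- readBin(con, "raw", 4)
    offset <- readBin(inline, "integer", 1, size = 4, endian = "big")
    entries[[i]] <- list(name = name, number = number, type = type,
                         el_size = el_size, n = n, size = size,
                         offset = offset, inline = inline)
  }
  # read all payloads eagerly, before the connection closes
  tags <- lapply(entries, function(e) abif_read_entry_data(con, e))
  names(tags) <- vapply(entries, function(e) paste0(e$name, ".", e$number), "")
  list(get = function(name, number) tags[[paste0(name, ".", number)]])
}

read_abif_trace <- function(path) {
  ab <- read_abif(path)
  order <- ab$get("FWO_", 1)
  if (is.null(order)) stop("ab1 file lacks FWO_ base order tag", call. = FALSE)
  order <- strsplit(order, "")[[1]]
  # DATA 9-12 hold the processed (analyzed) channels in FWO_ order
  chans <- lapply(9:12, function(i) ab$get("DATA", i))
  if (any(vapply(chans, is.null, TRUE))) {
    stop("ab1 file lacks processed DATA 9-12 channels", call. = FALSE)
  }
  lens <- lengths(chans)
  if (length(unique(lens)) != 1) stop("ab1 channel length mismatch", call. = FALSE)
  mat <- matrix(0, nrow = lens[1], ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in 1:4) mat[, order[i]] <- chans[[i]]
  ploc <- ab$get("PLOC", 2) %||% ab$get("PLOC", 1)
  pbas <- ab$get("PBAS", 2) %||% ab$get("PBAS", 1)
  bc <- tibble::tibble(scan = integer(), base = character())
  if (!is.null(ploc)) {
    base <- if (!is.null(pbas)) strsplit(pbas, "")[[1]] else rep("N", length(ploc))
    bc <- tibble::tibble(scan = as.integer(ploc), base = base[seq_along(ploc)])
  }
  sanger_trace(mat, bc)
}

#' Write a trace as a minimal ab1 (ABIF) file
#'
#' Emits the tags [read_trace()] consumes: `DATA` 9-12 (channels, as shorts in
#' `FWO_` order GATC), `PLOC.2` and `PBAS.2`. Intended for testing ab1 round
#' trips with simulated traces; intensities are truncated to the signed
#' 16-bit range.
#'
#' @param trace A [sanger_trace()].
#' @param path Output path (conventionally `.ab1`).
#' @return `path`, invisibly.
#' @export
write_abif_trace <- function(trace, path) {
  int2be <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  int4be <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  order <- c("G", "A", "T", "C")
  chan_data <- lapply(order, function(b) {
    v <- as.integer(pmin(pmax(round(trace$channels[, b]), -32768), 32767))
    v
  })
  ploc <- trace$basecalls$scan
  pbas <- paste(trace$basecalls$base, collapse = "")

  items <- list(
    list(name = "FWO_", number = 1L, type = 2L, el = 1L, data = charToRaw("GATC")),
    list(name = "DATA", number = 9L, type = 4L, el = 2L, data = chan_data[[1]]),
    list(name = "DATA", number = 10L, type = 4L, el = 2L, data = chan_data[[2]]),
    list(name = "DATA", number = 11L, type = 4L, el = 2L, data = chan_data[[3]]),
    list(name = "DATA", number = 12L, type = 4L, el = 2L, data = chan_data[[4]]),
    list(name = "PLOC", number = 2L, type = 4L, el = 2L, data = as.integer(ploc)),
    list(name = "PBAS", number = 2L, type = 2L, el = 1L, data = charToRaw(pbas))
  )
  payload <- lapply(items, function(it) {
    if (is.raw(it$data)) it$data
    else writeBin(it$data, raw(), size = it$el, endian = "big")
  })
  sizes <- vapply(payload, length, 1L)
  ns <- vapply(seq_along(items), function(i) {
    if (items[[i]]$el == 1) sizes[i] else sizes[i] %/% items[[i]]$el
  }, 1L)
  # layout: 128-byte header, then payload blocks (>4 bytes), then directory
  offsets <- integer(length(items))
  cursor <- 128L
  for (i in seq_along(items)) {
    if (sizes[i] > 4) { offsets[i] <- cursor; cursor <- cursor + sizes[i] }
  }
  dir_offset <- cursor

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("ABIF"), con)
  int2be(101)
  writeBin(charToRaw("tdir"), con); int4be(1L)
  int2be(1023L); int2be(28L)
  int4be(length(items)); int4be(length(items) * 28L); int4be(dir_offset)
  int4be(0L)
  writeBin(raw(128 - 34), con)  # pad header to 128 bytes
  for (i in seq_along(items)) {
    if (sizes[i] > 4) writeBin(payload[[i]], con)
  }
  for (i in seq_along(items)) {
    it <- items[[i]]
    writeBin(charToRaw(it$name), con)
    int4be(it$number); int2be(it$type); int2be(it$el)
    int4be(ns[i]); int4be(sizes[i])
    if (sizes[i] > 4) {
      int4be(offsets[i])
    } else {
      writeBin(c(payload[[i]], raw(4 - sizes[i])), con)
    }
    int4be(0L)
  }
  invisible(path)
}

# window [lo, hi) around basecall index i: inter-basecall midpoints,
# trace edges at the termini
peak_window <- function(trace, basecall_index) {
  scans <- trace$basecalls$scan
  n <- length(scans)
  if (basecall_index < 1 || basecall_index > n) {
    stop("basecall_index out of range (1..", n, ")", call. = FALSE)
  }
  center <- scans[basecall_index]
  lo <- if (basecall_index == 1) 0L
        else as.integer(floor((scans[basecall_index - 1] + center) / 2)) + 1L
  hi <- if (basecall_index == n) trace$length
        else as.integer(floor((center + scans[basecall_index + 1]) / 2)) + 1L
  c(lo = lo, hi = hi)
}

#' Integrate the peak area of one channel at one position
#'
#' The integration window spans from the midpoint to the previous basecall to
#' the midpoint to the next basecall (trace edges at the termini). The area is
#' the summed channel intensity over the window minus a per-window baseline,
#' taken as window length times the minimum intensity in the window; it is
#' therefore never negative and a flat channel has area zero.
#'
#' @param trace A [sanger_trace()].
#' @param channel One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param center Scan index (0-based) of the peak center; must coincide with a
#'   basecall or lie inside the trace, in which case the nearest basecall's
#'   window is used.
#' @return A one-row tibble: `channel`, `center`, `lo`, `hi`, `area`.
#' @export
peak_area <- function(trace, channel, center) {
  channel <- match.arg(channel, c("A", "C", "G", "T"))
  if (center < 0 || center >= trace$length) {
    stop("center outside trace (0..", trace$length - 1, ")", call. = FALSE)
  }
  idx <- which.min(abs(trace$basecalls$scan - center))
  if (length(idx) == 0) stop("trace has no basecalls", call. = FALSE)
  w <- peak_window(trace, idx)
  y <- trace$channels[(w["lo"] + 1):w["hi"], channel]
  area <- sum(y) - length(y) * min(y)
  tibble::tibble(channel = channel, center = as.integer(center),
                 lo = as.integer(w["lo"]), hi = as.integer(w["hi"]),
                 area = area)
}

#' Editing efficiency from a Sanger trace
#'
#' Estimates the edited fraction at one basecall as the proportion of the T
#' peak area to the total T plus C peak area at that position,
#' `area_T / (area_T + area_C)`. The paper-style raw ratio `area_T / area_C`
#' is also reported for transparency. Both areas zero yields `NA`.
#'
#' @param trace A [sanger_trace()].
#' @param basecall_index 1-based index into the trace's basecalls.
#' @return A one-row tibble: `basecall_index`, `scan`, `area_t`, `area_c`,
#'   `efficiency`, `ratio_t_c`.
#' @export
trace_editing_efficiency <- function(trace, basecall_index) {
  scans <- trace$basecalls$scan
  if (basecall_index < 1 || basecall_index > length(scans)) {
    stop("basecall_index out of range (1..", length(scans), ")", call. = FALSE)
  }
  center <- scans[basecall_index]
  area_t <- peak_area(trace, "T", center)$area
  area_c <- peak_area(trace, "C", center)$area
  eff <- if (area_t + area_c > 0) area_t / (area_t + area_c) else NA_real_
  ratio <- if (area_c > 0) area_t / area_c else NA_real_
  tibble::tibble(basecall_index = as.integer(basecall_index),
                 scan = center, area_t = area_t, area_c = area_c,
                 efficiency = eff, ratio_t_c = ratio)
}
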