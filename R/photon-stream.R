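#' Construct a time-tagged photon stream
#'
#' A `photon_stream` is the universal input of the package: a set of photon
#' records, each with a macrotime (absolute arrival time in integer clock
#' ticks), a microtime (TCSPC channel, i.e. delay after the excitation pulse)
#' and a detector id. The object is self-describing: it carries the clock
#' period, the TCSPC channel resolution and the number of TCSPC channels.
#'
#' Macrotimes are stored as doubles holding exact integers (R has no native
#' 64-bit integer); they remain exact up to 2^53 ticks.
#'
#' @param macrotime numeric vector of integer clock ticks, sorted ascending.
#' @param microtime integer vector, TCSPC channel of each photon, in
#'   `[0, n_tcspc)`.
#' @param detector integer vector of detector ids.
#' @param clock_period macrotime clock period in seconds.
#' @param tcspc_resolution TCSPC channel width in seconds.
#' @param n_tcspc number of TCSPC channels per excitation period.
#' @param metadata free-form named list.
#' @return An object of class `photon_stream`.
#' @export
photon_stream <- function(macrotime, microtime, detector,
                          clock_period, tcspc_resolution, n_tcspc,
                          metadata = list()) {
  n <- length(macrotime)
  if (length(microtime) != n || length(detector) != n)
    stop("macrotime, microtime and detector must have equal length")
  if (n > 1 && any(diff(macrotime) < 0))
    stop("unsorted stream")
  if (n > 0 && (any(microtime < 0) || any(microtime >= n_tcspc)))
    stop("microtime outside [0, n_tcspc)")
  structure(
    list(macrotime = as.numeric(macrotime),
         microtime = as.integer(microtime),
         detector = as.integer(detector),
         clock_period = clock_period,
         tcspc_resolution = tcspc_resolution,
         n_tcspc = as.integer(n_tcspc),
         metadata = metadata),
    class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  dur <- if (length(x$macrotime)) diff(range(x$macrotime)) * x$clock_period else 0
  cat(sprintf("photon_stream: %d photons, %.3f s, clock %.4g s, %d TCSPC channels\n",
              length(x$macrotime), dur, x$clock_period, x$n_tcspc))
  invisible(x)
}

#' @export
length.photon_stream <- function(x) length(x$macrotime)

#' Subset a photon stream by photon index
#'
#' @param stream a [photon_stream()].
#' @param i integer (or logical) index vector.
#' @return A `photon_stream` with the selected photons.
#' @export
stream_subset <- function(stream, i) {
  photon_stream(stream$macrotime[i], stream$microtime[i], stream$detector[i],
                stream$clock_period, stream$tcspc_resolution, stream$n_tcspc,
                stream$metadata)
}

#' Photon macrotimes in seconds
#' @param stream a [photon_stream()].
#' @return numeric vector of arrival times (s).
#' @export
stream_seconds <- function(stream) stream$macrotime * stream$clock_period

#' Write a photon stream to the plain-text photon container
#'
#' The container is a CSV with columns `macrotime,microtime,detector` and a
#' self-describing header of `#`-prefixed `key=value` lines carrying the
#' clock period, TCSPC resolution and channel count, so a write-then-read
#' round trip reproduces the stream exactly.
#'
#' @param stream a [photon_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_photon_csv <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# clock_period=%.17g", stream$clock_period),
    sprintf("# tcspc_resolution=%.17g", stream$tcspc_resolution),
    sprintf("# n_tcspc=%d", stream$n_tcspc),
    "macrotime,microtime,detector"), con)
  if (length(stream$macrotime))
    writeLines(sprintf("%.0f,%d,%d", stream$macrotime, stream$microtime,
                       stream$detector), con)
  invisible(path)
}

#' Read a photon stream from the plain-text photon container
#'
#' @param path file written by [write_photon_csv()] (or hand-written in the
#'   same dialect).
#' @return A [photon_stream()].
#' @export
read_photon_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", hdr))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_, "")
  meta <- stats::setNames(as.list(as.numeric(vals)), keys)
  need <- c("clock_period", "tcspc_resolution", "n_tcspc")
  if (!all(need %in% keys))
    stop("malformed container: missing ", paste(setdiff(need, keys), collapse = ", "))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 1 || !grepl("^macrotime", body[1]))
    stop("malformed container: missing column header")
  if (length(body) > 1) {
    dat <- utils::read.csv(text = body, header = TRUE)
  } else {
    dat <- data.frame(macrotime = numeric(0), microtime = integer(0),
                      detector = integer(0))
  }
  if (is.unsorted(dat$macrotime)) stop("unsorted stream")
  photon_stream(dat$macrotime, dat$microtime, dat$detector,
                meta$clock_period, meta$tcspc_resolution, meta$n_tcspc)
}

#' Define a pulsed-interleaved excitation (PIE) scheme
#'
#' PIE fires the lasers in non-overlapping microtime windows within one
#' repetition period, so the excitation source of every photon is read off
#' its microtime, and its detection color/polarization off its detector id.
#' Windows are half-open `[start, end)` TCSPC channels.
#'
#' @param windows data.frame with columns `label` (e.g. "B","G","R"),
#'   `start`, `end` (TCSPC channels, half-open).
#' @param detector_map data.frame with columns `detector`, `color`
#'   (e.g. "G","R"), `polarization` ("par"/"perp").
#' @param repetition_rate laser repetition rate (Hz).
#' @return An object of class `pie_scheme`.
#' @export
pie_scheme <- function(windows, detector_map, repetition_rate) {
  stopifnot(all(c("label", "start", "end") %in% names(windows)),
            all(c("detector", "color", "polarization") %in% names(detector_map)))
  w <- windows[order(windows$start), ]
  if (any(w$end <= w$start)) stop("empty excitation window")
  if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)]))
    stop("overlapping excitation windows")
  if (anyDuplicated(detector_map$detector))
    stop("detector mapped more than once")
  structure(list(windows = w, detector_map = detector_map,
                 repetition_rate = repetition_rate),
            class = "pie_scheme")
}

#' Standard two-color (green/red) PIE scheme
#'
#' Emulates the common MFD-PIE layout: green pulse at the start of the
#' period, red pulse delayed by half a period, two detection colors with two
#' polarizations each.
#'
#' @param n_tcspc TCSPC channels per period.
#' @param repetition_rate laser repetition rate (Hz).
#' @return A [pie_scheme()] with windows G = `[0, n/2)`, R = `[n/2, n)` and
#'   detectors 0/1 (G par/perp), 2/3 (R par/perp).
#' @export
pie_scheme_2c <- function(n_tcspc = 4096L, repetition_rate = 26.7e6) {
  half <- n_tcspc %/% 2
  pie_scheme(
    windows = data.frame(label = c("G", "R"), start = c(0L, half),
                         end = c(half, n_tcspc)),
    detector_map = data.frame(detector = 0:3,
                              color = c("G", "G", "R", "R"),
                              polarization = c("par", "perp", "par", "perp")),
    repetition_rate = repetition_rate)
}

#' Standard three-color (blue/green/red) PIE scheme
#'
#' Three interleaved pulses (B, G, R) each occupying a third of the
#' repetition period, six detectors (three colors times two polarizations).
#'
#' @inheritParams pie_scheme_2c
#' @return A [pie_scheme()].
#' @export
pie_scheme_3c <- function(n_tcspc = 3072L, repetition_rate = 16.7e6) {
  third <- n_tcspc %/% 3
  pie_scheme(
    windows = data.frame(label = c("B", "G", "R"),
                         start = c(0L, third, 2L * third),
                         end = c(third, 2L * third, n_tcspc)),
    detector_map = data.frame(detector = 0:5,
                              color = c("B", "B", "G", "G", "R", "R"),
                              polarization = rep(c("par", "perp"), 3)),
    repetition_rate = repetition_rate)
}

#' Assign every photon to a PIE channel
#'
#' Labels each photon `XY`: excitation window `X` from its microtime and
#' detection color `Y` from its detector. Photons whose microtime falls in
#' an inter-window gap are labeled `"outside"` and excluded from counts, so
#' the assignment is a partition: the per-channel counts plus the outside
#' count equal the number of photons.
#'
#' @param stream a [photon_stream()].
#' @param scheme a [pie_scheme()].
#' @return list with `label` (character per photon, e.g. "GR" or "outside"),
#'   `polarization` (per photon), and `counts` (named integer vector of
#'   `F_XY` totals, e.g. `F_GG`).
#' @export
assign_pie_channels <- function(stream, scheme) {
  dm <- scheme$detector_map
  unknown <- setdiff(unique(stream$detector), dm$detector)
  if (length(unknown))
    stop("unknown detector: ", paste(unknown, collapse = ", "))
  idx <- match(stream$detector, dm$detector)
  color <- dm$color[idx]
  pol <- dm$polarization[idx]
  w <- scheme$windows
  exc <- rep(NA_character_, length(stream$macrotime))
  for (k in seq_len(nrow(w))) {
    inw <- stream$microtime >= w$start[k] & stream$microtime < w$end[k]
    exc[inw] <- w$label[k]
  }
  label <- ifelse(is.na(exc), "outside", paste0(exc, color))
  chans <- as.vector(outer(w$label, unique(dm$color), paste0))
  counts <- vapply(chans, function(ch) sum(label == ch), 0L)
  names(counts) <- paste0("F_", chans)
  list(label = label, polarization = pol, counts = counts)
}
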