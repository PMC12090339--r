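# Plate-reader file dialects.
#
# Tidy dialect: one row per timepoint; first column `time_min`, then one
# column per well and channel named `<well>_480` / `<well>_520`. The layout
# travels in a companion CSV (well, variant_id, replicate, is_blank).
#
# "POLARstar-like" dialect: two channel blocks in one file, each introduced
# by a line `Channel <nm>`, followed by a header `Well,<t1>,<t2>,...` (times
# in minutes) and one row per well. Blocks are separated by a blank line.

#' Write and read the tidy plate CSV dialect
#'
#' @param plate A [fret_plate()].
#' @param signals_file CSV path for the two-channel time series.
#' @param layout_file CSV path for the well layout.
#' @return `read_plate_csv` returns a [fret_plate()].
#' @export
write_plate_csv <- function(plate, signals_file, layout_file) {
  stopifnot(inherits(plate, "fret_plate"))
  wells <- colnames(plate$f480)
  df <- data.frame(time_min = plate$time)
  for (w in wells) df[[paste0(w, "_480")]] <- plate$f480[, w]
  for (w in wells) df[[paste0(w, "_520")]] <- plate$f520[, w]
  write.csv(df, signals_file, row.names = FALSE, quote = FALSE)
  lay <- as.data.frame(plate$layout)
  lay$variant_id[is.na(lay$variant_id)] <- ""
  write.csv(lay, layout_file, row.names = FALSE, quote = FALSE)
  invisible(signals_file)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(signals_file, layout_file) {
  df <- read.csv(signals_file, check.names = FALSE)
  if (names(df)[1] != "time_min") {
    stop("tidy plate CSV must start with a `time_min` column", call. = FALSE)
  }
  time <- df$time_min
  cols <- names(df)[-1]
  ch <- sub(".*_(480|520)$", "\\1", cols)
  wells <- sub("_(480|520)$", "", cols)
  if (!all(ch %in% c("480", "520"))) {
    stop("signal columns must be named <well>_480 / <well>_520",
         call. = FALSE)
  }
  uw <- unique(wells)
  f480 <- as.matrix(df[, paste0(uw, "_480"), drop = FALSE])
  f520 <- as.matrix(df[, paste0(uw, "_520"), drop = FALSE])
  colnames(f480) <- colnames(f520) <- uw
  layout <- read.csv(layout_file,
                     colClasses = c(well = "character",
                                    variant_id = "character"))
  layout$variant_id[layout$variant_id == ""] <- NA_character_
  layout$is_blank <- as.logical(layout$is_blank)
  fret_plate(time, f480, f520, layout)
}

#' Read a POLARstar-like two-block plate export
#'
#' Parses a wide export in which each emission channel forms its own block:
#' a `Channel 480` / `Channel 520` marker line, a header row
#' `Well,<t1>,<t2>,...` with times in minutes, then one row per well.
#'
#' @param file Path to the two-block CSV.
#' @param layout Layout data frame or path to a layout CSV
#'   (well, variant_id, replicate, is_blank).
#' @return A [fret_plate()].
#' @export
read_plate_polarstar <- function(file, layout) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  marks <- grep("^Channel[ ,]*(480|520)", lines)
  if (length(marks) != 2) {
    stop("expected exactly two `Channel <nm>` blocks", call. = FALSE)
  }
  parse_block <- function(from, to) {
    header <- strsplit(lines[from + 1], ",")[[1]]
    times <- as.numeric(header[-1])
    rows <- strsplit(lines[(from + 2):to], ",")
    wells <- vapply(rows, `[[`, character(1), 1)
    vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                     numeric(length(times))))
    m <- t(vals)  # timepoints x wells
    colnames(m) <- wells
    list(time = times, m = m)
  }
  ends <- c(marks[2] - 1L, length(lines))
  b1 <- parse_block(marks[1], ends[1])
  b2 <- parse_block(marks[2], ends[2])
  ch1 <- sub("^Channel[ ,]*", "", lines[marks[1]])
  blocks <- if (startsWith(ch1, "480")) list(f480 = b1, f520 = b2)
            else list(f480 = b2, f520 = b1)
  if (!isTRUE(all.equal(blocks$f480$time, blocks$f520$time))) {
    stop("channel blocks disagree on timepoints", call. = FALSE)
  }
  if (is.character(layout)) {
    layout <- read.csv(layout, colClasses = c(well = "character",
                                              variant_id = "character"))
    layout$variant_id[layout$variant_id == ""] <- NA_character_
  }
  wells <- colnames(blocks$f480$m)
  fret_plate(blocks$f480$time, blocks$f480$m,
             blocks$f520$m[, wells, drop = FALSE], layout)
}
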