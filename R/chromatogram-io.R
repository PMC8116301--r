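new_chromatogram <- function(time, intensity) {
  if (length(time) < 2) abort("a chromatogram needs at least 2 points")
  if (anyNA(time) || anyNA(intensity)) abort("chromatogram contains missing values")
  bad <- which(diff(time) <= 0)
  if (length(bad)) {
    abort(sprintf("time axis not strictly increasing at row %d", bad[1] + 1))
  }
  out <- tibble::tibble(time = as.numeric(time),
                        intensity = as.numeric(intensity))
  class(out) <- c("fuco_chromatogram", class(out))
  out
}

sampling_interval_of <- function(chrom) median(diff(chrom$time))

#' Read a fluorescence chromatogram from delimited text
#'
#' Parses the open two-column text export of a fluorescence trace: column 1 is
#' retention time in minutes, column 2 intensity in arbitrary units. The
#' delimiter is auto-detected among tab, comma and semicolon; an optional
#' header line is skipped; rows with unparseable fields are rejected with
#' their positions reported as a warning.
#'
#' @param path Path to the text file (or a character vector of lines).
#' @return A chromatogram tibble (`time`, `intensity`).
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("time,fluorescence", "0,0", "0.5,2", "1,0"), f)
#' read_chromatogram(f)
read_chromatogram <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty chromatogram file")
  delim_of <- function(x) {
    counts <- c(`\t` = sum(strsplit(x, "")[[1]] == "\t"),
                `,` = lengths(regmatches(x, gregexpr(",", x, fixed = TRUE))),
                `;` = lengths(regmatches(x, gregexpr(";", x, fixed = TRUE))))
    names(which.max(counts))
  }
  delim <- delim_of(lines[min(2, length(lines))])
  parts <- strsplit(lines, delim, fixed = TRUE)
  parse_row <- function(p) {
    if (length(p) < 2) return(c(NA_real_, NA_real_))
    suppressWarnings(as.numeric(trimws(p[1:2])))
  }
  vals <- t(vapply(parts, parse_row, numeric(2)))
  ok <- stats::complete.cases(vals)
  bad <- which(!ok)
  # a single leading bad row is a header, not a data defect
  if (length(bad) && bad[1] == 1) bad <- bad[-1]
  if (length(bad)) {
    warn(sprintf("rejected %d unparseable row(s) at line(s): %s",
                 length(bad), paste(bad, collapse = ", ")))
  }
  vals <- vals[ok, , drop = FALSE]
  if (nrow(vals) < 2) abort("fewer than 2 valid data rows")
  nd <- which(diff(vals[, 1]) <= 0)
  if (length(nd)) {
    abort(sprintf("time axis not strictly increasing at data row %d", nd[1] + 1))
  }
  new_chromatogram(vals[, 1], vals[, 2])
}

#' Write a chromatogram as two-column delimited text
#'
#' @param chrom Chromatogram tibble.
#' @param path Output path.
#' @param delim Delimiter (default tab).
#' @param header Write a `time<delim>intensity` header line.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path, delim = "\t", header = TRUE) {
  lines <- paste(format(chrom$time, trim = TRUE, scientific = FALSE),
                 format(chrom$intensity, trim = TRUE, scientific = FALSE),
                 sep = delim)
  if (header) lines <- c(paste("time", "intensity", sep = delim), lines)
  writeLines(lines, path)
  invisible(path)
}

#' @export
autoplot.fuco_chromatogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Retention time [min]", y = "Fluorescence [a.u.]") +
    ggplot2::theme_minimal()
}

#' @export
plot.fuco_chromatogram <- function(x, ...) print(autoplot(x, ...))
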