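## Shared plain-text I/O. All interval formats are 0-based half-open
## (BED-native); bedGraph values must be finite; CRLF line endings are
## accepted and normalized. Malformed lines are reported with file name and
## line number. FASTA goes through Biostrings.

read_text_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sub("\r$", "", readLines(path, warn = FALSE))
}

parse_tsv <- function(path, n_min_fields, what) {
  lines <- read_text_lines(path)
  keep <- !grepl("^(#|track |browser )", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < n_min_fields)
  if (length(bad))
    stopf("%s:%d: expected >= %d tab-separated fields in %s record",
          path, idx[bad[1]], n_min_fields, what)
  list(fields = fields, lineno = idx)
}

check_coords <- function(path, lineno, start, end) {
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stopf("%s:%d: invalid interval (need integer 0 <= start < end)",
          path, lineno[bad[1]])
  if (any(end > .Machine$integer.max))
    stopf("%s: coordinate overflow (> %d)", path, .Machine$integer.max)
}

#' Read / write FASTA
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read / write BED intervals (0-based half-open)
#'
#' @param path file path.
#' @return data frame (`chrom`, `start`, `end`, and `name`, `score` when
#'   present).
#' @export
read_bed <- function(path) {
  p <- parse_tsv(path, 3, "BED")
  f <- p$fields
  start <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3)))
  check_coords(path, p$lineno, start, end)
  out <- data.frame(chrom = vapply(f, `[`, "", 1),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  if (all(lengths(f) >= 4)) out$name <- vapply(f, `[`, "", 4)
  if (all(lengths(f) >= 5))
    out$score <- suppressWarnings(as.numeric(vapply(f, `[`, "", 5)))
  out
}

#' @rdname read_bed
#' @param bed data frame with `chrom`, `start`, `end` and optional `name`,
#'   `score` columns.
#' @export
write_bed <- function(bed, path) {
  cols <- list(bed$chrom, format_coord(bed$start), format_coord(bed$end))
  if (!is.null(bed$name)) {
    cols <- c(cols, list(bed$name))
    if (!is.null(bed$score)) cols <- c(cols, list(as.character(bed$score)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read / write bedGraph tracks (0-based half-open, finite values)
#'
#' @param path file path.
#' @return data frame (`chrom`, `start`, `end`, `value`).
#' @export
read_bedgraph <- function(path) {
  p <- parse_tsv(path, 4, "bedGraph")
  f <- p$fields
  start <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3)))
  check_coords(path, p$lineno, start, end)
  value <- suppressWarnings(as.numeric(vapply(f, `[`, "", 4)))
  bad <- which(!is.finite(value))
  if (length(bad))
    stopf("%s:%d: non-finite bedGraph value", path, p$lineno[bad[1]])
  data.frame(chrom = vapply(f, `[`, "", 1), start = as.integer(start),
             end = as.integer(end), value = value, stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param track data frame with `chrom`, `start`, `end`, `value`.
#' @export
write_bedgraph <- function(track, path) {
  if (any(!is.finite(track$value)))
    stopf("write_bedgraph: non-finite value at record %d",
          which(!is.finite(track$value))[1])
  writeLines(paste(track$chrom, format_coord(track$start),
                   format_coord(track$end),
                   format(track$value, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

PROBE_COLS <- c("id", "chrom", "start", "end", "signal_resistant",
                "signal_total", "fold_change", "log2_ratio")

#' Read / write probe tables as TSV
#'
#' Header row with the canonical eight columns; real-data mode accepts the
#' same layout produced externally. Missing values are written as `.`.
#'
#' @param path file path.
#' @return a `probe_table`.
#' @export
read_probe_tsv <- function(path) {
  lines <- read_text_lines(path)
  if (length(lines) == 0) stopf("%s: empty probe table", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!all(PROBE_COLS %in% header))
    stopf("%s:1: probe TSV header must contain: %s", path,
          paste(PROBE_COLS, collapse = ", "))
  body <- lines[-1]
  body[body == ""] <- NA
  f <- strsplit(body[!is.na(body)], "\t", fixed = TRUE)
  short <- which(lengths(f) < length(header))
  if (length(short))
    stopf("%s:%d: truncated probe record", path, short[1] + 1L)
  df <- as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
  names(df) <- header
  df <- df[PROBE_COLS]
  df[df == "."] <- NA
  for (col in c("start", "end")) df[[col]] <- as.integer(df[[col]])
  for (col in PROBE_COLS[5:8]) df[[col]] <- as.numeric(df[[col]])
  check_coords(path, seq_len(nrow(df)) + 1L, df$start, df$end)
  if (anyDuplicated(df$id))
    stopf("%s: duplicate probe id %s", path, df$id[duplicated(df$id)][1])
  structure(df, class = c("probe_table", "data.frame"))
}

#' @rdname read_probe_tsv
#' @param grid a `probe_table`.
#' @export
write_probe_tsv <- function(grid, path) {
  df <- as.data.frame(grid)[PROBE_COLS]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE,
                                 digits = 15)))
  writeLines(c(paste(PROBE_COLS, collapse = "\t"),
               do.call(paste, c(df, sep = "\t"))), path)
  invisible(path)
}

#' Write a generic TSV report with header ('.' for missing)
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv_report <- function(df, path) {
  out <- df
  out[] <- lapply(out, function(x) {
    x <- if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE,
                                   digits = 10) else as.character(x)
    ifelse(is.na(x) | x == "NA", ".", x)
  })
  writeLines(c(paste(names(out), collapse = "\t"),
               if (nrow(out)) do.call(paste, c(out, sep = "\t"))), path)
  invisible(path)
}
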