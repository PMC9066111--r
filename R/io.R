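#' Read and write plain-text genomic interval files
#'
#' Readers/writers for the tab-delimited text formats the pipeline consumes
#' and emits: BED3+ (intervals with optional extra columns), BED12 gene
#' models, narrowPeak (BED6+4) ChIP peaks, and bedGraph signal tracks. All
#' coordinates are 0-based half-open on disk and in memory.
#'
#' @param path file path.
#' @param extra_names names for columns beyond chrom/start/end in BED3+ files.
#' @return a `data.frame` with `chrom`, `start`, `end` and format-specific
#'   columns.
#' @name interval_io
NULL

read_tsv_checked <- function(path, n_min, what) {
  if (!file.exists(path)) stop_named("io", paste0(what, " file not found: ", path))
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#", quote = ""),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame())
      stop_named("io", paste0("cannot parse ", what, " file ", path, ": ",
                              conditionMessage(e)))
    })
  if (nrow(df) > 0L && ncol(df) < n_min)
    stop_named("io", sprintf("%s file %s has %d columns, expected >= %d",
                             what, path, ncol(df), n_min))
  df
}

#' @rdname interval_io
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- read_tsv_checked(path, 3L, "BED")
  if (nrow(df) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer())
    for (nm in extra_names) out[[nm]] <- character()
    return(out)
  }
  names(df)[1:3] <- c("chrom", "start", "end")
  if (!is.null(extra_names)) {
    k <- min(length(extra_names), ncol(df) - 3L)
    if (k > 0L) names(df)[4:(3L + k)] <- extra_names[seq_len(k)]
  }
  df$chrom <- as.character(df$chrom)
  df
}

#' @rdname interval_io
#' @param df data frame to write.
#' @export
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

bed12_cols <- c("chrom", "start", "end", "name", "score", "strand",
                "thickStart", "thickEnd", "itemRgb", "blockCount",
                "blockSizes", "blockStarts")

#' @rdname interval_io
#' @export
read_bed12 <- function(path) {
  df <- read_tsv_checked(path, 12L, "BED12")
  if (nrow(df) == 0L)
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = 12)), bed12_cols))
  names(df) <- bed12_cols
  df$chrom <- as.character(df$chrom)
  df$blockSizes <- as.character(df$blockSizes)
  df$blockStarts <- as.character(df$blockStarts)
  validate_bed12(df, path)
  df
}

validate_bed12 <- function(df, path = "<data>") {
  for (i in seq_len(nrow(df))) {
    sizes <- as.integer(strsplit(df$blockSizes[i], ",")[[1]])
    offs <- as.integer(strsplit(df$blockStarts[i], ",")[[1]])
    if (length(sizes) != df$blockCount[i] || length(offs) != df$blockCount[i] ||
        anyNA(sizes) || anyNA(offs) ||
        any(df$start[i] + offs + sizes > df$end[i]) || offs[1] != 0L)
      stop_named("io", sprintf("malformed BED12 blocks in %s at line %d", path, i))
  }
  invisible(df)
}

#' @rdname interval_io
#' @export
write_bed12 <- function(df, path) write_bed(df[, bed12_cols], path)

np_cols <- c("chrom", "start", "end", "name", "score", "strand",
             "signalValue", "pValue", "qValue", "summit")

#' @rdname interval_io
#' @export
read_narrowpeak <- function(path) {
  df <- read_tsv_checked(path, 10L, "narrowPeak")
  if (nrow(df) == 0L) {
    out <- stats::setNames(data.frame(matrix(nrow = 0, ncol = 10)), np_cols)
    out$chrom <- character(); out$start <- integer(); out$end <- integer()
    return(out)
  }
  names(df) <- np_cols
  df$chrom <- as.character(df$chrom)
  bad <- which(!(df$summit == -1L | (df$summit >= 0L & df$summit < df$end - df$start)))
  if (length(bad))
    stop_named("io", sprintf("narrowPeak %s line %d: summit offset out of range",
                             path, bad[1]))
  df
}

#' @rdname interval_io
#' @export
write_narrowpeak <- function(df, path) write_bed(df[, np_cols], path)

#' @rdname interval_io
#' @export
read_bedgraph <- function(path) {
  df <- read_tsv_checked(path, 4L, "bedGraph")
  if (nrow(df) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  names(df)[1:4] <- c("chrom", "start", "end", "value")
  df$chrom <- as.character(df$chrom)
  df[, 1:4]
}

#' @rdname interval_io
#' @export
write_bedgraph <- function(df, path) write_bed(df[, c("chrom", "start", "end", "value")], path)

# summit position in bp (0-based); midpoint fallback when offset is -1
peak_summit <- function(peaks) {
  s <- ifelse(peaks$summit >= 0L, peaks$start + peaks$summit,
              (peaks$start + peaks$end) %/% 2L)
  as.integer(s)
}

#' Plain-text key-value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numeric when possible, otherwise kept as strings. Used to echo
#' simulation and pipeline parameters next to their outputs.
#'
#' @param x named list to write.
#' @param path file path.
#' @export
write_keyvalue <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    v <- x[[k]]
    sprintf("%s = %s", k, paste(format(v, scientific = FALSE, trim = TRUE),
                                collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_keyvalue
#' @export
read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
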