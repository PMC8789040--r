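# Plain-text I/O: 4-line FASTQ, TSV count tables, tidy sensorgram CSV, JSON
# fit reports, and run manifests. The FASTQ reader is deliberately a strict
# 4-line parser so malformed records are reported with their line numbers
# and sequence + quality round-trip losslessly.

#' Read a 4-line FASTQ file
#'
#' @param path file path (gzipped files are handled transparently).
#' @return data.frame with columns id, sequence, quality; 0 rows for an
#'   empty-but-valid file. Malformed records are rejected with the offending
#'   line number.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L)
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  if (n %% 4L != 0L)
    stop(sprintf("truncated FASTQ record: %d leftover line(s) at line %d",
                 n %% 4L, n - n %% 4L + 1L), call. = FALSE)
  h <- seq(1L, n, by = 4L)
  bad <- which(!startsWith(lines[h], "@"))
  if (length(bad) > 0L)
    stop(sprintf("malformed FASTQ header at line %d (must start with '@')",
                 h[bad[1L]]), call. = FALSE)
  bad <- which(!startsWith(lines[h + 2L], "+"))
  if (length(bad) > 0L)
    stop(sprintf("malformed FASTQ separator at line %d (must start with '+')",
                 h[bad[1L]] + 2L), call. = FALSE)
  seqs <- lines[h + 1L]
  quals <- lines[h + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0L)
    stop(sprintf("sequence/quality length mismatch at line %d",
                 h[bad[1L]] + 3L), call. = FALSE)
  data.frame(id = sub("^@", "", lines[h]), sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Write reads as 4-line FASTQ
#'
#' @param records data.frame with id, sequence, quality columns.
#' @param path output path; a ".gz" suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(records)))
  lines <- if (nrow(records) == 0L) character() else
    as.vector(rbind(paste0("@", records$id), records$sequence,
                    "+", records$quality))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a count table as TSV
#' @param table a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table from TSV
#'
#' Requires columns pool, round, sequence, count; abundance is recomputed
#' per (pool, round). A missing column is named in the error.
#'
#' @param path TSV path.
#' @return a `count_table`.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sequence = "character"))
  need <- c("pool", "round", "sequence", "count")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop(sprintf("count table %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[order(df$pool, df$round, -df$count, df$sequence), , drop = FALSE]
  tot <- stats::ave(df$count, df$pool, df$round, FUN = sum)
  df$abundance <- df$count / tot
  rownames(df) <- NULL
  class(df) <- c("count_table", "data.frame")
  df
}

#' Write sensorgrams as tidy CSV
#' @param sg a `sensorgram_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensorgram_csv <- function(sg, path) {
  utils::write.csv(as.data.frame(sg), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy sensorgram CSV
#'
#' Requires columns time, response, conc, phase.
#'
#' @param path CSV path.
#' @return a `sensorgram_set`.
#' @export
read_sensorgram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "response", "conc", "phase")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop(sprintf("sensorgram file %s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  class(df) <- c("sensorgram_set", "data.frame")
  df
}

#' Write a kinetic fit report as JSON
#' @param fit a `kinetic_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "kinetic_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a kinetic fit report from JSON
#' @param path JSON path.
#' @return a `kinetic_fit`.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$se <- unlist(x$se)
  structure(x, class = "kinetic_fit")
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: parameters, master seed, package
#' version, and output checksums, so a run is reproducible from its manifest
#' alone.
#'
#' @param path manifest path (JSON).
#' @param seed master seed.
#' @param params named list of parameters.
#' @param outputs character vector of output file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, params = list(), outputs = character()) {
  sums <- vapply(outputs, function(f)
    as.character(tools::md5sum(f)), character(1L))
  jsonlite::write_json(
    list(seed = seed, params = params,
         package_version = as.character(utils::packageVersion("pdselex")),
         outputs = as.list(sums)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
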