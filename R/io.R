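#' Read sequence records from FASTA or FASTQ
#'
#' The format is auto-detected from the first character of the file
#' (`>` for FASTA, `@` for FASTQ); plain and gzip-compressed files are both
#' accepted regardless of extension. FASTQ records are validated record by
#' record: a malformed record raises an error naming the file and the record
#' ordinal.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzip-compressed.
#' @return A tibble with columns `id`, `sequence` and `quality` (`NA` for
#'   FASTA input).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' write_sequences(tibble::tibble(id = "s1", sequence = "ACGTACGT"), tf)
#' read_sequences(tf)
read_sequences <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  first <- readChar(con, 1L, useBytes = TRUE)
  if (length(first) == 0 || !nzchar(first))
    return(tibble(id = character(), sequence = character(),
                  quality = character()))
  if (first == ">") {
    seqs <- Biostrings::readBStringSet(path, format = "fasta")
    return(tibble(id = names(seqs),
                  sequence = unname(toupper(as.character(seqs))),
                  quality = NA_character_))
  }
  if (first != "@")
    abort(sprintf("cannot detect FASTA/FASTQ format of %s", path))
  close(con)
  on.exit()
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4 != 0)
    abort(sprintf("malformed FASTQ in %s: line count %d is not a multiple of 4",
                  path, length(lines)))
  n <- length(lines) / 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seq <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    abort(sprintf("malformed FASTQ record %d in %s: bad header or separator line",
                  bad[1], path))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    abort(sprintf(
      "malformed FASTQ record %d in %s: sequence and quality lengths differ (%d vs %d)",
      bad[1], path, nchar(seq[bad[1]]), nchar(qual[bad[1]])))
  tibble(id = sub("^@", "", hdr), sequence = toupper(seq), quality = qual)
}

#' Write sequence records to FASTA or FASTQ
#'
#' Records with a non-missing `quality` column are written as 4-line FASTQ;
#' otherwise sequences are written as FASTA wrapped at 60 columns. Paths
#' ending in `.gz` are gzip-compressed.
#'
#' @param records A tibble with columns `id`, `sequence` and optionally
#'   `quality`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  fastq <- "quality" %in% names(records) && nrow(records) > 0 &&
    !anyNA(records$quality)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(records) == 0) {
    writeLines(character(0), con)
    return(invisible(path))
  }
  if (fastq) {
    if (any(nchar(records$sequence) != nchar(records$quality)))
      abort("sequence and quality lengths differ; refusing to write FASTQ")
    out <- as.vector(rbind(paste0("@", records$id), records$sequence,
                           "+", records$quality))
  } else {
    wrapped <- vapply(records$sequence, function(s) {
      starts <- seq(1, max(nchar(s), 1), by = 60)
      paste(substring(s, starts, pmin(starts + 59, nchar(s))), collapse = "\n")
    }, character(1), USE.NAMES = FALSE)
    out <- as.vector(rbind(paste0(">", records$id), wrapped))
  }
  writeLines(out, con)
  invisible(path)
}
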