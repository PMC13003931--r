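#' Read a FASTQ file strictly
#'
#' Reads 4-line FASTQ records in file order. Order preservation is
#' contractual: downstream UMI collapse keeps the *first* occurrence of each
#' UMI, so reads must come back exactly as stored. The parser is strict:
#' a truncated record, a record whose quality string differs in length from
#' its sequence, or a missing `+` separator is an error, never silently
#' repaired.
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return A [tibble::tibble] with columns `read_id`, `sequence`, `quality`,
#'   one row per read, in file order. An empty file gives zero rows.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L)
    return(tibble::tibble(read_id = character(0), sequence = character(0),
                          quality = character(0)))
  if (n %% 4L != 0L)
    stop("truncated FASTQ record in ", path, ": ", n,
         " lines is not a multiple of 4", call. = FALSE)
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  sep <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad_hdr <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad_hdr))
    stop("malformed FASTQ header at record ", bad_hdr[1], " in ", path,
         call. = FALSE)
  bad_sep <- which(substr(sep, 1L, 1L) != "+")
  if (length(bad_sep))
    stop("missing '+' separator at record ", bad_sep[1], " in ", path,
         call. = FALSE)
  bad_len <- which(nchar(seq) != nchar(qual))
  if (length(bad_len))
    stop("sequence/quality length mismatch at record ", bad_len[1], " in ",
         path, call. = FALSE)
  tibble::tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
    sequence = toupper(seq),
    quality = qual
  )
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `read_id` and `sequence` columns; a `quality`
#'   column is used when present, otherwise a constant Phred+33 `I` (Q40)
#'   quality is emitted.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) reads$quality else
    vapply(nchar(reads$sequence), function(w) strrep("I", w), character(1))
  con <- file(path, open = "wb")  # fixed newline convention for reproducibility
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                             "+", qual)),
             con, sep = "\n")
  invisible(path)
}
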