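#' Define an amplicon target locus
#'
#' An amplicon target describes one assayed uridine: the sense-orientation
#' reference sequence of the amplicon, the two 8-mer anchors that must match
#' perfectly in a read, and the central NpsiN triplet whose middle base is the
#' assayed U. Anchors flank the triplet immediately
#' (`anchor_up + center_triplet + anchor_down` occurs verbatim in the
#' reference) so that the gap between perfect anchor matches in a read is 3 nt
#' for an intact molecule and 2 nt when reverse transcription has deleted the
#' pseudouridine.
#'
#' @param locus_name Character scalar naming the locus.
#' @param reference Sense-orientation nucleotide string of the amplicon
#'   (`U` is accepted and normalized to `T`).
#' @param anchor_up,anchor_down 8-nt anchor sequences immediately upstream /
#'   downstream of the target triplet.
#' @param center_triplet 3-nt NpsiN context; the middle base must be `T`/`U`.
#' @param psi_index 0-based index of the assayed U in `reference`.
#'
#' @return An object of class `"amplicon_target"`: a list with the validated
#'   fields above (sequences upper-case DNA).
#' @examples
#' tg <- amplicon_target(
#'   locus_name = "demo",
#'   reference  = "GGACCTGAACCGATGCTTGACCAGTCCAAGGTAC",
#'   anchor_up  = "CTGAACCG", anchor_down = "CTTGACCA",
#'   center_triplet = "ATG", psi_index = 13
#' )
#' @export
amplicon_target <- function(locus_name, reference, anchor_up, anchor_down,
                            center_triplet, psi_index) {
  stopifnot(is.character(locus_name), length(locus_name) == 1L)
  reference <- .norm_seq(reference)
  anchor_up <- .norm_seq(anchor_up)
  anchor_down <- .norm_seq(anchor_down)
  center_triplet <- .norm_seq(center_triplet)

  problems <- character(0)
  if (nchar(anchor_up) != 8L)
    problems <- c(problems, sprintf("anchor_up has length %d, not 8", nchar(anchor_up)))
  if (nchar(anchor_down) != 8L)
    problems <- c(problems, sprintf("anchor_down has length %d, not 8", nchar(anchor_down)))
  if (nchar(center_triplet) != 3L)
    problems <- c(problems, sprintf("center_triplet has length %d, not 3", nchar(center_triplet)))
  if (!is.numeric(psi_index) || length(psi_index) != 1L || psi_index != round(psi_index))
    problems <- c(problems, "psi_index must be a single integer (0-based)")

  if (!length(problems)) {
    psi_index <- as.integer(psi_index)
    cassette <- paste0(anchor_up, center_triplet, anchor_down)
    cas_at <- regexpr(cassette, reference, fixed = TRUE)[1]
    if (cas_at < 0L) {
      problems <- c(problems,
        "anchors must occur in reference immediately flanking center_triplet")
    } else {
      expected_psi <- cas_at - 1L + 8L + 1L  # 0-based middle of triplet
      if (psi_index != expected_psi)
        problems <- c(problems, sprintf(
          "psi_index %d does not point at the middle of center_triplet (expected %d)",
          psi_index, expected_psi))
    }
    if (psi_index >= 0 && psi_index < nchar(reference) &&
        substr(reference, psi_index + 1L, psi_index + 1L) != "T")
      problems <- c(problems, sprintf(
        "reference base at psi_index %d is '%s', not T/U",
        psi_index, substr(reference, psi_index + 1L, psi_index + 1L)))
    if (substr(center_triplet, 2L, 2L) != "T")
      problems <- c(problems, "middle base of center_triplet must be T/U")
  }
  if (length(problems))
    stop("invalid target '", locus_name, "': ", paste(problems, collapse = "; "),
         call. = FALSE)

  structure(
    list(locus_name = locus_name, reference = reference,
         anchor_up = anchor_up, anchor_down = anchor_down,
         center_triplet = center_triplet, psi_index = as.integer(psi_index)),
    class = "amplicon_target"
  )
}

#' @export
print.amplicon_target <- function(x, ...) {
  cat(sprintf("<amplicon_target> %s: %d-nt reference, psi at %d (%s)\n",
              x$locus_name, nchar(x$reference), x$psi_index, x$center_triplet))
  invisible(x)
}

# Upper-case, RNA U -> DNA T, validate alphabet.
.norm_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  if (grepl("[^ACGTN]", x))
    stop("sequence contains non-ACGTUN characters", call. = FALSE)
  x
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Read and validate a target definition file
#'
#' Parses a TSV (columns `locus_name`, `reference`, `anchor_up`,
#' `anchor_down`, `center_triplet`, `psi_index`; `psi_index` 0-based) or a
#' JSON array of objects with the same fields, validates every
#' [amplicon_target()] invariant, and reports *all* violations at once, each
#' prefixed with the offending locus name.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` target file.
#' @return A named list of `amplicon_target` objects.
#' @export
validate_targets <- function(path) {
  if (!file.exists(path)) stop("target file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext == "json") {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!is.data.frame(df)) stop("JSON target file must be an array of objects", call. = FALSE)
    df
  } else {
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  required <- c("locus_name", "reference", "anchor_up", "anchor_down",
                "center_triplet", "psi_index")
  missing <- setdiff(required, names(rows))
  if (length(missing))
    stop("target file lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)

  targets <- list()
  errors <- character(0)
  for (i in seq_len(nrow(rows))) {
    tg <- tryCatch(
      amplicon_target(rows$locus_name[i], rows$reference[i], rows$anchor_up[i],
                      rows$anchor_down[i], rows$center_triplet[i],
                      as.numeric(rows$psi_index[i])),
      error = function(e) conditionMessage(e)
    )
    if (is.character(tg)) errors <- c(errors, tg)
    else targets[[tg$locus_name]] <- tg
  }
  if (length(errors))
    stop("target validation failed:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  targets
}

#' Built-in demonstration target
#'
#' A synthetic 46-nt amplicon with a central TTG triplet used by the
#' simulator defaults, examples and the end-to-end demo.
#' @return An `amplicon_target`.
#' @export
demo_target <- function() {
  amplicon_target(
    locus_name = "demo_locus",
    reference  = "ACGGTTCACCTGAACCGTTGCTTGACCAGTCCTTAGGCATTGCAAC",
    anchor_up = "CTGAACCG", anchor_down = "CTTGACCA",
    center_triplet = "TTG", psi_index = 18
  )
}
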