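#' Extract the UMI from raw reads
#'
#' The UMI occupies bases `[umi_offset, umi_offset + umi_length)` of each
#' read (0-based); the payload is the read with the UMI excised, any bases
#' before the UMI staying at the payload head.
#'
#' @param reads Tibble with `read_id` and `sequence` (e.g. from
#'   [read_fastq()]).
#' @param umi_length UMI length (default 10).
#' @param umi_offset 0-based UMI start within the read (default 0).
#' @return The input tibble with columns `umi` and `payload` added.
#' @export
extract_umi <- function(reads, umi_length = 10L, umi_offset = 0L) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  w <- nchar(reads$sequence)
  short <- which(w < umi_offset + umi_length)
  if (length(short))
    stop("read too short for UMI extraction: ",
         reads$read_id[short[1]], " (", w[short[1]], " nt < ",
         umi_offset + umi_length, ")", call. = FALSE)
  reads$umi <- substr(reads$sequence, umi_offset + 1L,
                      umi_offset + umi_length)
  reads$payload <- paste0(substr(reads$sequence, 1L, umi_offset),
                          substr(reads$sequence,
                                 umi_offset + umi_length + 1L, w))
  reads
}

#' Collapse reads by UMI, keeping the first occurrence
#'
#' PCR duplicates share a UMI; for each distinct UMI string exactly the
#' first-encountered read is retained, in the original relative order.
#' Matching is exact string identity with no mismatch tolerance, which makes
#' the operation idempotent.
#'
#' @param reads Tibble with a `umi` column (from [extract_umi()]), in the
#'   order they were sequenced.
#' @return The subset of `reads` with the first read per UMI.
#' @export
collapse_by_umi <- function(reads) {
  stopifnot("umi" %in% names(reads))
  reads[!duplicated(reads$umi), , drop = FALSE]
}

#' Match the two 8-mer anchors in read payloads
#'
#' Finds the leftmost exact occurrence of `anchor_up`, then the leftmost
#' exact occurrence of `anchor_down` after it, and reports the gap strictly
#' between them. A payload matches in sense orientation if both anchors are
#' found with `gap_length <= max_gap`; otherwise the reverse complement is
#' tried and the orientation recorded. Matching is perfect-only: any
#' substitution in an anchor disqualifies that occurrence. `gap_sequence` is
#' always reported in the sense orientation of the amplicon.
#'
#' @param payloads Character vector of read payloads (UMI already removed).
#' @param target An [amplicon_target()].
#' @param max_gap Maximum gap length accepted as a locus match (default 10).
#' @return A tibble with one row per payload: `matched` (logical),
#'   `gap_length`, `gap_sequence`, `orientation` (`"sense"`, `"revcomp"`, or
#'   `NA` when unmatched). No-match is a value, not an error.
#' @export
match_anchors <- function(payloads, target, max_gap = 10L) {
  stopifnot(inherits(target, "amplicon_target"))
  sense <- .match_one_strand(payloads, target$anchor_up, target$anchor_down,
                             max_gap)
  out <- tibble::tibble(matched = sense$matched,
                        gap_length = sense$gap_length,
                        gap_sequence = sense$gap_sequence,
                        orientation = ifelse(sense$matched, "sense",
                                             NA_character_))
  retry <- which(!sense$matched & nzchar(payloads))
  if (length(retry)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(payloads[retry])))
    alt <- .match_one_strand(rc, target$anchor_up, target$anchor_down,
                             max_gap)
    hit <- which(alt$matched)
    if (length(hit)) {
      out$matched[retry[hit]] <- TRUE
      out$gap_length[retry[hit]] <- alt$gap_length[hit]
      out$gap_sequence[retry[hit]] <- alt$gap_sequence[hit]
      out$orientation[retry[hit]] <- "revcomp"
    }
  }
  out
}

# One-strand anchor scan, vectorized over payloads.
.match_one_strand <- function(seqs, up, down, max_gap) {
  up_at <- regexpr(up, seqs, fixed = TRUE)
  up_end <- up_at + nchar(up) - 1L
  rest <- ifelse(up_at > 0L, substr(seqs, up_end + 1L, nchar(seqs)), "")
  down_at <- regexpr(down, rest, fixed = TRUE)
  gap <- down_at - 1L
  ok <- up_at > 0L & down_at > 0L & gap <= max_gap
  list(matched = ok,
       gap_length = ifelse(ok, gap, NA_integer_),
       gap_sequence = ifelse(ok, substr(rest, 1L, gap), NA_character_))
}

#' Classify anchor-matched reads at a locus
#'
#' Each read with both perfect anchors at gap `<= max_gap` is classified by
#' the gap between them: 2 nt is the deletion signature (`n_del`); 3 nt with
#' a `T` at the central gap base (the psi position, sense strand) is a
#' retained unmodified readout (`n_ret_T`); 3 nt with a non-T central base is
#' the misincorporation signature (`n_ret_nonT`); any other accepted gap goes
#' to `n_other_gap`. The four buckets partition `n_anchor_matched` exactly.
#' With `single_anchor = TRUE`, reads carrying at least one perfect anchor
#' (in either orientation) but no accepted two-anchor match also enter the
#' denominator, bucketed under `n_other_gap` since no gap is defined for
#' them; they never contribute to a signature numerator.
#'
#' @param reads UMI-collapsed tibble with a `payload` column.
#' @param target An [amplicon_target()].
#' @param max_gap Maximum accepted gap (default 10).
#' @param single_anchor Permissive mode including one-anchor reads in the
#'   denominator (default `FALSE`).
#' @return A list of class `"locus_counts"` with `locus_name`,
#'   `n_input_reads`, `n_after_umi`, `n_anchor_matched`, `n_del`, `n_ret_T`,
#'   `n_ret_nonT`, `n_other_gap`.
#' @export
count_locus <- function(reads, target, max_gap = 10L, single_anchor = FALSE) {
  stopifnot("payload" %in% names(reads))
  m <- match_anchors(reads$payload, target, max_gap = max_gap)
  gap <- m$gap_length[m$matched]
  mid <- substr(m$gap_sequence[m$matched], 2L, 2L)

  n_del <- sum(gap == 2L)
  n_ret_T <- sum(gap == 3L & mid == "T")
  n_ret_nonT <- sum(gap == 3L & mid != "T")
  n_other <- sum(gap != 2L & gap != 3L)
  n_matched <- sum(m$matched)

  if (single_anchor && any(!m$matched)) {
    un <- reads$payload[!m$matched]
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(un)))
    has_up <- regexpr(target$anchor_up, un, fixed = TRUE) > 0L |
      regexpr(target$anchor_up, rc, fixed = TRUE) > 0L
    has_down <- regexpr(target$anchor_down, un, fixed = TRUE) > 0L |
      regexpr(target$anchor_down, rc, fixed = TRUE) > 0L
    n_single <- sum(has_up | has_down)
    n_matched <- n_matched + n_single
    n_other <- n_other + n_single
  }

  structure(list(locus_name = target$locus_name,
                 n_input_reads = NA_integer_,
                 n_after_umi = nrow(reads),
                 n_anchor_matched = n_matched,
                 n_del = n_del, n_ret_T = n_ret_T, n_ret_nonT = n_ret_nonT,
                 n_other_gap = n_other),
            class = "locus_counts")
}

#' @export
print.locus_counts <- function(x, ...) {
  cat(sprintf(paste0("<locus_counts> %s: %d collapsed reads, %d anchor-",
                     "matched (del %d, ret-T %d, ret-nonT %d, other %d)\n"),
              x$locus_name, x$n_after_umi, x$n_anchor_matched, x$n_del,
              x$n_ret_T, x$n_ret_nonT, x$n_other_gap))
  invisible(x)
}

#' Deletion and mutation signature rates
#'
#' The deletion rate is the fraction of anchor-matched sequences at the locus
#' with 2 nt between the perfect 8-mer matches; the mutation rate is the
#' fraction with 3 nt between them and no T at the psi position. A locus with
#' zero anchor-matched reads is a no-data error (no pseudocounts), reported
#' with the locus name.
#'
#' @param counts A `"locus_counts"` from [count_locus()].
#' @return A list with `deletion_rate` and `mutation_rate`.
#' @export
signature_rates <- function(counts) {
  stopifnot(inherits(counts, "locus_counts"))
  if (counts$n_anchor_matched <= 0L)
    stop("no anchor-matched reads at locus '", counts$locus_name,
         "': rates undefined", call. = FALSE)
  list(deletion_rate = counts$n_del / counts$n_anchor_matched,
       mutation_rate = counts$n_ret_nonT / counts$n_anchor_matched)
}

#' Normalize a signature rate to the 100% PsiTP standard
#'
#' Effective pseudouridylation is the sample signature rate divided by the
#' rate observed on the matched 100% PsiTP synthetic standard. Sampling noise
#' or calibration bias can push the ratio above 1; by default it is reported
#' as-is with a warning so the bias stays visible, and clamping to 1 is
#' opt-in.
#'
#' @param sample_rate Signature rate of the sample, in `[0, 1]`.
#' @param standard_rate Signature rate of the 100% PsiTP standard; must be
#'   > 0 (a zero standard rate means the calibration failed).
#' @param clamp Clamp values above 1 to 1 (default `FALSE`).
#' @return A list with `effective_psi` and logical `clamped`.
#' @export
effective_psi <- function(sample_rate, standard_rate, clamp = FALSE) {
  if (!is.finite(standard_rate) || standard_rate <= 0)
    stop("standard deletion rate is ", standard_rate,
         ": 100% PsiTP standard failed, cannot normalize", call. = FALSE)
  eff <- sample_rate / standard_rate
  clamped <- FALSE
  if (eff > 1) {
    if (clamp) {
      eff <- 1
      clamped <- TRUE
    } else {
      warning("effective_psi = ", signif(eff, 4),
              " exceeds 1 (calibration bias or sampling noise)",
              call. = FALSE)
    }
  }
  list(effective_psi = eff, clamped = clamped)
}

#' Quantify effective pseudouridylation at one locus
#'
#' The full CMC amplicon pipeline: read sample and 100% PsiTP standard FASTQ
#' files (or in-memory read tibbles), extract UMIs, collapse by first UMI
#' occurrence, match anchors, count signatures, compute rates, and normalize
#' the sample deletion rate to the standard's. The report row carries every
#' intermediate count for both read sets, the strict-denominator rate
#' (gap-2/3 reads only) alongside the default all-matched denominator, and
#' the clamping flag.
#'
#' @param sample,standard FASTQ paths or read tibbles (with `read_id`,
#'   `sequence`).
#' @param target An [amplicon_target()].
#' @param umi_length,umi_offset UMI geometry (defaults 10, 0).
#' @param max_gap Maximum accepted anchor gap (default 10).
#' @param clamp Clamp effective values above 1 (default `FALSE`).
#' @param single_anchor Permissive one-anchor denominator (default `FALSE`).
#' @param rate `"deletion"` (default; matches standard-normalized deletion
#'   signatures) or `"combined"` (deletion + mutation rate, opt-in).
#' @param verbose Log read counts at each filtering stage (default `FALSE`).
#' @return A one-row tibble with locus name, all counts and rates for sample
#'   and standard, `effective_psi` and `clamped`.
#' @export
quantify_locus <- function(sample, standard, target, umi_length = 10L,
                           umi_offset = 0L, max_gap = 10L, clamp = FALSE,
                           single_anchor = FALSE,
                           rate = c("deletion", "combined"),
                           verbose = FALSE) {
  rate <- match.arg(rate)
  stage <- function(reads, label) {
    n_in <- nrow(reads)
    reads <- extract_umi(reads, umi_length = umi_length,
                         umi_offset = umi_offset)
    reads <- collapse_by_umi(reads)
    counts <- count_locus(reads, target, max_gap = max_gap,
                          single_anchor = single_anchor)
    counts$n_input_reads <- n_in
    if (verbose)
      message(sprintf("[%s/%s] input %d -> after UMI %d -> anchor-matched %d",
                      target$locus_name, label, n_in, counts$n_after_umi,
                      counts$n_anchor_matched))
    counts
  }
  as_reads <- function(x) if (is.character(x)) read_fastq(x) else x
  smp <- stage(as_reads(sample), "sample")
  std <- stage(as_reads(standard), "standard")
  if (smp$n_input_reads == 0L || std$n_input_reads == 0L)
    stop("empty read set for locus '", target$locus_name, "'", call. = FALSE)

  sr <- signature_rates(smp)
  tr <- signature_rates(std)
  pick <- function(r) if (rate == "deletion") r$deletion_rate else
    r$deletion_rate + r$mutation_rate
  eff <- effective_psi(pick(sr), pick(tr), clamp = clamp)

  strict_rate <- function(cts) {
    denom <- cts$n_del + cts$n_ret_T + cts$n_ret_nonT
    if (denom > 0) cts$n_del / denom else NA_real_
  }
  tibble::tibble(
    locus_name = target$locus_name,
    n_input_reads = smp$n_input_reads, n_after_umi = smp$n_after_umi,
    n_anchor_matched = smp$n_anchor_matched,
    n_del = smp$n_del, n_ret_T = smp$n_ret_T, n_ret_nonT = smp$n_ret_nonT,
    n_other_gap = smp$n_other_gap,
    deletion_rate = sr$deletion_rate, mutation_rate = sr$mutation_rate,
    deletion_rate_strict = strict_rate(smp),
    std_n_input_reads = std$n_input_reads, std_n_after_umi = std$n_after_umi,
    std_n_anchor_matched = std$n_anchor_matched, std_n_del = std$n_del,
    std_deletion_rate = tr$deletion_rate,
    std_mutation_rate = tr$mutation_rate,
    effective_psi = eff$effective_psi, clamped = eff$clamped
  )
}
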