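#' Build a per-position deletion pileup
#'
#' Aggregates per-read coverage/deletion records into per-position coverage
#' and deletion counts; the deletion rate is `deletions / coverage`, left
#' `NA` (no-call, flagged by `defined = FALSE`) wherever coverage is zero —
#' never a division error and never a spurious 0.
#'
#' @param records Tibble/data frame with `position` (0-based), `covered`,
#'   `deleted` (e.g. from [simulate_bidseq_records()] or a TSV of the same
#'   shape).
#' @param reference_length Number of reference positions.
#' @return A tibble with one row per position: `position` (0-based),
#'   `coverage`, `deletions`, `deletion_rate`, `defined`.
#' @export
build_pileup <- function(records, reference_length) {
  stopifnot(all(c("position", "covered", "deleted") %in% names(records)))
  reference_length <- as.integer(reference_length)
  if (any(records$position < 0L | records$position >= reference_length))
    stop("record position out of reference bounds", call. = FALSE)
  if (any(records$deleted & !records$covered))
    stop("invalid record: deleted at an uncovered position", call. = FALSE)
  cov <- tabulate(records$position[records$covered] + 1L,
                  nbins = reference_length)
  del <- tabulate(records$position[records$covered & records$deleted] + 1L,
                  nbins = reference_length)
  rate <- ifelse(cov > 0L, del / cov, NA_real_)
  tibble::tibble(position = seq_len(reference_length) - 1L,
                 coverage = cov, deletions = del,
                 deletion_rate = rate, defined = cov > 0L)
}

#' Effective pseudouridylation at one BID-seq site
#'
#' The sample's per-position deletion rate divided by the matched 100%
#' PsiTP standard's rate at the same site — the identical normalization
#' contract as [effective_psi()] for CMC amplicons. Sites under
#' `min_coverage` in either profile are a no-call error rather than a rate.
#'
#' @param sample,standard Pileup tibbles from [build_pileup()].
#' @param site 0-based reference position of the assayed U.
#' @param min_coverage Minimum coverage required in both profiles
#'   (default 100).
#' @param clamp Clamp values above 1 (default `FALSE`).
#' @return A list with `effective_psi`, `clamped`, plus the two rates and
#'   coverages used.
#' @export
effective_psi_at_site <- function(sample, standard, site,
                                  min_coverage = 100L, clamp = FALSE) {
  row_of <- function(p, what) {
    i <- which(p$position == site)
    if (!length(i)) stop("site ", site, " absent from ", what, " pileup",
                         call. = FALSE)
    p[i[1], ]
  }
  s <- row_of(sample, "sample")
  t <- row_of(standard, "standard")
  if (s$coverage < min_coverage || t$coverage < min_coverage)
    stop("insufficient coverage at site ", site, " (sample ", s$coverage,
         ", standard ", t$coverage, ", need ", min_coverage, "): no call",
         call. = FALSE)
  eff <- effective_psi(s$deletion_rate, t$deletion_rate, clamp = clamp)
  c(eff, list(sample_rate = s$deletion_rate, standard_rate = t$deletion_rate,
              sample_coverage = s$coverage, standard_coverage = t$coverage))
}
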