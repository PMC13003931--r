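#' Simulate per-read BID-seq coverage/deletion records
#'
#' Bisulfite-induced deletion sequencing registers pseudouridine as a 1-nt
#' deletion at the modified position in aligned reads. This generator skips
#' the alignment layer entirely: reads of length `read_length` tile the
#' reference systematically, and each read reports an explicit
#' `(position, covered, deleted)` triple for every reference position it
#' spans, so downstream quantification needs no alignment engine. Per
#' molecule (read), pseudouridylation at the annotated sites is drawn with
#' probability `params$psi_fraction`; a covered pseudouridylated site
#' deletes with `params$p_del_psi`, an unmodified one with `params$p_del_u`.
#' Non-target positions never delete.
#'
#' @param reference Reference nucleotide string (sense orientation).
#' @param psi_positions Integer vector of 0-based indices of assayed U sites;
#'   each must be a `T`/`U` in `reference`.
#' @param params A [cmc_sim_params()]; `n_molecules` is the number of reads.
#' @param read_length Read length in nt (default: `min(50, nchar(reference))`).
#' @return A tibble of records (`read_id`, `position` 0-based, `covered`,
#'   `deleted`), one row per read x covered position, plus rows with
#'   `covered = FALSE` for annotated sites a read does not span.
#' @export
simulate_bidseq_records <- function(reference, psi_positions, params,
                                    read_length = NULL) {
  stopifnot(inherits(params, "cmc_sim_params"))
  reference <- .norm_seq(reference)
  L <- nchar(reference)
  psi_positions <- as.integer(psi_positions)
  if (any(psi_positions < 0L | psi_positions >= L))
    stop("psi position out of reference bounds", call. = FALSE)
  ref_bases <- substring(reference, psi_positions + 1L, psi_positions + 1L)
  if (any(ref_bases != "T"))
    stop("psi position(s) not at a U/T base: ",
         paste(psi_positions[ref_bases != "T"], collapse = ", "),
         call. = FALSE)
  read_length <- as.integer(read_length %||% min(50L, L))
  stopifnot(read_length >= 1L, read_length <= L)

  withr::local_seed(params$seed)
  n <- params$n_molecules
  n_starts <- L - read_length + 1L
  start <- (seq_len(n) - 1L) %% n_starts  # 0-based, systematic tiling
  end <- start + read_length - 1L

  is_psi <- runif(n) < params$psi_fraction
  read_id <- sprintf("bid_read%06d", seq_len(n))

  # covered grid: one row per read x offset within read
  off <- rep(seq_len(read_length) - 1L, times = n)
  ridx <- rep.int(seq_len(n), rep(read_length, n))
  pos <- start[ridx] + off
  is_site <- pos %in% psi_positions
  p_del <- ifelse(is_site, ifelse(is_psi[ridx], params$p_del_psi,
                                  params$p_del_u), 0)
  deleted <- runif(length(pos)) < p_del

  covered <- tibble::tibble(read_id = read_id[ridx], position = pos,
                            covered = TRUE, deleted = deleted)
  # annotated sites outside each read's span, marked uncovered
  un <- do.call(rbind, lapply(psi_positions, function(p) {
    miss <- which(start > p | end < p)
    if (!length(miss)) return(NULL)
    data.frame(read_id = read_id[miss], position = p, covered = FALSE,
               deleted = FALSE)
  }))
  out <- if (is.null(un)) covered else
    tibble::as_tibble(rbind(as.data.frame(covered), un))
  out[order(match(out$read_id, read_id), out$position), ]
}
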