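#' Simulation parameters for CMC amplicon reads
#'
#' Bundles and validates the stochastic model behind [simulate_cmc_reads()].
#' Per molecule, the model draws pseudouridylation with probability
#' `psi_fraction`; a pseudouridylated molecule yields a 1-nt deletion of the
#' target base with probability `p_del_psi`, otherwise it misreads as a
#' non-T base with probability `p_mut_psi`; an unmodified molecule deletes
#' with background probability `p_del_u`. Each molecule receives a random
#' UMI and a geometric number of PCR duplicates (mean `dup_mean`); per-base
#' sequencing error at rate `seq_error` is applied after duplication, so
#' duplicates can disagree and anchors can be corrupted.
#'
#' @param psi_fraction True pseudouridine stoichiometry theta in `[0, 1]`.
#' @param p_del_psi Probability a pseudouridylated molecule yields the 1-nt
#'   deletion signature (default 0.8).
#' @param p_del_u Background deletion probability for unmodified U
#'   (default 0.01).
#' @param p_mut_psi Probability a non-deleted pseudouridine reads as a non-T
#'   base (default 0.05).
#' @param seq_error Per-base substitution error rate after PCR (default 1e-3).
#' @param n_molecules Number of distinct molecules (default 10000).
#' @param dup_mean Mean PCR duplicates per molecule, geometric, >= 1
#'   (default 3).
#' @param umi_length UMI length in nt (default 10).
#' @param seed Integer seed; mandatory, no global random state is consulted.
#' @return A validated list of class `"cmc_sim_params"`.
#' @export
cmc_sim_params <- function(psi_fraction, p_del_psi = 0.8, p_del_u = 0.01,
                           p_mut_psi = 0.05, seq_error = 0.001,
                           n_molecules = 10000L, dup_mean = 3,
                           umi_length = 10L, seed) {
  probs <- c(psi_fraction = psi_fraction, p_del_psi = p_del_psi,
             p_del_u = p_del_u, p_mut_psi = p_mut_psi, seq_error = seq_error)
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad))
    stop("probabilities out of [0,1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (n_molecules < 1L) stop("n_molecules must be >= 1", call. = FALSE)
  if (dup_mean < 1) stop("dup_mean must be >= 1", call. = FALSE)
  if (umi_length < 1L) stop("umi_length must be >= 1", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an integer seed is required", call. = FALSE)
  structure(
    list(psi_fraction = psi_fraction, p_del_psi = p_del_psi,
         p_del_u = p_del_u, p_mut_psi = p_mut_psi, seq_error = seq_error,
         n_molecules = as.integer(n_molecules), dup_mean = dup_mean,
         umi_length = as.integer(umi_length), seed = as.integer(seed)),
    class = "cmc_sim_params"
  )
}

.random_strings <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(alphabet, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Vectorized per-base substitution error; returns mutated sequences.
.apply_seq_error <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  widths <- nchar(seqs)
  n_err <- rbinom(length(seqs), widths, rate)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(widths[i], n_err[i])
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate CMC amplicon reads with known pseudouridine stoichiometry
#'
#' Generates a FASTQ-ready read set plus a per-molecule truth table under the
#' model described in [cmc_sim_params()]. Each read is the amplicon payload
#' with the molecule's UMI inserted at `umi_offset` (default: read prefix).
#' Duplicates of a molecule share UMI and payload before sequencing error.
#'
#' @param target An [amplicon_target()].
#' @param params A [cmc_sim_params()].
#' @param umi_offset 0-based position of the UMI within the read (default 0,
#'   i.e. the read starts with the UMI).
#' @return A list of class `"cmc_simulation"`:
#'   * `reads` -- tibble (`read_id`, `sequence`, `quality`) suitable for
#'     [write_fastq()],
#'   * `truth` -- tibble (`molecule_id`, `umi`, `label`) with label one of
#'     `psi_deleted`, `psi_retained_mut`, `psi_retained_T`, `u_deleted`,
#'     `u_retained`,
#'   * `params`, `target`, `umi_offset` -- provenance.
#' @examples
#' sim <- simulate_cmc_reads(demo_target(),
#'   cmc_sim_params(psi_fraction = 0.5, n_molecules = 100, seed = 1))
#' table(sim$truth$label)
#' @export
simulate_cmc_reads <- function(target, params, umi_offset = 0L) {
  stopifnot(inherits(target, "amplicon_target"),
            inherits(params, "cmc_sim_params"))
  ref <- target$reference
  k <- target$psi_index + 1L  # 1-based psi position
  cassette_at <- regexpr(paste0(target$anchor_up, target$center_triplet,
                                target$anchor_down), ref, fixed = TRUE)[1]
  if (cassette_at < 0L)
    stop("anchors absent from reference or not flanking the target triplet",
         call. = FALSE)

  withr::local_seed(params$seed)
  n <- params$n_molecules

  is_psi <- runif(n) < params$psi_fraction
  u1 <- runif(n)  # deletion draw
  u2 <- runif(n)  # mutation draw (psi, non-deleted only)
  deleted <- ifelse(is_psi, u1 < params$p_del_psi, u1 < params$p_del_u)
  mutated <- is_psi & !deleted & (u2 < params$p_mut_psi)

  label <- character(n)
  label[is_psi & deleted] <- "psi_deleted"
  label[mutated] <- "psi_retained_mut"
  label[is_psi & !deleted & !mutated] <- "psi_retained_T"
  label[!is_psi & deleted] <- "u_deleted"
  label[!is_psi & !deleted] <- "u_retained"

  payload_del <- paste0(substr(ref, 1L, k - 1L), substr(ref, k + 1L, nchar(ref)))
  payloads <- rep(ref, n)
  payloads[deleted] <- payload_del
  mut_idx <- which(mutated)
  if (length(mut_idx)) {
    mut_base <- sample(c("A", "C", "G"), length(mut_idx), replace = TRUE)
    payloads[mut_idx] <- paste0(substr(ref, 1L, k - 1L), mut_base,
                                substr(ref, k + 1L, nchar(ref)))
  }

  umis <- .random_strings(n, params$umi_length)
  dup_n <- if (params$dup_mean > 1)
    1L + rgeom(n, prob = 1 / params$dup_mean) else rep(1L, n)

  mol_of_read <- rep.int(seq_len(n), dup_n)
  dup_rank <- sequence(dup_n)
  raw <- paste0(substr(payloads[mol_of_read], 1L, umi_offset),
                umis[mol_of_read],
                substr(payloads[mol_of_read], umi_offset + 1L,
                       nchar(payloads[mol_of_read])))
  raw <- .apply_seq_error(raw, params$seq_error)

  reads <- tibble::tibble(
    read_id = sprintf("%s_mol%06d_dup%d", target$locus_name, mol_of_read,
                      dup_rank),
    sequence = raw,
    quality = strrep("I", nchar(raw))
  )
  truth <- tibble::tibble(molecule_id = seq_len(n), umi = umis, label = label)
  structure(list(reads = reads, truth = truth, params = params,
                 target = target, umi_offset = as.integer(umi_offset)),
            class = "cmc_simulation")
}

#' Simulate a calibration standard read set
#'
#' A 100% PsiTP in-vitro-transcribed standard (`kind = "psi100"`) contains
#' pseudouridine at every U, so it is [simulate_cmc_reads()] with
#' `psi_fraction` forced to 1; the unmodified standard (`kind = "u100"`)
#' forces it to 0. All other chemistry parameters are taken from `params`,
#' which is what "matched chemistry" means for normalization.
#'
#' @inheritParams simulate_cmc_reads
#' @param kind `"psi100"` or `"u100"`.
#' @return A `"cmc_simulation"`, as [simulate_cmc_reads()].
#' @export
simulate_standard <- function(target, params, kind = c("psi100", "u100"),
                              umi_offset = 0L) {
  kind <- match.arg(kind)
  params$psi_fraction <- if (kind == "psi100") 1 else 0
  simulate_cmc_reads(target, params, umi_offset = umi_offset)
}

#' Write a CMC simulation to disk
#'
#' Emits `<prefix>.fastq` (reads), `<prefix>.truth.tsv` (per-molecule truth)
#' and `<prefix>.json` (all simulation parameters and seed) so any run can be
#' reproduced from its sidecar alone.
#'
#' @param sim A `"cmc_simulation"`.
#' @param prefix Output path prefix.
#' @return Character vector of the three paths written, invisibly.
#' @export
write_cmc_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "cmc_simulation"))
  fq <- paste0(prefix, ".fastq")
  tr <- paste0(prefix, ".truth.tsv")
  js <- paste0(prefix, ".json")
  write_fastq(sim$reads, fq)
  utils::write.table(sim$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- c(unclass(sim$params),
            list(umi_offset = sim$umi_offset,
                 locus_name = sim$target$locus_name,
                 reference = sim$target$reference))
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fq, tr, js))
}
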