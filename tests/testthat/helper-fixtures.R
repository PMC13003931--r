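# Shared fixtures and independent oracles for the test suite.

test_target <- function() demo_target()

# Quadratic brute-force first-occurrence UMI collapse: for each read, scan
# all earlier reads for the same UMI. Independent of collapse_by_umi().
brute_force_collapse <- function(reads) {
  keep <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    seen <- FALSE
    j <- 1L
    while (j < i) {
      if (reads$umi[j] == reads$umi[i]) { seen <- TRUE; break }
      j <- j + 1L
    }
    keep[i] <- !seen
  }
  reads[keep, , drop = FALSE]
}

# Textbook sums-based Pearson r and t-test p, coded independently of
# pearson_with_p (no cor(), no shared helpers).
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  r <- num / den
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * (1 - stats::pt(abs(t_stat), n - 2)))
}

# Base-4 encoding of integers as unique 10-mer UMIs.
int_to_umi <- function(i, len = 10L) {
  vapply(i, function(k) {
    digits <- integer(len)
    for (d in seq_len(len)) { digits[d] <- k %% 4L; k <- k %/% 4L }
    paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
  }, character(1))
}

# Reads built directly from payload strings (no simulator involved).
reads_from_payloads <- function(payloads, umis = NULL) {
  n <- length(payloads)
  if (is.null(umis)) umis <- int_to_umi(seq_len(n))
  tibble::tibble(read_id = sprintf("r%d", seq_len(n)),
                 sequence = paste0(umis, payloads))
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

quick_params <- function(theta, seed, n = 2000L, p_del_psi = 0.8,
                         p_del_u = 0, p_mut_psi = 0.05, seq_error = 0,
                         dup_mean = 2) {
  cmc_sim_params(psi_fraction = theta, p_del_psi = p_del_psi,
                 p_del_u = p_del_u, p_mut_psi = p_mut_psi,
                 seq_error = seq_error, n_molecules = n,
                 dup_mean = dup_mean, seed = seed)
}
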