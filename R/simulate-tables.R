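#' Simulate a long-form qPCR Cq table
#'
#' Under perfect doubling, one Cq unit corresponds to a 2-fold abundance
#' change, so `Cq = baseline - log2(abundance) + N(0, noise_sd)`. The
#' baseline (Cq of unit abundance) is fixed at 20; only Cq differences enter
#' any downstream computation, so its value is arbitrary but documented.
#'
#' @param design Data frame with columns `sample_id`, `fraction` (one of
#'   `nuclear`, `cytosolic`, `whole`), `gene`, `true_relative_abundance`
#'   (> 0).
#' @param noise_sd Additive Gaussian noise on the Cq scale (default 0.2).
#' @param n_replicates Technical replicates per design row (default 3).
#' @param seed Integer seed.
#' @param baseline Cq of unit abundance (default 20).
#' @return A tibble (`sample_id`, `fraction`, `gene`, `replicate`, `cq`).
#' @export
simulate_cq_table <- function(design, noise_sd = 0.2, n_replicates = 3L,
                              seed, baseline = 20) {
  stopifnot(all(c("sample_id", "fraction", "gene",
                  "true_relative_abundance") %in% names(design)))
  if (any(design$true_relative_abundance <= 0))
    stop("true_relative_abundance must be > 0", call. = FALSE)
  withr::local_seed(seed)
  idx <- rep(seq_len(nrow(design)), each = n_replicates)
  tibble::tibble(
    sample_id = design$sample_id[idx],
    fraction = design$fraction[idx],
    gene = design$gene[idx],
    replicate = rep(seq_len(n_replicates), times = nrow(design)),
    cq = baseline - log2(design$true_relative_abundance[idx]) +
      rnorm(length(idx), 0, noise_sd)
  )
}

#' Simulate assay fixture tables
#'
#' One dispatcher for the three table-shaped assay inputs:
#'
#' * `gel_bands`: `truth` has `lane`, `isoform`, `molar_amount`, `length_bp`;
#'   band intensity is `molar_amount * length_bp` (intercalating-dye signal
#'   is proportional to mass, i.e. moles x length) plus Gaussian noise,
#'   floored at 0.
#' * `trace_peaks`: `truth` has `site` and `editing` in `[0, 1]`; A and G
#'   peak heights at the edited adenosine are proportional to `(1 - e, e)`
#'   (scale 1000) plus noise; C and T carry a small constant baseline.
#' * `performance`: `truth` is a list with `n_genes` (default 15) and `r`
#'   (planted Pearson correlation between the per-gene construct performance
#'   ratio and exon count, default 0.9). The *sample* correlation is planted
#'   exactly by orthogonalized-residual construction, so with `noise_sd = 0`
#'   the downstream fitted r equals the planted r up to floating-point
#'   division. Gene length and nuclear export rate columns are independent
#'   covariates.
#'
#' @param kind `"gel_bands"`, `"trace_peaks"` or `"performance"`.
#' @param truth Ground-truth parameters for the chosen kind (see above).
#' @param seed Integer seed.
#' @param noise_sd Additive noise (intensity units for gels, peak-height
#'   units for traces, performance-ratio units for performance tables;
#'   default 0).
#' @return A tibble in the shape the matching `assay_stats` function expects.
#' @export
simulate_assay_tables <- function(kind = c("gel_bands", "trace_peaks",
                                           "performance"),
                                  truth, seed, noise_sd = 0) {
  kind <- match.arg(kind)
  withr::local_seed(seed)
  switch(kind,
    gel_bands = {
      stopifnot(all(c("lane", "isoform", "molar_amount", "length_bp")
                    %in% names(truth)))
      tibble::tibble(
        lane = truth$lane, isoform = truth$isoform,
        intensity = pmax(0, truth$molar_amount * truth$length_bp +
                           rnorm(nrow(truth), 0, noise_sd)),
        length_bp = as.integer(truth$length_bp)
      )
    },
    trace_peaks = {
      stopifnot(all(c("site", "editing") %in% names(truth)),
                all(truth$editing >= 0 & truth$editing <= 1))
      n <- nrow(truth); scale <- 1000
      tibble::tibble(
        site = truth$site,
        a = pmax(0, (1 - truth$editing) * scale + rnorm(n, 0, noise_sd)),
        c = pmax(0, 20 + rnorm(n, 0, noise_sd)),
        g = pmax(0, truth$editing * scale + rnorm(n, 0, noise_sd)),
        t = pmax(0, 20 + rnorm(n, 0, noise_sd))
      )
    },
    performance = {
      n <- truth$n_genes %||% 15L
      r <- truth$r %||% 0.9
      stopifnot(n >= 3L, abs(r) <= 1)
      exon_count <- sort(sample(2:60, n, replace = FALSE))
      zx <- as.numeric(scale(exon_count))
      e <- rnorm(n)
      e <- e - mean(e)
      e <- e - zx * sum(e * zx) / sum(zx^2)   # orthogonalize against x
      ze <- e / sd(e)                         # mean 0, unit sample variance
      y <- r * zx + sqrt(1 - r^2) * ze        # sample cor(y, exon_count) == r
      ratio <- 1.5 + 0.3 * y + rnorm(n, 0, noise_sd)
      cad <- runif(n, 0.10, 0.30)
      tibble::tibble(
        gene = sprintf("gene%02d", seq_len(n)),
        mean_edit_u7 = ratio * cad,
        mean_edit_cad = cad,
        exon_count = as.integer(exon_count),
        gene_length = round(runif(n, 5e3, 2e5)),
        export_rate = runif(n, 0.05, 1.5)
      )
    }
  )
}
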