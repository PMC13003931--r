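#' Relative expression from Cq values
#'
#' Classic delta-Cq quantification at perfect doubling efficiency: replicate
#' Cq values are averaged on the Cq scale within (sample, fraction, gene),
#' then relative expression of the target versus the control gene is
#' `2^(mean Cq_control - mean Cq_target)`. Averaging ratios instead of Cqs
#' is available via `average = "ratio"` (replicates are paired by order).
#'
#' @param cq Long-form Cq tibble (`sample_id`, `fraction`, `gene`,
#'   `replicate`, `cq`).
#' @param target_gene,control_gene Gene names (e.g. guide vs `"GAPDH"`).
#' @param sample_id Sample to quantify.
#' @param fraction Fraction to quantify (`"nuclear"`, `"cytosolic"`,
#'   `"whole"`).
#' @param average `"cq"` (default, standard convention) or `"ratio"`.
#' @return Relative expression (numeric scalar).
#' @export
relative_expression <- function(cq, target_gene, control_gene, sample_id,
                                fraction = "whole",
                                average = c("cq", "ratio")) {
  average <- match.arg(average)
  pick <- function(gene) {
    rows <- cq[cq$sample_id == sample_id & cq$fraction == fraction &
                 cq$gene == gene, , drop = FALSE]
    if (!nrow(rows))
      stop("no Cq rows for gene '", gene, "' in sample '", sample_id,
           "', fraction '", fraction, "'", call. = FALSE)
    rows$cq[order(rows$replicate)]
  }
  tgt <- pick(target_gene)
  ctl <- pick(control_gene)
  if (average == "cq") {
    2^(mean(ctl) - mean(tgt))
  } else {
    if (length(tgt) != length(ctl))
      stop("ratio averaging needs paired replicates", call. = FALSE)
    mean(2^(ctl - tgt))
  }
}

#' Nuclear/cytosolic enrichment ratio
#'
#' Normalizes the target gene to the control gene within each subcellular
#' fraction, then takes the ratio of these normalized expressions,
#' nuclear over cytosolic. Because each fraction is normalized internally,
#' any per-fraction additive Cq shift (e.g. different cDNA dilution factors)
#' cancels exactly.
#'
#' @inheritParams relative_expression
#' @return Nuclear-to-cytosolic ratio of normalized expression.
#' @export
nuclear_cytosolic_ratio <- function(cq, target_gene, control_gene,
                                    sample_id, average = c("cq", "ratio")) {
  average <- match.arg(average)
  nuc <- relative_expression(cq, target_gene, control_gene, sample_id,
                             fraction = "nuclear", average = average)
  cyt <- relative_expression(cq, target_gene, control_gene, sample_id,
                             fraction = "cytosolic", average = average)
  nuc / cyt
}

#' Percent spliced-in from gel band intensities
#'
#' Intercalating-dye band intensity scales with mass, so intensities are
#' first converted to molar amounts by dividing by fragment length
#' ("adjusting bands for relative molecular weights"); PSI is the molar
#' fraction of the exon-included isoform.
#'
#' @param bands Tibble for one lane with columns `isoform` (`"included"` /
#'   `"excluded"`), `intensity` (>= 0) and `length_bp` (> 0). Multiple bands
#'   per isoform are summed on the molar scale.
#' @return PSI in `[0, 1]`.
#' @export
psi_from_bands <- function(bands) {
  stopifnot(all(c("isoform", "intensity", "length_bp") %in% names(bands)))
  if (any(bands$intensity < 0) || any(bands$length_bp <= 0))
    stop("intensities must be >= 0 and lengths > 0", call. = FALSE)
  molar <- bands$intensity / bands$length_bp
  inc <- sum(molar[bands$isoform == "included"])
  exc <- sum(molar[bands$isoform == "excluded"])
  if (inc + exc <= 0)
    stop("both molar amounts are zero: PSI undefined", call. = FALSE)
  inc / (inc + exc)
}

#' Difference in PSI between conditions
#'
#' `delta_psi = psi_treated - psi_control`; exon skipping induced by a
#' treatment therefore appears as a negative dPSI.
#'
#' @param psi_treated,psi_control PSI values in `[0, 1]`.
#' @return dPSI in `[-1, 1]`.
#' @export
delta_psi <- function(psi_treated, psi_control) psi_treated - psi_control

#' A-to-I editing fraction from Sanger peak heights
#'
#' Inosine pairs like guanosine, so at the targeted adenosine the editing
#' fraction is the G share of the A+G signal: `g / (a + g)`.
#'
#' @param a,c,g,t Peak heights at the edited position (`c` and `t` are
#'   accepted for completeness and ignored by the formula).
#' @return Editing fraction in `[0, 1]` (vectorized).
#' @export
sanger_editing <- function(a, g, c = NULL, t = NULL) {
  if (any(a < 0 | g < 0)) stop("peak heights must be >= 0", call. = FALSE)
  if (any(a + g <= 0))
    stop("A + G peak height is zero: editing undefined", call. = FALSE)
  g / (a + g)
}

#' Dual-luciferase reporter ratio
#'
#' Per-well firefly/renilla ratio; with a `condition` grouping, also the
#' per-condition mean ratio.
#'
#' @param fluc Firefly luminescence (>= 0), vectorized.
#' @param rluc Renilla luminescence (> 0), vectorized.
#' @param condition Optional condition labels per well.
#' @return Without `condition`: numeric vector of per-well ratios. With it:
#'   a list with `wells` (tibble of per-well ratios) and `condition_means`.
#' @export
luciferase_ratio <- function(fluc, rluc, condition = NULL) {
  if (any(rluc <= 0)) stop("RLuc must be > 0", call. = FALSE)
  if (any(fluc < 0)) stop("FLuc must be >= 0", call. = FALSE)
  ratio <- fluc / rluc
  if (is.null(condition)) return(ratio)
  wells <- tibble::tibble(condition = condition, fluc = fluc, rluc = rluc,
                          ratio = ratio)
  means <- vapply(split(ratio, condition), mean, numeric(1))
  list(wells = wells,
       condition_means = tibble::tibble(condition = names(means),
                                        mean_ratio = unname(means)))
}

#' Construct performance ratios
#'
#' Per-gene ratio of the mean editing efficiency of the U7smOPT snRNA
#' construct to that of the cadRNA construct.
#'
#' @param table Tibble with `gene`, `mean_edit_u7`, `mean_edit_cad`.
#' @return Named numeric vector of ratios (names are genes).
#' @export
performance_ratio <- function(table) {
  stopifnot(all(c("gene", "mean_edit_u7", "mean_edit_cad") %in% names(table)))
  zero <- which(table$mean_edit_cad <= 0)
  if (length(zero))
    stop("zero cadRNA mean editing for gene(s): ",
         paste(table$gene[zero], collapse = ", "), call. = FALSE)
  stats::setNames(table$mean_edit_u7 / table$mean_edit_cad, table$gene)
}

#' Pearson correlation with a two-sided p value
#'
#' Sample Pearson r with the textbook t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-sided. Perfectly colinear data give `r = +/-1` and `p = 0`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return A list with `r`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need n >= 3 for a correlation test", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}
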