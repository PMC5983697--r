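#' Define a two-group perturbation contrast
#'
#' @param label Free-text label, conventionally `"overexpression"` or
#'   `"knockdown"`.
#' @param treatment_samples,control_samples Non-empty, disjoint sets of
#'   sample ids.
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(label, treatment_samples, control_samples) {
  if (length(treatment_samples) == 0 || length(control_samples) == 0)
    stop("treatment and control sample sets must be non-empty")
  if (length(intersect(treatment_samples, control_samples)) > 0)
    stop("treatment and control sample sets must be disjoint")
  structure(list(label = label,
                 treatment_samples = as.character(treatment_samples),
                 control_samples = as.character(control_samples)),
            class = "contrast_spec")
}

#' Per-gene expression ratio for a perturbation contrast
#'
#' The ratio estimator is `(mean(treatment) + eps) / (mean(control) + eps)`
#' on the linear scale, with an additive pseudocount `eps` so ratios are
#' always positive and finite even for silent genes. Matrices on the
#' log2(x + 1) scale are back-transformed first.
#'
#' @param matrix An [expr_matrix].
#' @param contrast A [contrast_spec()]; every sample id must be a column of
#'   `matrix`.
#' @param pseudocount Positive additive constant `eps` (default 1).
#' @return Data.frame `gene_id`, `ratio` (treatment/control), `log2_ratio`.
#' @export
compute_ratio <- function(matrix, contrast, pseudocount = 1) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(contrast, "contrast_spec"))
  if (pseudocount <= 0) stop("'pseudocount' must be positive")
  v <- as_linear(matrix)$values
  missing <- setdiff(c(contrast$treatment_samples, contrast$control_samples),
                     colnames(v))
  if (length(missing))
    stop("contrast samples missing from the matrix: ",
         paste(missing, collapse = ", "))
  trt <- rowMeans(v[, contrast$treatment_samples, drop = FALSE])
  ctl <- rowMeans(v[, contrast$control_samples, drop = FALSE])
  ratio <- (trt + pseudocount) / (ctl + pseudocount)
  data.frame(gene_id = rownames(v), ratio = ratio,
             log2_ratio = log2(ratio), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Concordance between an overexpression and a knockdown contrast
#'
#' For a gene positively regulated by the factor, overexpression raises and
#' knockdown lowers its expression, so the knockdown axis is sign-flipped:
#' each shared gene contributes the point
#' `(log2(OE/Ctr), -log2(KD/Ctr))` and concordant regulation scores
#' positive on both axes. Pearson correlation of those points is the
#' concordance summary.
#'
#' @param oe,kd Contrast results from [compute_ratio()].
#' @param flip_kd Flip the knockdown axis (default TRUE). The unflipped
#'   mode is a diagnostic only.
#' @return List with `points` (data.frame `gene_id`, `oe_log2`, `kd_log2`),
#'   `r` (NA when either axis has zero variance), and `n`.
#' @export
cross_contrast_concordance <- function(oe, kd, flip_kd = TRUE) {
  shared <- intersect(oe$gene_id, kd$gene_id)
  if (length(shared) < 3)
    stop("need >= 3 shared genes with defined ratios, got ", length(shared))
  x <- oe$log2_ratio[match(shared, oe$gene_id)]
  y <- kd$log2_ratio[match(shared, kd$gene_id)]
  if (flip_kd) y <- -y
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y, method = "pearson")
  list(points = data.frame(gene_id = shared, oe_log2 = x, kd_log2 = y,
                           stringsAsFactors = FALSE),
       r = r, n = length(shared))
}

#' Cohort-wide correlation of every gene with the regulator
#'
#' Pearson (default) correlation of each gene with the regulator across all
#' cohort samples, computed on the log2(x + 1) scale (linear matrices are
#' transformed; log2p1 matrices are used as stored). Genes with zero
#' variance get an explicit `NA` marker, never a zero, so they can be
#' excluded from threshold rules downstream.
#'
#' @param matrix An [expr_matrix] with at least 3 samples.
#' @param regulator_gene Gene id of the regulator; must be a row of the
#'   matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data.frame `gene_id`, `r`, `n_samples`.
#' @export
regulator_correlation <- function(matrix, regulator_gene,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- as_log2p1(matrix)$values
  if (!regulator_gene %in% rownames(v))
    stop("regulator gene '", regulator_gene, "' not in the matrix")
  if (ncol(v) < 3) stop("need >= 3 samples")
  reg <- v[regulator_gene, ]
  if (stats::sd(reg) == 0) stop("regulator has zero variance across the cohort")
  sds <- apply(v, 1, stats::sd)
  r <- rep(NA_real_, nrow(v))
  ok <- sds > 0
  r[ok] <- suppressWarnings(
    as.vector(stats::cor(t(v[ok, , drop = FALSE]), reg, method = method)))
  data.frame(gene_id = rownames(v), r = r, n_samples = ncol(v),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Standard qPCR relative quantification: the target gene's cycle threshold
#' (Ct) is normalized to a reference gene within each condition, and the
#' treated condition is compared to the control:
#' `ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)`; the fold change is `2^-ddCt`.
#'
#' @param ct_target_treated,ct_reference_treated Ct cycles in the treated
#'   condition.
#' @param ct_target_control,ct_reference_control Ct cycles in the control
#'   condition.
#' @return Positive fold change (vectorized over its arguments).
#' @examples
#' ddct_fold_change(25, 20, 26, 20)  # 2.0
#' @export
ddct_fold_change <- function(ct_target_treated, ct_reference_treated,
                             ct_target_control, ct_reference_control) {
  args <- cbind(ct_target_treated, ct_reference_treated,
                ct_target_control, ct_reference_control)
  if (!all(is.finite(args))) stop("all Ct values must be finite")
  ddct <- (ct_target_treated - ct_reference_treated) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}
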