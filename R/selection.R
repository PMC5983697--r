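#' Thresholds for the disjunctive candidate-selection rule
#'
#' A gene is a candidate target when it shows either a consistent
#' perturbation response (up under regulator overexpression AND down under
#' knockdown) or a high absolute cohort correlation with the regulator.
#' Promoter occupancy can be required as an additional gate, but is off by
#' default because long-range (>100 kb) candidates are legitimate.
#'
#' @param oe_up_min Minimum overexpression/control ratio to call a gene up
#'   (> 1; default 1.5).
#' @param kd_down_max Maximum knockdown/control ratio to call a gene down
#'   (in (0,1); default 0.75).
#' @param abs_r_min Minimum absolute cohort correlation (default 0.20).
#'   Negative correlations qualify by absolute value.
#' @param promoter_window Promoter half-width in bp (default 2000).
#' @param require_promoter Require promoter occupancy for selection
#'   (default FALSE).
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(oe_up_min = 1.5, kd_down_max = 0.75,
                             abs_r_min = 0.20, promoter_window = 2000L,
                             require_promoter = FALSE) {
  if (oe_up_min <= 1) stop("'oe_up_min' must exceed 1")
  if (kd_down_max <= 0 || kd_down_max >= 1) stop("'kd_down_max' must be in (0, 1)")
  if (abs_r_min < 0 || abs_r_min > 1) stop("'abs_r_min' must be in [0, 1]")
  if (promoter_window <= 0) stop("'promoter_window' must be positive")
  structure(list(oe_up_min = oe_up_min, kd_down_max = kd_down_max,
                 abs_r_min = abs_r_min, promoter_window = promoter_window,
                 require_promoter = isTRUE(require_promoter)),
            class = "selection_params")
}

#' Classify a gene's perturbation response direction
#'
#' @param oe_ratio,kd_ratio Positive expression ratios
#'   (overexpression/control, knockdown/control), vectorized.
#' @param params A [selection_params()] object.
#' @return Character vector: `"positive_target"` (up on overexpression,
#'   down on knockdown), `"negative_target"` (the mirror image),
#'   `"unchanged"` (both ratios inside the no-change band around 1), else
#'   `"inconsistent"`.
#' @export
classify_direction <- function(oe_ratio, kd_ratio, params = selection_params()) {
  stopifnot(inherits(params, "selection_params"))
  if (any(!is.finite(oe_ratio)) || any(!is.finite(kd_ratio)) ||
      any(oe_ratio <= 0) || any(kd_ratio <= 0))
    stop("ratios must be positive and finite")
  up <- params$oe_up_min; dn <- params$kd_down_max
  ifelse(oe_ratio >= up & kd_ratio <= dn, "positive_target",
    ifelse(oe_ratio <= 1 / up & kd_ratio >= 1 / dn, "negative_target",
      ifelse(oe_ratio > dn & oe_ratio < up & kd_ratio > dn & kd_ratio < up,
             "unchanged", "inconsistent")))
}

#' Select candidate target genes by the disjunctive rule
#'
#' Integrates promoter occupancy, the two perturbation contrasts and the
#' cohort correlation into a ranked candidate table. A gene is selected iff
#' (`consistent_change` OR `high_correlation`) and, only when
#' `require_promoter` is set, `promoter_bound`:
#' * `consistent_change`: `oe_ratio >= oe_up_min` and
#'   `kd_ratio <= kd_down_max`;
#' * `high_correlation`: `|cohort_r| >= abs_r_min` (undefined correlations
#'   never qualify).
#'
#' Only genes present in all expression inputs are considered; the number
#' excluded is reported. The rank score
#' `|log2(oe)| + |log2(kd)| + |r|` is a display convenience that orders
#' records without ever changing membership.
#'
#' @param occupancy Per-gene occupancy table from [promoter_occupancy()].
#'   Genes absent from it are treated as unbound with no distance.
#' @param oe,kd Contrast results from [compute_ratio()].
#' @param corr Correlation table from [regulator_correlation()].
#' @param params A [selection_params()] object.
#' @return An object of class `candidate_screen`: list with `candidates`
#'   (the selected, ranked records), `all` (every evaluated gene with its
#'   flags), `params`, `n_excluded`.
#' @export
select_candidates <- function(occupancy, oe, kd, corr,
                              params = selection_params()) {
  stopifnot(inherits(params, "selection_params"))
  shared <- Reduce(intersect, list(oe$gene_id, kd$gene_id, corr$gene_id))
  if (length(shared) == 0) stop("no gene ids shared across expression inputs")
  n_excluded <- length(unique(c(oe$gene_id, kd$gene_id, corr$gene_id))) -
    length(shared)

  df <- data.frame(gene_id = shared,
                   oe_ratio = oe$ratio[match(shared, oe$gene_id)],
                   kd_ratio = kd$ratio[match(shared, kd$gene_id)],
                   cohort_r = corr$r[match(shared, corr$gene_id)],
                   stringsAsFactors = FALSE)
  m <- match(shared, occupancy$gene_id)
  df$promoter_bound <- !is.na(m) & occupancy$bound[m]
  df$best_distance <- ifelse(is.na(m), NA_integer_, occupancy$best_distance[m])

  df$consistent_change <- df$oe_ratio >= params$oe_up_min &
    df$kd_ratio <= params$kd_down_max
  df$high_correlation <- !is.na(df$cohort_r) &
    abs(df$cohort_r) >= params$abs_r_min
  df$selected <- (df$consistent_change | df$high_correlation) &
    (df$promoter_bound | !params$require_promoter)
  df$direction <- classify_direction(df$oe_ratio, df$kd_ratio, params)
  df$rank_score <- abs(log2(df$oe_ratio)) + abs(log2(df$kd_ratio)) +
    ifelse(is.na(df$cohort_r), 0, abs(df$cohort_r))

  cand <- df[df$selected, , drop = FALSE]
  cand <- cand[order(-cand$rank_score, cand$gene_id), , drop = FALSE]
  cand$selection_basis <- paste0(
    ifelse(cand$consistent_change, "consistent_change", ""),
    ifelse(cand$consistent_change & cand$high_correlation, "+", ""),
    ifelse(cand$high_correlation, "high_correlation", ""))
  cols <- c("gene_id", "best_distance", "promoter_bound", "kd_ratio",
            "oe_ratio", "cohort_r", "selection_basis", "consistent_change",
            "high_correlation", "direction", "rank_score")
  rownames(cand) <- rownames(df) <- NULL
  structure(list(candidates = cand[, cols], all = df, params = params,
                 n_excluded = n_excluded),
            class = "candidate_screen")
}

#' @export
print.candidate_screen <- function(x, ...) {
  cat(sprintf("candidate_screen: %d of %d genes selected (%d excluded for missing data)\n",
              nrow(x$candidates), nrow(x$all), x$n_excluded))
  cat(sprintf("  thresholds: OE/Ctr >= %.3g & KD/Ctr <= %.3g, or |r| >= %.3g%s\n",
              x$params$oe_up_min, x$params$kd_down_max, x$params$abs_r_min,
              if (x$params$require_promoter) "; promoter occupancy required" else ""))
  if (nrow(x$candidates))
    print(utils::head(x$candidates, 10), row.names = FALSE)
  invisible(x)
}

#' @export
summary.candidate_screen <- function(object, ...) {
  cand <- object$candidates
  out <- list(n_evaluated = nrow(object$all), n_selected = nrow(cand),
              n_consistent_change = sum(cand$consistent_change),
              n_high_correlation = sum(cand$high_correlation),
              n_both = sum(cand$consistent_change & cand$high_correlation),
              n_promoter_bound = sum(cand$promoter_bound),
              params = object$params)
  class(out) <- "summary.candidate_screen"
  out
}

#' @export
print.summary.candidate_screen <- function(x, ...) {
  cat(sprintf("%d/%d genes selected: %d consistent change, %d high correlation, %d both; %d promoter-bound\n",
              x$n_selected, x$n_evaluated, x$n_consistent_change,
              x$n_high_correlation, x$n_both, x$n_promoter_bound))
  invisible(x)
}

#' @export
plot.candidate_screen <- function(x, ...) {
  df <- x$all
  graphics::plot(log2(df$oe_ratio), -log2(df$kd_ratio),
                 col = ifelse(df$selected, "firebrick", "grey60"),
                 pch = ifelse(df$promoter_bound, 19, 1),
                 xlab = "log2(OE/Ctr)", ylab = "-log2(KD/Ctr)", ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  invisible(x)
}

#' @export
as.data.frame.candidate_screen <- function(x, ...) x$candidates

#' Write a candidate table as TSV
#'
#' Columns mirror the candidate record: gene, signed distance to the TSS,
#' KD/Ctr and OE/Ctr ratios, cohort correlation, selection basis, and the
#' rank score; ordering is deterministic (rank score descending, gene id on
#' ties). An empty selection yields a header-only file.
#'
#' @param x A `candidate_screen` (or its `candidates` data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(x, path) {
  df <- if (inherits(x, "candidate_screen")) x$candidates else x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a candidate table written by [write_candidate_table()]
#'
#' @param path TSV path.
#' @return The candidate data.frame.
#' @export
read_candidate_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
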