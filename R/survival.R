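#' Split a cohort at the median expression of one gene
#'
#' Median bifurcation for expression-versus-survival analysis: samples with
#' expression at or below the median form the low group, the rest the high
#' group. The median of an even number of samples is the mean of the two
#' central values, so ties at the split always go to the low group.
#'
#' @param expression_values Named numeric vector (names are sample ids).
#' @param clinical Clinical data.frame from [read_clinical()].
#' @return An object of class `grouped_survival`: list with `low` and
#'   `high` (data.frames `sample_id`, `time`, `event`), `split_value`, and
#'   `n_dropped` (samples present in only one input).
#' @export
median_split <- function(expression_values, clinical) {
  shared <- intersect(names(expression_values), clinical$sample_id)
  if (length(shared) < 2)
    stop("need >= 2 samples shared between expression and clinical inputs")
  n_dropped <- (length(expression_values) - length(shared)) +
    (nrow(clinical) - length(shared))
  x <- expression_values[shared]
  if (max(x) == min(x))
    stop("degenerate split: all expression values identical")
  med <- stats::median(x)
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  low <- x <= med
  grouped <- list(
    low = data.frame(sample_id = shared[low], time = cl$time[low],
                     event = cl$event[low], stringsAsFactors = FALSE),
    high = data.frame(sample_id = shared[!low], time = cl$time[!low],
                      event = cl$event[!low], stringsAsFactors = FALSE),
    split_value = med, n_dropped = n_dropped)
  if (nrow(grouped$low) == 0 || nrow(grouped$high) == 0)
    stop("degenerate split: one group is empty")
  structure(grouped, class = "grouped_survival")
}

#' @export
print.grouped_survival <- function(x, ...) {
  cat(sprintf("grouped_survival: low n=%d (%d events), high n=%d (%d events), split at %.4g\n",
              nrow(x$low), sum(x$low$event), nrow(x$high), sum(x$high$event),
              x$split_value))
  invisible(x)
}

#' Kaplan-Meier product-limit survival curve
#'
#' At each distinct event time `t` with `d` events among `n` subjects still
#' at risk, the survival estimate is updated as `S <- S * (1 - d/n)`;
#' censored subjects leave the risk set after their recorded time and
#' contribute no step. The curve starts at `S(0) = 1` and is non-increasing
#' within `[0, 1]`.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return An object of class `km_curve`: data.frame `time`, `n_risk`,
#'   `n_event`, `survival`, beginning with the `(0, 1)` anchor row.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop("need >= 1 subject")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  ev_times <- sort(unique(times[events == 1]))
  surv <- 1
  rows <- data.frame(time = 0, n_risk = length(times), n_event = 0L,
                     survival = 1)
  for (t in ev_times) {
    n_t <- sum(times >= t)
    d_t <- sum(times == t & events == 1)
    surv <- surv * (1 - d_t / n_t)
    rows <- rbind(rows, data.frame(time = t, n_risk = n_t, n_event = d_t,
                                   survival = surv))
  }
  structure(rows, class = c("km_curve", "data.frame"))
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(x$time, x$survival, type = "s", ylim = c(0, 1),
                 xlab = "time", ylab = "survival probability", ...)
  invisible(x)
}

#' Two-group log-rank test with an O/E hazard-ratio estimate
#'
#' At each distinct event time `j` pooled across the two groups, with
#' `n_j` subjects at risk (`n1j` in the low group) and `d_j` events, the
#' low group's expected events are `E1j = d_j * n1j / n_j` and the
#' hypergeometric variance is
#' `Vj = d_j * (n1j/n_j) * (1 - n1j/n_j) * (n_j - d_j) / (n_j - 1)`
#' (`Vj = 0` when `n_j = 1`). The statistic
#' `(sum(O1j - E1j))^2 / sum(Vj)` is referred to a 1-df chi-square, and the
#' hazard ratio is the observed-over-expected estimator
#' `(O1/E1) / (O2/E2)` (low versus high; `NA` when any of the four counts
#' is zero).
#'
#' @param grouped A [median_split()] result (class `grouped_survival`).
#' @return An object of class `logrank_test`: list with `statistic`,
#'   `p_value`, `observed` and `expected` (length-2, low/high),
#'   `hazard_ratio` (low vs high), `variance`, and group sizes `n`.
#'   A zero total variance yields an `NA` statistic marker.
#' @export
logrank_test <- function(grouped) {
  stopifnot(inherits(grouped, "grouped_survival"))
  t1 <- grouped$low$time;  e1 <- grouped$low$event
  t2 <- grouped$high$time; e2 <- grouped$high$event
  times <- c(t1, t2); events <- c(e1, e2)
  grp1 <- c(rep(TRUE, length(t1)), rep(FALSE, length(t2)))
  if (sum(events) == 0) stop("no events in either group")

  ev_times <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    n1j <- sum(at_risk & grp1)
    d_j <- sum(times == t & events == 1)
    O1 <- O1 + sum(times == t & events == 1 & grp1)
    E1 <- E1 + d_j * n1j / n_j
    if (n_j > 1)
      V <- V + d_j * (n1j / n_j) * (1 - n1j / n_j) * (n_j - d_j) / (n_j - 1)
  }
  O <- sum(events); O2 <- O - O1; E2 <- O - E1
  statistic <- if (V > 0) (O1 - E1)^2 / V else NA_real_
  p_value <- if (is.na(statistic)) NA_real_ else
    stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  hr <- if (O1 > 0 && O2 > 0 && E1 > 0 && E2 > 0)
    (O1 / E1) / (O2 / E2) else NA_real_
  structure(list(statistic = statistic, p_value = p_value,
                 observed = c(low = O1, high = O2),
                 expected = c(low = E1, high = E2),
                 hazard_ratio = hr, variance = V,
                 n = c(low = length(t1), high = length(t2))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test (low vs high expression group)\n")
  cat(sprintf("  n: low %d, high %d;  events O: low %g, high %g;  E: low %.3f, high %.3f\n",
              x$n["low"], x$n["high"], x$observed["low"], x$observed["high"],
              x$expected["low"], x$expected["high"]))
  cat(sprintf("  chi-square = %.4f (1 df), p = %.4g, HR (low/high) = %s\n",
              x$statistic, x$p_value,
              if (is.na(x$hazard_ratio)) "undefined" else
                sprintf("%.3f", x$hazard_ratio)))
  invisible(x)
}

#' Median-bifurcation survival screen over many genes
#'
#' For each gene: split the cohort at its median expression
#' ([median_split()]) and compare the two groups by [logrank_test()].
#' Genes that cannot be split (constant expression, empty group) are
#' reported with an explicit skip reason rather than dropped.
#'
#' @param matrix An [expr_matrix] of the cohort.
#' @param clinical Clinical data.frame from [read_clinical()].
#' @param genes Gene ids to screen; all must be rows of `matrix`.
#' @return Data.frame `gene_id`, `n_low`, `n_high`, `statistic`, `p_value`,
#'   `hazard_ratio`, `skipped`, `skip_reason`.
#' @export
survival_screen <- function(matrix, clinical, genes) {
  stopifnot(inherits(matrix, "expr_matrix"))
  missing <- setdiff(genes, rownames(matrix$values))
  if (length(missing))
    stop("genes not in the matrix: ", paste(missing, collapse = ", "))
  rows <- lapply(genes, function(g) {
    res <- tryCatch({
      grp <- median_split(matrix$values[g, ], clinical)
      lr <- logrank_test(grp)
      data.frame(gene_id = g, n_low = nrow(grp$low), n_high = nrow(grp$high),
                 statistic = lr$statistic, p_value = lr$p_value,
                 hazard_ratio = lr$hazard_ratio, skipped = FALSE,
                 skip_reason = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(gene_id = g, n_low = NA_integer_, n_high = NA_integer_,
                 statistic = NA_real_, p_value = NA_real_,
                 hazard_ratio = NA_real_, skipped = TRUE,
                 skip_reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Side-by-side Kaplan-Meier curves for a median split
#'
#' Convenience table for plotting: the low- and high-group product-limit
#' curves of a [median_split()] result.
#'
#' @param grouped A `grouped_survival` object.
#' @return Data.frame `group`, `time`, `n_risk`, `n_event`, `survival`.
#' @export
km_by_group <- function(grouped) {
  stopifnot(inherits(grouped, "grouped_survival"))
  lo <- km_curve(grouped$low$time, grouped$low$event)
  hi <- km_curve(grouped$high$time, grouped$high$event)
  rbind(data.frame(group = "low", as.data.frame(lo)),
        data.frame(group = "high", as.data.frame(hi)))
}
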