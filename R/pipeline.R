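#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or an equivalent nested list, checks every
#' field, and reports all problems together (not fail-fast) so a config can
#' be fixed in one pass. Unknown keys draw a warning, not an error, to keep
#' configs forward-compatible.
#'
#' @param config Path to a YAML or JSON file, or a list with elements:
#'   `inputs` (paths `genes`, `peaks` (one or more), `expr_oe`, `expr_kd`,
#'   `cohort`, optional `clinical`, plus optional `*_format` / `*_scale`
#'   overrides), `regulator` (gene id), `contrasts`
#'   (`oe`/`kd`, each with `treatment` and `control` sample-id vectors),
#'   and optional `selection`, `peak_options`, `survival`, `seed`.
#' @return The validated config (class `pipeline_config`), invisibly
#'   usable by [run_all()]. Throws one error listing every problem found.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config)) jsonlite::fromJSON(config)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  known <- c("inputs", "regulator", "contrasts", "selection",
             "peak_options", "survival", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))

  ins <- config$inputs
  if (is.null(ins)) note("missing 'inputs' section")
  for (f in c("genes", "expr_oe", "expr_kd", "cohort")) {
    if (is.null(ins[[f]])) note(paste0("missing input path 'inputs$", f, "'"))
    else if (!all(file.exists(ins[[f]])))
      note(paste0("input file not found: ", ins[[f]][!file.exists(ins[[f]])][1]))
  }
  if (is.null(ins$peaks)) note("missing input path(s) 'inputs$peaks'")
  else if (!all(file.exists(ins$peaks)))
    note(paste0("peak file not found: ", ins$peaks[!file.exists(ins$peaks)][1]))
  if (!is.null(ins$clinical) && !file.exists(ins$clinical))
    note(paste0("clinical file not found: ", ins$clinical))

  if (is.null(config$regulator) || !nzchar(config$regulator[1]))
    note("missing 'regulator' gene id")
  for (cn in c("oe", "kd")) {
    cc <- config$contrasts[[cn]]
    if (is.null(cc) || is.null(cc$treatment) || is.null(cc$control))
      note(paste0("contrast '", cn, "' needs 'treatment' and 'control' sample ids"))
    else if (length(intersect(cc$treatment, cc$control)))
      note(paste0("contrast '", cn, "' treatment and control overlap"))
  }
  sel <- tryCatch(do.call(selection_params, as.list(config$selection)),
                  error = function(e) {
                    note(paste0("selection: ", conditionMessage(e))); NULL
                  })
  po <- config$peak_options
  if (!is.null(po$reference_point) &&
      !po$reference_point %in% c("midpoint", "summit", "nearest_edge"))
    note("peak_options$reference_point must be midpoint, summit or nearest_edge")
  if (!is.null(po$sign_convention) &&
      !po$sign_convention %in% c("upstream_negative", "upstream_positive"))
    note("peak_options$sign_convention must be upstream_negative or upstream_positive")
  if (!is.null(po$pool_mode) &&
      !po$pool_mode %in% c("union_merge", "intersection"))
    note("peak_options$pool_mode must be union_merge or intersection")
  if (!is.null(po$merge_gap) && po$merge_gap < 0)
    note("peak_options$merge_gap must be >= 0")

  if (length(errors))
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "))

  config$selection_params <- sel
  config$peak_options <- utils::modifyList(
    list(reference_point = "midpoint", sign_convention = "upstream_negative",
         pool_mode = "union_merge", merge_gap = 0L,
         histogram_bin = 500L, histogram_max = 10000L), as.list(po))
  config$survival <- utils::modifyList(list(alpha = 0.05),
                                       as.list(config$survival))
  if (is.null(config$seed)) config$seed <- 1L
  class(config) <- "pipeline_config"
  invisible(config)
}

.stage <- function(name, log, expr) {
  log(sprintf("stage %s: start", name))
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full target-screening pipeline
#'
#' Executes peak pooling, nearest-TSS assignment, the distance histogram
#' and promoter statistics, both perturbation contrasts, the cohort
#' correlation screen, candidate selection, and (when a clinical table is
#' configured) a survival screen over the selected candidates. Every stage
#' logs its input/output row counts to the console and to `run.log` in the
#' output directory; all stage outputs are written as TSV and the summary
#' as `report.json`. The report carries no timestamps, so one config and
#' seed reproduce it byte for byte.
#'
#' @param config A config accepted by [validate_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results, the
#'   `report` list, and `files` (named output paths).
#' @export
run_all <- function(config, outdir) {
  config <- validate_config(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  echo_cfg <- unclass(config)
  echo_cfg$selection_params <- unclass(echo_cfg$selection_params)
  log(paste0("resolved config: ",
             jsonlite::toJSON(echo_cfg, auto_unbox = TRUE)))
  ins <- config$inputs
  po <- config$peak_options

  genes <- .stage("read_annotation", log,
                  read_gene_models(ins$genes,
                                   format = ins$genes_format %||% "gtf"))
  log(sprintf("stage read_annotation: %d genes", nrow(genes)))

  peak_paths <- ins$peaks
  labels <- ins$peak_labels %||% basename(peak_paths)
  peak_sets <- .stage("read_peaks", log, lapply(seq_along(peak_paths), function(i)
    read_peaks(peak_paths[i], format = ins$peaks_format %||% "narrowPeak",
               source_label = labels[i])))
  log(sprintf("stage read_peaks: %d set(s), %d peaks",
              length(peak_sets), sum(vapply(peak_sets, nrow, integer(1)))))

  loci <- .stage("pool_peaks", log,
                 pool_peaks(peak_sets, mode = po$pool_mode,
                            merge_gap = po$merge_gap))
  log(sprintf("stage pool_peaks: %d loci", nrow(loci)))

  assignments <- .stage("assign_nearest_tss", log,
                        assign_nearest_tss(loci, genes,
                                           reference_point = po$reference_point,
                                           sign_convention = po$sign_convention))
  hist <- distance_histogram(assignments, bin_width = po$histogram_bin,
                             max_bp = po$histogram_max)
  window <- config$selection_params$promoter_window
  pf <- promoter_fraction(assignments, window = window)
  occupancy <- promoter_occupancy(assignments, window = window, genes = genes)
  log(sprintf("stage assign_nearest_tss: %d assigned, %d unassigned, promoter fraction %.4f",
              pf$n_assigned, pf$n_unassigned, pf$fraction))

  oe_mat <- .stage("contrasts", log,
                   read_expression(ins$expr_oe, scale = ins$expr_oe_scale %||% "linear"))
  kd_mat <- read_expression(ins$expr_kd, scale = ins$expr_kd_scale %||% "linear")
  oe <- compute_ratio(oe_mat, contrast_spec("overexpression",
                                            config$contrasts$oe$treatment,
                                            config$contrasts$oe$control))
  kd <- compute_ratio(kd_mat, contrast_spec("knockdown",
                                            config$contrasts$kd$treatment,
                                            config$contrasts$kd$control))
  conc <- cross_contrast_concordance(oe, kd)
  log(sprintf("stage contrasts: %d genes, concordance r = %.4f", conc$n, conc$r))

  cohort <- .stage("correlate", log,
                   read_expression(ins$cohort, scale = ins$cohort_scale %||% "log2p1"))
  corr <- regulator_correlation(cohort, config$regulator)
  log(sprintf("stage correlate: %d genes x %d samples",
              nrow(corr), corr$n_samples[1]))

  screen <- .stage("select", log,
                   select_candidates(occupancy, oe, kd, corr,
                                     config$selection_params))
  ssum <- summary(screen)
  log(sprintf("stage select: %d candidates (%d consistent change, %d high correlation)",
              ssum$n_selected, ssum$n_consistent_change, ssum$n_high_correlation))

  surv <- NULL
  if (!is.null(ins$clinical) && nrow(screen$candidates) > 0) {
    clinical <- read_clinical(ins$clinical)
    surv_genes <- intersect(screen$candidates$gene_id, rownames(cohort$values))
    surv <- .stage("survival", log,
                   survival_screen(cohort, clinical, surv_genes))
    log(sprintf("stage survival: %d genes screened, %d significant at alpha = %g",
                nrow(surv), sum(!surv$skipped & surv$p_value <= config$survival$alpha),
                config$survival$alpha))
  }

  files <- c(assignments = file.path(outdir, "assignments.tsv"),
             histogram = file.path(outdir, "histogram.tsv"),
             occupancy = file.path(outdir, "occupancy.tsv"),
             contrast_oe = file.path(outdir, "contrast_oe.tsv"),
             contrast_kd = file.path(outdir, "contrast_kd.tsv"),
             correlation = file.path(outdir, "correlation.tsv"),
             concordance = file.path(outdir, "concordance.tsv"),
             candidates = file.path(outdir, "candidates.tsv"),
             report = file.path(outdir, "report.json"))
  wt <- function(df, path) utils::write.table(df, path, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
  wt(assignments, files["assignments"])
  wt(hist$bins, files["histogram"])
  wt(occupancy, files["occupancy"])
  wt(oe, files["contrast_oe"])
  wt(kd, files["contrast_kd"])
  wt(corr, files["correlation"])
  wt(conc$points, files["concordance"])
  write_candidate_table(screen, files["candidates"])
  if (!is.null(surv)) {
    files["survival"] <- file.path(outdir, "survival.tsv")
    wt(surv, files["survival"])
  }

  report <- list(
    seed = config$seed,
    n_genes = nrow(genes),
    n_loci = nrow(loci),
    promoter_window_bp = window,
    promoter_fraction = pf$fraction,
    n_unassigned = pf$n_unassigned,
    histogram = list(upstream = hist$upstream, downstream = hist$downstream,
                     out_of_range = hist$out_of_range),
    concordance_r = conc$r,
    candidates = list(n_selected = ssum$n_selected,
                      n_consistent_change = ssum$n_consistent_change,
                      n_high_correlation = ssum$n_high_correlation,
                      n_both = ssum$n_both,
                      n_promoter_bound = ssum$n_promoter_bound),
    thresholds = unclass(config$selection_params),
    survival = if (!is.null(surv)) list(
      n_screened = nrow(surv),
      n_significant = sum(!surv$skipped &
                            surv$p_value <= config$survival$alpha),
      alpha = config$survival$alpha) else NULL)
  jsonlite::write_json(report, files["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  log("pipeline complete")
  invisible(list(genes = genes, loci = loci, assignments = assignments,
                 histogram = hist, occupancy = occupancy, oe = oe, kd = kd,
                 concordance = conc, correlation = corr, screen = screen,
                 survival = surv, report = report, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
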