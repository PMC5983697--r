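#' Configuration for the synthetic-data generator
#'
#' The defaults are the generator's study conditions: roughly 3000 pooled
#' loci of which about two thirds are promoter-proximal, perturbation folds
#' near 2x (overexpression) and 0.5x (knockdown), cohort correlations near
#' 0.5 in magnitude, and a planted low-expression hazard ratio near 0.4 —
#' the scales at which an integrative regulator-target screen operates.
#'
#' @param seed Master seed. Every output draws from its own labeled
#'   substream derived from this seed (see Details), so adding one
#'   generator never perturbs another's output.
#' @param n_genes,n_chromosomes,chrom_length_bp Annotation geometry.
#' @param target_fraction Fraction of genes that are true targets.
#' @param n_peaks Number of simulated ChIP loci.
#' @param promoter_peak_weight Probability `w` that a peak is planted at a
#'   true-target TSS (offset drawn from a zero-mean normal with
#'   `promoter_offset_sd`, truncated to +/-2000 bp, so `w` is exactly the
#'   expected promoter fraction at a 2-kb window); the rest are uniform
#'   background at least 10 kb from every TSS.
#' @param promoter_offset_sd SD (bp) of the planted TSS offset.
#' @param oe_fold,kd_fold Planted expression folds for positively regulated
#'   targets in the overexpression and knockdown treatments (inverted for
#'   negatively regulated targets).
#' @param n_perturb_replicates Replicates per arm of each contrast.
#' @param cohort_n Cohort size for the correlation screen.
#' @param target_correlation Planted population correlation (magnitude)
#'   between each true target and the regulator, signed by the target's
#'   regulation sign.
#' @param expression_noise_sd Replicate / residual noise SD in log2 units.
#' @param survival_n Sample size for a standalone survival simulation
#'   (used when no cohort matrix is supplied to [simulate_survival()]).
#' @param true_hr_low_expression Planted hazard ratio of the low-expression
#'   group relative to the high-expression group for the reporter gene.
#' @param censoring_rate Expected fraction of censored records
#'   (independent exponential censoring, tuned per group).
#' @param positive_regulation_fraction Fraction of true targets that are
#'   positively regulated.
#' @param baseline_hazard Event hazard (per day) of the high-expression
#'   group.
#' @details Substream seeds are derived from the master seed by hashing a
#'   stream label ("annotation", "targets", "peaks", "contrasts", "cohort",
#'   "survival") into `[0, 2^31)` with a 31-multiplier polynomial hash.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 2000L, n_chromosomes = 4L,
                       chrom_length_bp = 10000000L, target_fraction = 0.05,
                       n_peaks = 3086L, promoter_peak_weight = 0.665,
                       promoter_offset_sd = 600, oe_fold = 2.0,
                       kd_fold = 0.5, n_perturb_replicates = 3L,
                       cohort_n = 100L, target_correlation = 0.5,
                       expression_noise_sd = 0.5, survival_n = 200L,
                       true_hr_low_expression = 0.4, censoring_rate = 0.3,
                       positive_regulation_fraction = 0.8,
                       baseline_hazard = 0.001) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              target_fraction = as.numeric(target_fraction),
              n_peaks = as.integer(n_peaks),
              promoter_peak_weight = as.numeric(promoter_peak_weight),
              promoter_offset_sd = as.numeric(promoter_offset_sd),
              oe_fold = as.numeric(oe_fold), kd_fold = as.numeric(kd_fold),
              n_perturb_replicates = as.integer(n_perturb_replicates),
              cohort_n = as.integer(cohort_n),
              target_correlation = as.numeric(target_correlation),
              expression_noise_sd = as.numeric(expression_noise_sd),
              survival_n = as.integer(survival_n),
              true_hr_low_expression = as.numeric(true_hr_low_expression),
              censoring_rate = as.numeric(censoring_rate),
              positive_regulation_fraction =
                as.numeric(positive_regulation_fraction),
              baseline_hazard = as.numeric(baseline_hazard))
  counts <- c("n_genes", "n_chromosomes", "chrom_length_bp", "n_peaks",
              "n_perturb_replicates", "cohort_n", "survival_n")
  for (f in counts) if (cfg[[f]] <= 0) stop("'", f, "' must be positive")
  fracs <- c("target_fraction", "promoter_peak_weight", "censoring_rate",
             "positive_regulation_fraction")
  for (f in fracs) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop("'", f, "' must be in [0, 1]")
  if (cfg$oe_fold <= 0 || cfg$kd_fold <= 0) stop("folds must be positive")
  if (cfg$true_hr_low_expression <= 0) stop("'true_hr_low_expression' must be positive")
  if (abs(cfg$target_correlation) > 1) stop("'target_correlation' must be in [-1, 1]")
  if (cfg$expression_noise_sd < 0) stop("'expression_noise_sd' must be >= 0")
  structure(cfg, class = "sim_config")
}

# edge margin (bp) kept free of TSSs at both chromosome ends
.TSS_MARGIN <- 100000L

.stream_seed <- function(seed, label) {
  s <- as.double(seed %% 2147483647L)
  for (b in utf8ToInt(label)) s <- (s * 31 + b) %% 2147483647
  as.integer(s)
}

.set_stream <- function(config, label) {
  set.seed(.stream_seed(config$seed, label))
}

#' Simulate a gene annotation
#'
#' Genes are placed on `n_chromosomes` chromosomes with collision-free TSS
#' positions drawn uniformly (keeping a margin clear of the chromosome
#' ends), strands Bernoulli(0.5), and lengths uniform in 1-50 kb.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A gene-model data.frame (see [read_gene_models()]).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .set_stream(config, "annotation")
  avail <- config$chrom_length_bp - 2L * .TSS_MARGIN
  if (avail <= 0)
    stop("chromosome too short for TSS placement margins")
  chrom <- sprintf("chr%d", sample.int(config$n_chromosomes,
                                       config$n_genes, replace = TRUE))
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  tss <- integer(config$n_genes)
  for (ch in sort(unique(chrom))) {
    idx <- which(chrom == ch)
    if (length(idx) > avail / 50)
      stop("genes too dense to place on ", ch)
    tss[idx] <- sample.int(avail, length(idx), replace = FALSE) +
      .TSS_MARGIN - 1L
  }
  len <- sample(1000:50000, config$n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss,
                  pmax(tss + 1L - len, 0L))
  end <- ifelse(strand == "+",
                pmin(tss + len, config$chrom_length_bp), tss + 1L)
  df <- data.frame(gene_id = sprintf("g%05d", seq_len(config$n_genes)),
                   symbol = sprintf("G%05d", seq_len(config$n_genes)),
                   chrom = chrom, strand = strand,
                   start = as.integer(start), end = as.integer(end),
                   tss = as.integer(tss), stringsAsFactors = FALSE)
  df
}

#' Plant the ground truth: targets, signs, effects
#'
#' Chooses the true-target set (`ceiling(target_fraction * n_genes)`
#' genes), assigns each a regulation sign, and derives the planted
#' perturbation effects and cohort correlation per gene. The regulator is
#' the first non-target gene; the survival reporter is the first
#' positively regulated target.
#'
#' @param config A [sim_config()].
#' @param genes Annotation from [simulate_annotation()].
#' @return A truth manifest: list with `config`, `regulator_gene`,
#'   `reporter_gene`, and a per-gene data.frame `genes`.
#' @export
simulate_truth <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  .set_stream(config, "targets")
  n_targets <- ceiling(config$target_fraction * config$n_genes)
  target_ids <- sort(sample(genes$gene_id, n_targets))
  is_target <- genes$gene_id %in% target_ids
  sign <- rep(NA_character_, nrow(genes))
  sign[is_target] <- ifelse(
    stats::runif(n_targets) < config$positive_regulation_fraction, "+", "-")
  oe_eff <- ifelse(is_target,
                   ifelse(sign == "+", config$oe_fold, 1 / config$oe_fold),
                   1)
  kd_eff <- ifelse(is_target,
                   ifelse(sign == "+", config$kd_fold, 1 / config$kd_fold),
                   1)
  rho <- ifelse(is_target,
                ifelse(sign == "+", config$target_correlation,
                       -config$target_correlation), 0)
  gtab <- data.frame(gene_id = genes$gene_id, is_true_target = is_target,
                     regulation_sign = sign,
                     planted_peak_distance = NA_integer_,
                     planted_oe_effect = oe_eff, planted_kd_effect = kd_eff,
                     planted_correlation = rho, stringsAsFactors = FALSE)
  regulator <- genes$gene_id[!is_target][1]
  reporter <- gtab$gene_id[is_target & sign == "+"][1]
  if (is.na(reporter)) reporter <- target_ids[1]
  list(config = unclass(config), regulator_gene = regulator,
       reporter_gene = reporter, genes = gtab)
}

#' Simulate ChIP-seq peaks with planted promoter enrichment
#'
#' Each of `n_peaks` loci is promoter-proximal with probability
#' `promoter_peak_weight`: centered on a uniformly chosen true-target TSS
#' plus a signed normal offset (sd `promoter_offset_sd`) truncated to
#' +/-2000 bp. The remainder are uniform background at least 10 kb from
#' every TSS, so the planted weight is exactly the expected 2-kb promoter
#' fraction.
#'
#' @param config A [sim_config()].
#' @param genes Annotation from [simulate_annotation()].
#' @param manifest Truth manifest from [simulate_truth()]; the minimal
#'   absolute planted offset per target is recorded in it.
#' @return List with `peaks` (a peak data.frame) and the updated
#'   `manifest`.
#' @export
simulate_peaks <- function(config, genes, manifest) {
  stopifnot(inherits(config, "sim_config"))
  .set_stream(config, "peaks")
  n <- config$n_peaks
  targets <- manifest$genes$gene_id[manifest$genes$is_true_target]
  if (length(targets) == 0 && config$promoter_peak_weight > 0)
    stop("no true targets to anchor promoter peaks (weight > 0)")
  is_prom <- stats::runif(n) < config$promoter_peak_weight

  tss_of <- stats::setNames(genes$tss, genes$gene_id)
  chrom_of <- stats::setNames(genes$chrom, genes$gene_id)

  # truncated-normal offsets by resampling
  n_prom <- sum(is_prom)
  offs <- numeric(0)
  while (length(offs) < n_prom) {
    cand <- stats::rnorm(max(n_prom, 100L), 0, config$promoter_offset_sd)
    offs <- c(offs, cand[abs(cand) <= 2000])
  }
  offs <- as.integer(round(offs[seq_len(n_prom)]))
  prom_gene <- if (n_prom) sample(targets, n_prom, replace = TRUE) else character(0)

  # background positions >= 10 kb from every TSS, uniform, by rejection
  tss_by_chrom <- split(genes$tss, genes$chrom)
  tss_by_chrom <- lapply(tss_by_chrom, sort)
  n_bg <- n - n_prom
  bg_chrom <- character(0); bg_pos <- integer(0)
  while (length(bg_pos) < n_bg) {
    m <- max(n_bg, 100L)
    ch <- sprintf("chr%d", sample.int(config$n_chromosomes, m, replace = TRUE))
    pos <- sample.int(config$chrom_length_bp - 2000L, m) + 1000L
    ok <- vapply(seq_len(m), function(i) {
      ts <- tss_by_chrom[[ch[i]]]
      if (is.null(ts)) return(TRUE)
      j <- findInterval(pos[i], ts)
      dl <- if (j >= 1) pos[i] - ts[j] else Inf
      dr <- if (j < length(ts)) ts[j + 1] - pos[i] else Inf
      min(dl, dr) >= 10000
    }, logical(1))
    bg_chrom <- c(bg_chrom, ch[ok]); bg_pos <- c(bg_pos, pos[ok])
  }
  bg_chrom <- bg_chrom[seq_len(n_bg)]; bg_pos <- bg_pos[seq_len(n_bg)]

  half <- sample(100:300, n, replace = TRUE)
  center <- integer(n); chrom <- character(n)
  center[is_prom] <- as.integer(tss_of[prom_gene] + offs)
  chrom[is_prom] <- chrom_of[prom_gene]
  center[!is_prom] <- bg_pos
  chrom[!is_prom] <- bg_chrom

  peaks <- data.frame(chrom = chrom, start = center - half,
                      end = center + half,
                      name = sprintf("peak_%05d", seq_len(n)),
                      signal = round(stats::runif(n, 5, 100), 2),
                      summit_offset = half,
                      source_label = "sim", stringsAsFactors = FALSE)
  if (any(peaks$start < 0)) peaks$start <- pmax(peaks$start, 0L)

  if (n_prom) {
    best <- tapply(offs, prom_gene, function(o) o[which.min(abs(o))])
    i <- match(names(best), manifest$genes$gene_id)
    manifest$genes$planted_peak_distance[i] <- as.integer(best)
  }
  list(peaks = peaks, manifest = manifest)
}

#' Simulate overexpression and knockdown contrast matrices
#'
#' Per-gene baseline log2 means are uniform in 3-10 with
#' normal(0, `expression_noise_sd`) replicate noise in log2. True targets
#' are shifted by `oe_fold` in the overexpression arm and `kd_fold` in the
#' knockdown arm (inverted for negatively regulated targets); the regulator
#' itself is strongly shifted (4x up / 4x down) so the perturbation is
#' visible in its own matrix; non-targets are unshifted.
#'
#' @param config A [sim_config()].
#' @param manifest Truth manifest from [simulate_truth()].
#' @return List with `oe` and `kd` ([expr_matrix], linear scale) and the
#'   matching [contrast_spec()]s `oe_contrast`, `kd_contrast`.
#' @export
simulate_contrasts <- function(config, manifest) {
  stopifnot(inherits(config, "sim_config"))
  .set_stream(config, "contrasts")
  g <- manifest$genes
  n <- nrow(g); R <- config$n_perturb_replicates
  mu <- stats::runif(n, 3, 10)
  reg <- g$gene_id == manifest$regulator_gene

  build <- function(effect, prefix, reg_fold) {
    shift <- log2(effect)
    shift[reg] <- log2(reg_fold)
    trt <- matrix(mu + shift, n, R) +
      matrix(stats::rnorm(n * R, 0, config$expression_noise_sd), n, R)
    ctl <- matrix(mu, n, R) +
      matrix(stats::rnorm(n * R, 0, config$expression_noise_sd), n, R)
    v <- signif(2^cbind(trt, ctl), 7)
    dimnames(v) <- list(g$gene_id,
                        c(sprintf("%s_trt_%d", prefix, seq_len(R)),
                          sprintf("%s_ctl_%d", prefix, seq_len(R))))
    expr_matrix(v, "linear")
  }
  oe <- build(g$planted_oe_effect, "oe", 4)
  kd <- build(g$planted_kd_effect, "kd", 0.25)
  list(oe = oe, kd = kd,
       oe_contrast = contrast_spec("overexpression",
                                   sprintf("oe_trt_%d", seq_len(R)),
                                   sprintf("oe_ctl_%d", seq_len(R))),
       kd_contrast = contrast_spec("knockdown",
                                   sprintf("kd_trt_%d", seq_len(R)),
                                   sprintf("kd_ctl_%d", seq_len(R))))
}

#' Simulate a tumor-cohort expression matrix
#'
#' The regulator's (log2) expression varies across `cohort_n` samples;
#' each true target tracks it linearly with a coefficient chosen so its
#' population correlation with the regulator equals the planted
#' `target_correlation` (signed by regulation sign); non-targets are
#' independent noise around their baselines. Values are on the
#' log2(x + 1) scale (clamped at 0).
#'
#' @param config A [sim_config()].
#' @param manifest Truth manifest from [simulate_truth()].
#' @return An [expr_matrix] (scale `log2p1`).
#' @export
simulate_cohort <- function(config, manifest) {
  stopifnot(inherits(config, "sim_config"))
  .set_stream(config, "cohort")
  g <- manifest$genes
  n <- nrow(g); m <- config$cohort_n
  s <- config$expression_noise_sd
  mu <- stats::runif(n, 3, 10)
  z <- stats::rnorm(m)  # standardized regulator signal
  v <- matrix(0, n, m, dimnames = list(g$gene_id, sprintf("pt_%04d", seq_len(m))))
  for (i in seq_len(n)) {
    rho <- g$planted_correlation[i]
    v[i, ] <- if (g$gene_id[i] == manifest$regulator_gene) {
      mu[i] + z
    } else if (abs(rho) == 1) {
      mu[i] + sign(rho) * z
    } else if (rho != 0) {
      beta <- s * rho / sqrt(1 - rho^2)
      mu[i] + beta * z + stats::rnorm(m, 0, s)
    } else {
      mu[i] + stats::rnorm(m, 0, s)
    }
  }
  expr_matrix(signif(pmax(v, 0), 7), "log2p1")
}

#' Simulate a clinical table with a planted expression-survival link
#'
#' Samples are split at the median expression of the reporter gene; the
#' low-expression group's exponential event hazard is
#' `baseline_hazard * true_hr_low_expression` (the high group keeps the
#' baseline), so the planted hazard ratio (low vs high) is
#' `true_hr_low_expression`. Censoring is independent exponential, tuned
#' per group so the expected censored fraction is `censoring_rate`. Times
#' are in days, rounded to 0.01.
#'
#' @param config A [sim_config()].
#' @param manifest Truth manifest from [simulate_truth()].
#' @param cohort Optional cohort [expr_matrix]; when supplied, the clinical
#'   table covers its samples and the split uses the reporter's cohort
#'   expression. When `NULL`, a standalone reporter-expression vector of
#'   `survival_n` samples is generated.
#' @return List with `clinical` (data.frame `sample_id`, `time`, `event`)
#'   and `reporter_expression` (named vector used for the split).
#' @export
simulate_survival <- function(config, manifest, cohort = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .set_stream(config, "survival")
  reporter <- manifest$reporter_gene
  if (is.null(cohort)) {
    n <- config$survival_n
    x <- stats::rnorm(n, 8, 1)
    names(x) <- sprintf("surv_%04d", seq_len(n))
  } else {
    stopifnot(inherits(cohort, "expr_matrix"))
    x <- cohort$values[reporter, ]
    n <- length(x)
  }
  low <- x <= stats::median(x)
  h <- ifelse(low, config$baseline_hazard * config$true_hr_low_expression,
              config$baseline_hazard)
  t_event <- stats::rexp(n, rate = h)
  if (config$censoring_rate > 0) {
    c_rate <- h * config$censoring_rate / (1 - config$censoring_rate)
    t_cens <- stats::rexp(n, rate = c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmax(round(pmin(t_event, t_cens), 2), 0.01)
  clinical <- data.frame(sample_id = names(x), time = time,
                         event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)
  list(clinical = clinical, reporter_expression = x)
}

.MANIFEST_FIELDS <- c("config", "regulator_gene", "reporter_gene", "genes")
.MANIFEST_GENE_COLS <- c("gene_id", "is_true_target", "regulation_sign",
                         "planted_peak_distance", "planted_oe_effect",
                         "planted_kd_effect", "planted_correlation")

#' Write / read the truth manifest as JSON
#'
#' The manifest JSON round trip is lossless (full-precision numbers); a
#' missing required field on read is a schema error.
#'
#' @param manifest Truth manifest from [simulate_truth()].
#' @param path JSON path.
#' @return `path` invisibly (write); the manifest (read).
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(.MANIFEST_FIELDS %in% names(manifest)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path)
  missing <- setdiff(.MANIFEST_FIELDS, names(m))
  if (length(missing))
    stop("manifest schema mismatch: missing field(s) ",
         paste(missing, collapse = ", "))
  missing_cols <- setdiff(.MANIFEST_GENE_COLS, names(m$genes))
  if (length(missing_cols))
    stop("manifest schema mismatch: missing gene column(s) ",
         paste(missing_cols, collapse = ", "))
  # restore stable types lost in JSON (ints vs doubles, NA markers)
  int_cfg <- c("seed", "n_genes", "n_chromosomes", "chrom_length_bp",
               "n_peaks", "n_perturb_replicates", "cohort_n", "survival_n")
  for (f in names(m$config))
    m$config[[f]] <- if (f %in% int_cfg) as.integer(m$config[[f]])
                     else as.numeric(m$config[[f]])
  g <- m$genes
  g$gene_id <- as.character(g$gene_id)
  g$is_true_target <- as.logical(g$is_true_target)
  g$regulation_sign <- as.character(g$regulation_sign)
  g$planted_peak_distance <- as.integer(g$planted_peak_distance)
  g$planted_oe_effect <- as.numeric(g$planted_oe_effect)
  g$planted_kd_effect <- as.numeric(g$planted_kd_effect)
  g$planted_correlation <- as.numeric(g$planted_correlation)
  m$genes <- g
  m[.MANIFEST_FIELDS]
}

#' Generate every pipeline input with planted ground truth
#'
#' Runs the full generator chain (annotation, truth, peaks, contrasts,
#' cohort, clinical) and optionally writes the standard file set:
#' `genes.gtf`, `peaks.narrowPeak`, `expr_oe.tsv`, `expr_kd.tsv`,
#' `cohort.tsv`, `clinical.tsv`, `truth.json`. One seed reproduces every
#' file byte for byte.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @return List with `genes`, `peaks`, `manifest`, `oe`, `kd`,
#'   `oe_contrast`, `kd_contrast`, `cohort`, `clinical`,
#'   `reporter_expression`, and `files` (named paths when `dir` is given).
#' @export
simulate_all <- function(config = sim_config(), dir = NULL) {
  genes <- simulate_annotation(config)
  manifest <- simulate_truth(config, genes)
  pk <- simulate_peaks(config, genes, manifest)
  manifest <- pk$manifest
  ct <- simulate_contrasts(config, manifest)
  cohort <- simulate_cohort(config, manifest)
  sv <- simulate_survival(config, manifest, cohort)
  out <- list(genes = genes, peaks = pk$peaks, manifest = manifest,
              oe = ct$oe, kd = ct$kd, oe_contrast = ct$oe_contrast,
              kd_contrast = ct$kd_contrast, cohort = cohort,
              clinical = sv$clinical,
              reporter_expression = sv$reporter_expression)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(genes = file.path(dir, "genes.gtf"),
               peaks = file.path(dir, "peaks.narrowPeak"),
               expr_oe = file.path(dir, "expr_oe.tsv"),
               expr_kd = file.path(dir, "expr_kd.tsv"),
               cohort = file.path(dir, "cohort.tsv"),
               clinical = file.path(dir, "clinical.tsv"),
               truth = file.path(dir, "truth.json"))
    write_gene_models_gtf(genes, files["genes"])
    write_peaks_narrowpeak(pk$peaks, files["peaks"])
    write_expression(ct$oe, files["expr_oe"])
    write_expression(ct$kd, files["expr_kd"])
    write_expression(cohort, files["cohort"])
    write_clinical(sv$clinical, files["clinical"])
    write_manifest(manifest, files["truth"])
    out$files <- files
  }
  out
}
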