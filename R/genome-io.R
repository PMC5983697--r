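#' @name genome_io
#' @title Readers and writers for annotation, peak, expression and clinical files
#'
#' @description
#' All genomic coordinates are held internally in the 0-based half-open
#' convention (`[start, end)`), the convention of BED/narrowPeak. GTF is
#' 1-based inclusive and is converted on read and on write, so the
#' conversion is an identity round trip. The transcription start site (TSS)
#' of a gene is its first transcribed base: `start` on the + strand and
#' `end - 1` on the - strand.
#'
#' Readers validate aggressively and report the offending line (and cell,
#' for matrices) because silent coordinate or id corruption is the classic
#' failure mode of hand-assembled genomics inputs.
NULL

.split_tsv_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

.check_int <- function(x, what, lineno) {
  ok <- grepl("^-?[0-9]+$", x)
  if (!all(ok))
    stop(sprintf("line %d: non-integer %s '%s'", lineno[!ok][1], what,
                 x[!ok][1]))
  as.integer(x)
}

#' Read gene models from a GTF or TSS BED file
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` (Ensembl dialect; only `gene` feature rows are
#'   used, each carrying a `gene_id "..."` attribute and optionally
#'   `gene_name`) or `"tss-bed"` (BED6: chrom, start, end, gene id, score,
#'   strand).
#' @return A data.frame with one row per gene: `gene_id`, `symbol`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open) and the derived
#'   `tss`.
#' @details GTF 1-based inclusive coordinates are converted to 0-based
#'   half-open. A duplicated `gene_id` is an error, as is a missing strand.
#' @export
read_gene_models <- function(path, format = c("gtf", "tss-bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- .split_tsv_lines(path)
  if (format == "gtf") {
    nf <- lengths(parsed$fields)
    if (any(nf != 9))
      stop(sprintf("line %d: malformed GTF row (%d fields, expected 9)",
                   parsed$lineno[nf != 9][1], nf[nf != 9][1]))
    m <- do.call(rbind, parsed$fields)
    lineno <- parsed$lineno
    gene <- m[, 3] == "gene"
    m <- m[gene, , drop = FALSE]
    lineno <- lineno[gene]
    if (nrow(m) == 0) stop("no 'gene' feature rows in ", path)
    strand <- m[, 7]
    bad <- !strand %in% c("+", "-")
    if (any(bad))
      stop(sprintf("line %d: missing or invalid strand '%s'",
                   lineno[bad][1], strand[bad][1]))
    start1 <- .check_int(m[, 4], "start", lineno)
    end1   <- .check_int(m[, 5], "end", lineno)
    if (any(start1 > end1))
      stop(sprintf("line %d: start > end", lineno[start1 > end1][1]))
    gid <- sub('.*gene_id "([^"]*)".*', "\\1", m[, 9])
    nohit <- !grepl('gene_id "', m[, 9], fixed = TRUE)
    if (any(nohit))
      stop(sprintf("line %d: no gene_id attribute", lineno[nohit][1]))
    sym <- ifelse(grepl('gene_name "', m[, 9], fixed = TRUE),
                  sub('.*gene_name "([^"]*)".*', "\\1", m[, 9]), gid)
    start0 <- start1 - 1L
    end0 <- end1
    df <- data.frame(gene_id = gid, symbol = sym, chrom = m[, 1],
                     strand = strand, start = start0, end = end0,
                     stringsAsFactors = FALSE)
  } else {
    nf <- lengths(parsed$fields)
    if (any(nf < 6))
      stop(sprintf("line %d: TSS BED needs 6 columns (chrom, start, end, gene id, score, strand)",
                   parsed$lineno[nf < 6][1]))
    m <- do.call(rbind, lapply(parsed$fields, `[`, 1:6))
    lineno <- parsed$lineno
    strand <- m[, 6]
    bad <- !strand %in% c("+", "-")
    if (any(bad))
      stop(sprintf("line %d: missing or invalid strand '%s'",
                   lineno[bad][1], strand[bad][1]))
    df <- data.frame(gene_id = m[, 4], symbol = m[, 4], chrom = m[, 1],
                     strand = strand,
                     start = .check_int(m[, 2], "start", lineno),
                     end = .check_int(m[, 3], "end", lineno),
                     stringsAsFactors = FALSE)
  }
  if (any(df$start < 0)) stop("negative start coordinate")
  if (any(df$start >= df$end)) stop("gene with start >= end")
  dup <- duplicated(df$gene_id)
  if (any(dup))
    stop("duplicate gene_id: ", paste(unique(df$gene_id[dup]), collapse = ", "))
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tss <- as.integer(df$tss)
  rownames(df) <- NULL
  df
}

#' Write gene models as a GTF file
#'
#' Inverse of [read_gene_models()] for the `gtf` format: internal 0-based
#' half-open coordinates are converted back to 1-based inclusive.
#'
#' @param genes Gene-model data.frame as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(genes, path) {
  lines <- sprintf('%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
                   genes$chrom, genes$start + 1L, genes$end, genes$strand,
                   genes$gene_id, genes$symbol)
  writeLines(lines, path)
  invisible(path)
}

#' Read ChIP-seq peaks from a BED or narrowPeak file
#'
#' @param path Path to the peak file.
#' @param format `"bed"` (>= 3 columns) or `"narrowPeak"` (the ENCODE
#'   10-column BED6+4 dialect).
#' @param source_label Tag recorded on every peak (e.g. a cell-line name).
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `signal`, `summit_offset` (NA when absent) and
#'   `source_label`.
#' @details The narrowPeak point-source column (column 10, an offset from
#'   `start`) maps to `summit_offset`; the sentinel `-1` maps to `NA`.
#'   Coordinates must be integers with `start < end`, and a point source
#'   must lie inside its interval.
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak"),
                       source_label = "") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- .split_tsv_lines(path)
  nf <- lengths(parsed$fields)
  lineno <- parsed$lineno
  need <- if (format == "narrowPeak") 10L else 3L
  if (any(nf < need))
    stop(sprintf("line %d: %s row has %d columns, expected >= %d",
                 lineno[nf < need][1], format, nf[nf < need][1], need))
  get <- function(i) vapply(parsed$fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  start <- .check_int(get(2), "start", lineno)
  end <- .check_int(get(3), "end", lineno)
  if (any(start < 0))
    stop(sprintf("line %d: negative start", lineno[start < 0][1]))
  if (any(start >= end))
    stop(sprintf("line %d: start >= end", lineno[start >= end][1]))
  name <- if (all(nf >= 4)) get(4) else sprintf("peak_%d", seq_along(start))
  name[is.na(name) | name == "."] <-
    sprintf("peak_%d", which(is.na(name) | name == "."))
  if (format == "narrowPeak") {
    signal <- suppressWarnings(as.numeric(get(7)))
    if (anyNA(signal))
      stop(sprintf("line %d: non-numeric signalValue", lineno[is.na(signal)][1]))
    summit <- .check_int(get(10), "point-source offset", lineno)
    summit[summit == -1L] <- NA_integer_
    bad <- !is.na(summit) & (summit < 0L | summit >= end - start)
    if (any(bad))
      stop(sprintf("line %d: point source outside the peak interval",
                   lineno[bad][1]))
  } else {
    signal <- if (all(nf >= 5))
      suppressWarnings(as.numeric(get(5))) else rep(0, length(start))
    signal[is.na(signal)] <- 0
    summit <- rep(NA_integer_, length(start))
  }
  if (any(signal < 0))
    stop(sprintf("line %d: negative signal", lineno[signal < 0][1]))
  data.frame(chrom = get(1), start = start, end = end, name = name,
             signal = signal, summit_offset = summit,
             source_label = source_label, stringsAsFactors = FALSE)
}

#' Write peaks as a narrowPeak file
#'
#' Inverse of [read_peaks()] for the narrowPeak format. An absent
#' `summit_offset` is written as the `-1` sentinel.
#'
#' @param peaks Peak data.frame as returned by [read_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_narrowpeak <- function(peaks, path) {
  summit <- ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%s\t-1\t-1\t%d",
                   peaks$chrom, peaks$start, peaks$end, peaks$name,
                   format(peaks$signal, trim = TRUE, scientific = FALSE),
                   summit)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' @param path TSV with a header row of sample ids and a first column of
#'   gene ids.
#' @param scale Scale the stored values are on: `"linear"` or `"log2p1"`.
#' @return An [expr_matrix].
#' @details Ragged rows, duplicate gene or sample ids, missing cells and
#'   negative linear values are all errors; missing cells are reported by
#'   gene and sample id.
#' @export
read_expression <- function(path, scale = c("linear", "log2p1")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- .split_tsv_lines(path)
  if (length(parsed$fields) < 2) stop("expression file needs a header and at least one gene row")
  header <- parsed$fields[[1]]
  samples <- header[-1]
  if (length(samples) == 0) stop("no sample columns in header")
  body <- parsed$fields[-1]
  lineno <- parsed$lineno[-1]
  nf <- lengths(body)
  expect <- length(header)
  if (any(nf != expect))
    stop(sprintf("line %d: ragged row (%d fields, expected %d)",
                 lineno[nf != expect][1], nf[nf != expect][1], expect))
  m <- do.call(rbind, body)
  genes <- m[, 1]
  vals <- suppressWarnings(matrix(as.numeric(m[, -1, drop = FALSE]),
                                  nrow = nrow(m)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("missing or non-numeric value at gene '%s', sample '%s'",
                 genes[idx[1]], samples[idx[2]]))
  }
  dimnames(vals) <- list(genes, samples)
  expr_matrix(vals, scale)  # enforces unique ids, finiteness, sign
}

#' Write an expression matrix as TSV
#'
#' @param x An [expr_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical (survival) table from TSV
#'
#' @param path TSV with header columns `sample`, `time`, `event`.
#' @return A data.frame with `sample_id` (unique), `time` (positive, days)
#'   and `event` (0 censored / 1 event).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample),
                    time = as.numeric(df$time),
                    event = df$event, stringsAsFactors = FALSE)
  if (anyNA(out$time) || any(out$time <= 0))
    stop("clinical times must be positive; offending sample: ",
         out$sample_id[which(is.na(out$time) | out$time <= 0)[1]])
  if (!all(out$event %in% c(0, 1)))
    stop("event must be 0 or 1; offending sample: ",
         out$sample_id[which(!out$event %in% c(0, 1))[1]])
  out$event <- as.integer(out$event)
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  out
}

#' Write a clinical table as TSV
#'
#' @param clinical Data.frame as returned by [read_clinical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  df <- data.frame(sample = clinical$sample_id, time = clinical$time,
                   event = clinical$event)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
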