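# Independent oracles and small fixture builders. Every oracle here is a
# direct, unoptimized transcription of the definition it checks, kept free
# of the package's own code paths.

make_genes <- function(gene_id, chrom, strand, start, end) {
  data.frame(gene_id = gene_id, symbol = gene_id, chrom = chrom,
             strand = strand, start = as.integer(start),
             end = as.integer(end),
             tss = as.integer(ifelse(strand == "+", start, end - 1L)),
             stringsAsFactors = FALSE)
}

make_peaks <- function(chrom, start, end, name = NULL, summit = NA) {
  n <- length(start)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = if (is.null(name)) sprintf("p%d", seq_len(n)) else name,
             signal = rep(1, n), summit_offset = as.integer(rep_len(summit, n)),
             source_label = "test", stringsAsFactors = FALSE)
}

random_genes <- function(n, chroms = c("chr1", "chr2"), len = 1e6) {
  chrom <- sample(chroms, n, replace = TRUE)
  tss <- sample.int(len - 2000L, n)  # collisions allowed: exercises ties
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- ifelse(strand == "+", tss, pmax(tss - sample(500:5000, n, TRUE), 0L))
  end <- ifelse(strand == "+", tss + sample(500:5000, n, TRUE), tss + 1L)
  make_genes(sprintf("g%04d", sample.int(9999L, n)), chrom, strand, start, end)
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), len = 1e6) {
  start <- sample.int(len - 1000L, n)
  make_peaks(sample(chroms, n, replace = TRUE), start,
             start + sample(100:800, n, replace = TRUE))
}

# exhaustive nearest-TSS search with the documented tie-break
oracle_nearest <- function(peaks, genes,
                           reference_point = "midpoint",
                           sign_convention = "upstream_negative") {
  t(vapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(c(NA_character_, NA_character_))
    s <- peaks$start[i]; e <- peaks$end[i]
    p_per_gene <- switch(reference_point,
      midpoint = rep((s + e) %/% 2L, nrow(g)),
      summit = rep(if (is.na(peaks$summit_offset[i])) (s + e) %/% 2L
                   else s + peaks$summit_offset[i], nrow(g)),
      nearest_edge = pmin(pmax(g$tss, s), e - 1L))
    d_abs <- abs(p_per_gene - g$tss)
    best <- which(d_abs == min(d_abs))
    j <- best[order(g$gene_id[best])[1]]
    raw <- p_per_gene[j] - g$tss[j]
    d <- if (g$strand[j] == "+") raw else -raw
    if (sign_convention == "upstream_positive") d <- -d
    c(g$gene_id[j], as.character(d))
  }, character(2)))
}

# brute-force per-base occupancy scan (merge_gap = 0)
oracle_merge <- function(peak_sets, len = 1e6) {
  all <- do.call(rbind, peak_sets)
  out <- list()
  for (ch in sort(unique(all$chrom))) {
    pk <- all[all$chrom == ch, , drop = FALSE]
    cov <- logical(len)
    for (i in seq_len(nrow(pk)))
      cov[(pk$start[i] + 1L):pk$end[i]] <- TRUE  # base b -> index b+1
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep))
      out[[ch]] <- data.frame(chrom = ch, start = starts[keep] - 1L,
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# textbook Pearson correlation from raw sums
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

toy_expr <- function(values, genes, samples, scale = "linear") {
  m <- matrix(values, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  expr_matrix(m, scale)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Table-1-shaped worked example: the three published candidate rows
table1_inputs <- function() {
  genes <- c("CKS1B", "FADD", "MEIS2")
  list(
    occupancy = data.frame(
      gene_id = genes, bound = c(TRUE, TRUE, FALSE),
      best_distance = c(-319L, 152L, 521171L), n_peaks = 1L,
      stringsAsFactors = FALSE),
    oe = data.frame(gene_id = genes, ratio = c(1.90, 2.10, 1.01),
                    log2_ratio = log2(c(1.90, 2.10, 1.01)),
                    stringsAsFactors = FALSE),
    kd = data.frame(gene_id = genes, ratio = c(0.66, 1.06, 0.77),
                    log2_ratio = log2(c(0.66, 1.06, 0.77)),
                    stringsAsFactors = FALSE),
    corr = data.frame(gene_id = genes, r = c(0.29, 0.24, -0.32),
                      n_samples = 100L, stringsAsFactors = FALSE))
}
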