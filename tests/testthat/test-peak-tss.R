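test_that("union_merge is the identity on one disjoint set and merges overlaps", {
  pk <- make_peaks("chr1", c(100L, 500L), c(200L, 600L))
  out <- pool_peaks(list(pk), "union_merge", 0L)
  expect_equal(out$start, c(100L, 500L))
  expect_equal(out$end, c(200L, 600L))

  a <- make_peaks("chr1", 100L, 200L)
  b <- make_peaks("chr1", 150L, 250L)
  out <- pool_peaks(list(a, b), "union_merge", 0L)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(100L, 250L))

  # touching half-open intervals merge at gap 0; a 5-bp gap needs merge_gap >= 5
  touch <- pool_peaks(list(make_peaks("chr1", c(100L, 200L), c(200L, 300L))),
                      "union_merge", 0L)
  expect_equal(nrow(touch), 1L)
  gap5 <- make_peaks("chr1", c(100L, 205L), c(200L, 300L))
  expect_equal(nrow(pool_peaks(list(gap5), "union_merge", 4L)), 2L)
  expect_equal(nrow(pool_peaks(list(gap5), "union_merge", 5L)), 1L)

  expect_error(pool_peaks(list(), "union_merge"), "non-empty")
})

test_that("union_merge matches the brute-force occupancy oracle on random sets", {
  set.seed(42)
  for (rep in 1:10) {
    sets <- lapply(seq_len(sample(2:4, 1)), function(i)
      random_peaks(sample(10:60, 1), len = 20000L))
    out <- pool_peaks(sets, "union_merge", 0L)
    ref <- oracle_merge(sets, len = 21000L)
    ref <- ref[order(ref$chrom, ref$start), ]
    expect_equal(out[c("chrom", "start", "end")], ref[c("chrom", "start", "end")],
                 ignore_attr = TRUE)
    # disjointness and sortedness
    for (ch in unique(out$chrom)) {
      oc <- out[out$chrom == ch, ]
      expect_true(all(diff(oc$start) > 0))
      expect_true(all(oc$start[-1] > oc$end[-nrow(oc)]))
    }
  }
})

test_that("union_merge agrees with GenomicRanges::reduce", {
  skip_if_not_installed("GenomicRanges")
  set.seed(7)
  sets <- lapply(1:3, function(i) random_peaks(40, len = 50000L))
  out <- pool_peaks(sets, "union_merge", 0L)
  all <- do.call(rbind, sets)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    all$chrom, IRanges::IRanges(all$start + 1L, all$end)))
  ref <- as.data.frame(gr)
  ref <- ref[order(as.character(ref$seqnames), ref$start), ]
  expect_equal(out$start, ref$start - 1L)
  expect_equal(out$end, ref$end)
})

test_that("intersection keeps only loci overlapped by every input set", {
  a <- make_peaks("chr1", 100L, 200L)
  b <- make_peaks("chr1", c(150L, 400L), c(250L, 500L))
  out <- pool_peaks(list(a, b), "intersection", 0L)
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(100L, 250L))
})

test_that("nearest-TSS distance is zero at the TSS and mirrors with the sign convention", {
  g <- make_genes("gA", "chr1", "+", 10000L, 15000L)
  atpeak <- make_peaks("chr1", 9900L, 10100L)  # midpoint 10000 == tss
  expect_equal(assign_nearest_tss(atpeak, g)$distance, 0L)

  up <- make_peaks("chr1", 9400L, 9600L)  # midpoint 9500, 500 bp upstream
  expect_equal(assign_nearest_tss(up, g)$distance, -500L)
  expect_equal(assign_nearest_tss(up, g,
               sign_convention = "upstream_positive")$distance, 500L)

  # minus-strand gene: lower coordinate is downstream in reading direction
  gm <- make_genes("gB", "chr1", "-", 5000L, 10001L)  # tss = 10000
  expect_equal(assign_nearest_tss(up, gm)$distance, 500L)
})

test_that("assignment equals exhaustive search with the tie-break, all options", {
  set.seed(99)
  for (rep in 1:6) {
    genes <- random_genes(60, len = 50000L)
    genes <- genes[!duplicated(genes$gene_id), ]
    peaks <- random_peaks(150, len = 50000L)
    peaks$summit_offset <- ifelse(seq_len(nrow(peaks)) %% 3 == 0,
                                  NA_integer_, 50L)
    for (rp in c("midpoint", "summit", "nearest_edge"))
      for (sc in c("upstream_negative", "upstream_positive")) {
        got <- assign_nearest_tss(peaks, genes, rp, sc)
        ref <- oracle_nearest(peaks, genes, rp, sc)
        expect_equal(got$gene_id, ref[, 1])
        expect_equal(got$distance, as.integer(ref[, 2]))
      }
  }
})

test_that("assignment is invariant to peak and gene input order", {
  set.seed(21)
  genes <- random_genes(40, len = 30000L)
  genes <- genes[!duplicated(genes$gene_id), ]
  peaks <- random_peaks(80, len = 30000L)
  base <- assign_nearest_tss(peaks, genes)
  perm <- assign_nearest_tss(peaks[sample(nrow(peaks)), ],
                             genes[sample(nrow(genes)), ])
  perm <- perm[match(base$name, perm$name), ]
  expect_equal(perm$gene_id, base$gene_id)
  expect_equal(perm$distance, base$distance)
})

test_that("peaks on chromosomes without annotation are reported unassigned", {
  g <- make_genes("gA", "chr1", "+", 1000L, 2000L)
  pk <- make_peaks(c("chr1", "chrUn"), c(900L, 500L), c(1100L, 600L))
  out <- assign_nearest_tss(pk, g)
  expect_equal(out$assigned, c(TRUE, FALSE))
  expect_equal(nrow(out), 2L)  # retained, not dropped
  expect_error(assign_nearest_tss(make_peaks("chr9", 1L, 10L), g),
               "share no chromosome")
})

test_that("distance histogram bins half-open, conserves counts, reports asymmetry", {
  mk <- function(d) data.frame(distance = as.integer(d),
                               assigned = TRUE, gene_id = "g",
                               stringsAsFactors = FALSE)
  h0 <- distance_histogram(mk(rep(0L, 5)), bin_width = 100L, max_bp = 200L)
  expect_equal(sum(h0$bins$count > 0), 1L)
  expect_equal(h0$bins$count[h0$bins$bin_lo == 0], 5L)

  h <- distance_histogram(mk(c(-150L, -50L, 50L)), 100L, 200L)
  expect_equal(h$bins$count[h$bins$bin_lo == -200], 1L)
  expect_equal(h$bins$count[h$bins$bin_lo == -100], 1L)
  expect_equal(h$bins$count[h$bins$bin_lo == 0], 1L)
  expect_equal(h$upstream, 2L)
  expect_equal(h$downstream, 1L)

  set.seed(8)
  d <- sample(-5000:5000, 500, replace = TRUE)
  hh <- distance_histogram(mk(d), 500L, 2000L)
  expect_equal(sum(hh$bins$count) + hh$out_of_range, 500L)
  expect_error(distance_histogram(mk(0L), 300L, 1000L), "multiple")
})

test_that("promoter fraction counts |d| <= window over assigned peaks only", {
  mk <- function(d, assigned = TRUE)
    data.frame(distance = as.integer(d), assigned = assigned,
               gene_id = "g", stringsAsFactors = FALSE)
  expect_equal(promoter_fraction(mk(c(0L, 0L)), 2000L)$fraction, 1.0)
  expect_equal(promoter_fraction(mk(c(5000L, -9000L)), 2000L)$fraction, 0.0)
  expect_equal(promoter_fraction(mk(2000L), 2000L)$fraction, 1.0)  # inclusive
  mixed <- rbind(mk(c(100L, 3000L)), mk(NA, assigned = FALSE))
  pf <- promoter_fraction(mixed, 2000L)
  expect_equal(pf$fraction, 0.5)
  expect_equal(pf$n_unassigned, 1L)
  none <- data.frame(distance = integer(0), assigned = logical(0),
                     gene_id = character(0), stringsAsFactors = FALSE)
  expect_error(promoter_fraction(none), "no assigned")
})

test_that("promoter occupancy flags bound genes and picks the best distance", {
  mk <- function(gene, d) data.frame(distance = as.integer(d), assigned = TRUE,
                                     gene_id = gene, stringsAsFactors = FALSE)
  # a promoter assignment 152 bp downstream is bound; 521 kb away is not
  occ <- promoter_occupancy(rbind(mk("FADD", 152L), mk("MEIS2", 521171L)),
                            window = 2000L)
  expect_equal(occ$bound, c(TRUE, FALSE))
  expect_equal(occ$best_distance, c(152L, 521171L))

  occ2 <- promoter_occupancy(mk("gA", c(500L, -100L)), 2000L)
  expect_equal(occ2$best_distance, -100L)
  occ3 <- promoter_occupancy(mk("gA", c(100L, -100L)), 2000L)
  expect_equal(occ3$best_distance, -100L)  # |d| tie goes upstream

  genes <- make_genes(c("gA", "gZ"), "chr1", "+", c(1L, 100L), c(50L, 200L))
  occ4 <- promoter_occupancy(mk("gA", 10L), 2000L, genes = genes)
  expect_equal(occ4$gene_id, c("gA", "gZ"))
  expect_equal(occ4$bound, c(TRUE, FALSE))
  expect_true(is.na(occ4$best_distance[2]))
})
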