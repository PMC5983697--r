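#' Pool peak sets into one collection of loci
#'
#' ChIP-seq peak sets from several sources (cell lines, replicates) are
#' combined into a single set of disjoint loci before distance analysis.
#' `union_merge` concatenates all sets and merges intervals whose gap is at
#' most `merge_gap` base pairs; `intersection` keeps only those merged loci
#' that are overlapped by at least one peak from every input set.
#'
#' @param peak_sets A list of peak data.frames (see [read_peaks()]), or a
#'   single peak data.frame.
#' @param mode `"union_merge"` or `"intersection"`.
#' @param merge_gap Non-negative integer; intervals separated by at most
#'   this many bases are merged into one locus (0 merges touching or
#'   overlapping intervals).
#' @return A peak data.frame of disjoint loci, sorted by chromosome and
#'   start, named `locus_1`, `locus_2`, ... Signal is the maximum of the
#'   merged peaks; `source_label` lists the contributing sources.
#' @export
pool_peaks <- function(peak_sets, mode = c("union_merge", "intersection"),
                       merge_gap = 0L) {
  mode <- match.arg(mode)
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  if (!is.list(peak_sets) || length(peak_sets) == 0)
    stop("'peak_sets' must be a non-empty list of peak data.frames")
  if (any(!vapply(peak_sets, is.data.frame, logical(1))) ||
      any(vapply(peak_sets, nrow, integer(1)) == 0))
    stop("every peak set must be a non-empty data.frame")
  stopifnot(merge_gap >= 0)
  all_peaks <- do.call(rbind, peak_sets)

  merged <- do.call(rbind, lapply(split(all_peaks, all_peaks$chrom), function(pk) {
    o <- order(pk$start, pk$end)
    s <- pk$start[o]; e <- pk$end[o]; sig <- pk$signal[o]
    src <- pk$source_label[o]
    # sorted scan: extend the open locus while the next start is within gap
    grp <- cumsum(c(1L, as.integer(s[-1] > cummax(e[-length(e)]) + merge_gap)))
    data.frame(chrom = pk$chrom[1],
               start = as.integer(tapply(s, grp, min)),
               end = as.integer(tapply(e, grp, max)),
               signal = as.numeric(tapply(sig, grp, max)),
               source_label = vapply(split(src, grp), function(x)
                 paste(sort(unique(x)), collapse = ","), character(1)),
               stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]

  if (mode == "intersection") {
    hit_all <- rep(TRUE, nrow(merged))
    for (set in peak_sets) {
      hit <- logical(nrow(merged))
      for (ch in unique(merged$chrom)) {
        mi <- which(merged$chrom == ch)
        pk <- set[set$chrom == ch, , drop = FALSE]
        if (nrow(pk) == 0) next
        hit[mi] <- vapply(mi, function(i)
          any(pk$start < merged$end[i] & pk$end > merged$start[i]),
          logical(1))
      }
      hit_all <- hit_all & hit
    }
    merged <- merged[hit_all, , drop = FALSE]
  }

  n <- nrow(merged)
  data.frame(chrom = merged$chrom, start = merged$start, end = merged$end,
             name = if (n) sprintf("locus_%d", seq_len(n)) else character(0),
             signal = merged$signal,
             summit_offset = rep(NA_integer_, n),
             source_label = merged$source_label,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Minimal lexicographic gene id among genes on one chromosome whose tss
# equals one of the candidate positions.
.min_gene_at <- function(pos_map, positions) {
  ids <- pos_map[as.character(as.integer(positions))]
  ids <- ids[!is.na(ids)]
  if (length(ids) == 0) NA_character_ else min(ids)
}

#' Assign each peak to the nearest transcription start site
#'
#' For every peak a reference coordinate is chosen (interval midpoint, the
#' reported summit, or the TSS-closest edge) and the gene whose TSS
#' minimizes the absolute offset on the same chromosome is assigned, with a
#' signed, strand-oriented distance. Ties in absolute distance are broken
#' by the lexicographically smallest gene id, so the assignment is a pure
#' function of its inputs.
#'
#' @param peaks Peak data.frame (see [read_peaks()] / [pool_peaks()]).
#' @param genes Gene-model data.frame (see [read_gene_models()]).
#' @param reference_point `"midpoint"` (`floor((start+end)/2)`, default),
#'   `"summit"` (`start + summit_offset`; midpoint when no summit is
#'   recorded), or `"nearest_edge"` (the point of the peak interval closest
#'   to the TSS, so a peak covering a TSS has distance 0).
#' @param sign_convention `"upstream_negative"` (default; a peak upstream
#'   of the TSS in the gene's reading direction gets d < 0) or
#'   `"upstream_positive"` (the mirrored convention, matching published
#'   tables that print upstream sites with a + sign).
#' @return A data.frame with one row per peak: peak `name`, `chrom`,
#'   `start`, `end`, `ref_coord`, assigned `gene_id`, signed `distance`
#'   and `assigned` (FALSE for peaks on chromosomes absent from the
#'   annotation, which are retained, never silently dropped). Attributes
#'   `reference_point` and `sign_convention` record the options used.
#' @export
assign_nearest_tss <- function(peaks, genes,
                               reference_point = c("midpoint", "summit",
                                                   "nearest_edge"),
                               sign_convention = c("upstream_negative",
                                                   "upstream_positive")) {
  reference_point <- match.arg(reference_point)
  sign_convention <- match.arg(sign_convention)
  if (!is.data.frame(genes) || nrow(genes) == 0)
    stop("'genes' must be a non-empty gene-model data.frame")
  if (!is.data.frame(peaks) || nrow(peaks) == 0)
    stop("'peaks' must be a non-empty peak data.frame")
  if (length(intersect(unique(peaks$chrom), unique(genes$chrom))) == 0)
    stop("peaks and gene models share no chromosome; ",
         "check chromosome-name dialects ('chr1' vs '1')")

  strand_of <- stats::setNames(genes$strand, genes$gene_id)
  out <- data.frame(name = peaks$name, chrom = peaks$chrom,
                    start = peaks$start, end = peaks$end,
                    ref_coord = NA_integer_, gene_id = NA_character_,
                    distance = NA_integer_, assigned = FALSE,
                    stringsAsFactors = FALSE)

  for (ch in unique(peaks$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    pi <- which(peaks$chrom == ch)
    if (nrow(g) == 0) next  # reported unassigned
    o <- order(g$tss, g$gene_id)
    ts <- g$tss[o]; gid <- g$gene_id[o]
    # minimal gene id per distinct tss position (duplicate-TSS tie-break)
    pos_map <- vapply(split(gid, ts), min, character(1))

    s <- peaks$start[pi]; e <- peaks$end[pi]
    if (reference_point == "nearest_edge") {
      e1 <- e - 1L
      iL <- findInterval(e1, ts)            # largest tss <= e1
      iR <- findInterval(s - 1L, ts) + 1L   # smallest tss >= s
      dL <- ifelse(iL >= 1L, pmax(s - ts[pmax(iL, 1L)], 0L), NA_integer_)
      dR <- ifelse(iR <= length(ts), pmax(ts[pmin(iR, length(ts))] - e1, 0L),
                   NA_integer_)
      dmin <- pmin(dL, dR, na.rm = TRUE)
      gene <- character(length(pi))
      for (k in seq_along(pi)) {
        if (dmin[k] == 0L) {
          inside <- ts >= s[k] & ts <= e1[k]
          gene[k] <- min(gid[inside])
        } else {
          gene[k] <- .min_gene_at(pos_map, c(s[k] - dmin[k], e1[k] + dmin[k]))
        }
      }
      tss_g <- genes$tss[match(gene, genes$gene_id)]
      p <- pmin(pmax(tss_g, s), e1)  # clamp the TSS into the interval
    } else {
      p <- if (reference_point == "summit") {
        ifelse(is.na(peaks$summit_offset[pi]),
               (s + e) %/% 2L, s + peaks$summit_offset[pi])
      } else {
        (s + e) %/% 2L
      }
      i <- findInterval(p, ts)
      dL <- ifelse(i >= 1L, p - ts[pmax(i, 1L)], NA_integer_)
      dR <- ifelse(i < length(ts), ts[pmin(i + 1L, length(ts))] - p,
                   NA_integer_)
      dmin <- pmin(dL, dR, na.rm = TRUE)
      gene <- vapply(seq_along(pi), function(k)
        .min_gene_at(pos_map, unique(c(p[k] - dmin[k], p[k] + dmin[k]))),
        character(1))
      tss_g <- genes$tss[match(gene, genes$gene_id)]
    }
    raw <- as.integer(p) - as.integer(tss_g)
    oriented <- ifelse(strand_of[gene] == "+", raw, -raw)
    if (sign_convention == "upstream_positive") oriented <- -oriented
    out$ref_coord[pi] <- as.integer(p)
    out$gene_id[pi] <- gene
    out$distance[pi] <- as.integer(oriented)
    out$assigned[pi] <- TRUE
  }
  attr(out, "reference_point") <- reference_point
  attr(out, "sign_convention") <- sign_convention
  out
}

#' Histogram of signed peak-to-TSS distances
#'
#' Bins the signed distances of assigned peaks into fixed-width bins over a
#' symmetric window, the summary behind the classic promoter-proximity
#' histogram. Bins are half-open `[lo, hi)`; distances outside
#' `[-max_bp, max_bp)` are counted separately, never dropped, so bin counts
#' plus the out-of-range count always equal the number of assignments.
#'
#' @param assignments Output of [assign_nearest_tss()].
#' @param bin_width Positive bin width in bp.
#' @param max_bp Half-range in bp; must be a multiple of `bin_width`.
#' @param per `"assignment"` (one count per peak, default) or `"gene"`
#'   (one count per gene, at its best distance, see
#'   [promoter_occupancy()]).
#' @return An object of class `distance_histogram`: list with `bins` (a
#'   data.frame `bin_lo`, `bin_hi`, `midpoint`, `count`), `out_of_range`,
#'   `n`, and the `upstream` (d < 0) and `downstream` (d > 0) totals.
#' @export
distance_histogram <- function(assignments, bin_width = 500L,
                               max_bp = 10000L,
                               per = c("assignment", "gene")) {
  per <- match.arg(per)
  if (bin_width <= 0) stop("'bin_width' must be positive")
  if (max_bp %% bin_width != 0) stop("'max_bp' must be a multiple of 'bin_width'")
  d <- assignments$distance[assignments$assigned]
  if (per == "gene") {
    occ <- promoter_occupancy(assignments, window = max_bp)
    d <- occ$best_distance[!is.na(occ$best_distance)]
  }
  k <- floor(d / bin_width)
  kmax <- max_bp %/% bin_width
  in_range <- k >= -kmax & k < kmax
  counts <- tabulate(k[in_range] + kmax + 1L, nbins = 2L * kmax)
  lo <- (seq_len(2L * kmax) - kmax - 1L) * bin_width
  structure(list(
    bins = data.frame(bin_lo = lo, bin_hi = lo + bin_width,
                      midpoint = lo + bin_width / 2, count = counts),
    out_of_range = sum(!in_range), n = length(d),
    upstream = sum(d < 0), downstream = sum(d > 0),
    bin_width = bin_width, max_bp = max_bp, per = per),
    class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("distance_histogram (per %s): %d assignments, bin %d bp, range +/-%d bp\n",
              x$per, x$n, x$bin_width, x$max_bp))
  cat(sprintf("  upstream (d<0): %d   downstream (d>0): %d   out of range: %d\n",
              x$upstream, x$downstream, x$out_of_range))
  invisible(x)
}

#' @export
plot.distance_histogram <- function(x, ...) {
  graphics::barplot(x$bins$count, names.arg = x$bins$midpoint,
                    xlab = "distance to TSS (bp)", ylab = "count",
                    border = NA, ...)
  invisible(x)
}

#' Fraction of assigned peaks within a promoter window
#'
#' @param assignments Output of [assign_nearest_tss()].
#' @param window Half-width of the promoter window in bp; `|d| <= window`
#'   counts as promoter-proximal (inclusive, so the default covers the
#'   "within 2 kb of the TSS" convention).
#' @return List with `fraction`, `n_within`, `n_assigned`, `n_unassigned`.
#'   Unassigned peaks are excluded from the denominator but reported.
#' @export
promoter_fraction <- function(assignments, window = 2000L) {
  if (window <= 0) stop("'window' must be positive")
  d <- assignments$distance[assignments$assigned]
  if (length(d) == 0) stop("no assigned peaks")
  list(fraction = mean(abs(d) <= window),
       n_within = sum(abs(d) <= window),
       n_assigned = length(d),
       n_unassigned = sum(!assignments$assigned))
}

#' Per-gene promoter occupancy table
#'
#' Summarizes assignments gene-wise: a gene is `bound` when at least one
#' assigned peak lies within the promoter window, and `best_distance` is
#' its assignment of smallest absolute distance (on a `+d`/`-d` tie the
#' upstream, negative one).
#'
#' @param assignments Output of [assign_nearest_tss()].
#' @param window Promoter half-width in bp (inclusive).
#' @param genes Optional gene-model data.frame; when given, genes without
#'   any assignment are included with `bound = FALSE` and no distance.
#' @return Data.frame `gene_id`, `bound`, `best_distance`, `n_peaks`.
#' @export
promoter_occupancy <- function(assignments, window = 2000L, genes = NULL) {
  a <- assignments[assignments$assigned, , drop = FALSE]
  if (nrow(a)) {
    o <- order(a$gene_id, abs(a$distance), a$distance)  # tie: negative first
    a <- a[o, , drop = FALSE]
    first <- !duplicated(a$gene_id)
    tab <- data.frame(gene_id = a$gene_id[first],
                      bound = as.logical(tapply(abs(a$distance) <= window,
                                                a$gene_id, any)[a$gene_id[first]]),
                      best_distance = a$distance[first],
                      n_peaks = as.integer(table(a$gene_id)[a$gene_id[first]]),
                      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(gene_id = character(0), bound = logical(0),
                      best_distance = integer(0), n_peaks = integer(0),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes$gene_id, tab$gene_id)
    if (length(missing))
      tab <- rbind(tab, data.frame(gene_id = missing, bound = FALSE,
                                   best_distance = NA_integer_,
                                   n_peaks = 0L, stringsAsFactors = FALSE))
    tab <- tab[match(genes$gene_id, tab$gene_id), , drop = FALSE]
  } else {
    tab <- tab[order(tab$gene_id), , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}
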