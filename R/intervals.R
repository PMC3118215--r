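#' Genomic interval algebra on tibbles
#'
#' All coordinates in this package are 0-based half-open `[start, end)`;
#' conversion to and from 1-based-inclusive file dialects happens only at I/O
#' boundaries. An interval table is any tibble with columns `chrom` (character),
#' `start` and `end` (numeric, `start < end`). Chromosome names are compared as
#' exact strings.
#'
#' @name interval-algebra
NULL

assert_intervals <- function(x, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    abort(sprintf("%s must have columns chrom, start, end", what))
  }
  bad <- which(!(x$start < x$end))
  if (length(bad)) {
    abort(sprintf("%s row %d: start must be < end (got [%s, %s))",
                  what, bad[1], format(x$start[bad[1]]), format(x$end[bad[1]])))
  }
  invisible(x)
}

## 0-based half-open tibble -> 1-based closed GRanges; an optional shared
## seqlevel universe keeps pairwise set ops quiet when chromosome sets differ
as_granges <- function(x, seqlevels = NULL) {
  assert_intervals(x)
  GenomicRanges::GRanges(
    factor(x$chrom, levels = seqlevels %||% unique(x$chrom)),
    IRanges::IRanges(x$start + 1L, x$end))
}

granges_pair <- function(a, b) {
  lv <- unique(c(a$chrom, b$chrom))
  list(as_granges(a, lv), as_granges(b, lv))
}

## GRanges -> 0-based half-open tibble
granges_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end   = as.numeric(GenomicRanges::end(gr))
  )
}

#' Intersect two interval tables
#'
#' Returns the region-by-region intersection of the unions of `a` and `b`.
#'
#' @param a,b Interval tables (`chrom`, `start`, `end`).
#' @return A tibble of disjoint sorted intervals covering the bases present in
#'   both `a` and `b`; zero rows when they share no base.
#' @export
#' @examples
#' iv_intersect(tibble::tibble(chrom = "chr1", start = 0, end = 1000),
#'              tibble::tibble(chrom = "chr1", start = 500, end = 1500))
iv_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  gp <- granges_pair(a, b)
  gr <- GenomicRanges::intersect(gp[[1]], gp[[2]])
  arrange(granges_tbl(gr), .data$chrom, .data$start)
}

#' Union (reduce) an interval table
#'
#' @param x Interval table; rows may overlap and appear in any order.
#' @return Disjoint sorted intervals covering the same bases. Abutting
#'   intervals are merged.
#' @export
iv_union <- function(x) {
  if (nrow(x) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  gr <- GenomicRanges::reduce(as_granges(x))
  arrange(granges_tbl(gr), .data$chrom, .data$start)
}

#' Subtract one interval set from another
#'
#' @param x,y Interval tables; returns the bases of `x` not covered by `y`.
#' @return Disjoint sorted intervals.
#' @export
iv_setdiff <- function(x, y) {
  if (nrow(x) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  if (nrow(y) == 0) return(iv_union(x))
  gp <- granges_pair(x, y)
  gr <- GenomicRanges::setdiff(gp[[1]], gp[[2]])
  arrange(granges_tbl(gr), .data$chrom, .data$start)
}

#' Gap between two intervals
#'
#' @param a,b Single-row interval tables on the same chromosome.
#' @return A tibble with the interval strictly between `a` and `b` (zero rows
#'   when they overlap or abut).
#' @export
iv_gap <- function(a, b) {
  assert_intervals(a); assert_intervals(b)
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (a$chrom != b$chrom) abort("iv_gap: intervals on different chromosomes")
  lo <- min(a$end, b$end); hi <- max(a$start, b$start)
  if (hi <= lo) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  tibble(chrom = a$chrom, start = lo, end = hi)
}

#' Edge-to-edge distance between intervals
#'
#' Distance is 0 for overlapping or abutting intervals, the bp gap between the
#' closest edges otherwise, and `Inf` across chromosomes. "Within 500 bp" in
#' the location rules means `iv_distance(...) <= 500`.
#'
#' @param a,b Interval tables of equal length (or length 1, recycled).
#' @return Numeric vector of distances.
#' @export
#' @examples
#' iv_distance(tibble::tibble(chrom = "chr1", start = 0, end = 100),
#'             tibble::tibble(chrom = "chr1", start = 600, end = 700))  # 500
iv_distance <- function(a, b) {
  assert_intervals(a); assert_intervals(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), ]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), ]
  stopifnot(nrow(a) == nrow(b))
  gap <- pmax(a$start, b$start) - pmin(a$end, b$end)
  d <- pmax(gap, 0)
  d[a$chrom != b$chrom] <- Inf
  d
}

## Minimum edge-to-edge distance from each row of `x` to any row of `y`.
## Inf where no same-chromosome y exists.
iv_nearest_distance <- function(x, y) {
  if (nrow(x) == 0) return(numeric(0))
  if (nrow(y) == 0) return(rep(Inf, nrow(x)))
  gp <- granges_pair(x, y)
  gx <- gp[[1]]; gy <- gp[[2]]
  d <- rep(Inf, nrow(x))
  hit <- GenomicRanges::distanceToNearest(gx, gy)
  d[S4Vectors::queryHits(hit)] <- as.numeric(S4Vectors::mcols(hit)$distance)
  d
}

## Overlap indicator: does each row of x overlap any row of y?
iv_overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  gp <- granges_pair(x, y)
  IRanges::overlapsAny(gp[[1]], gp[[2]])
}

## Total bp of overlap between each row of x and the union of y.
iv_overlap_bp <- function(x, y) {
  if (nrow(x) == 0) return(numeric(0))
  out <- numeric(nrow(x))
  if (nrow(y) == 0) return(out)
  gp <- granges_pair(x, y)
  gx <- gp[[1]]; gy <- GenomicRanges::reduce(gp[[2]])
  hits <- GenomicRanges::findOverlaps(gx, gy)
  if (length(hits)) {
    w <- IRanges::width(IRanges::pintersect(
      gx[S4Vectors::queryHits(hits)], gy[S4Vectors::subjectHits(hits)]))
    ov <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(ov))] <- as.numeric(ov)
  }
  out
}

iv_total_bp <- function(x) {
  u <- iv_union(x)
  sum(u$end - u$start)
}
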