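#' Callable-region mask
#'
#' A set of non-overlapping, sorted intervals on one sequence (0-based,
#' half-open, BED convention) defining the territory where genotype calls
#' are reliable.  Its total length is the effective number of callable
#' sites `L` used to convert mutation counts into time.
#'
#' @param start,end Integer vectors of interval bounds, 0-based half-open.
#'   Overlapping or adjacent input intervals are merged.
#' @return An object of class `region_mask` with fields `start`, `end` and
#'   `effective_length_bp`.
#' @export
region_mask <- function(start = integer(0), end = integer(0)) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(end <= start)) stop("mask intervals require end > start")
  if (length(start)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1, end = end))
    start <- IRanges::start(ir) - 1
    end <- IRanges::end(ir)
  }
  structure(list(start = start, end = end,
                 effective_length_bp = sum(end - start)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask: %d intervals, effective length %s bp\n",
              length(x$start), format(x$effective_length_bp, big.mark = ",")))
  invisible(x)
}

#' Read a BED3 file into a region mask
#'
#' Intervals are merged and sorted on input; only the coordinates are used
#' (the mask is defined on a single sequence, here the Y chromosome).
#'
#' @param path Path to a BED file (0-based half-open).
#' @return A [region_mask()].
#' @export
read_region_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask file: ", path)
  if (file.size(path) == 0L) return(region_mask())
  gr <- rtracklayer::import(path, format = "BED")
  region_mask(start = GenomicRanges::start(gr) - 1,
              end = GenomicRanges::end(gr))
}

#' Write a region mask as BED3
#' @param mask A [region_mask()].
#' @param path Output path.
#' @param seqname Sequence name for the BED records.
#' @return `path`, invisibly.
#' @export
write_region_mask <- function(mask, path, seqname = "chrY") {
  df <- data.frame(chrom = rep(seqname, length(mask$start)),
                   start = format(mask$start, scientific = FALSE, trim = TRUE),
                   end = format(mask$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Test 1-based positions for mask membership
#' @param mask A [region_mask()].
#' @param positions Integer vector of 1-based genomic positions.
#' @return Logical vector: `TRUE` where the position falls in the mask.
#' @export
mask_contains <- function(mask, positions) {
  if (length(mask$start) == 0L) return(rep(FALSE, length(positions)))
  ir <- IRanges::IRanges(start = mask$start + 1, end = mask$end)
  q <- IRanges::IRanges(start = positions, width = 1L)
  IRanges::overlapsAny(q, ir)
}

# Map offsets 1..effective_length_bp to 1-based genomic positions.  Used by
# the simulator to draw mutation sites uniformly over the mask.
mask_offset_to_position <- function(mask, offsets) {
  widths <- mask$end - mask$start
  cum <- cumsum(widths)
  idx <- findInterval(offsets - 1, c(0, cum), rightmost.closed = FALSE)
  within <- offsets - c(0, cum)[idx]
  as.integer(mask$start[idx] + within)
}
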