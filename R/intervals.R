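## Internal interval utilities.
##
## All in-memory coordinates in this package are 0-based half-open.
## IRanges (1-based closed) does the set arithmetic; these helpers own the
## +/-1 conversion so it happens in exactly one place.

## data.frame(start, end) [0-based half-open] -> IRanges
iv_to_iranges <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(IRanges::IRanges())
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

iranges_to_iv <- function(ir) {
  data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

## Union (reduce) of 0-based half-open intervals; optionally merge across
## gaps of <= merge_gap bp.
iv_reduce <- function(iv, merge_gap = 0L) {
  ir <- IRanges::reduce(iv_to_iranges(iv), min.gapwidth = merge_gap + 1L)
  iranges_to_iv(ir)
}

## Total bp covered by the union of intervals.
iv_union_len <- function(iv) {
  sum(BiocGenerics::width(IRanges::reduce(iv_to_iranges(iv))))
}

## Set difference a \ b on 0-based half-open intervals.
iv_setdiff <- function(a, b) {
  ir <- IRanges::setdiff(IRanges::reduce(iv_to_iranges(a)),
                         IRanges::reduce(iv_to_iranges(b)))
  iranges_to_iv(ir)
}

## Logical membership: which 0-based positions `pos` fall in any interval.
iv_contains <- function(iv, pos) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  ir <- IRanges::reduce(iv_to_iranges(iv))
  IRanges::overlapsAny(IRanges::IRanges(pos + 1L, pos + 1L), ir)
}

iv_df <- function(start = integer(), end = integer()) {
  data.frame(start = as.integer(start), end = as.integer(end))
}
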