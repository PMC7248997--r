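# Multivariate dynamic time warping.

#' Dynamic time warping distance between two multichannel windows
#'
#' Dependent multivariate DTW: a single warping path is shared across all
#' channels and the local cost of aligning time points `i` and `j` is the
#' squared Euclidean distance across channels. The classic full dynamic
#' program is used (no Sakoe-Chiba band), so series of different lengths
#' are allowed as long as the channel count matches. The distance is
#' symmetric, nonnegative and zero for identical series.
#'
#' @param a,b Numeric matrices (`length x channels`) or vectors
#'   (univariate series).
#' @return Nonnegative scalar distance.
#' @examples
#' dtw_distance(c(0, 0), c(1, 1))  # 2: both alignments cost 1 each
#' @export
dtw_distance <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, ncol = 1)
  if (is.vector(b)) b <- matrix(b, ncol = 1)
  dtw_distance_cpp(a, b)
}

# All pairwise DTW distances between two window stacks (n x L x 3 arrays).
dtw_cross <- function(query_values, ref_values) {
  dtw_cross_cpp(query_values, ref_values)
}
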