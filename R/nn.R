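#' Exact nearest-neighbour match between point clouds
#'
#' For every row of `query`, the index of (and distance to) the closest
#' row of `target`.  Backed by a compiled brute-force kernel.
#'
#' @param query,target n x 3 numeric matrices (mm).
#' @return list with integer `index` (into `target`) and numeric
#'   `distance` (mm), both of length `nrow(query)`.
#' @useDynLib trident3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @export
nnMatch <- function(query, target) {
  query <- asPointMatrix(query)
  target <- asPointMatrix(target)
  if (nrow(target) == 0L) t3dError("empty target cloud", "domainError")
  .nnMatchCpp(query, target)
}
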