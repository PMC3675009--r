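#' Enumerate all k-position subsets
#'
#' Three-position subsets are the unit of comparison: three points admit a
#' unique rigid superposition, keeping the structural term well defined
#' while still decomposing the binding site.  A 20-position site yields
#' `choose(20, 3) = 1140` subsets; a 27-position site yields 2925.
#'
#' @param P number of positions (or a vector of position identifiers).
#' @param k subset size (default 3).
#' @return integer matrix with `choose(P, k)` rows, one strictly increasing
#'   k-tuple per row, in lexicographic order.
#' @export
#' @examples
#' nrow(enumerate_subsets(20))  # 1140
enumerate_subsets <- function(P, k = 3) {
  items <- if (length(P) == 1L) seq_len(P) else P
  n <- length(items)
  assert_that(k >= 1L && k <= n, "need 1 <= k <= P")
  m <- t(combn(items, k))
  storage.mode(m) <- "integer"
  m
}

#' Least RMSD of two corresponding point sets
#'
#' Optimal translation plus proper rotation (reflections disallowed) via
#' the closed-form SVD solution; correspondence is fixed by row order, as
#' substructure residues correspond through their alignment columns.
#'
#' @param a,b numeric n x 3 matrices (rows = points, Angstrom).
#' @return non-negative least RMSD in Angstrom.
#' @export
superpose_lrmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  assert_that(ncol(a) == 3L && ncol(b) == 3L && nrow(a) == nrow(b),
              "a and b must be n x 3 matrices with equal rows")
  assert_that(all(is.finite(a)) && all(is.finite(b)),
              "coordinates must be finite")
  .lrmsd3_cpp(a, b)
}

#' Combined substructure dissimilarity
#'
#' `D(a, b) = w_struct * lRMSD(a, b) +
#'   w_pharm * sum_i pharm(type_a[i], type_b[i])`
#' over the three alignment-corresponding residues.  Symmetric,
#' non-negative, zero for identical substructures.
#'
#' @param coords_a,coords_b 3 x 3 centroid matrices (rows = residues in
#'   subset order).
#' @param types_a,types_b residue codes, length 3.
#' @param matrix pharmacophore dissimilarity matrix.
#' @param w_struct,w_pharm non-negative term weights (default 1 each; the
#'   published equation's weighting is not recoverable, so both are
#'   exposed as configuration).
#' @return non-negative dissimilarity.
#' @export
substructure_distance <- function(coords_a, types_a, coords_b, types_b,
                                  matrix = default_pharm_matrix(),
                                  w_struct = 1, w_pharm = 1) {
  assert_that(w_struct >= 0 && w_pharm >= 0,
              "weights must be non-negative")
  ta <- aa_one_letter(types_a)
  tb <- aa_one_letter(types_b)
  assert_that(length(ta) == 3L && length(tb) == 3L,
              "substructures carry exactly 3 residues")
  w_struct * superpose_lrmsd(coords_a, coords_b) +
    w_pharm * sum(matrix[cbind(ta, tb)])
}

#' Pairwise distance matrix for one position subset
#'
#' @param set an `aligned_set` (or the dense arrays from an earlier
#'   internal conversion).
#' @param subset integer vector of 3 column indices, all in
#'   `set$position_columns`.
#' @param matrix pharmacophore matrix.
#' @param w_struct,w_pharm term weights.
#' @return symmetric N x N matrix with zero diagonal; `dimnames` carry the
#'   structure ids and attribute `subset` the column triple.
#' @export
distance_matrix <- function(set, subset, matrix = default_pharm_matrix(),
                            w_struct = 1, w_pharm = 1) {
  arrays <- if (inherits(set, "aligned_set")) as_site_arrays(set) else set
  subset <- as.integer(subset)
  assert_that(length(subset) == 3L && all(subset %in% arrays$columns),
              "subset must be 3 columns of the set")
  assert_that(w_struct >= 0 && w_pharm >= 0, "weights must be non-negative")
  matrix <- validate_pharm_matrix(matrix)
  ix <- match(subset, arrays$columns)
  slab <- function(j) {
    m <- arrays$coords[, j, , drop = FALSE]
    dim(m) <- c(dim(m)[1], 3L)
    m
  }
  coords <- cbind(slab(ix[1]), slab(ix[2]), slab(ix[3]))
  types <- arrays$types[, ix, drop = FALSE]
  D <- .pairwise_dist_cpp(coords, types, matrix, w_struct, w_pharm)
  dimnames(D) <- list(arrays$structure_ids, arrays$structure_ids)
  attr(D, "subset") <- subset
  D
}
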