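#' Amino-acid codes and the pharmacophore dissimilarity matrix
#'
#' The chemical term of the substructure distance compares residue types
#' through a symmetric 20 x 20 dissimilarity matrix.  The default matrix is
#' derived from six binary per-residue pharmacophore features (hydrogen-bond
#' donor, hydrogen-bond acceptor, aromatic, positively ionizable, negatively
#' ionizable, hydrophobic): the dissimilarity between two residue types is
#' the number of features on which they differ, times a configurable scale
#' chosen to be commensurate with an Angstrom-scale RMSD.  A replacement
#' matrix (e.g. one transcribed from a published feature set) can be loaded
#' with [read_pharm_matrix()].
#'
#' @name pharm-matrix
NULL

#' One-letter amino-acid codes in the package's fixed (alphabetical) order;
#' this order indexes the pharmacophore matrix everywhere.
#' @rdname pharm-matrix
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# binary pharmacophore features per residue type
# columns: donor, acceptor, aromatic, pos_ionizable, neg_ionizable, hydrophobic
.pharm_features <- local({
  f <- rbind(
    A = c(0, 0, 0, 0, 0, 1),
    C = c(0, 0, 0, 0, 0, 1),
    D = c(0, 1, 0, 0, 1, 0),
    E = c(0, 1, 0, 0, 1, 0),
    F = c(0, 0, 1, 0, 0, 1),
    G = c(0, 0, 0, 0, 0, 0),
    H = c(1, 1, 1, 1, 0, 0),
    I = c(0, 0, 0, 0, 0, 1),
    K = c(1, 0, 0, 1, 0, 0),
    L = c(0, 0, 0, 0, 0, 1),
    M = c(0, 0, 0, 0, 0, 1),
    N = c(1, 1, 0, 0, 0, 0),
    P = c(0, 0, 0, 0, 0, 1),
    Q = c(1, 1, 0, 0, 0, 0),
    R = c(1, 0, 0, 1, 0, 0),
    S = c(1, 1, 0, 0, 0, 0),
    T = c(1, 1, 0, 0, 0, 1),
    V = c(0, 0, 0, 0, 0, 1),
    W = c(1, 0, 1, 0, 0, 1),
    Y = c(1, 1, 1, 0, 0, 1)
  )
  colnames(f) <- c("donor", "acceptor", "aromatic",
                   "pos_ionizable", "neg_ionizable", "hydrophobic")
  f[AA_CODES, , drop = FALSE]
})

#' Normalise residue codes to one-letter form
#'
#' @param x character vector of one- or three-letter residue codes.
#' @return character vector of validated one-letter codes.
#' @export
aa_one_letter <- function(x) {
  x <- toupper(as.character(x))
  three <- nchar(x) == 3L
  x[three] <- unname(AA_THREE[x[three]])
  bad <- is.na(x) | !(x %in% AA_CODES)
  if (any(bad)) {
    stop_triad("unknown residue type(s): ",
               paste(unique(x[bad]), collapse = ", "))
  }
  x
}

#' Default pharmacophore dissimilarity matrix
#'
#' @param scale multiplier applied to the feature-difference counts
#'   (default 1), used to balance the chemical term against the
#'   Angstrom-scale structural term.
#' @return symmetric 20 x 20 numeric matrix with zero diagonal, rows and
#'   columns named by one-letter residue code.
#' @export
#' @examples
#' m <- default_pharm_matrix()
#' m["D", "E"]  # identical feature sets
#' m["D", "F"]  # acidic vs aromatic-hydrophobic
default_pharm_matrix <- function(scale = 1) {
  assert_that(is.numeric(scale) && length(scale) == 1L && scale >= 0,
              "scale must be a single non-negative number")
  f <- .pharm_features
  n <- nrow(f)
  m <- matrix(0, n, n, dimnames = list(AA_CODES, AA_CODES))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- sum(f[i, ] != f[j, ])
    }
  }
  m * scale
}

validate_pharm_matrix <- function(m) {
  assert_that(is.matrix(m) && nrow(m) == 20L && ncol(m) == 20L,
              "pharmacophore matrix must be 20 x 20")
  assert_that(identical(sort(rownames(m)), sort(AA_CODES)) &&
                identical(rownames(m), colnames(m)),
              "pharmacophore matrix must have matching residue-letter dimnames")
  assert_that(all(m >= 0), "pharmacophore dissimilarities must be non-negative")
  assert_that(all(diag(m) == 0), "pharmacophore matrix must have a zero diagonal")
  assert_that(max(abs(m - t(m))) < 1e-9, "pharmacophore matrix must be symmetric")
  m[AA_CODES, AA_CODES]
}

#' Read / write a pharmacophore matrix as CSV
#'
#' The on-disk format is a 20-row CSV whose first column and header carry
#' one-letter residue codes.
#'
#' @param path file path.
#' @return `read_pharm_matrix()` returns a validated 20 x 20 matrix.
#' @export
read_pharm_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_pharm_matrix(m)
}

#' @rdname read_pharm_matrix
#' @param m matrix to write.
#' @export
write_pharm_matrix <- function(m, path) {
  m <- validate_pharm_matrix(m)
  df <- tibble::as_tibble(m)
  df <- tibble::add_column(df, residue = rownames(m), .before = 1)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Pharmacophore dissimilarity between two residue types
#'
#' @param t1,t2 residue codes (one- or three-letter).
#' @param matrix a validated pharmacophore matrix; defaults to
#'   [default_pharm_matrix()].
#' @return non-negative dissimilarity; zero when `t1 == t2`.
#' @export
pharm_dissimilarity <- function(t1, t2, matrix = default_pharm_matrix()) {
  t1 <- aa_one_letter(t1)
  t2 <- aa_one_letter(t2)
  matrix[cbind(t1, t2)]
}
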