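#' Aligned structure sets
#'
#' An aligned structure set holds, for every retained structure, one residue
#' site per selected master-alignment column: the residue type and the
#' side-chain heavy-atom centroid.  It is the common input of the distance,
#' clustering and prediction stages.
#'
#' The tidy representation is a *site table*: one row per
#' (structure, column) pair with columns `structure_id`, `sequence_id`,
#' `family`, `column` (0-based master-alignment column), `residue`
#' (one-letter code) and `x`, `y`, `z` (Angstrom).
#'
#' @param sites site table as described above.  Rows with `NA` residue or
#'   coordinates mark gaps/unresolved residues.
#' @param position_columns integer vector of selected 0-based columns;
#'   defaults to the sorted distinct columns present in `sites`.
#' @param provenance named list recording filtering applied upstream.
#' @return an object of class `aligned_set`: a list with elements `sites`
#'   (tibble), `position_columns` and `provenance`.
#' @export
aligned_structure_set <- function(sites, position_columns = NULL,
                                  provenance = list()) {
  sites <- tibble::as_tibble(sites)
  required <- c("structure_id", "sequence_id", "column", "residue",
                "x", "y", "z")
  missing <- setdiff(required, names(sites))
  assert_that(length(missing) == 0L,
              paste("site table lacks column(s):",
                    paste(missing, collapse = ", ")))
  if (!"family" %in% names(sites)) sites$family <- NA_character_
  sites$column <- as.integer(sites$column)
  if (is.null(position_columns)) {
    position_columns <- sort(unique(sites$column))
  }
  out <- structure(
    list(sites = sites,
         position_columns = as.integer(sort(position_columns)),
         provenance = provenance),
    class = "aligned_set")
  validate_structure_set(out)
  out
}

#' Validate an aligned structure set
#'
#' Checks the container invariants: every retained structure has exactly one
#' non-gap residue site at every selected column, residue codes are valid,
#' and centroids are finite.
#'
#' @param set an `aligned_set`.
#' @return the set, invisibly; errors on violation.
#' @export
validate_structure_set <- function(set) {
  assert_that(inherits(set, "aligned_set"), "not an aligned_set")
  s <- set$sites
  pc <- set$position_columns
  assert_that(length(pc) >= 1L, "no position columns selected")
  keep <- s$column %in% pc
  s <- s[keep, , drop = FALSE]
  assert_that(!anyNA(s$residue) && !anyNA(s$x) && !anyNA(s$y) && !anyNA(s$z),
              "gap or unresolved residue present at a selected column")
  assert_that(all(is.finite(s$x)) && all(is.finite(s$y)) && all(is.finite(s$z)),
              "non-finite centroid coordinates")
  aa_one_letter(s$residue)
  counts <- table(s$structure_id)
  assert_that(all(counts == length(pc)),
              "every structure must cover every selected column exactly once")
  dup <- anyDuplicated(s[, c("structure_id", "column")])
  assert_that(dup == 0L, "duplicate (structure, column) rows")
  invisible(set)
}

#' @export
print.aligned_set <- function(x, ...) {
  st <- structure_table(x)
  cat("<aligned_set> ", nrow(st), " structures / ",
      length(unique(st$sequence_id)), " sequences at ",
      length(x$position_columns), " positions\n", sep = "")
  invisible(x)
}

#' Structure-level metadata of a set
#'
#' @param set an `aligned_set`.
#' @return tibble with one row per structure: `structure_id`, `sequence_id`,
#'   `family`.
#' @export
structure_table <- function(set) {
  dplyr::distinct(set$sites, .data$structure_id, .data$sequence_id,
                  .data$family)
}

#' Build an aligned structure set from a raw site table
#'
#' Structures with a gap or unresolved residue at any selected column are
#' dropped (the conservative reading of the gap filter) and counted in the
#' provenance record.
#'
#' @param sites raw site table (as for [aligned_structure_set()]); missing
#'   rows, `NA` residues or `NA` coordinates at a selected column all count
#'   as gaps.
#' @param columns integer vector of selected 0-based alignment columns.
#' @return an `aligned_set` containing only complete structures, with
#'   provenance counts of the structures dropped.
#' @export
build_structure_set <- function(sites, columns) {
  columns <- as.integer(columns)
  assert_that(length(columns) >= 1L, "empty column list")
  sites <- tibble::as_tibble(sites)
  if (!"family" %in% names(sites)) sites$family <- NA_character_
  sites$column <- as.integer(sites$column)
  sel <- dplyr::filter(sites, .data$column %in% columns)
  ok_row <- !is.na(sel$residue) & !is.na(sel$x) & !is.na(sel$y) & !is.na(sel$z)
  sel <- sel[ok_row, , drop = FALSE]
  cover <- dplyr::count(sel, .data$structure_id)
  complete <- cover$structure_id[cover$n == length(columns)]
  all_ids <- unique(sites$structure_id)
  dropped <- setdiff(all_ids, complete)
  if (length(dropped)) {
    message(length(dropped), " structure(s) dropped for gaps at selected ",
            "columns: ", paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  assert_that(length(complete) >= 1L,
              "no structure covers all selected columns")
  kept <- dplyr::filter(sel, .data$structure_id %in% complete)
  kept <- dplyr::arrange(kept, .data$structure_id, .data$column)
  aligned_structure_set(
    kept, position_columns = columns,
    provenance = list(n_input = length(all_ids),
                      n_retained = length(complete),
                      n_dropped_gaps = length(dropped),
                      dropped = dropped))
}

# Internal dense representation used by the distance stage: per-structure
# coordinate and residue-type-index arrays in fixed column order.
as_site_arrays <- function(set) {
  validate_structure_set(set)
  s <- dplyr::filter(set$sites, .data$column %in% set$position_columns)
  s <- dplyr::arrange(s, .data$structure_id, .data$column)
  ids <- unique(s$structure_id)
  P <- length(set$position_columns)
  N <- length(ids)
  coords <- array(NA_real_, dim = c(N, P, 3))
  types <- matrix(NA_integer_, N, P)
  idx <- match(s$structure_id, ids)
  cix <- match(s$column, set$position_columns)
  coords[cbind(idx, cix, 1L)] <- s$x
  coords[cbind(idx, cix, 2L)] <- s$y
  coords[cbind(idx, cix, 3L)] <- s$z
  types[cbind(idx, cix)] <- match(aa_one_letter(s$residue), AA_CODES)
  list(structure_ids = ids, columns = set$position_columns,
       coords = coords, types = types)
}
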