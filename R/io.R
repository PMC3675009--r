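#' Side-chain heavy-atom centroid of a residue
#'
#' The structural term of the substructure distance compares residues by
#' their side-chain centroid: the arithmetic mean of the side-chain heavy
#' atoms (backbone N, CA, C, O and terminal OXT excluded, hydrogens
#' ignored).  Glycine, which has no side-chain heavy atom, falls back to its
#' CA position.
#'
#' @param atoms data frame of a single residue's atoms with columns `elety`
#'   (atom name, PDB convention), `x`, `y`, `z`, and optionally `elesy`
#'   (element symbol, used to drop hydrogens).
#' @return numeric 3-vector (Angstrom).
#' @export
extract_sidechain_centroid <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  assert_that(all(c("elety", "x", "y", "z") %in% names(atoms)),
              "atoms need columns elety, x, y, z")
  name <- toupper(trimws(atoms$elety))
  if ("elesy" %in% names(atoms)) {
    hyd <- toupper(trimws(atoms$elesy)) %in% c("H", "D")
  } else {
    hyd <- grepl("^[0-9]*[HD]", name)
  }
  atoms <- atoms[!hyd, , drop = FALSE]
  name <- name[!hyd]
  backbone <- name %in% c("N", "CA", "C", "O", "OXT")
  side <- atoms[!backbone, , drop = FALSE]
  if (nrow(side) == 0L) {
    ca <- atoms[name == "CA", , drop = FALSE]
    assert_that(nrow(ca) >= 1L,
                "malformed residue: no side-chain heavy atoms and no CA")
    return(c(ca$x[1], ca$y[1], ca$z[1]))
  }
  c(mean(side$x), mean(side$y), mean(side$z))
}

#' Binding-site position specification
#'
#' Either an explicit list of master-alignment columns, or a reference
#' structure plus a ligand-proximity cutoff (every residue with at least one
#' atom within `cutoff` Angstrom of at least one ligand atom is selected).
#' Candidate columns whose alignment gap fraction exceeds
#' `max_gap_fraction` are discarded as highly gapped.
#'
#' @param mode `"explicit"` or `"proximity"`.
#' @param columns 0-based alignment columns (explicit mode).
#' @param reference_structure_id,ligand_id,cutoff proximity-mode settings;
#'   `cutoff` in Angstrom (the kinome analysis this package mirrors used
#'   5 Angstrom around a bound type II inhibitor).
#' @param max_gap_fraction columns with a higher gap fraction are dropped
#'   (default 0.5).
#' @return a `position_spec` list.
#' @export
position_spec <- function(mode = c("explicit", "proximity"),
                          columns = NULL, reference_structure_id = NULL,
                          ligand_id = NULL, cutoff = 5,
                          max_gap_fraction = 0.5) {
  mode <- match.arg(mode)
  if (mode == "explicit") {
    assert_that(length(columns) >= 1L, "explicit mode needs columns")
  } else {
    assert_that(is.numeric(cutoff) && cutoff > 0, "cutoff must be > 0")
    assert_that(!is.null(ligand_id), "proximity mode needs a ligand_id")
  }
  assert_that(max_gap_fraction >= 0 && max_gap_fraction <= 1,
              "max_gap_fraction must be in [0, 1]")
  structure(list(mode = mode, columns = as.integer(columns),
                 reference_structure_id = reference_structure_id,
                 ligand_id = ligand_id, cutoff = cutoff,
                 max_gap_fraction = max_gap_fraction),
            class = "position_spec")
}

#' Select binding-site alignment columns by ligand proximity
#'
#' @param atom_table atom records of the reference structure (one row per
#'   atom) with columns `elety`, `resno`, `resid`, `x`, `y`, `z`, and
#'   `type` (`"ATOM"`/`"HETATM"`); a bio3d `pdb` object's `$atom` table
#'   works directly.
#' @param spec a [position_spec()] in proximity mode.
#' @param residue_columns tibble mapping the reference structure's residues
#'   to alignment columns: columns `resno` and `column` (0-based).
#' @param msa optional named character vector of aligned sequences (gap
#'   `-`/`.`); when given, candidate columns whose gap fraction exceeds
#'   `spec$max_gap_fraction` are removed.
#' @return sorted integer vector of selected 0-based columns.
#' @export
select_binding_site_positions <- function(atom_table, spec, residue_columns,
                                          msa = NULL) {
  assert_that(inherits(spec, "position_spec") && spec$mode == "proximity",
              "spec must be a proximity-mode position_spec")
  atom_table <- tibble::as_tibble(atom_table)
  lig <- dplyr::filter(atom_table, .data$resid == spec$ligand_id)
  assert_that(nrow(lig) > 0L,
              paste0("ligand '", spec$ligand_id, "' absent from structure"))
  prot <- dplyr::filter(atom_table, .data$resid %in% names(AA_THREE))
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  # min distance from each protein atom to any ligand atom
  d2 <- outer(rowSums(pxyz^2), rep(1, nrow(lxyz))) +
    outer(rep(1, nrow(pxyz)), rowSums(lxyz^2)) - 2 * pxyz %*% t(lxyz)
  near <- sqrt(pmax(apply(d2, 1, min), 0)) <= spec$cutoff
  resnos <- sort(unique(prot$resno[near]))
  cols <- residue_columns$column[match(resnos, residue_columns$resno)]
  cols <- sort(unique(cols[!is.na(cols)]))
  if (!is.null(msa)) {
    gf <- vapply(cols, function(cc) gap_fraction(msa, cc), numeric(1))
    cols <- cols[gf <= spec$max_gap_fraction]
  }
  assert_that(length(cols) > 0L, "no columns survive position selection")
  as.integer(cols)
}

#' Gap fraction of an alignment column
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param column 0-based column index.
#' @return fraction of sequences with a gap (`-` or `.`) at that column.
#' @export
gap_fraction <- function(msa, column) {
  ch <- substr(msa, column + 1L, column + 1L)
  mean(ch %in% c("-", "."))
}

#' Read a multiple sequence alignment
#'
#' Thin wrapper over Biostrings for aligned FASTA and Stockholm files,
#' returned as a named character vector of equal-length rows.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return named character vector of aligned sequences.
#' @export
read_msa <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aln <- Biostrings::readAAMultipleAlignment(path, format = format)
    seqs <- as.character(Biostrings::unmasked(aln))
  } else {
    assert_that(format == "fasta",
                "Stockholm reading requires the Biostrings package")
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0,
                   character(1), collapse = "")
    names(seqs) <- ids
  }
  assert_that(length(unique(nchar(seqs))) == 1L,
              "alignment rows have unequal length")
  toupper(seqs)
}

#' Map a structure's residues to master-alignment columns
#'
#' Matches the structure's one-letter residue sequence as an exact substring
#' of the ungapped alignment row for its sequence, and returns the 0-based
#' column of each residue.
#'
#' @param resno integer residue numbers, in sequence order.
#' @param restype residue codes (one- or three-letter), same length.
#' @param msa_row one aligned sequence (single string, gaps `-`/`.`).
#' @return tibble with columns `resno`, `column`.
#' @export
map_residues_to_columns <- function(resno, restype, msa_row) {
  one <- aa_one_letter(restype)
  chars <- strsplit(msa_row, "")[[1]]
  non_gap <- which(!chars %in% c("-", "."))
  ungapped <- paste0(chars[non_gap], collapse = "")
  hit <- regexpr(paste0(one, collapse = ""), ungapped, fixed = TRUE)
  assert_that(hit > 0L,
              "structure sequence not found in the alignment row")
  offset <- as.integer(hit) - 1L
  tibble::tibble(resno = as.integer(resno),
                 column = non_gap[offset + seq_along(one)] - 1L)
}

#' Build a site table from a PDB structure
#'
#' Extracts one residue site (type + side-chain centroid) per mapped
#' alignment column from a bio3d-read structure.
#'
#' @param pdb a bio3d `pdb` object (from `bio3d::read.pdb()` or
#'   `bio3d::read.cif()`).
#' @param structure_id,sequence_id identifiers for the emitted rows.
#' @param residue_columns tibble with `resno`, `column` (0-based), e.g.
#'   from [map_residues_to_columns()].
#' @param chain optional chain identifier to restrict to.
#' @param family optional family label.
#' @return site table tibble (see [aligned_structure_set()]).
#' @export
sites_from_pdb <- function(pdb, structure_id, sequence_id, residue_columns,
                           chain = NULL, family = NA_character_) {
  atoms <- tibble::as_tibble(pdb$atom)
  atoms <- dplyr::filter(atoms, .data$type == "ATOM")
  if (!is.null(chain)) atoms <- dplyr::filter(atoms, .data$chain == !!chain)
  # highest-occupancy alternate conformer per atom name within a residue
  if ("alt" %in% names(atoms) && "o" %in% names(atoms)) {
    atoms <- atoms |>
      dplyr::group_by(.data$resno, .data$elety) |>
      dplyr::slice_max(.data$o, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  rows <- purrr::pmap(residue_columns, function(resno, column) {
    res <- dplyr::filter(atoms, .data$resno == !!resno)
    if (nrow(res) == 0L) {
      return(tibble::tibble(column = column, residue = NA_character_,
                            x = NA_real_, y = NA_real_, z = NA_real_))
    }
    cen <- tryCatch(extract_sidechain_centroid(res), error = function(e) NULL)
    restype <- tryCatch(aa_one_letter(res$resid[1]),
                        error = function(e) NA_character_)
    if (is.null(cen) || is.na(restype)) {
      return(tibble::tibble(column = column, residue = NA_character_,
                            x = NA_real_, y = NA_real_, z = NA_real_))
    }
    tibble::tibble(column = column, residue = restype,
                   x = cen[1], y = cen[2], z = cen[3])
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(structure_id = structure_id, sequence_id = sequence_id,
                  family = family, .before = 1)
}

#' Bin affinity values into binary labels
#'
#' Dissociation constants at or below the threshold map to `"true"`
#' (binding), above it to `"false"`; missing values become `"unknown"`.
#' The default threshold is 10,000 nM (10 micromolar), the largest Kd
#' conventionally considered meaningful for inhibitor binding.
#'
#' @param kd_table tibble with columns `sequence_id`, `compound_id`,
#'   `kd_nm` (positive or `NA`).
#' @param threshold_nm binning threshold in nM.
#' @return label table tibble: `sequence_id`, `compound_id`, `label` in
#'   `"true"`/`"false"`/`"unknown"`.
#' @export
bin_affinities <- function(kd_table, threshold_nm = 10000) {
  kd_table <- tibble::as_tibble(kd_table)
  assert_that(all(c("sequence_id", "compound_id", "kd_nm") %in%
                    names(kd_table)),
              "kd_table needs sequence_id, compound_id, kd_nm")
  kd <- kd_table$kd_nm
  assert_that(all(is.na(kd) | kd > 0), "Kd values must be positive")
  dplyr::mutate(
    kd_table,
    label = dplyr::case_when(
      is.na(.data$kd_nm) ~ "unknown",
      .data$kd_nm <= threshold_nm ~ "true",
      TRUE ~ "false"),
    .keep = "unused")
}

#' Read a label table from CSV
#'
#' Accepts either raw affinities (header `sequence_id,compound_id,kd_nm`,
#' binned via [bin_affinities()]) or pre-binned labels (header
#' `sequence_id,compound_id,label`).
#'
#' @param path CSV file.
#' @param threshold_nm binning threshold for the affinity variant.
#' @return label table tibble.
#' @export
read_label_table <- function(path, threshold_nm = 10000) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("kd_nm" %in% names(df)) {
    return(bin_affinities(df, threshold_nm))
  }
  assert_that("label" %in% names(df),
              "label CSV needs a kd_nm or label column")
  df$label[is.na(df$label)] <- "unknown"
  assert_that(all(df$label %in% c("true", "false", "unknown")),
              "labels must be true/false/unknown")
  tibble::as_tibble(df)
}

#' Look up labels for one compound
#'
#' @param labels label table tibble.
#' @param compound_id compound to extract.
#' @return named character vector sequence_id -> label; sequences absent
#'   from the table are implicitly `"unknown"`.
#' @export
compound_labels <- function(labels, compound_id) {
  sub <- dplyr::filter(labels, .data$compound_id == !!compound_id)
  assert_that(nrow(sub) > 0L,
              paste0("compound '", compound_id, "' absent from label table"))
  setNames(sub$label, sub$sequence_id)
}

#' Read / write a site table as CSV
#'
#' @param path CSV file with the site-table columns (see
#'   [aligned_structure_set()]).
#' @return `read_site_table()` returns a tibble.
#' @export
read_site_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    structure_id = readr::col_character(),
                    sequence_id = readr::col_character(),
                    column = readr::col_integer(),
                    residue = readr::col_character()))
}

#' @rdname read_site_table
#' @param sites site table tibble to write.
#' @export
write_site_table <- function(sites, path) {
  readr::write_csv(tibble::as_tibble(sites), path, progress = FALSE)
  invisible(path)
}
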