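#' Synthetic aligned-structure datasets with planted signal
#'
#' Generates a seeded dataset that emulates the statistical structure the
#' method assumes: several structures per sequence with non-uniform counts,
#' a shared background geometry at most positions, and a small number of
#' *signal* position subsets where true- and false-labeled sequences adopt
#' distinct, well-separated geometric/residue-type archetypes.  Multiple
#' archetypes per class mimic the observation that several structurally
#' distinct versions of the same substructure can all be associated with
#' binding.
#'
#' @param n_sequences number of distinct sequences.
#' @param structures_per_sequence mean structure count per sequence;
#'   counts are drawn as `1 + Geometric` with this mean, emulating the
#'   skewed distribution of crystal structures per protein.
#' @param P number of aligned positions (columns `0 .. P-1`).
#' @param n_families number of family labels, assigned round-robin so that
#'   archetypes span families.
#' @param signal_subsets list of 0-based column triples carrying signal.
#' @param n_signal_archetypes distinct archetypes per class per signal
#'   subset.
#' @param geometric_noise_sd per-structure coordinate jitter at signal
#'   positions (Angstrom).
#' @param background_noise_sd jitter at background positions (Angstrom).
#' @param label_noise_rate fraction of known labels flipped.
#' @param fraction_true fraction of sequences whose true label is
#'   `"true"`.
#' @param fraction_unlabeled fraction of sequences masked to `"unknown"`
#'   in the emitted label table.
#' @param compound_id compound name used in the label table.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_sequences = 60, structures_per_sequence = 2,
                         P = 27, n_families = 4,
                         signal_subsets = list(c(1L, 5L, 9L),
                                               c(12L, 17L, 22L)),
                         n_signal_archetypes = 2,
                         geometric_noise_sd = 0.1,
                         background_noise_sd = 0.5,
                         label_noise_rate = 0, fraction_true = 0.5,
                         fraction_unlabeled = 0.25,
                         compound_id = "cmpd-1") {
  cfg <- list(n_sequences = as.integer(n_sequences),
              structures_per_sequence = structures_per_sequence,
              P = as.integer(P), n_families = as.integer(n_families),
              signal_subsets = lapply(signal_subsets, as.integer),
              n_signal_archetypes = as.integer(n_signal_archetypes),
              geometric_noise_sd = geometric_noise_sd,
              background_noise_sd = background_noise_sd,
              label_noise_rate = label_noise_rate,
              fraction_true = fraction_true,
              fraction_unlabeled = fraction_unlabeled,
              compound_id = compound_id)
  assert_that(cfg$n_sequences >= 2 && cfg$P >= 3 && cfg$n_families >= 1,
              "counts must be positive (and P >= 3)")
  assert_that(cfg$structures_per_sequence >= 1,
              "structures_per_sequence must be >= 1")
  rates <- c(cfg$label_noise_rate, cfg$fraction_true,
             cfg$fraction_unlabeled)
  assert_that(all(rates >= 0 & rates <= 1), "rates must lie in [0, 1]")
  ok_cols <- vapply(cfg$signal_subsets, function(s) {
    length(s) == 3L && all(s >= 0L & s < cfg$P) && !anyDuplicated(s)
  }, logical(1))
  assert_that(all(ok_cols), "signal subsets must be 3 distinct columns < P")
  assert_that(cfg$n_signal_archetypes >= 1 &&
                cfg$n_signal_archetypes <= cfg$n_sequences,
              "more archetypes than sequences per class")
  structure(cfg, class = "synth_config")
}

# sample a well-separated 3-point constellation near the given anchors
.sample_archetype <- function(anchors, existing, min_sep, max_tries = 2000) {
  for (t in seq_len(max_tries)) {
    pts <- anchors + base::matrix(runif(9, -5, 5), 3, 3)
    ok <- all(vapply(existing,
                     function(e) superpose_lrmsd(pts, e) >= min_sep,
                     logical(1)))
    if (ok) return(pts)
  }
  stop_triad("could not place a separated archetype; ",
             "lower n_signal_archetypes or the noise level")
}

#' Generate a synthetic dataset
#'
#' Fully reproducible from `seed`: the same seed yields byte-identical
#' output.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return list with `set` (an `aligned_set`), `labels` (label table as
#'   emitted, after masking and label noise), `families` tibble, `truth`
#'   (pre-noise per-sequence labels, families, per-subset archetype ids)
#'   and `sequences` (named character vector: per-sequence residue string
#'   over the P columns, usable as the aligned domain for identity folds).
#' @export
synth_generate <- function(config = synth_config(), seed = 1) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  with_seed(seed, .synth_generate_impl(config))
}

.synth_generate_impl <- function(cfg) {
  n <- cfg$n_sequences
  P <- cfg$P
  seq_ids <- sprintf("seq%03d", seq_len(n))
  families <- paste0("fam", (seq_len(n) - 1L) %% cfg$n_families + 1L)
  n_true <- round(cfg$fraction_true * n)
  true_seqs <- sample(seq_ids, n_true)
  true_label <- ifelse(seq_ids %in% true_seqs, "true", "false")
  # column anchor geometry: coarse 3-D grid, 8 A spacing
  j <- seq_len(P) - 1L
  anchors <- cbind(8 * (j %% 3L), 8 * ((j %/% 3L) %% 3L), 8 * (j %/% 9L))
  # residue types: uniform background per sequence
  restype <- base::matrix(sample(AA_CODES, n * P, replace = TRUE), n, P)
  # archetype margin: 5 sigma of the coordinate jitter, floored at 2 A and
  # capped by the sampling-box scale (beyond that, noise genuinely swamps
  # the planted separation, which is the point of high-noise settings)
  min_sep <- min(max(5 * cfg$geometric_noise_sd, 2), 3.5)
  # archetypes per signal subset: geometry + residue triple per archetype,
  # classes get disjoint archetype sets
  arch <- list()
  arch_assign <- list()
  for (si in seq_along(cfg$signal_subsets)) {
    sub <- cfg$signal_subsets[[si]]
    sub_anchors <- anchors[sub + 1L, , drop = FALSE]
    geoms <- list()
    meta <- list()
    for (class in c("true", "false")) {
      for (a in seq_len(cfg$n_signal_archetypes)) {
        pts <- .sample_archetype(sub_anchors, geoms, min_sep)
        geoms[[length(geoms) + 1L]] <- pts
        meta[[length(meta) + 1L]] <- list(
          id = paste0(class, "-", a), class = class, geometry = pts,
          residues = sample(AA_CODES, 3, replace = TRUE))
      }
    }
    arch[[si]] <- meta
    classes <- vapply(meta, function(m) m$class, character(1))
    pick <- vapply(seq_len(n), function(i) {
      candidates <- which(classes == true_label[i])
      candidates[sample.int(length(candidates), 1L)]
    }, integer(1))
    arch_assign[[si]] <- pick
    # archetype-specific residue types at the signal columns
    for (i in seq_len(n)) {
      restype[i, sub + 1L] <- meta[[pick[i]]]$residues
    }
  }
  # structure counts: 1 + geometric, emulating skewed crystal coverage
  p_geom <- 1 / cfg$structures_per_sequence
  n_structs <- 1L + stats::rgeom(n, p_geom)
  site_rows <- vector("list", n)
  for (i in seq_len(n)) {
    per_struct <- vector("list", n_structs[i])
    for (s in seq_len(n_structs[i])) {
      xyz <- anchors + base::matrix(
        rnorm(P * 3, sd = cfg$background_noise_sd), P, 3)
      for (si in seq_along(cfg$signal_subsets)) {
        sub <- cfg$signal_subsets[[si]]
        pts <- arch[[si]][[arch_assign[[si]][i]]]$geometry
        xyz[sub + 1L, ] <- pts + base::matrix(
          rnorm(9, sd = cfg$geometric_noise_sd), 3, 3)
      }
      per_struct[[s]] <- tibble::tibble(
        structure_id = sprintf("%s_x%02d", seq_ids[i], s),
        sequence_id = seq_ids[i], family = families[i],
        column = j, residue = restype[i, ],
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }
    site_rows[[i]] <- dplyr::bind_rows(per_struct)
  }
  sites <- dplyr::bind_rows(site_rows)
  set <- aligned_structure_set(sites, position_columns = j,
                               provenance = list(generator = "synthetic"))
  # emitted labels: mask a fraction to unknown, flip a fraction of the rest
  observed <- true_label
  masked <- sample(seq_ids, round(cfg$fraction_unlabeled * n))
  observed[seq_ids %in% masked] <- "unknown"
  if (cfg$label_noise_rate > 0) {
    flip <- observed != "unknown" & runif(n) < cfg$label_noise_rate
    observed[flip] <- ifelse(observed[flip] == "true", "false", "true")
  }
  labels <- tibble::tibble(sequence_id = seq_ids,
                           compound_id = cfg$compound_id,
                           label = observed)
  archetype_tbl <- dplyr::bind_rows(lapply(seq_along(arch_assign),
    function(si) {
      tibble::tibble(
        sequence_id = seq_ids, signal_subset = si,
        archetype = vapply(arch_assign[[si]],
                           function(k) arch[[si]][[k]]$id, character(1)))
    }))
  truth <- list(
    sequences = tibble::tibble(sequence_id = seq_ids, family = families,
                               true_label = true_label,
                               n_structures = n_structs),
    archetypes = archetype_tbl,
    signal_subsets = cfg$signal_subsets)
  seq_strings <- setNames(
    apply(restype, 1, paste0, collapse = ""), seq_ids)
  list(set = set, labels = labels,
       families = tibble::tibble(sequence_id = seq_ids, family = families),
       truth = truth, sequences = seq_strings, config = cfg)
}

#' Write / read a synthetic dataset through the public file formats
#'
#' Emits exactly the formats the readers consume: a site-table CSV, an
#' aligned FASTA of the per-sequence residue strings, and label/family
#' CSVs.
#'
#' @param data result of [synth_generate()].
#' @param dir output directory (created if needed).
#' @return `synth_write()` returns `dir` invisibly; `synth_read()` returns
#'   a list with `set`, `labels`, `families`, `sequences`.
#' @export
synth_write <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_site_table(data$set$sites, file.path(dir, "sites.csv"))
  readr::write_csv(data$labels, file.path(dir, "labels.csv"),
                   progress = FALSE)
  readr::write_csv(data$families, file.path(dir, "families.csv"),
                   progress = FALSE)
  writeLines(paste0(">", names(data$sequences), "\n", data$sequences),
             file.path(dir, "msa.fasta"))
  invisible(dir)
}

#' @rdname synth_write
#' @export
synth_read <- function(dir) {
  sites <- read_site_table(file.path(dir, "sites.csv"))
  set <- build_structure_set(sites, sort(unique(sites$column)))
  labels <- read_label_table(file.path(dir, "labels.csv"))
  families <- readr::read_csv(file.path(dir, "families.csv"),
                              show_col_types = FALSE, progress = FALSE)
  msa <- read_msa(file.path(dir, "msa.fasta"), format = "fasta")
  list(set = set, labels = labels, families = families, sequences = msa)
}

#' Hand-written micro-fixture
#'
#' A deterministic toy dataset (six sequences, twelve structures, five
#' positions) exercising every code path: one structure excluded for a gap
#' at a selected column, a glycine site, unknown labels, and one far
#' outlier structure that ends up a singleton in every clustering and so
#' receives zero votes.
#'
#' @return list with `raw_sites` (before gap filtering), `set`, `labels`,
#'   `families`, `sequences` (aligned residue strings).
#' @export
worked_example_fixture <- function() {
  columns <- 0:4
  anchors <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0),
                   c(8, 8, 0), c(4, 4, 6))
  res_true <- c("A", "K", "D", "F", "S")
  res_false <- c("W", "E", "R", "G", "T")   # includes a glycine site
  shift_false <- c(3, 0, 0)
  mk <- function(structure_id, sequence_id, res, shift, jitter) {
    xyz <- sweep(anchors, 2, shift, "+") + jitter
    tibble::tibble(structure_id = structure_id, sequence_id = sequence_id,
                   column = columns, residue = res,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  jit <- function(k) base::matrix(0.1 * ((seq_len(15) %% 7) - 3) * k,
                                  5, 3)
  rows <- list(
    mk("sA_x1", "sA", res_true, c(0, 0, 0), jit(1)),
    mk("sA_x2", "sA", res_true, c(0, 0, 0), jit(2)),
    mk("sB_x1", "sB", res_true, c(0, 0, 0), jit(3)),
    mk("sB_x2", "sB", res_true, c(0, 0, 0), jit(-1)),
    mk("sC_x1", "sC", res_false, shift_false, jit(1)),
    mk("sC_x2", "sC", res_false, shift_false, jit(-2)),
    mk("sD_x1", "sD", res_false, shift_false, jit(2)),
    mk("sD_x2", "sD", res_false, shift_false, jit(-3)),
    mk("sE_x1", "sE", res_true, c(0, 0, 0), jit(4)),
    mk("sE_x2", "sE", res_true, c(0, 0, 0), jit(-4)),
    mk("sF_x1", "sF", c("G", "G", "G", "G", "G"), c(60, 60, 60), jit(1)))
  # one structure with a gap at a selected column -> excluded by the filter
  gap <- mk("sE_x3", "sE", res_true, c(0, 0, 0), jit(5))
  gap$residue[4] <- NA_character_
  gap$x[4] <- NA_real_; gap$y[4] <- NA_real_; gap$z[4] <- NA_real_
  raw_sites <- dplyr::bind_rows(c(rows, list(gap)))
  fams <- tibble::tibble(
    sequence_id = c("sA", "sB", "sC", "sD", "sE", "sF"),
    family = c("famA", "famB", "famA", "famB", "famC", "famC"))
  raw_sites$family <- fams$family[match(raw_sites$sequence_id,
                                        fams$sequence_id)]
  set <- suppressMessages(build_structure_set(raw_sites, columns))
  labels <- tibble::tibble(
    sequence_id = c("sA", "sB", "sC", "sD", "sE", "sF"),
    compound_id = "toy-compound",
    label = c("true", "true", "false", "false", "unknown", "unknown"))
  seqs <- setNames(
    c(paste0(res_true, collapse = ""), paste0(res_true, collapse = ""),
      paste0(res_false, collapse = ""), paste0(res_false, collapse = ""),
      paste0(res_true, collapse = ""), "GGGGG"),
    fams$sequence_id)
  list(raw_sites = raw_sites, set = set, labels = labels,
       families = fams, sequences = seqs)
}
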