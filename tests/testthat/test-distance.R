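test_that("lRMSD is zero under identity and rigid motions", {
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(superpose_lrmsd(a, a), 0)
  expect_equal(superpose_lrmsd(a, a + 5), 0)
  set.seed(11)
  for (i in 1:25) {
    R <- random_rotation()
    b <- a %*% t(R) + matrix(rnorm(3), 3, 3, byrow = TRUE)
    expect_lt(superpose_lrmsd(a, b), 1e-6)
  }
})

test_that("lRMSD matches the brute-force rotation oracle", {
  # the fixed instance: a unit triangle vs its doubling
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  b <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  expect_equal(superpose_lrmsd(a, b), brute_lrmsd(a, b), tolerance = 1e-3)
  set.seed(22)
  for (i in 1:100) {
    p <- matrix(rnorm(9, sd = 3), 3, 3)
    q <- matrix(rnorm(9, sd = 3), 3, 3)
    expect_equal(superpose_lrmsd(p, q), brute_lrmsd(p, q),
                 tolerance = 1e-3)
  }
})

test_that("mirrored triads agree with the proper-rotation oracle", {
  # three points are always coplanar, so a mirror image is reachable by a
  # proper rotation; the reflection guard must not inflate the distance
  a <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 1))
  b <- a %*% diag(c(1, 1, -1))
  expect_equal(superpose_lrmsd(a, b), brute_lrmsd(a, b), tolerance = 1e-3)
  expect_lt(superpose_lrmsd(a, b), 1e-3)
})

test_that("degenerate coincident points still yield a defined RMSD", {
  a <- matrix(0, 3, 3)
  b <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))
  expect_equal(superpose_lrmsd(a, b), 0)
  expect_equal(superpose_lrmsd(a, a), 0)
})

test_that("pharmacophore dissimilarity is a symmetric zero-diagonal score", {
  m <- default_pharm_matrix()
  expect_equal(pharm_dissimilarity("A", "A", m), 0)
  expect_equal(unname(diag(m)), rep(0, 20))
  # chemically similar pair scores below a dissimilar pair
  expect_lt(pharm_dissimilarity("D", "E", m),
            pharm_dissimilarity("D", "F", m))
  expect_true(all(m == t(m)))
  expect_true(all(m >= 0))
  expect_error(pharm_dissimilarity("Z", "A", m), "unknown residue")
  # three-letter codes accepted
  expect_equal(pharm_dissimilarity("ASP", "GLU", m),
               pharm_dissimilarity("D", "E", m))
})

test_that("pharmacophore matrix round-trips through CSV", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  m <- default_pharm_matrix(scale = 0.5)
  write_pharm_matrix(m, tmp)
  expect_equal(read_pharm_matrix(tmp), m)
})

test_that("substructure distance combines the two terms as a weighted sum", {
  co <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  m <- default_pharm_matrix()
  expect_equal(substructure_distance(co, c("A", "K", "D"),
                                     co, c("A", "K", "D"), m), 0)
  # same coordinates, one residue type differs: only the chemical term
  expect_equal(substructure_distance(co, c("A", "K", "D"),
                                     co, c("A", "K", "F"), m,
                                     w_pharm = 2.5),
               2.5 * m["D", "F"])
  set.seed(33)
  for (i in 1:10) {
    ca <- matrix(rnorm(9), 3, 3); cb <- matrix(rnorm(9), 3, 3)
    ta <- sample(rownames(m), 3, replace = TRUE)
    tb <- sample(rownames(m), 3, replace = TRUE)
    expect_equal(substructure_distance(ca, ta, cb, tb, m),
                 substructure_distance(cb, tb, ca, ta, m))
    expect_gte(substructure_distance(ca, ta, cb, tb, m), 0)
  }
  expect_error(substructure_distance(co, c("A", "K", "D"), co,
                                     c("A", "K", "D"), m, w_struct = -1),
               "non-negative")
})

test_that("distance matrices are symmetric with exact self-consistency", {
  fx <- worked_example_fixture()
  set <- fx$set
  sub <- set$position_columns[1:3]
  D <- distance_matrix(set, sub)
  expect_true(isSymmetric(unclass(D), tol = 1e-9))
  expect_equal(unname(diag(D)), rep(0, nrow(D)))

  # spot-check entries against direct substructure_distance calls
  arrays <- triadclust:::as_site_arrays(set)
  ix <- match(sub, arrays$columns)
  set.seed(44)
  pick <- cbind(sample(nrow(D), 5), sample(nrow(D) - 1, 5))
  pick[, 2] <- ifelse(pick[, 2] >= pick[, 1], pick[, 2] + 1L, pick[, 2])
  for (r in seq_len(5)) {
    i <- pick[r, 1]; j <- pick[r, 2]
    ca <- t(vapply(ix, function(k) arrays$coords[i, k, ], numeric(3)))
    cb <- t(vapply(ix, function(k) arrays$coords[j, k, ], numeric(3)))
    ta <- AA_CODES[arrays$types[i, ix]]
    tb <- AA_CODES[arrays$types[j, ix]]
    expect_equal(D[i, j], substructure_distance(ca, ta, cb, tb),
                 tolerance = 1e-8)
  }

  # duplicated structure: identical rows, zero between the copies
  dup <- set$sites |>
    dplyr::filter(structure_id == "sA_x1") |>
    dplyr::mutate(structure_id = "sA_x1copy")
  set2 <- aligned_structure_set(dplyr::bind_rows(set$sites, dup),
                                set$position_columns)
  D2 <- distance_matrix(set2, sub)
  expect_equal(D2["sA_x1", "sA_x1copy"], 0, tolerance = 1e-6)
  expect_equal(unname(D2["sA_x1", -c(1, nrow(D2))]),
               unname(D2["sA_x1copy", -c(1, nrow(D2))]), tolerance = 1e-6)
})

test_that("subset enumeration is lexicographic and complete", {
  expect_equal(nrow(enumerate_subsets(20)), 1140L)
  expect_equal(nrow(enumerate_subsets(27)), 2925L)
  expect_equal(nrow(enumerate_subsets(3)), 1L)
  expect_error(enumerate_subsets(2, k = 3), "1 <= k <= P")
  for (P in 3:30) {
    expect_equal(nrow(enumerate_subsets(P)), choose(P, 3))
  }
  s <- enumerate_subsets(5)
  expect_true(all(s[, 1] < s[, 2] & s[, 2] < s[, 3]))
  # lexicographic order
  key <- s[, 1] * 100 + s[, 2] * 10 + s[, 3]
  expect_true(all(diff(key) > 0))
  # enumeration over actual column ids
  cols <- c(0L, 4L, 7L, 9L)
  sc <- enumerate_subsets(cols)
  expect_equal(nrow(sc), choose(4, 3))
  expect_true(all(sc %in% cols))
})
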