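test_that("candidate detection honors the distance cutoff", {
  # Asp OD1 placed 3.0 A from Lys NZ, static -> one pair
  ens <- read_structure(write_tmp_pdb(asp_lys_pdb_text(d_od1_nz = 3.0)))
  pairs <- find_candidate_pairs(ens)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$acidic, "ASP1.A")
  expect_equal(pairs$basic, "LYS5.B")

  # same geometry at 9 A -> none at the default 8 A cutoff
  far <- read_structure(write_tmp_pdb(asp_lys_pdb_text(d_od1_nz = 9.0,
                                                       d_od2_nz = 11.0)))
  expect_equal(nrow(find_candidate_pairs(far)), 0)
  expect_equal(nrow(find_candidate_pairs(far, cutoff = 12)), 1)

  # no charged residues -> empty, not an error
  plain <- read_structure(write_tmp_pdb(tiny_pdb_text()))
  expect_equal(nrow(find_candidate_pairs(plain)), 0)
})

test_that("candidate detection equals a brute-force all-pairs scan", {
  toy <- toy_complex_topology(10, 3, 8, 0.6, seed = 5)
  spec <- synthetic_spec(toy$topology, toy$coords, amplitudes = 0.4,
                         n_frames = 6, seed = 6)
  ens <- generate_ensemble(spec)
  pairs <- find_candidate_pairs(ens, cutoff = 8)

  g <- ens$topology$charged_groups
  acid <- Filter(function(x) x$polarity == "acidic", g)
  base <- Filter(function(x) x$polarity == "basic", g)
  found <- character()
  for (ga in acid) for (gb in base) {
    hit <- FALSE
    for (t in seq_len(n_frames(ens))) {
      x <- frame_coords(ens, t)
      for (i in ga$atom_idx) for (j in gb$atom_idx)
        if (sqrt(sum((x[i, ] - x[j, ])^2)) <= 8) hit <- TRUE
    }
    if (hit) found <- c(found, paste0(ga$resname, ga$residue_id, ".",
                                      ga$chain, "|", gb$resname,
                                      gb$residue_id, ".", gb$chain))
  }
  expect_setequal(paste0(pairs$acidic, "|", pairs$basic), found)
})

test_that("distance series takes the minimum over member-atom combinations", {
  ens <- read_structure(write_tmp_pdb(asp_lys_pdb_text(d_od1_nz = 3.0,
                                                       d_od2_nz = 5.0)))
  pairs <- find_candidate_pairs(ens)
  ds <- distance_series(ens, pairs[1, ])
  expect_length(ds$values, 1)
  expect_equal(ds$values, 3.0, tolerance = 1e-6)

  # scheduled two-state generator reproduces its schedule
  st <- scheduled_toy(n_frames = 10, fraction = 0.6)
  ds2 <- distance_series(generate_ensemble(st$spec), st$pair)
  expect_equal(ds2$values, c(rep(2.8, 6), rep(6.0, 4)), tolerance = 1e-9)

  # missing member atoms are named
  expect_error(distance_series(ens, list(acidic = "GLU9.C",
                                         basic = "LYS5.B")), "GLU9.C")
})

test_that("adjacency weights are time-averaged inverse distances", {
  # constant 4 A pair -> 0.25 1/A
  ens <- read_structure(write_tmp_pdb(asp_lys_pdb_text(d_od1_nz = 4.0,
                                                       d_od2_nz = 6.0)))
  pairs <- find_candidate_pairs(ens)
  m <- adjacency_matrix(ens, pairs)
  expect_equal(m["ASP1.A", "LYS5.B"], 0.25, tolerance = 1e-9)

  # a tight 2.86 A contact sits at the top of the usual grey scale (~0.35)
  tight <- read_structure(write_tmp_pdb(asp_lys_pdb_text(d_od1_nz = 2.86,
                                                         d_od2_nz = 5.0)))
  mt <- adjacency_matrix(tight, find_candidate_pairs(tight))
  expect_equal(mt["ASP1.A", "LYS5.B"], 0.3497, tolerance = 1e-3)

  # random series vs brute-force mean of reciprocals
  st <- scheduled_toy(n_frames = 50, fraction = 0.5, noise = 0.1,
                      amplitudes = 0.2, seed = 12)
  ens2 <- generate_ensemble(st$spec)
  pairs2 <- find_candidate_pairs(ens2)
  m2 <- adjacency_matrix(ens2, pairs2)
  for (k in seq_len(nrow(pairs2))) {
    d <- distance_series(ens2, pairs2[k, ])$values
    expect_equal(m2[pairs2$acidic[k], pairs2$basic[k]], mean(1 / d),
                 tolerance = 1e-12)
  }

  # normalization records its constant
  mn <- adjacency_matrix(ens, pairs, normalize = TRUE)
  expect_equal(attr(mn, "norm_constant"), 1 / 2.8)
  expect_equal(as.numeric(mn["ASP1.A", "LYS5.B"]), 0.25 * 2.8,
               tolerance = 1e-9)
})

test_that("Frobenius inner product follows its closed forms", {
  lab <- function(m) {
    dimnames(m) <- list(paste0("ASP", seq_len(nrow(m)), ".A"),
                        paste0("LYS", seq_len(ncol(m)), ".B"))
    m
  }
  I2 <- lab(diag(2))
  expect_equal(frobenius_inner(I2, I2), 2)
  A <- lab(matrix(c(1, 0, 0, 0), 2, 2))
  B <- lab(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(frobenius_inner(A, B), 0)
  set.seed(13)
  for (k in 1:5) {
    M1 <- lab(matrix(runif(25), 5, 5)); M2 <- lab(matrix(runif(25), 5, 5))
    brute <- 0
    for (i in 1:5) for (j in 1:5) brute <- brute + M1[i, j] * M2[i, j]
    expect_equal(frobenius_inner(M1, M2), brute, tolerance = 1e-12)
    expect_equal(frobenius_inner(M1, M2), frobenius_inner(M2, M1))
  }
  expect_error(frobenius_inner(I2, lab(diag(3))), "label")
})

test_that("normalized Frobenius distance is a scale-invariant metric", {
  set.seed(14)
  # self-distance is identically zero (the diagonal of any distance table)
  for (k in 1:5) {
    A <- random_labeled_matrix(4, 4)
    expect_equal(as.numeric(frobenius_distance(A, A)), 0)
  }
  # disjoint-support unit matrices are maximally distant: sqrt(2)
  A <- matrix(c(1, 0, 0, 0), 2, 2,
              dimnames = list(c("ASP1.A", "ASP2.A"), c("LYS1.B", "LYS2.B")))
  B <- matrix(c(0, 0, 0, 1), 2, 2, dimnames = dimnames(A))
  expect_equal(as.numeric(frobenius_distance(A, B)), sqrt(2))

  # metric axioms on random triples
  for (k in 1:300) {
    A <- random_labeled_matrix(3, 3); B <- random_labeled_matrix(3, 3)
    C <- random_labeled_matrix(3, 3)
    dab <- as.numeric(frobenius_distance(A, B))
    dba <- as.numeric(frobenius_distance(B, A))
    dac <- as.numeric(frobenius_distance(A, C))
    dbc <- as.numeric(frobenius_distance(B, C))
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_gte(dab, 0)
    expect_lte(dac, dab + dbc + 1e-12)
  }

  # scale invariance and degenerate zero-zero case
  A <- random_labeled_matrix(4, 4); B <- random_labeled_matrix(4, 4)
  expect_equal(as.numeric(frobenius_distance(7.3 * A, B)),
               as.numeric(frobenius_distance(A, B)), tolerance = 1e-12)
  Z <- A * 0
  dz <- frobenius_distance(Z, Z)
  expect_equal(as.numeric(dz), 0)
  expect_true(attr(dz, "degenerate"))
})

test_that("matrix alignment pads onto the union label set", {
  A <- matrix(1:4 / 10, 2, 2,
              dimnames = list(c("ASP1.A", "ASP2.A"), c("LYS1.B", "LYS2.B")))
  al <- align_matrices(A, A)
  expect_equal(al$a, al$b)
  expect_equal(dim(al$a), c(2, 2))

  B <- matrix(1, 1, 1, dimnames = list("GLU9.A", "ARG9.B"))
  al2 <- align_matrices(A, B)
  expect_equal(dim(al2$a), c(3, 3))
  expect_equal(sum(al2$a), sum(A))
  expect_equal(sum(al2$b), 1)
  expect_equal(al2$a["GLU9.A", "ARG9.B"], 0)
  expect_equal(al2$b["GLU9.A", "ARG9.B"], 1)

  C <- matrix(2, 1, 1, dimnames = list("ASP2.A", "ARG9.B"))
  al3 <- align_matrices(A, C)
  expect_equal(dim(al3$a), c(2, 3))
})

test_that("adjacency is permutation-equivariant and distances permutation-invariant", {
  st <- scheduled_toy(n_frames = 20, amplitudes = 0.3, seed = 15)
  ens <- generate_ensemble(st$spec)
  pairs <- find_candidate_pairs(ens)
  m <- adjacency_matrix(ens, pairs)
  # row/column permutation of both arguments leaves the distance unchanged
  set.seed(16)
  p1 <- sample(nrow(m)); p2 <- sample(ncol(m))
  mp <- m[p1, p2, drop = FALSE]
  m2 <- m * matrix(runif(length(m)), nrow(m))
  dimnames(m2) <- dimnames(m)
  m2p <- m2[p1, p2, drop = FALSE]
  expect_equal(as.numeric(frobenius_distance(mp, m2p)),
               as.numeric(frobenius_distance(m, m2)), tolerance = 1e-12)
})

test_that("intermolecular submatrix keeps only interface-spanning pairs", {
  st <- scheduled_toy(n_frames = 5, amplitudes = 0.3, seed = 17)
  ens <- generate_ensemble(st$spec)
  top <- ens$topology
  pairs <- find_candidate_pairs(ens)
  m <- adjacency_matrix(ens, pairs)
  sub <- intermolecular_submatrix(m, top)
  # brute-force role check per entry
  side <- function(ch) {
    role <- top$chains[[ch]]
    if (role %in% c("presenter", "peptide")) "pmhc"
    else if (role %in% c("receptor_alpha", "receptor_beta")) "tcr"
    else NA_character_
  }
  for (i in rownames(m)) for (j in colnames(m)) {
    si <- side(sub("^.*\\.", "", i)); sj <- side(sub("^.*\\.", "", j))
    spanning <- !is.na(si) && !is.na(sj) && si != sj
    expect_equal(sub[i, j], if (spanning) m[i, j] else 0)
  }
  # matrix of only intramolecular bridges collapses to zero
  intra <- m
  keep <- outer(rownames(m), colnames(m), function(x, y)
    substr(x, nchar(x), nchar(x)) == substr(y, nchar(y), nchar(y)))
  intra <- m * keep
  dimnames(intra) <- dimnames(m)
  sub2 <- intermolecular_submatrix(
    structure(intra, class = class(m)), top)
  expect_true(all(sub2 == 0))
  # unresolvable chain label errors
  bad <- m
  rownames(bad)[1] <- "ASP1.Z"
  expect_error(intermolecular_submatrix(bad, top), "chain")
})

test_that("occupancy counting separates detection from contact formation", {
  # 100% formed at 2.8 A -> counted with occupancy 1
  ens <- read_structure(write_tmp_pdb(asp_lys_pdb_text(d_od1_nz = 2.8,
                                                       d_od2_nz = 5.0)))
  pairs <- find_candidate_pairs(ens)
  cb <- count_bridges(ens, pairs)
  expect_equal(cb$count, 1)
  expect_equal(cb$occupancies$occupancy, 1)

  # 3.3 A throughout -> candidate, but never a formed contact at 3.2 A
  near <- read_structure(write_tmp_pdb(asp_lys_pdb_text(d_od1_nz = 3.3,
                                                        d_od2_nz = 5.5)))
  cb2 <- count_bridges(near, find_candidate_pairs(near))
  expect_equal(cb2$count, 0)
  expect_equal(cb2$occupancies$occupancy, 0)

  # scheduled 60% formed fraction recovered exactly on a noise-free schedule
  st <- scheduled_toy(n_frames = 10, fraction = 0.6)
  ens3 <- generate_ensemble(st$spec)
  cb3 <- count_bridges(ens3, find_candidate_pairs(ens3))
  occ <- cb3$occupancies
  hit <- occ$acidic == st$pair$acidic & occ$basic == st$pair$basic
  expect_equal(occ$occupancy[hit], 0.6)
  expect_true(occ$counted[hit])
})
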