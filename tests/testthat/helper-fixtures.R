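# Fixtures built in code: tiny PDB texts, toy topologies/ensembles, and a
# brute-force toolbox of independent oracles.

pdb_line <- function(serial, name, resn, chain, resid, x, y, z,
                     record = "ATOM  ", elem = substr(name, 1, 1)) {
  sprintf("%s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, resn, chain, resid, x, y, z, elem)
}

# 3-atom single-model PDB (N-CA-C of one glycine)
tiny_pdb_text <- function() {
  c(pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 1, 1.45, 0, 0),
    pdb_line(3, "C", "GLY", "A", 1, 2.4, 1.1, 0),
    "TER", "END")
}

# One Asp + one Lys, sidechain contact at a controllable OD1-NZ distance
asp_lys_pdb_text <- function(d_od1_nz = 3.0, d_od2_nz = 5.0) {
  c(pdb_line(1, "N", "ASP", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "ASP", "A", 1, 1.45, 0, 0),
    pdb_line(3, "C", "ASP", "A", 1, 2.4, 1.1, 0),
    pdb_line(4, "O", "ASP", "A", 1, 2.1, 2.3, 0),
    pdb_line(5, "CB", "ASP", "A", 1, 1.45, 0, 1.5),
    pdb_line(6, "OD1", "ASP", "A", 1, 1.45, 0, 3.0),
    pdb_line(7, "OD2", "ASP", "A", 1, 1.45, d_od1_nz - d_od2_nz, 3.0),
    pdb_line(8, "N", "LYS", "B", 5, 0, d_od1_nz, 0),
    pdb_line(9, "CA", "LYS", "B", 5, 1.45, d_od1_nz, 0),
    pdb_line(10, "C", "LYS", "B", 5, 2.4, d_od1_nz + 1.1, 0),
    pdb_line(11, "O", "LYS", "B", 5, 2.1, d_od1_nz + 2.3, 0),
    pdb_line(12, "NZ", "LYS", "B", 5, 1.45, d_od1_nz, 3.0),
    "TER", "END")
}

write_tmp_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# random mass-weighted point topology (single chain of CA pseudo-atoms)
random_point_topology <- function(n, seed = 1, masses = NULL) {
  set.seed(seed)
  atoms <- data.frame(
    serial = seq_len(n), atom_name = "CA", residue_name = "ALA",
    residue_id = seq_len(n), chain_id = "A", element = "C",
    mass = if (is.null(masses)) runif(n, 1, 20) else masses,
    is_atom = TRUE, stringsAsFactors = FALSE)
  topology(atoms)
}

random_ensemble <- function(n, T, seed = 1, masses = NULL, sd = 1) {
  top <- random_point_topology(n, seed = seed, masses = masses)
  set.seed(seed + 1)
  coords <- array(rnorm(T * n * 3, sd = sd), c(T, n, 3))
  ensemble(top, coords)
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3, byrow = TRUE)
}

# random labeled matrix on shared label pools, for Frobenius property tests
random_labeled_matrix <- function(nr = 4, nc = 4, sparsity = 0.4) {
  m <- matrix(runif(nr * nc), nr, nc) * (matrix(runif(nr * nc), nr, nc) >
                                           sparsity)
  dimnames(m) <- list(paste0("ASP", seq_len(nr), ".A"),
                      paste0("LYS", seq_len(nc), ".B"))
  m
}

# toy complex + one scheduled Asp(A)-Lys(B) bridge, reused across tests
scheduled_toy <- function(n_frames = 10, fraction = 0.6, noise = 0,
                          amplitudes = 0, seed = 7, formed = 2.8,
                          broken = 6.0, pattern = "block") {
  toy <- toy_complex_topology(10, 3, 8, 0.5, seed = 1)
  g <- toy$topology$charged_groups
  lab <- function(x) paste0(x$resname, x$residue_id, ".", x$chain)
  acid <- Filter(function(x) x$polarity == "acidic" && x$chain == "A", g)
  base <- Filter(function(x) x$polarity == "basic" && x$chain == "B" &&
                   x$resname == "LYS", g)
  sch <- list(list(acidic = lab(acid[[1]]), basic = lab(base[[1]]),
                   formed = formed, broken = broken, fraction = fraction,
                   pattern = pattern))
  spec <- synthetic_spec(toy$topology, toy$coords, amplitudes = amplitudes,
                         schedules = sch, n_frames = n_frames, noise = noise,
                         seed = seed)
  list(toy = toy, spec = spec, pair = list(acidic = sch[[1]]$acidic,
                                           basic = sch[[1]]$basic))
}
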