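static_ensemble <- function(n = 8, T = 5, seed = 21) {
  set.seed(seed)
  top <- random_point_topology(n, seed = seed)
  base <- matrix(rnorm(n * 3, sd = 3), n, 3)
  coords <- array(NA_real_, c(T, n, 3))
  for (t in seq_len(T)) coords[t, , ] <- base
  ensemble(top, coords)
}

test_that("RMSD series is zero for a static ensemble and linear drift is recovered", {
  ens <- static_ensemble()
  sel <- select_atoms(ens$topology)
  rs <- rmsd_series(ens, frame_coords(ens, 1), sel)
  expect_equal(rs$average, 0, tolerance = 1e-10)
  expect_equal(rs$maximum, 0, tolerance = 1e-10)
  expect_equal(rs$drift, 0, tolerance = 1e-4)

  # constructed series rising 0.004 A/ns (frames 1 ps apart) -> 4 pm/ns:
  # displace one atom along x by exactly the RMSD target per frame
  n <- 4; T <- 2001
  top <- random_point_topology(n, masses = rep(1, n))
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  coords <- array(NA_real_, c(T, n, 3))
  t_ns <- (seq_len(T) - 1) / 1000
  target <- 1.0 + 0.04 * t_ns           # A; 0.04 A/ns = 4 pm/ns
  for (t in seq_len(T)) {
    fr <- base
    fr[1, 3] <- fr[1, 3] + target[t] * sqrt(n)  # RMSD = disp / sqrt(n)
    coords[t, , ] <- fr
  }
  ens2 <- ensemble(top, coords)
  # fit on the three anchored atoms so the displaced atom carries the RMSD
  rs3 <- rmsd_series(ens2, base, fit_sel = selection(2:4),
                     measure_sel = selection(1:4))
  expect_equal(rs3$drift, 4, tolerance = 1e-6)
  expect_equal(rs3$average, mean(target), tolerance = 1e-9)
})

test_that("average RMSD of a harmonic ensemble matches the resampling expectation", {
  toy <- toy_complex_topology(8, 2, 6, 0.3, seed = 2)
  sigma <- 0.3
  spec <- synthetic_spec(toy$topology, toy$coords, amplitudes = sigma,
                         n_frames = 2000, seed = 31)
  ens <- generate_ensemble(spec)
  bb <- select_atoms(ens$topology, "backbone")
  rs <- rmsd_series(ens, toy$coords, bb)
  # Monte-Carlo oracle: same displacement statistics, direct formula,
  # independent draws (no superposition; the fit makes the estimate only
  # slightly smaller, bounded by the rigid-body mode fraction)
  set.seed(99)
  n <- length(as.integer(bb))
  mc <- replicate(400, sqrt(3 * mean(rnorm(3 * n, sd = sigma)^2)))
  expect_equal(rs$average, mean(mc), tolerance = 0.03)
})

test_that("iteratively fitted average structure honors its contracts", {
  ens <- static_ensemble()
  sel <- select_atoms(ens$topology)
  avg <- average_structure(ens, sel)
  expect_equal(unclass(avg), frame_coords(ens, 1), ignore_attr = TRUE)

  # two frames symmetric about a mean -> that mean
  n <- 6
  top <- random_point_topology(n, masses = rep(1, n))
  set.seed(32)
  mid <- matrix(rnorm(n * 3, sd = 2), n, 3)
  dev <- matrix(rnorm(n * 3, sd = 0.05), n, 3)
  coords <- array(NA_real_, c(2, n, 3))
  coords[1, , ] <- mid + dev; coords[2, , ] <- mid - dev
  avg2 <- average_structure(ensemble(top, coords), selection(1:n))
  fit <- kabsch_superpose(avg2, mid, selection(1:n))
  # agreement is up to the rotational refit of the two frames, O(|dev|)
  expect_lt(fit$rmsd, 5e-3)
  expect_lt(fit$rmsd, sqrt(mean(dev^2)))

  # harmonic ensemble: mean recovered within 3 sigma / sqrt(T) per coordinate
  toy <- toy_complex_topology(8, 2, 6, 0.3, seed = 2)
  sigma <- 0.3; T <- 4000
  spec <- synthetic_spec(toy$topology, toy$coords, amplitudes = sigma,
                         n_frames = T, seed = 33)
  ens3 <- generate_ensemble(spec)
  bb <- select_atoms(ens3$topology, "backbone")
  avg3 <- average_structure(ens3, bb)
  fit3 <- kabsch_superpose(avg3, toy$coords, bb)
  expect_lt(max(abs(fit3$coords - toy$coords)), 3 * sigma / sqrt(T) * 4)
})

test_that("RMSF is zero for static ensembles and sqrt(3) sigma for isotropic noise", {
  ens <- static_ensemble()
  prof <- rmsf_profile(ens, select_atoms(ens$topology), scope = "all")
  expect_true(all(prof$rmsf < 1e-10))

  toy <- toy_complex_topology(10, 3, 8, 0.3, seed = 2)
  sigma <- 0.5
  spec <- synthetic_spec(toy$topology, toy$coords, amplitudes = sigma,
                         n_frames = 4000, seed = 41)
  ens2 <- generate_ensemble(spec)
  prof2 <- rmsf_profile(ens2, select_atoms(ens2$topology, "backbone"),
                        scope = "backbone")
  expect_equal(mean(prof2$rmsf), sqrt(3) * sigma, tolerance = 0.03)

  # two-amplitude generator: presenter twice as mobile as receptor
  amps <- c(A = 0.6, P = 0.6, B = 0.3)
  spec3 <- synthetic_spec(toy$topology, toy$coords, amplitudes = amps,
                          n_frames = 4000, seed = 42)
  prof3 <- rmsf_profile(generate_ensemble(spec3),
                        select_atoms(toy$topology, "backbone"),
                        scope = "backbone")
  ratio <- mean(prof3$rmsf[prof3$chain == "A"]) /
    mean(prof3$rmsf[prof3$chain == "B"])
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("profile differences follow the a-minus-b sign convention", {
  toy <- toy_complex_topology(6, 2, 4, 0.3, seed = 3)
  mk <- function(amp, seed) {
    spec <- synthetic_spec(toy$topology, toy$coords, amplitudes = amp,
                           n_frames = 300, seed = seed)
    rmsf_profile(generate_ensemble(spec),
                 select_atoms(toy$topology, "backbone"))
  }
  a <- mk(0.5, 1); b <- mk(0.5, 2)
  d <- profile_difference(a, a)
  expect_true(all(d$delta_rmsf == 0))
  # a fluctuating vs near-static b -> all positive
  b0 <- mk(0.01, 3)
  expect_true(all(profile_difference(a, b0)$delta_rmsf > 0))
  # definition: elementwise subtraction
  expect_equal(profile_difference(a, b)$delta_rmsf, a$rmsf - b$rmsf)
  # mismatched residue sets are refused with the culprits named
  b_sub <- b[-1, ]
  class(b_sub) <- class(b)
  expect_error(profile_difference(a, b_sub), "residues")
})

test_that("profile t-test flags forced effects and degenerate inputs", {
  toy <- toy_complex_topology(6, 2, 4, 0.3, seed = 3)
  spec <- synthetic_spec(toy$topology, toy$coords, amplitudes = 0.5,
                         n_frames = 300, seed = 4)
  a <- rmsf_profile(generate_ensemble(spec),
                    select_atoms(toy$topology, "backbone"))
  r0 <- compare_profiles_ttest(a, a)
  expect_true(r0$degenerate)
  expect_true(is.nan(r0$p_value))
  expect_false(r0$significant)

  # constant 0.5 A shift with tiny noise -> significant at alpha = 0.01
  b <- a
  set.seed(5)
  b$rmsf <- a$rmsf + 0.5 + rnorm(nrow(a), sd = 1e-3)
  r1 <- compare_profiles_ttest(b, a, alpha = 0.01)
  expect_true(r1$significant)
  expect_equal(r1$mean_difference, 0.5, tolerance = 1e-3)
  expect_equal(r1$df, nrow(a) - 1)

  # Welch variant runs unpaired and reports its own degrees of freedom
  r2 <- compare_profiles_ttest(b, a, paired = FALSE)
  expect_false(r2$paired)
  expect_true(r2$significant)
  expect_false(isTRUE(all.equal(r2$df, nrow(a) - 1)))
})

test_that("t-test type-I error stays at its nominal level", {
  # null simulation: both profiles draw from the same distribution
  toy <- toy_complex_topology(6, 2, 4, 0.3, seed = 3)
  prof_template <- rmsf_profile(
    generate_ensemble(synthetic_spec(toy$topology, toy$coords,
                                     amplitudes = 0.4, n_frames = 50,
                                     seed = 6)),
    select_atoms(toy$topology, "backbone"))
  nres <- nrow(prof_template)
  set.seed(7)
  n_rej <- 0; n_sim <- 1000
  for (k in seq_len(n_sim)) {
    a <- prof_template; b <- prof_template
    a$rmsf <- 0.6 + rnorm(nres, sd = 0.1)
    b$rmsf <- 0.6 + rnorm(nres, sd = 0.1)
    if (compare_profiles_ttest(a, b, alpha = 0.05)$significant)
      n_rej <- n_rej + 1
  }
  # binomial 99% band around 0.05 with n = 1000
  expect_gte(n_rej / n_sim, 0.036)
  expect_lte(n_rej / n_sim, 0.065)
})

test_that("drift on a stationary ensemble is rarely significant", {
  top <- random_point_topology(5, masses = rep(1, 5))
  base <- matrix(rnorm(15, sd = 4), 5, 3)
  n_sig <- 0; n_seed <- 200
  for (s in seq_len(n_seed)) {
    set.seed(1000 + s)
    T <- 60
    coords <- array(rnorm(T * 5 * 3, sd = 0.3), c(T, 5, 3)) +
      rep(base, each = T)
    rs <- rmsd_series(ensemble(top, coords), base, selection(1:5))
    tstat <- rs$drift / rs$drift_se
    if (abs(tstat) > qt(0.975, T - 2)) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / n_seed, 0.05 + 0.045)  # 95% of seeds non-significant
})

test_that("residue RMSD maps localize a constructed displacement", {
  toy <- toy_complex_topology(6, 2, 4, 0, seed = 8)
  top <- toy$topology
  bb_all <- select_atoms(top, "backbone")
  # identical structures -> all zeros
  map0 <- residue_rmsd_map(top, toy$coords, toy$coords, bb_all)
  expect_true(all(map0$rmsd < 1e-10))

  # displace one residue rigidly by 2 A, fit on the others
  moved <- toy$coords
  idx <- which(top$atoms$chain_id == "P" & top$atoms$residue_id == 1)
  moved[idx, 1] <- moved[idx, 1] + 2
  fit_rest <- selection(setdiff(which(top$atoms$atom_name %in%
                                        c("N", "CA", "C", "O")), idx))
  map1 <- residue_rmsd_map(top, toy$coords, moved, fit_rest)
  hit <- map1$chain == "P" & map1$residue_id == 1
  expect_equal(map1$rmsd[hit], 2, tolerance = 1e-8)
  expect_true(all(map1$rmsd[!hit] < 1e-8))

  # random pair vs brute-force per-residue computation
  set.seed(9)
  pert <- toy$coords + matrix(rnorm(length(toy$coords), sd = 0.3),
                              nrow(toy$coords), 3)
  map2 <- residue_rmsd_map(top, toy$coords, pert, bb_all)
  fit <- kabsch_superpose(pert, toy$coords, bb_all)
  for (r in seq_len(nrow(map2))) {
    i <- which(top$atoms$chain_id == map2$chain[r] &
                 top$atoms$residue_id == map2$residue_id[r] &
                 top$atoms$atom_name %in% c("N", "CA", "C", "O"))
    brute <- sqrt(mean(rowSums((fit$coords[i, , drop = FALSE] -
                                  toy$coords[i, , drop = FALSE])^2)))
    expect_equal(map2$rmsd[r], brute, tolerance = 1e-12)
  }
})
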