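# Config-driven end-to-end comparison of labeled ensembles: stability
# statistics, RMSF profiles and significance tests, salt-bridge matrices and
# Frobenius distance tables, and the entropy binding cycle.

.fmt <- function(x) {
  # fixed-precision formatting so repeated runs are byte-identical
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.6g", v)
  }, "")
}

.write_csv_det <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], .fmt)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Build a run configuration
#'
#' @param entries list of entries; each a list with `label` (unique), either
#'   `ensemble` (an [ensemble()]) or `topology`/`trajectory` file paths plus
#'   optional `roles` (chain role map), `species` (grouping tag, e.g. "TAX"),
#'   and `kind` ("binary", "ternary", "free_receptor" or "other").
#' @param reference label of the reference species for Delta-Delta columns.
#' @param backbone atom names treated as main chain.
#' @param entropy_scope "all" or "backbone" atoms entering the covariance.
#' @param detection_cutoff salt-bridge detection cutoff (Angstrom).
#' @param contact_cutoff formed-contact cutoff (Angstrom).
#' @param occupancy occupancy threshold for counting.
#' @param temperature temperature (K) for entropy.
#' @param alpha significance level for profile t-tests.
#' @param outdir output directory.
#' @param seed integer seed (analyses are deterministic; the seed fixes any
#'   seeded synthesis done upstream and is logged).
#' @return object of class `run_config`.
#' @export
run_config <- function(entries, reference, backbone = c("N", "CA", "C", "O"),
                       entropy_scope = c("all", "backbone"),
                       detection_cutoff = 8.0, contact_cutoff = 3.2,
                       occupancy = 0.5, temperature = 298, alpha = 0.05,
                       outdir = "phladyn_out", seed = 1) {
  entropy_scope <- match.arg(entropy_scope)
  labels <- vapply(entries, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("entry labels must be unique")
  species <- vapply(entries, function(e)
    if (is.null(e$species)) e$label else e$species, "")
  if (!(reference %in% species) && !(reference %in% labels))
    stop("reference label '", reference, "' not present among entries")
  structure(list(entries = entries, reference = reference,
                 backbone = backbone, entropy_scope = entropy_scope,
                 detection_cutoff = detection_cutoff,
                 contact_cutoff = contact_cutoff, occupancy = occupancy,
                 temperature = temperature, alpha = alpha,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose fields mirror the arguments of
#'   [run_config()]; entries reference topology/trajectory files.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  p <- yaml::read_yaml(path)
  args <- p[intersect(names(p),
                      setdiff(names(formals(run_config)), "entries"))]
  args$entries <- p$entries
  do.call(run_config, args)
}

.load_entry <- function(e) {
  if (!is.null(e$ensemble)) return(e$ensemble)
  if (is.null(e$topology) || !file.exists(e$topology))
    stop("entry '", e$label, "': topology file not found: ", e$topology)
  roles <- if (is.null(e$roles)) NULL else unlist(e$roles)
  if (is.null(e$trajectory) || identical(e$trajectory, e$topology))
    read_structure(e$topology, chain_roles = roles, label = e$label)
  else {
    if (!file.exists(e$trajectory))
      stop("entry '", e$label, "': trajectory file not found: ", e$trajectory)
    read_trajectory(e$topology, e$trajectory, chain_roles = roles)
  }
}

#' Run the full comparison pipeline
#'
#' For every entry: RMSD series with drift, radius-of-gyration statistics,
#' backbone RMSF profile, salt-bridge detection, adjacency matrix (full and
#' intermolecular), occupancy counts, bridge time traces, and quasi-harmonic
#' entropy.  Across entries: RMSF difference maps and t-tests against the
#' reference species (same kind), pairwise normalized Frobenius distance
#' matrices (full and intermolecular-only), and the entropy binding cycle
#' for every species holding a binary and a ternary entry, relative to the
#' reference species.  All outputs are written to `config$outdir` as CSV and
#' JSON at fixed precision; any stage failure aborts the run and removes the
#' partial outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of result objects per stage.
#' @export
run_comparison <- function(config) {
  out <- config$outdir
  created <- !dir.exists(out)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }
  log_lines <- character()
  logf <- function(...) {
    log_lines <<- c(log_lines, paste0("[", length(log_lines) + 1L, "] ", ...))
  }

  res <- tryCatch(
    .run_comparison_impl(config, out, emit, logf),
    error = function(e) {
      unlink(written)
      if (created) unlink(out, recursive = TRUE)
      stop("pipeline aborted: ", conditionMessage(e), call. = FALSE)
    })
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(res)
}

.run_comparison_impl <- function(config, out, emit, logf) {
  set.seed(config$seed)
  entries <- config$entries
  labels <- vapply(entries, `[[`, "", "label")

  logf("stage load: ", length(entries), " entries, seed ", config$seed)
  ens_list <- lapply(entries, function(e) {
    ens <- .load_entry(e)
    if (!is.null(e$trajectory) && is.character(e$trajectory) &&
        file.exists(e$trajectory))
      logf("input '", e$label, "' md5 ",
           tools::md5sum(e$trajectory)[[1]])
    ens
  })
  names(ens_list) <- labels
  kinds <- vapply(entries, function(e)
    if (is.null(e$kind)) "other" else e$kind, "")
  species <- vapply(entries, function(e)
    if (is.null(e$species)) e$label else e$species, "")

  # (a) per-entry stability summary -----------------------------------------
  logf("stage summary")
  summary_rows <- list()
  profiles <- list(); matrices <- list(); inter_matrices <- list()
  entropies <- list()
  for (i in seq_along(ens_list)) {
    ens <- ens_list[[i]]; lab <- labels[i]
    bb <- selection(which(ens$topology$atoms$atom_name %in% config$backbone &
                            ens$topology$atoms$is_atom),
                    "backbone", nrow(ens$topology$atoms))
    rs <- rmsd_series(ens, frame_coords(ens, 1), bb)
    rg <- radius_of_gyration(ens, select_atoms(ens$topology, "all"))
    summary_rows[[i]] <- data.frame(
      label = lab, kind = kinds[i], species = species[i],
      frames = n_frames(ens),
      time_ns = n_frames(ens) * ens$frame_interval / 1000,
      avg_rmsd = rs$average, max_rmsd = rs$maximum,
      drift_pm_ns = rs$drift, mean_rg = rg$mean, sem_rg = rg$sem,
      stringsAsFactors = FALSE)

    # (b) RMSF profile
    if (n_frames(ens) >= 2) {
      prof <- rmsf_profile(ens, bb, scope = "backbone")
      profiles[[lab]] <- prof
      emit(.write_csv_det(as.data.frame(prof),
                          file.path(out, paste0("rmsf_", lab, ".csv"))))
    }

    # (c) salt bridges
    pairs <- find_candidate_pairs(ens, config$detection_cutoff)
    m <- adjacency_matrix(ens, pairs)
    matrices[[lab]] <- m
    inter_matrices[[lab]] <- intermolecular_submatrix(m, ens$topology)
    emit(write_matrix(m, file.path(out, paste0("sb_matrix_", lab, ".csv"))))
    cnt <- count_bridges(ens, pairs, config$contact_cutoff, config$occupancy)
    emit(write_report_json(
      list(label = lab, count = cnt$count, occupancies = cnt$occupancies),
      file.path(out, paste0("sb_counts_", lab, ".json"))))
    if (nrow(pairs)) {
      traces <- lapply(seq_len(nrow(pairs)), function(k) {
        ds <- distance_series(ens, pairs[k, ])
        data.frame(pair = paste0(pairs$acidic[k], "-", pairs$basic[k]),
                   frame = seq_along(ds$values), time_ps = ds$time,
                   distance_A = ds$values, inv_distance = 1 / ds$values,
                   stringsAsFactors = FALSE)
      })
      emit(.write_csv_det(do.call(rbind, traces),
                          file.path(out, paste0("sb_traces_", lab, ".csv"))))
    }

    # (d) entropy
    if (n_frames(ens) >= 2) {
      scope_sel <- if (config$entropy_scope == "backbone") bb
                   else select_atoms(ens$topology, "all")
      cov <- mass_weighted_covariance(ens, scope_sel, fit_sel = bb)
      spec <- quasiharmonic_spectrum(cov, temperature = config$temperature)
      entropies[[lab]] <- quasiharmonic_entropy(spec, label = lab)
    }
    logf("entry '", lab, "' done: ", nrow(pairs), " candidate bridges")
  }
  emit(.write_csv_det(do.call(rbind, summary_rows),
                      file.path(out, "summary.csv")))

  # (b cont.) difference maps + t-tests vs the reference species ------------
  logf("stage profile comparison")
  ttests <- list()
  for (i in seq_along(labels)) {
    ref_i <- which(species == config$reference & kinds == kinds[i])
    if (!length(ref_i) || ref_i[1] == i) next
    ref_lab <- labels[ref_i[1]]
    if (is.null(profiles[[labels[i]]]) || is.null(profiles[[ref_lab]])) next
    dif <- profile_difference(profiles[[labels[i]]], profiles[[ref_lab]])
    emit(.write_csv_det(dif, file.path(
      out, paste0("rmsf_diff_", labels[i], "_minus_", ref_lab, ".csv"))))
    ttests[[paste0(labels[i], "_vs_", ref_lab)]] <-
      compare_profiles_ttest(profiles[[labels[i]]], profiles[[ref_lab]],
                             alpha = config$alpha)
  }
  if (length(ttests))
    emit(write_report_json(ttests, file.path(out, "rmsf_ttests.json")))

  # (e) pairwise Frobenius distance matrices --------------------------------
  logf("stage frobenius")
  fd_table <- function(mats) {
    n <- length(mats)
    fm <- matrix(0, n, n, dimnames = list(names(mats), names(mats)))
    for (i in seq_len(n)) for (j in seq_len(n))
      fm[i, j] <- as.numeric(frobenius_distance(mats[[i]], mats[[j]]))
    fm
  }
  emit(write_matrix(fd_table(matrices), file.path(out, "frobenius_full.csv")))
  emit(write_matrix(fd_table(inter_matrices),
                    file.path(out, "frobenius_intermolecular.csv")))

  # (d cont.) binding cycle per species -------------------------------------
  logf("stage cycle")
  cycles <- list()
  free_lab <- labels[kinds == "free_receptor"]
  if (length(free_lab) == 1 && length(entropies)) {
    ref_cycle <- NULL
    sp_order <- unique(species[kinds %in% c("binary", "ternary")])
    sp_order <- c(intersect(config$reference, sp_order),
                  setdiff(sp_order, config$reference))
    for (sp in sp_order) {
      b <- labels[species == sp & kinds == "binary"]
      t3 <- labels[species == sp & kinds == "ternary"]
      if (length(b) != 1 || length(t3) != 1) next
      if (is.null(entropies[[b]]) || is.null(entropies[[t3]])) next
      cy <- binding_cycle(entropies[[b]], entropies[[t3]],
                          entropies[[free_lab]], reference = ref_cycle,
                          label = sp)
      if (sp == config$reference) ref_cycle <- cy
      cycles[[sp]] <- cy
    }
    if (length(cycles)) {
      cyc_df <- do.call(rbind, lapply(cycles, function(cy) {
        data.frame(species = cy$label, minus_tds_binary = cy$binary,
                   minus_tds_ternary = cy$ternary,
                   minus_tds_free_receptor = cy$free_receptor,
                   minus_tds_binding = cy$binding,
                   dd_binding = if (is.null(cy$delta_delta_binding)) 0
                                else cy$delta_delta_binding,
                   dd_binary = if (is.null(cy$delta_delta_binary)) 0
                               else cy$delta_delta_binary,
                   stringsAsFactors = FALSE)
      }))
      emit(.write_csv_det(cyc_df, file.path(out, "entropy_cycle.csv")))
    }
  }
  if (length(entropies))
    emit(write_report_json(
      lapply(entropies, function(e) list(
        label = e$label, minus_T_dS_kJ_mol = e$minus_T_dS,
        S_J_mol_K = e$S_molar, n_modes = length(e$spectrum$eigenvalues),
        n_dropped = e$spectrum$n_dropped,
        temperature_K = e$spectrum$temperature)),
      file.path(out, "entropy.json")))

  logf("done")
  invisible(list(summary = do.call(rbind, summary_rows),
                 profiles = profiles, ttests = ttests, matrices = matrices,
                 intermolecular = inter_matrices, entropies = entropies,
                 cycles = cycles))
}

#' Built-in paired synthetic demonstration
#'
#' Builds a "reactive" and a "nonreactive" synthetic species sharing one toy
#' topology: the reactive ternary complex carries three extra scheduled
#' intermolecular bridges and the nonreactive binary species fluctuates with
#' larger amplitudes (the statistical signature separating responsive from
#' unresponsive complexes), plus a shared free-receptor ensemble.
#'
#' @param n_frames frames per ensemble.
#' @param seed integer seed.
#' @param outdir output directory.
#' @return the [run_config()] (not yet run).
#' @export
demo_config <- function(n_frames = 300, seed = 1, outdir = "phladyn_demo") {
  toy <- toy_complex_topology(n_presenter = 12, n_peptide = 3,
                              n_receptor = 10, charged_fraction = 0.5,
                              seed = seed)
  top <- toy$topology
  g <- top$charged_groups
  lab_of <- function(g) .residue_label(g$resname, g$residue_id, g$chain)
  acids_A <- Filter(function(x) x$polarity == "acidic" & x$chain == "A", g)
  bases_B <- Filter(function(x) x$polarity == "basic" & x$chain == "B", g)
  bases_A <- Filter(function(x) x$polarity == "basic" & x$chain == "A", g)
  sched <- function(a, b, f)
    list(acidic = lab_of(a), basic = lab_of(b), formed = 2.8, broken = 6.0,
         fraction = f, pattern = "block")
  # shared intramolecular bridge + three extra intermolecular ones that only
  # the reactive species forms
  common <- if (length(acids_A) && length(bases_A))
    list(sched(acids_A[[1]], bases_A[[1]], 0.8)) else list()
  extra <- list()
  k <- min(3, length(acids_A) - 1, length(bases_B))
  if (k > 0) for (i in seq_len(k))
    extra[[i]] <- sched(acids_A[[i + 1]], bases_B[[i]], 0.9)

  amp_reactive <- c(A = 0.25, P = 0.25, B = 0.3)
  amp_nonreactive <- c(A = 0.45, P = 0.45, B = 0.3)
  mk <- function(amps, schedules, seed_off, lab) {
    sp <- synthetic_spec(top, toy$coords, amplitudes = amps,
                         schedules = schedules, n_frames = n_frames,
                         noise = 0.05, seed = seed + seed_off)
    e <- generate_ensemble(sp); e$label <- lab; e
  }
  free_top <- toy_complex_topology(n_presenter = 1, n_peptide = 1,
                                   n_receptor = 10, charged_fraction = 0.5,
                                   seed = seed + 4)
  free_spec <- synthetic_spec(free_top$topology, free_top$coords,
                              amplitudes = 0.3, n_frames = n_frames,
                              seed = seed + 5)
  free_ens <- generate_ensemble(free_spec); free_ens$label <- "freeTCR"

  entries <- list(
    list(label = "reactive_binary", species = "reactive", kind = "binary",
         ensemble = mk(amp_reactive, common, 0, "reactive_binary")),
    list(label = "reactive_ternary", species = "reactive", kind = "ternary",
         ensemble = mk(amp_reactive, c(common, extra), 1, "reactive_ternary")),
    list(label = "nonreactive_binary", species = "nonreactive",
         kind = "binary",
         ensemble = mk(amp_nonreactive, list(), 2, "nonreactive_binary")),
    # receptor binding restrains the ternary complexes of both species to
    # similar mobility; the species differ mainly in their binary forms
    list(label = "nonreactive_ternary", species = "nonreactive",
         kind = "ternary",
         ensemble = mk(amp_reactive, common, 3, "nonreactive_ternary")),
    list(label = "freeTCR", species = "freeTCR", kind = "free_receptor",
         ensemble = free_ens))
  run_config(entries, reference = "reactive", outdir = outdir, seed = seed)
}
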