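# Synthetic ensembles with known ground truth: per-residue harmonic
# fluctuations around a fixed mean structure, scheduled two-state salt
# bridges, and a miniature three-chain presenter/peptide/receptor topology.
# The generator imitates the statistics the analyses assume -- not physics:
# there is no force field, integrator or solvent.

.sidechain_templates <- list(
  ASP = list(names = c("CB", "CG", "OD1", "OD2"),
             along = c(1.5, 3.0, 4.2, 4.2), perp = c(0, 0, 0.6, -0.6)),
  GLU = list(names = c("CB", "CG", "CD", "OE1", "OE2"),
             along = c(1.5, 3.0, 4.5, 5.7, 5.7), perp = c(0, 0, 0, 0.6, -0.6)),
  LYS = list(names = c("CB", "CG", "CD", "CE", "NZ"),
             along = c(1.5, 3.0, 4.5, 6.0, 7.3), perp = c(0, 0, 0, 0, 0)),
  ARG = list(names = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
             along = c(1.5, 3.0, 4.5, 5.8, 7.0, 8.1, 8.1),
             perp = c(0, 0, 0, 0, 0, 0.9, -0.9)),
  ALA = list(names = "CB", along = 1.5, perp = 0)
)

.residue_atoms <- function(resname, ca, side_dir, perp_dir) {
  # backbone cross: N / C flank the CA along x, carbonyl O off the C
  bb <- rbind(N = ca + c(-1.2, 0.4, 0), CA = ca, C = ca + c(1.2, 0.4, 0),
              O = ca + c(1.4, 1.6, 0))
  tpl <- .sidechain_templates[[resname]]
  sc <- t(vapply(seq_along(tpl$names), function(k) {
    ca + tpl$along[k] * side_dir + tpl$perp[k] * perp_dir
  }, numeric(3)))
  rownames(sc) <- tpl$names
  rbind(bb, sc)
}

#' Miniature presenter/peptide/receptor complex topology
#'
#' Builds a deterministic three-chain toy complex: chain A (role
#' `presenter`) as two parallel rails forming a groove, chain P (role
#' `peptide`) lying in the groove, and chain B (role `receptor_alpha`)
#' stacked above the groove with its sidechains pointing down -- a miniature
#' stand-in for a class-I p-MHC-TCR architecture.  A seeded subset of
#' residues (fraction `charged_fraction` per chain) is assigned charged
#' types cycling Asp, Lys, Glu, Arg with correctly named sidechain O/N
#' atoms; the rest are alanines.
#'
#' @param n_presenter,n_peptide,n_receptor residue counts per chain (>= 1).
#' @param charged_fraction fraction of residues per chain that are charged,
#'   in [0, 1].
#' @param seed integer seed (charged-residue placement is reproducible).
#' @return list with `topology` (a [topology()]) and `coords` (N x 3 mean
#'   structure, Angstrom).
#' @export
toy_complex_topology <- function(n_presenter = 10, n_peptide = 3,
                                 n_receptor = 8, charged_fraction = 0.4,
                                 seed = 1) {
  if (min(n_presenter, n_peptide, n_receptor) < 1)
    stop("residue counts must be >= 1")
  if (charged_fraction < 0 || charged_fraction > 1)
    stop("charged_fraction must be in [0, 1]")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  charged_types <- c("ASP", "LYS", "GLU", "ARG")
  pick <- function(n) {
    k <- round(charged_fraction * n)
    sort(sample.int(n, k))
  }

  rows <- list(); xyz <- list(); serial <- 0L; type_cursor <- 0L
  add_chain <- function(chain, n_res, ca_of, side_dir, perp_dir) {
    ch_idx <- pick(n_res)
    for (r in seq_len(n_res)) {
      if (r %in% ch_idx) {
        type_cursor <<- type_cursor + 1L
        resname <- charged_types[(type_cursor - 1L) %% 4L + 1L]
      } else resname <- "ALA"
      at <- .residue_atoms(resname, ca_of(r), side_dir, perp_dir)
      for (k in seq_len(nrow(at))) {
        serial <<- serial + 1L
        nm <- rownames(at)[k]
        rows[[length(rows) + 1L]] <<- data.frame(
          serial = serial, atom_name = nm, residue_name = resname,
          residue_id = r, chain_id = chain,
          element = substr(nm, 1, 1), stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1L]] <<- at[k, ]
      }
    }
  }

  half <- ceiling(n_presenter / 2)
  add_chain("A", n_presenter,
            function(r) if (r <= half) c(3.8 * (r - 1), -5, 0)
                        else c(3.8 * (r - half - 1), 5, 0),
            side_dir = c(0, 0, 1), perp_dir = c(1, 0, 0))
  add_chain("P", n_peptide,
            function(r) c(3.8 * (r - 1) + 1.0, 0, 1.5),
            side_dir = c(0, 0, 1), perp_dir = c(1, 0, 0))
  add_chain("B", n_receptor,
            function(r) c(3.8 * (r - 1) - 1.0, 0, 14),
            side_dir = c(0, 0, -1), perp_dir = c(1, 0, 0))

  atoms <- do.call(rbind, rows)
  atoms$mass <- element_mass(atoms$element)
  atoms$is_atom <- TRUE
  top <- topology(atoms, chain_roles = c(A = "presenter", P = "peptide",
                                         B = "receptor_alpha"))
  list(topology = top, coords = do.call(rbind, xyz))
}

# save/restore the global RNG state so generators are self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specification of a synthetic ensemble
#'
#' @param topology a [topology()].
#' @param mean_coords N x 3 mean structure (Angstrom).
#' @param amplitudes per-residue harmonic fluctuation amplitude sigma
#'   (Angstrom): a single number, a named vector by chain id, or a
#'   data.frame with columns `chain`, `residue_id`, `sigma`.
#' @param schedules list of bridge schedules; each a list with `acidic` and
#'   `basic` residue labels (e.g. "ASP3.A"), `formed` and `broken` distances
#'   (Angstrom), `fraction` of formed frames in [0, 1], and `pattern`
#'   ("block": the first round(fraction*T) frames are formed; "bernoulli":
#'   seeded per-frame draws).
#' @param n_frames frame count T (>= 1).
#' @param frame_interval ps per frame.
#' @param noise jitter sigma (Angstrom) applied along the bridge axis to
#'   scheduled distances (0 = exact schedule).
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(topology, mean_coords, amplitudes = 0.3,
                           schedules = list(), n_frames = 1000,
                           frame_interval = 1, noise = 0, seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (noise < 0) stop("noise must be >= 0")
  for (s in schedules) {
    if (!all(c("acidic", "basic", "formed", "broken", "fraction") %in%
             names(s)))
      stop("schedule must name acidic, basic, formed, broken, fraction")
    if (s$fraction < 0 || s$fraction > 1)
      stop("schedule fraction must be in [0, 1]")
    .find_group(topology, s$acidic)  # errors if the pair does not exist
    .find_group(topology, s$basic)
  }
  sig <- .resolve_amplitudes(topology, amplitudes)
  if (any(sig < 0)) stop("amplitudes must be >= 0")
  structure(list(topology = topology, mean_coords = mean_coords,
                 amplitudes = amplitudes, atom_sigma = sig,
                 schedules = schedules, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, noise = noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Expand the amplitude map to one sigma per atom.
.resolve_amplitudes <- function(top, amplitudes) {
  a <- top$atoms
  if (is.data.frame(amplitudes)) {
    key <- paste(a$chain_id, a$residue_id)
    mkey <- paste(amplitudes$chain, amplitudes$residue_id)
    sig <- amplitudes$sigma[match(key, mkey)]
    if (anyNA(sig)) stop("amplitude map misses residue(s): ",
                         paste(unique(key[is.na(sig)]), collapse = ", "))
    return(sig)
  }
  if (!is.null(names(amplitudes))) {
    sig <- amplitudes[a$chain_id]
    if (anyNA(sig)) stop("amplitude map misses chain(s): ",
                         paste(setdiff(a$chain_id, names(amplitudes)),
                               collapse = ", "))
    return(unname(sig))
  }
  rep(as.numeric(amplitudes), nrow(a))
}

# Formed/broken frame pattern for one schedule; block patterns realise the
# fraction exactly (round(f * T) formed frames first).
.schedule_states <- function(s, T) {
  pattern <- if (is.null(s$pattern)) "block" else s$pattern
  if (pattern == "block") {
    k <- round(s$fraction * T)
    c(rep(TRUE, k), rep(FALSE, T - k))
  } else if (pattern == "bernoulli") {
    stats::runif(T) < s$fraction
  } else stop("unknown switching pattern: ", pattern)
}

#' Generate a synthetic ensemble from a specification
#'
#' Frame t is the mean structure plus per-atom isotropic Gaussian
#' displacement with the residue's amplitude sigma; atoms belonging to a
#' scheduled bridge's basic group are instead placed so that the pair's
#' minimum O-N distance follows the schedule (moved along the inter-group
#' axis; the acidic group stays harmonic).  The harmonic-noise and schedule
#' random streams are seeded separately, so changing one leaves the other
#' unchanged at a fixed seed.  Bit-reproducible for identical spec + seed.
#'
#' @param spec a [synthetic_spec()].
#' @return an [ensemble()] labeled "synthetic".
#' @export
generate_ensemble <- function(spec) {
  top <- spec$topology
  N <- nrow(top$atoms); T <- spec$n_frames
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  set.seed(spec$seed)                       # stream 1: harmonic noise
  coords <- array(stats::rnorm(T * N * 3), c(T, N, 3))
  coords <- coords * rep(spec$atom_sigma, each = T)
  coords <- coords + rep(spec$mean_coords, each = T)

  set.seed(spec$seed + 10007L)              # stream 2: schedules
  for (s in spec$schedules) {
    ga <- .find_group(top, s$acidic)
    gb <- .find_group(top, s$basic)
    # closest O-N member combination in the mean structure defines the axis
    best <- c(NA, NA); dbest <- Inf
    for (i in ga$atom_idx) for (j in gb$atom_idx) {
      d <- sqrt(sum((spec$mean_coords[j, ] - spec$mean_coords[i, ])^2))
      if (d < dbest) { dbest <- d; best <- c(i, j) }
    }
    u <- (spec$mean_coords[best[2], ] - spec$mean_coords[best[1], ]) / dbest
    states <- .schedule_states(s, T)
    target <- ifelse(states, s$formed, s$broken)
    if (spec$noise > 0) target <- target + stats::rnorm(T, 0, spec$noise)
    shift <- target - dbest                 # per-frame displacement along u
    for (j in gb$atom_idx) {
      base <- spec$mean_coords[j, ]
      for (k in 1:3) coords[, j, k] <- base[k] + shift * u[k]
    }
  }
  ensemble(top, coords, frame_interval = spec$frame_interval,
           label = "synthetic")
}

#' Closed-form ground truth for a synthetic specification
#'
#' Analytic expectations against which the analysis operations are checked:
#' per-residue RMSF sqrt(3) sigma (exact for residues untouched by
#' schedules); adjacency weight f/d_formed + (1-f)/d_broken and occupancy f
#' for noise-free schedules (f is the realised block fraction round(f*T)/T
#' for block patterns); and, in the independent-oscillator regime (no
#' schedules), the quasi-harmonic entropy of the diagonal covariance
#' lambda = m_i sigma_i^2 summed over the 3N modes.
#'
#' @param spec a [synthetic_spec()].
#' @param temperature temperature in K for the entropy oracle.
#' @param include character vector from c("rmsf", "adjacency", "occupancy",
#'   "entropy"); NULL (default) includes everything applicable.  Requesting
#'   "entropy" for a spec with schedules is an error (the oracle assumes
#'   independent oscillators).
#' @return list with elements `rmsf` (data.frame chain/residue_id/rmsf),
#'   `adjacency` and `occupancy` (per schedule), `entropy`
#'   (an [quasiharmonic_entropy()]-style result) as requested.
#' @export
analytic_oracles <- function(spec, temperature = 298, include = NULL) {
  has_sched <- length(spec$schedules) > 0
  if (is.null(include)) {
    include <- c("rmsf", "adjacency", "occupancy",
                 if (!has_sched) "entropy")
  }
  if ("entropy" %in% include && has_sched)
    stop("entropy oracle assumes the independent-oscillator regime: ",
         "spec has bridge schedules")
  out <- list()
  a <- spec$topology$atoms
  if ("rmsf" %in% include) {
    rt <- .residue_table(spec$topology)
    key <- paste(a$chain_id, a$residue_id)
    sig <- vapply(paste(rt$chain, rt$residue_id), function(k) {
      spec$atom_sigma[which(key == k)[1]]
    }, 0)
    out$rmsf <- data.frame(chain = rt$chain, residue_id = rt$residue_id,
                           rmsf = sqrt(3) * unname(sig),
                           stringsAsFactors = FALSE)
  }
  if (has_sched && any(c("adjacency", "occupancy") %in% include)) {
    T <- spec$n_frames
    sched <- lapply(spec$schedules, function(s) {
      pattern <- if (is.null(s$pattern)) "block" else s$pattern
      f <- if (pattern == "block") round(s$fraction * T) / T else s$fraction
      data.frame(acidic = s$acidic, basic = s$basic,
                 occupancy = f,
                 weight = f / s$formed + (1 - f) / s$broken,
                 stringsAsFactors = FALSE)
    })
    sched <- do.call(rbind, sched)
    if ("adjacency" %in% include) out$adjacency <- sched[c("acidic", "basic", "weight")]
    if ("occupancy" %in% include) out$occupancy <- sched[c("acidic", "basic", "occupancy")]
  }
  if ("entropy" %in% include) {
    lam <- rep(a$mass * spec$atom_sigma^2, each = 3)
    lam <- sort(lam[lam > 0], decreasing = TRUE)
    omega <- sqrt(.kB * temperature / (lam * .amu_kg * 1e-20))
    spec_qh <- structure(list(eigenvalues = lam, frequencies = omega,
                              n_dropped = 3 * nrow(a) - length(lam),
                              temperature = temperature),
                         class = "qh_spectrum")
    out$entropy <- quasiharmonic_entropy(spec_qh, label = "oracle")
  }
  out
}

#' Serialize a synthetic specification to YAML
#'
#' Only toy-topology-based specs can be round-tripped; the YAML records the
#' toy parameters, amplitude map, schedules and sampling settings.
#'
#' @param params list with `toy` (arguments to [toy_complex_topology()]) and
#'   the remaining [synthetic_spec()] arguments (`amplitudes`, `schedules`,
#'   `n_frames`, `frame_interval`, `noise`, `seed`).
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_synthetic_yaml <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}

#' Read a synthetic specification from YAML
#'
#' @param path YAML file written by [write_synthetic_yaml()] (or hand
#'   authored with the same fields).
#' @return a [synthetic_spec()].
#' @export
read_synthetic_yaml <- function(path) {
  p <- yaml::read_yaml(path)
  toy <- do.call(toy_complex_topology, p$toy)
  amp <- p$amplitudes
  if (is.list(amp) && !is.data.frame(amp)) amp <- unlist(amp)
  synthetic_spec(toy$topology, toy$coords,
                 amplitudes = if (is.null(amp)) 0.3 else amp,
                 schedules = if (is.null(p$schedules)) list() else p$schedules,
                 n_frames = if (is.null(p$n_frames)) 1000 else p$n_frames,
                 frame_interval = if (is.null(p$frame_interval)) 1
                                  else p$frame_interval,
                 noise = if (is.null(p$noise)) 0 else p$noise,
                 seed = if (is.null(p$seed)) 1 else p$seed)
}
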