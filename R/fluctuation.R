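# RMSD series and drift, iterative average structures, per-residue RMSF
# profiles, difference maps and significance tests between ensembles.

# Tight batch Kabsch fit of every frame onto `ref` over fit indices; same
# math as kabsch_superpose() with the per-frame overhead stripped (the loop
# runs once per frame for every trajectory-level statistic).
.fit_frames <- function(coords, ref, fidx) {
  T <- dim(coords)[1]; N <- dim(coords)[2]
  nf <- length(fidx)
  if (nf < 3) stop("superposition needs at least 3 fit atoms")
  Q <- ref[fidx, , drop = FALSE]
  cQ <- colMeans(Q)
  Q0 <- Q - rep(cQ, each = nf)
  sv <- svd(Q0, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-10 * max(sv[1], 1e-30))
    stop("degenerate (collinear) fit selection")
  out <- array(NA_real_, dim(coords))
  for (t in seq_len(T)) {
    X <- coords[t, , ]
    dim(X) <- c(N, 3)
    P <- X[fidx, , drop = FALSE]
    cP <- colMeans(P)
    s <- La.svd(crossprod(P - rep(cP, each = nf), Q0))
    V <- t(s$vt)
    if (det(V %*% t(s$u)) < 0) V[, 3] <- -V[, 3]
    R <- V %*% t(s$u)
    tr <- cQ - as.numeric(cP %*% t(R))
    out[t, , ] <- X %*% t(R) + rep(tr, each = N)
  }
  out
}

#' RMSD time series against a reference structure
#'
#' Each frame is Kabsch-fitted to `reference` on `fit_sel` and the RMSD is
#' measured over `measure_sel`.  The drift is the ordinary-least-squares slope
#' of RMSD versus time, converted from Angstrom/ps to pm/ns (x 1e5), the
#' convention used for trajectory stability tables.
#'
#' @param ens an [ensemble()].
#' @param reference N x 3 reference coordinates (e.g. the initial minimised
#'   structure, `frame_coords(ens, 1)`).
#' @param fit_sel [selection()] used for the superposition.
#' @param measure_sel [selection()] over which RMSD is measured (defaults to
#'   `fit_sel`).
#' @return object of class `rmsd_series`: `values` (Angstrom), `time` (ps),
#'   `average`, `maximum`, `drift` (pm/ns), `drift_se` (pm/ns), `reference`
#'   descriptor.
#' @export
rmsd_series <- function(ens, reference, fit_sel, measure_sel = fit_sel) {
  T <- n_frames(ens)
  midx <- .sel_idx(measure_sel)
  fitted <- .fit_frames(ens$coords, reference, .sel_idx(fit_sel))
  d2 <- (fitted[, midx, , drop = FALSE] -
           rep(reference[midx, , drop = FALSE], each = T))^2
  vals <- sqrt(rowSums(d2, dims = 1) / length(midx))
  time <- (seq_len(T) - 1) * ens$frame_interval
  if (T > 1 && stats::var(time) > 0) {
    ols <- stats::lm.fit(cbind(1, time), vals)
    slope <- ols$coefficients[2]
    resid <- ols$residuals
    se <- if (T > 2)
      sqrt(sum(resid^2) / (T - 2) / sum((time - mean(time))^2)) else NA_real_
  } else {
    slope <- 0; se <- NA_real_
  }
  structure(list(values = vals, time = time, average = mean(vals),
                 maximum = max(vals), drift = unname(slope) * 1e5,
                 drift_se = se * 1e5,
                 reference = "supplied reference frame"),
            class = "rmsd_series")
}

#' Iteratively fitted average structure
#'
#' Fits all frames to a running mean structure (starting from frame 1) and
#' re-averages until the mean moves by less than `tol` per coordinate RMS,
#' up to `max_iter` iterations.
#'
#' @param ens an [ensemble()] with at least 2 frames (a single frame is
#'   returned as-is).
#' @param fit_sel [selection()] used for the superposition.
#' @param tol convergence threshold on the RMS shift of the mean (Angstrom).
#' @param max_iter maximum iterations.
#' @return N x 3 matrix of mean coordinates with attribute `iterations`.
#' @export
average_structure <- function(ens, fit_sel, tol = 1e-6, max_iter = 10) {
  T <- n_frames(ens)
  ref <- frame_coords(ens, 1)
  if (T == 1) return(ref)
  fidx <- .sel_idx(fit_sel)
  for (it in seq_len(max_iter)) {
    fitted <- .fit_frames(ens$coords, ref, fidx)
    new_mean <- colMeans(fitted, dims = 1)
    shift <- sqrt(mean((new_mean - ref)^2))
    ref <- new_mean
    if (shift < tol) {
      attr(ref, "iterations") <- it
      return(ref)
    }
  }
  stop("average structure did not converge: last shift ",
       format(shift, digits = 4), " A after ", max_iter, " iterations")
}

# Fit all frames to the converged average; returns T x N x 3 array.
.fitted_coords <- function(ens, fit_sel) {
  avg <- average_structure(ens, fit_sel)
  .fit_frames(ens$coords, avg, .sel_idx(fit_sel))
}

#' Per-residue RMSF profile
#'
#' Frames are superposed onto the iteratively fitted average structure; the
#' per-atom RMSF is \eqn{\sqrt{\langle |r_i - \langle r_i\rangle|^2\rangle}}
#' and residues aggregate their scope atoms by a mass-weighted mean
#' (consistent with the mass weighting of the entropy covariance).
#'
#' @param ens an [ensemble()] with at least 2 frames.
#' @param fit_sel [selection()] used for the superposition.
#' @param scope "backbone" (main-chain N, CA, C, O) or "all".
#' @return object of class `fluct_profile`: data.frame with columns `chain`,
#'   `residue_id`, `rmsf` (Angstrom); attributes `scope` and `label`.
#' @export
rmsf_profile <- function(ens, fit_sel, scope = c("backbone", "all")) {
  scope <- match.arg(scope)
  if (n_frames(ens) < 2) stop("RMSF needs at least 2 frames")
  fitted <- .fitted_coords(ens, fit_sel)
  mean_xyz <- apply(fitted, c(2, 3), mean)
  dev2 <- sweep(fitted, c(2, 3), mean_xyz)^2
  atom_rmsf <- sqrt(apply(dev2, 2, mean) * 3)  # mean over T and xyz, x3 -> |dr|^2

  a <- ens$topology$atoms
  in_scope <- a$is_atom &
    (scope == "all" | a$atom_name %in% .backbone_names)
  key <- paste(a$chain_id, a$residue_id)
  keys <- unique(key[in_scope])
  rows <- lapply(keys, function(k) {
    i <- which(key == k & in_scope)
    data.frame(chain = a$chain_id[i[1]], residue_id = a$residue_id[i[1]],
               rmsf = sum(a$mass[i] * atom_rmsf[i]) / sum(a$mass[i]),
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  attr(prof, "scope") <- scope
  attr(prof, "label") <- ens$label
  class(prof) <- c("fluct_profile", "data.frame")
  prof
}

.check_profile_keys <- function(a, b) {
  ka <- paste(a$chain, a$residue_id)
  kb <- paste(b$chain, b$residue_id)
  if (length(ka) != length(kb) || any(ka != kb)) {
    unmatched <- union(setdiff(ka, kb), setdiff(kb, ka))
    stop("profiles cover different residues: ",
         paste(unmatched, collapse = ", "))
  }
}

#' Difference between two fluctuation profiles (a - b)
#'
#' A positive value means greater mobility in `a` than in `b` for that
#' residue (the sign convention of free-vs-bound comparisons: `a` = bound
#' species, `b` = reference/free species, or as the caller chooses).
#'
#' @param a,b [rmsf_profile()] objects over identical residues.
#' @return data.frame with `chain`, `residue_id`, `delta_rmsf` (Angstrom).
#' @export
profile_difference <- function(a, b) {
  .check_profile_keys(a, b)
  data.frame(chain = a$chain, residue_id = a$residue_id,
             delta_rmsf = a$rmsf - b$rmsf, stringsAsFactors = FALSE)
}

#' t-test between two fluctuation profiles
#'
#' Tests whether the mean per-residue RMSF differs between the two profiles.
#' Default is the paired two-sided Student t-test across residues (pairing by
#' residue); `paired = FALSE` gives Welch's unpaired variant.
#'
#' @param a,b [rmsf_profile()] objects over identical residues.
#' @param alpha significance level (default 0.05).
#' @param paired pair by residue (default TRUE).
#' @return list with `t`, `df`, `p_value`, `mean_difference`, `significant`,
#'   `alpha`, `paired`, `degenerate` (TRUE when the difference vector has zero
#'   variance, in which case `p_value` is NaN).
#' @export
compare_profiles_ttest <- function(a, b, alpha = 0.05, paired = TRUE) {
  .check_profile_keys(a, b)
  if (nrow(a) < 3) stop("need at least 3 residues for a t-test")
  d <- a$rmsf - b$rmsf
  if (paired && stats::var(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1, p_value = NaN,
                mean_difference = mean(d), significant = FALSE,
                alpha = alpha, paired = paired, degenerate = TRUE))
  }
  ht <- if (paired) stats::t.test(a$rmsf, b$rmsf, paired = TRUE)
        else stats::t.test(a$rmsf, b$rmsf, paired = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = mean(d),
       significant = ht$p.value < alpha, alpha = alpha, paired = paired,
       degenerate = FALSE)
}

#' Per-residue RMSD map between two structures
#'
#' After a single global Kabsch fit of `coords_b` onto `coords_a` over
#' `fit_sel`, reports per-residue RMSD over the scope atoms (used to map
#' where two average structures differ along the sequence).
#'
#' @param top the shared [topology()].
#' @param coords_a,coords_b N x 3 coordinate matrices on `top`.
#' @param fit_sel [selection()] for the global fit.
#' @param scope "backbone" or "all".
#' @return data.frame with `chain`, `residue_id`, `rmsd` (Angstrom).
#' @export
residue_rmsd_map <- function(top, coords_a, coords_b, fit_sel,
                             scope = c("backbone", "all")) {
  scope <- match.arg(scope)
  fit <- kabsch_superpose(coords_b, coords_a, fit_sel)
  a <- top$atoms
  in_scope <- a$is_atom & (scope == "all" | a$atom_name %in% .backbone_names)
  key <- paste(a$chain_id, a$residue_id)
  keys <- unique(key[in_scope])
  d2 <- rowSums((fit$coords - coords_a)^2)
  rows <- lapply(keys, function(k) {
    i <- which(key == k & in_scope)
    data.frame(chain = a$chain_id[i[1]], residue_id = a$residue_id[i[1]],
               rmsd = sqrt(mean(d2[i])), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
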