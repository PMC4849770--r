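# Geometry: centers of mass, radius of gyration, Kabsch superposition,
# principal inertia axes, and projection of a probe CoM into a body frame.

.sel_idx <- function(sel) {
  idx <- as.integer(sel)
  if (!length(idx)) stop("empty selection")
  idx
}

#' Center of mass of a selection in one frame
#'
#' @param ens an [ensemble()].
#' @param sel a [selection()].
#' @param frame frame index.
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(ens, sel, frame = 1) {
  idx <- .sel_idx(sel)
  x <- frame_coords(ens, frame)[idx, , drop = FALSE]
  m <- ens$topology$atoms$mass[idx]
  colSums(x * m) / sum(m)
}

#' Radius of gyration series
#'
#' Per frame, the mass-weighted RMS distance of the selected atoms from their
#' center of mass:
#' \deqn{R_G = \sqrt{\sum_i m_i |r_i - r_{CoM}|^2 / \sum_i m_i}.}
#' R_G grows when a complex dissociates or a chain unfolds, so a flat series
#' is the standard stability check on a trajectory.
#'
#' @param ens an [ensemble()].
#' @param sel a [selection()].
#' @return object of class `rg_series`: list with `values` (Angstrom, one per
#'   frame), `mean`, `sem`, `selection` descriptor.
#' @export
radius_of_gyration <- function(ens, sel) {
  idx <- .sel_idx(sel)
  m <- ens$topology$atoms$mass[idx]
  M <- sum(m)
  T <- n_frames(ens)
  vals <- numeric(T)
  for (t in seq_len(T)) {
    x <- frame_coords(ens, t)[idx, , drop = FALSE]
    com <- colSums(x * m) / M
    d2 <- rowSums(sweep(x, 2, com)^2)
    vals[t] <- sqrt(sum(m * d2) / M)
  }
  structure(list(values = vals, mean = mean(vals),
                 sem = if (T > 1) stats::sd(vals) / sqrt(T) else 0,
                 selection = attr(sel, "descriptor")),
            class = "rg_series")
}

#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation + translation minimising the RMSD between
#' `mobile` and `reference` over the atoms in `sel`, applies it to all mobile
#' atoms, and reports the minimised RMSD over `sel`.  The SVD determinant
#' correction guarantees a rotation (no reflection).
#'
#' @param mobile N x 3 coordinate matrix to move.
#' @param reference N x 3 coordinate matrix held fixed.
#' @param sel a [selection()] with at least 3 non-collinear atoms (used for
#'   the fit; defaults to all atoms).
#' @param weights optional per-atom fit weights over `sel` (default uniform).
#' @return list with `coords` (transformed mobile, N x 3), `rmsd` (Angstrom,
#'   over `sel`), `rotation` (3 x 3), `translation` (length 3).
#' @export
kabsch_superpose <- function(mobile, reference, sel = NULL, weights = NULL) {
  if (is.null(sel)) sel <- selection(seq_len(nrow(mobile)))
  idx <- .sel_idx(sel)
  if (length(idx) < 3) stop("superposition needs at least 3 fit atoms")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, length(idx)) else weights
  w <- w / sum(w)
  cP <- colSums(P * w); cQ <- colSums(Q * w)
  P0 <- sweep(P, 2, cP); Q0 <- sweep(Q, 2, cQ)
  s <- svd(crossprod(P0 * w, Q0))
  # collinearity: centred fit atoms must span at least a plane
  if (s$d[2] <= 1e-10 * max(s$d[1], 1e-30))
    stop("degenerate (collinear) fit selection")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- sweep(mobile, 2, cP) %*% t(R)
  moved <- sweep(moved, 2, cQ, FUN = "+")
  rmsd <- sqrt(sum(w * rowSums((moved[idx, , drop = FALSE] - Q)^2)))
  list(coords = moved, rmsd = rmsd, rotation = R,
       translation = as.numeric(cQ - cP %*% t(R)))
}

# Inertia tensor of a mass-weighted point set about its CoM.
.inertia_tensor <- function(x, m) {
  com <- colSums(x * m) / sum(m)
  d <- sweep(x, 2, com)
  diag(sum(m * rowSums(d^2)), 3) - crossprod(d * m, d)
}

#' Principal inertia frame of a selection in one frame
#'
#' Diagonalises the inertia tensor of the selected atoms.  Axis rows are
#' ordered by descending inertia moment, so the third row is the long
#' (smallest-moment) axis of the body.  Eigenvector sign is arbitrary; by
#' default the largest-magnitude component of rows 1-2 is made positive and
#' row 3 completes a right-handed frame; pass `prev` (a previous frame's
#' `axes`) to instead pick signs by continuity.
#'
#' @param ens an [ensemble()].
#' @param sel a [selection()] with >= 3 non-collinear atoms.
#' @param frame frame index.
#' @param prev optional 3 x 3 axes matrix for sign continuity.
#' @return object of class `principal_frame`: list with `com` (Angstrom),
#'   `axes` (3 x 3, rows = principal axes, det +1), `moments` (amu Angstrom^2,
#'   descending), `degenerate` flag (near-equal moments).
#' @export
principal_frame <- function(ens, sel, frame = 1, prev = NULL) {
  idx <- .sel_idx(sel)
  if (length(idx) < 3) stop("principal frame needs at least 3 atoms")
  x <- frame_coords(ens, frame)[idx, , drop = FALSE]
  m <- ens$topology$atoms$mass[idx]
  I <- .inertia_tensor(x, m)
  e <- eigen(I, symmetric = TRUE)   # eigenvalues descending
  if (e$values[1] <= 1e-10 * sum(m))
    stop("degenerate (collinear or single-point) selection")
  axes <- t(e$vectors)
  degenerate <- (e$values[1] - e$values[3]) <= 1e-8 * max(e$values[1], 1e-30)
  for (k in 1:2) {
    s <- if (!is.null(prev)) sign(sum(axes[k, ] * prev[k, ]))
         else sign(axes[k, which.max(abs(axes[k, ]))])
    if (s < 0) axes[k, ] <- -axes[k, ]
  }
  axes[3, ] <- .cross3(axes[1, ], axes[2, ])
  structure(list(com = colSums(x * m) / sum(m), axes = axes,
                 moments = e$values, degenerate = degenerate),
            class = "principal_frame")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Trace of a probe center of mass in a body's principal frame
#'
#' For each frame, expresses the CoM of `probe` in the principal-axis
#' coordinate system of `body` (e.g. the antigenic peptide's CoM in the HLA
#' frame).  Axis signs are anchored, per frame, so that the projection of the
#' CoM offset on axes 1-2 is non-negative in the first frame and continuous
#' thereafter; the third axis completes a right-handed frame.  The trace is
#' therefore invariant under any global rigid motion applied to the whole
#' system.
#'
#' @param ens an [ensemble()].
#' @param body [selection()] defining the reference body.
#' @param probe [selection()] whose CoM is tracked.
#' @return T x 3 matrix of local coordinates (columns x, y, z; z is the body
#'   long axis).
#' @export
project_com_trace <- function(ens, body, probe) {
  T <- n_frames(ens)
  out <- matrix(NA_real_, T, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  anchor <- NULL
  for (t in seq_len(T)) {
    pf <- principal_frame(ens, body, t, prev = anchor)
    off <- center_of_mass(ens, probe, t) - pf$com
    axes <- pf$axes
    nrm <- sqrt(sum(off^2))
    for (k in 1:2) {
      dp <- sum(axes[k, ] * off)
      if (abs(dp) > 1e-9 * max(nrm, 1e-30)) {
        if (dp < 0) axes[k, ] <- -axes[k, ]
      } # else keep continuity/default sign
    }
    axes[3, ] <- .cross3(axes[1, ], axes[2, ])
    anchor <- axes
    out[t, ] <- as.numeric(axes %*% off)
  }
  out
}
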