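# Quasi-harmonic conformational entropy from mass-weighted covariance
# matrices, and the binding thermodynamic cycle
# (-TdS_binding = -TdS_ternary - (-TdS_freeReceptor) - (-TdS_binary)).

#' Mass-weighted coordinate covariance matrix
#'
#' Stacks the selected atoms' coordinates as q = sqrt(m_i) r_i and returns
#' C = <dq dq^T> over frames (population normalisation, 1/T) in amu
#' Angstrom^2.  When `fit_sel` is given, frames are first superposed onto the
#' iteratively fitted average structure over that selection, which removes
#' (most of) the rigid-body contribution; pass `fit_sel = NULL` for raw
#' covariances (e.g. for independent-oscillator benchmarks).
#'
#' @param ens an [ensemble()] with at least 2 frames.
#' @param sel [selection()] of atoms entering the covariance (entropy scope).
#' @param fit_sel optional [selection()] for superposition (NULL = no fit).
#' @return symmetric positive-semidefinite 3n x 3n matrix (amu Angstrom^2).
#' @export
mass_weighted_covariance <- function(ens, sel, fit_sel = NULL) {
  T <- n_frames(ens)
  if (T < 2) stop("covariance needs at least 2 frames")
  idx <- .sel_idx(sel)
  coords <- if (is.null(fit_sel)) ens$coords else .fitted_coords(ens, fit_sel)
  n <- length(idx)
  X <- matrix(NA_real_, T, 3 * n)
  for (t in seq_len(T)) {
    fr <- coords[t, idx, , drop = TRUE]
    dim(fr) <- c(n, 3)
    X[t, ] <- as.numeric(t(fr))   # x1,y1,z1,x2,...
  }
  w <- rep(sqrt(ens$topology$atoms$mass[idx]), each = 3)
  X <- sweep(X, 2, w, `*`)
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / T
  (C + t(C)) / 2
}

#' Quasi-harmonic mode spectrum of a covariance matrix
#'
#' Diagonalises the mass-weighted covariance; each retained eigenvalue
#' lambda_i (amu Angstrom^2) defines an effective harmonic-oscillator
#' frequency \eqn{\omega_i = \sqrt{k_B T / \lambda_i}}.  By default the 6
#' smallest eigenvalues are discarded (superposed ensembles leave ~6
#' quasi-null rigid-body modes) along with anything below `tolerance`.
#'
#' @param cov symmetric PSD matrix from [mass_weighted_covariance()].
#' @param temperature temperature in K (default 298).
#' @param tolerance eigenvalue floor in amu Angstrom^2 (default 1e-8).
#' @param n_drop number of smallest eigenvalues to discard regardless of
#'   magnitude (default 6; use 0 for unfitted benchmark covariances).
#' @return object of class `qh_spectrum`: `eigenvalues` (amu Angstrom^2,
#'   descending), `frequencies` (rad/s), `n_dropped`, `temperature`.
#' @export
quasiharmonic_spectrum <- function(cov, temperature = 298, tolerance = 1e-8,
                                   n_drop = 6) {
  asym <- max(abs(cov - t(cov)))
  if (asym > 1e-8 * max(abs(cov), 1))
    stop("covariance matrix is not symmetric (max asymmetry ",
         format(asym, digits = 3), ")")
  lam <- eigen((cov + t(cov)) / 2, symmetric = TRUE,
               only.values = TRUE)$values   # descending
  n <- length(lam)
  keep <- lam[seq_len(max(0, n - n_drop))]
  keep <- keep[keep > tolerance]
  omega <- sqrt(.kB * temperature / (keep * .amu_kg * 1e-20))
  structure(list(eigenvalues = keep, frequencies = omega,
                 n_dropped = n - length(keep), temperature = temperature),
            class = "qh_spectrum")
}

# Per-mode quantum harmonic-oscillator entropy in units of kB, as a function
# of alpha = hbar*omega / (kB*T); overflow-safe for large alpha.
.qho_entropy_kb <- function(alpha) {
  out <- numeric(length(alpha))
  ok <- alpha < 700
  a <- alpha[ok]
  out[ok] <- a / expm1(a) - log1p(-exp(-a))
  out
}

#' Quasi-harmonic conformational entropy
#'
#' Quantum harmonic-oscillator estimator over the retained modes:
#' \deqn{S = k_B \sum_i \left[\frac{\hbar\omega_i/k_BT}
#' {e^{\hbar\omega_i/k_BT} - 1} - \ln\!\left(1 -
#' e^{-\hbar\omega_i/k_BT}\right)\right],}
#' reported as the molar quantity -T S in kJ/mol (the sign convention of
#' binding-cycle tables, where single-species entries are negative).  Very
#' stiff modes contribute nothing (quantum freeze-out); softer modes (larger
#' eigenvalues) strictly increase S.
#'
#' @param spectrum a [quasiharmonic_spectrum()].
#' @param label species tag carried into reports.
#' @return object of class `entropy_result`: `minus_T_dS` (kJ/mol),
#'   `S_molar` (J/mol/K), `spectrum`, `label`.
#' @export
quasiharmonic_entropy <- function(spectrum, label = "") {
  Tk <- spectrum$temperature
  alpha <- .hbar * spectrum$frequencies / (.kB * Tk)
  S <- .R_gas * sum(.qho_entropy_kb(alpha))   # J / mol / K
  structure(list(minus_T_dS = -Tk * S / 1000, S_molar = S,
                 spectrum = spectrum, label = label),
            class = "entropy_result")
}

.minus_tds <- function(x) {
  if (inherits(x, "entropy_result")) x$minus_T_dS else as.numeric(x)
}

.temp_of <- function(x) {
  if (inherits(x, "entropy_result")) x$spectrum$temperature else NA_real_
}

#' Binding thermodynamic cycle for conformational entropy
#'
#' Combines per-species -TdS values through the cycle
#' \deqn{-T\Delta S_{binding} = -T\Delta S_{ternary} -
#' (-T\Delta S_{freeReceptor}) - (-T\Delta S_{binary}),}
#' i.e. the entropic cost of assembling the ternary complex from the free
#' receptor and the binary complex.  When a `reference` cycle is supplied,
#' the relative quantities (Delta-Delta) are reported against it.
#'
#' @param binary,ternary,free_receptor [quasiharmonic_entropy()] results or
#'   bare -TdS values in kJ/mol.
#' @param reference optional `cycle_result` of the reference species.
#' @param label species tag.
#' @return object of class `cycle_result`: `binding` (kJ/mol), `binary`,
#'   `ternary`, `free_receptor`, and (with a reference)
#'   `delta_delta_binding`, `delta_delta_binary` (kJ/mol).
#' @export
binding_cycle <- function(binary, ternary, free_receptor, reference = NULL,
                          label = "") {
  temps <- c(.temp_of(binary), .temp_of(ternary), .temp_of(free_receptor))
  temps <- temps[!is.na(temps)]
  if (length(temps) > 1 && diff(range(temps)) > 1e-9)
    stop("temperature mismatch across cycle inputs: ",
         paste(format(temps), collapse = ", "))
  b <- .minus_tds(binary); t3 <- .minus_tds(ternary)
  fr <- .minus_tds(free_receptor)
  res <- list(label = label, binary = b, ternary = t3, free_receptor = fr,
              binding = t3 - fr - b)
  if (!is.null(reference)) {
    res$delta_delta_binding <- res$binding - reference$binding
    res$delta_delta_binary <- b - reference$binary
  }
  structure(res, class = "cycle_result")
}
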