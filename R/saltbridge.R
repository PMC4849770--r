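# Salt-bridge network analysis: candidate detection, per-pair O-N distance
# series, time-averaged inverse-distance adjacency matrices, Frobenius
# inner products / normalized distances, intermolecular submatrices, and
# occupancy-based bridge counting.

# Side of the binding interface for a chain role.
.role_side <- function(role) {
  ifelse(role %in% c("presenter", "peptide"), "pmhc",
         ifelse(role %in% c("receptor_alpha", "receptor_beta"), "tcr",
                NA_character_))
}

.group_label <- function(g) .residue_label(g$resname, g$residue_id, g$chain)

# Per-frame minimum O-N distance between two charged groups, vectorised over
# frames: T-vector.
.pair_min_distance <- function(coords, idx_a, idx_b) {
  T <- dim(coords)[1]
  dmin <- rep(Inf, T)
  for (i in idx_a) for (j in idx_b) {
    dx <- coords[, i, 1] - coords[, j, 1]
    dy <- coords[, i, 2] - coords[, j, 2]
    dz <- coords[, i, 3] - coords[, j, 3]
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy + dz * dz))
  }
  dmin
}

#' Find candidate salt-bridge pairs
#'
#' A pair of charged groups (acidic carboxylate oxygens vs basic sidechain
#' nitrogens, per the topology's catalog) is a candidate if its minimum O-N
#' distance is within `cutoff` in at least one frame.  The default 8 Angstrom
#' cutoff is the customary generous detection radius; occupancy-based
#' counting ([count_bridges()]) applies the tighter contact criterion.
#'
#' @param ens an [ensemble()].
#' @param cutoff detection cutoff in Angstrom (default 8).
#' @return object of class `bridge_pairs`: data.frame with acidic/basic
#'   labels, chains, residue ids and an `intermolecular` flag (pair spans the
#'   presenter/peptide side and the receptor side).
#' @export
find_candidate_pairs <- function(ens, cutoff = 8.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  g <- ens$topology$charged_groups
  acid <- Filter(function(x) x$polarity == "acidic", g)
  base <- Filter(function(x) x$polarity == "basic", g)
  roles <- ens$topology$chains
  rows <- list()
  for (ga in acid) for (gb in base) {
    d <- .pair_min_distance(ens$coords, ga$atom_idx, gb$atom_idx)
    if (min(d) <= cutoff) {
      sa <- .role_side(roles[[ga$chain]])
      sb <- .role_side(roles[[gb$chain]])
      rows[[length(rows) + 1L]] <- data.frame(
        acidic = .group_label(ga), acidic_chain = ga$chain,
        acidic_resid = ga$residue_id,
        basic = .group_label(gb), basic_chain = gb$chain,
        basic_resid = gb$residue_id,
        intermolecular = !is.na(sa) && !is.na(sb) && sa != sb,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(acidic = character(), acidic_chain = character(),
                      acidic_resid = integer(), basic = character(),
                      basic_chain = character(), basic_resid = integer(),
                      intermolecular = logical(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$acidic_chain, out$acidic_resid,
                     out$basic_chain, out$basic_resid), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("bridge_pairs", "data.frame")
  out
}

.find_group <- function(top, label) {
  hits <- Filter(function(g) .group_label(g) == label, top$charged_groups)
  if (!length(hits))
    stop("charged group not found in topology: ", label)
  hits[[1]]
}

#' Per-frame O-N distance series for one bridge pair
#'
#' Per frame, the minimum over all (acidic O) x (basic N) member-atom
#' combinations — the standard multi-atom salt-bridge convention, symmetric
#' in the guanidinium nitrogens of arginine.
#'
#' @param ens an [ensemble()].
#' @param pair one row of a [find_candidate_pairs()] result (or a list with
#'   `acidic`/`basic` labels).
#' @return object of class `distance_series`: list with `values` (Angstrom,
#'   per frame), `pair` labels, `time` (ps).
#' @export
distance_series <- function(ens, pair) {
  ga <- .find_group(ens$topology, pair$acidic)
  gb <- .find_group(ens$topology, pair$basic)
  d <- .pair_min_distance(ens$coords, ga$atom_idx, gb$atom_idx)
  structure(list(values = d,
                 time = (seq_along(d) - 1) * ens$frame_interval,
                 pair = c(acidic = pair$acidic, basic = pair$basic)),
            class = "distance_series")
}

#' Time-averaged inverse-distance adjacency matrix
#'
#' Builds the weighted adjacency matrix A over acidic (rows) x basic
#' (columns) residues with
#' \deqn{a_{ij} = \frac{1}{T}\sum_t \frac{1}{d_{ij}(t)}}
#' in 1/Angstrom, where d_ij(t) is the per-frame minimum O-N distance.  The
#' electrostatic pair energy is proportional to 1/d, so these weights rank
#' bridge strength.  With `normalize = TRUE` the weights are divided by
#' `norm_constant` (default 1/2.8, the inverse of a tight contact distance,
#' capping a fully formed bridge near 1).
#'
#' @param ens an [ensemble()].
#' @param pairs a [find_candidate_pairs()] result for this ensemble.
#' @param normalize divide weights by `norm_constant`.
#' @param norm_constant normalization constant in 1/Angstrom.
#' @return object of class `sb_matrix`: numeric matrix with residue labels
#'   and attributes `normalized`, `norm_constant`.
#' @export
adjacency_matrix <- function(ens, pairs, normalize = FALSE,
                             norm_constant = 1 / 2.8) {
  rl <- unique(pairs$acidic[order(pairs$acidic_chain, pairs$acidic_resid)])
  cl <- unique(pairs$basic[order(pairs$basic_chain, pairs$basic_resid)])
  m <- matrix(0, length(rl), length(cl), dimnames = list(rl, cl))
  for (k in seq_len(nrow(pairs))) {
    d <- distance_series(ens, pairs[k, ])$values
    if (any(d <= 0)) stop("zero O-N distance for pair ", pairs$acidic[k],
                          " / ", pairs$basic[k], ": non-physical input")
    m[pairs$acidic[k], pairs$basic[k]] <- mean(1 / d)
  }
  if (normalize) m <- m / norm_constant
  structure(m, normalized = normalize,
            norm_constant = if (normalize) norm_constant else NA_real_,
            class = c("sb_matrix", "matrix", "array"))
}

.as_plain_matrix <- function(m) {
  matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
}

.check_same_labels <- function(a, b) {
  if (!identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b)))
    stop("matrices have different labels; use align_matrices() first")
}

#' Frobenius inner product of two adjacency matrices
#'
#' \eqn{\langle A, B\rangle_F = Tr(A B^T) = \sum_{ij} a_{ij} b_{ij}} for
#' real matrices on identical label sets.
#'
#' @param a,b labeled numeric matrices with identical row/column labels.
#' @return scalar inner product.
#' @export
frobenius_inner <- function(a, b) {
  .check_same_labels(a, b)
  sum(a * b)
}

# Sort residue labels deterministically by (chain, residue id, name).
.sort_labels <- function(labels) {
  if (!length(labels)) return(labels)
  p <- .parse_residue_label(labels)
  labels[order(p$chain, p$residue_id, p$resname)]
}

#' Align two adjacency matrices on the union of their labels
#'
#' Different complexes exhibit different bridge sets; before comparing
#' patterns both matrices are re-indexed on the union of row and column
#' labels (deterministic chain/residue order), absent entries zero.
#'
#' @param a,b `sb_matrix` objects (or labeled matrices).
#' @return list with elements `a` and `b` on the union label set.
#' @export
align_matrices <- function(a, b) {
  rl <- .sort_labels(union(rownames(a), rownames(b)))
  cl <- .sort_labels(union(colnames(a), colnames(b)))
  pad <- function(m) {
    out <- matrix(0, length(rl), length(cl), dimnames = list(rl, cl))
    if (nrow(m) && ncol(m))
      out[rownames(m), colnames(m)] <- .as_plain_matrix(m)
    attributes(out)$normalized <- attr(m, "normalized")
    out
  }
  list(a = pad(a), b = pad(b))
}

#' Normalized Frobenius distance between salt-bridge patterns
#'
#' With `normalized = TRUE` (default) each matrix is first scaled to unit
#' Frobenius norm (a zero matrix is left as zero) and the distance is
#' \deqn{d(A,B) = \|\hat A - \hat B\|_F = \sqrt{2 - 2\langle\hat A,\hat
#' B\rangle_F},}
#' which is zero for identical patterns, bounded by sqrt(2) for patterns with
#' disjoint support, scale-invariant, and satisfies the metric axioms.  With
#' `normalized = FALSE` the plain Frobenius norm of the difference is
#' returned.  Matrices with different label sets are aligned first.
#'
#' @param a,b `sb_matrix` objects or labeled matrices.
#' @param normalized use unit-Frobenius-normalized matrices (default TRUE).
#' @return non-negative scalar; attribute `degenerate` is TRUE when both
#'   matrices are zero (distance defined as 0).
#' @export
frobenius_distance <- function(a, b, normalized = TRUE) {
  if (!identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    al <- align_matrices(a, b); a <- al$a; b <- al$b
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (normalized) {
    if (na == 0 && nb == 0)
      return(structure(0, degenerate = TRUE))
    ah <- if (na > 0) a / na else a
    bh <- if (nb > 0) b / nb else b
    d <- sqrt(sum((ah - bh)^2))
  } else {
    if (na == 0 && nb == 0) return(structure(0, degenerate = TRUE))
    d <- sqrt(sum((a - b)^2))
  }
  structure(as.numeric(d), degenerate = FALSE)
}

#' Intermolecular submatrix of a salt-bridge matrix
#'
#' Keeps only entries whose residue pair spans the presenter/peptide side and
#' the receptor side of the interface (chain roles from the topology); all
#' other entries are zeroed.  Used to compare interface-only bridge patterns.
#'
#' @param m an `sb_matrix`.
#' @param top the [topology()] providing chain roles.
#' @return `sb_matrix` of the same shape.
#' @export
intermolecular_submatrix <- function(m, top) {
  if (!nrow(m) || !ncol(m)) return(m)
  side_of <- function(labels) {
    ch <- .parse_residue_label(labels)$chain
    unknown <- !(ch %in% names(top$chains))
    if (any(unknown))
      stop("label chain not present in topology: ",
           paste(labels[unknown], collapse = ", "))
    .role_side(top$chains[ch])
  }
  rs <- side_of(rownames(m)); cs <- side_of(colnames(m))
  keep <- outer(rs, cs, function(x, y) !is.na(x) & !is.na(y) & x != y)
  out <- .as_plain_matrix(m) * keep
  structure(out, normalized = attr(m, "normalized"),
            norm_constant = attr(m, "norm_constant"),
            class = class(m))
}

#' Count salt bridges by contact occupancy
#'
#' A pair counts as a salt bridge if its minimum O-N distance is below
#' `contact_cutoff` in at least a fraction `occupancy` of the frames.  The
#' default 3.2 Angstrom is the standard formed-contact criterion; detection
#' (8 Angstrom, any frame) and counting are deliberately separate passes.
#'
#' @param ens an [ensemble()].
#' @param pairs a [find_candidate_pairs()] result.
#' @param contact_cutoff contact distance in Angstrom (default 3.2).
#' @param occupancy minimum fraction of frames (default 0.5).
#' @return list with `count` (integer) and `occupancies` (data.frame with
#'   pair labels, `occupancy`, `counted`, `intermolecular`).
#' @export
count_bridges <- function(ens, pairs, contact_cutoff = 3.2, occupancy = 0.5) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive")
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
  occ <- vapply(seq_len(nrow(pairs)), function(k) {
    mean(distance_series(ens, pairs[k, ])$values < contact_cutoff)
  }, 0)
  counted <- occ >= occupancy
  df <- data.frame(acidic = pairs$acidic, basic = pairs$basic,
                   occupancy = occ, counted = counted,
                   intermolecular = pairs$intermolecular,
                   stringsAsFactors = FALSE)
  list(count = sum(counted), occupancies = df)
}
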