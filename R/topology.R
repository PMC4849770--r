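# Domain containers: topology (atoms + chain roles + charged-group catalog),
# ensemble (frames x atoms x 3 coordinates), and atom selections.

#' Default charged sidechain group catalog
#'
#' Salt-bridge searches pair sidechain carboxylate oxygens of acidic residues
#' with sidechain nitrogens of basic residues.  The default catalog covers
#' Asp/Glu (acidic) and Lys/Arg (basic); histidine and chain-terminal
#' amino/carboxylate groups are excluded by default, because interface salt
#' bridges in class-I p-HLA-TCR systems are dominated by Asp/Glu vs Lys/Arg
#' pairs.  Supply a modified catalog to include them.
#'
#' @return data.frame with columns `resname`, `polarity` ("acidic"/"basic")
#'   and `atoms` (comma-separated member atom names).
#' @export
default_charged_catalog <- function() {
  data.frame(
    resname  = c("ASP", "GLU", "LYS", "ARG"),
    polarity = c("acidic", "acidic", "basic", "basic"),
    atoms    = c("OD1,OD2", "OE1,OE2", "NZ", "NE,NH1,NH2"),
    stringsAsFactors = FALSE
  )
}

#' Construct a topology
#'
#' A topology binds an ordered atom table to chain role tags and a catalog of
#' charged sidechain groups.  Chain roles label the sides of the binding
#' interface: `presenter` (the MHC/HLA molecule), `peptide` (the antigen),
#' `receptor_alpha`/`receptor_beta` (the TCR chains), or `other`.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `residue_name`,
#'   `residue_id`, `chain_id`, `element`, `mass`, `is_atom` (ATOM vs HETATM).
#' @param chain_roles named character vector mapping chain id to role; chains
#'   not named default to "other".
#' @param catalog charged-group catalog (see [default_charged_catalog()]).
#' @return object of class `topology`.
#' @export
topology <- function(atoms, chain_roles = NULL,
                     catalog = default_charged_catalog()) {
  req <- c("serial", "atom_name", "residue_name", "residue_id", "chain_id",
           "element", "mass", "is_atom")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atom masses must be positive and finite")
  key <- paste(atoms$chain_id, atoms$residue_id, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue_id, atom_name): ",
         key[anyDuplicated(key)])

  chains <- sort(unique(atoms$chain_id))
  roles <- setNames(rep("other", length(chains)), chains)
  if (!is.null(chain_roles)) {
    ok <- c("presenter", "peptide", "receptor_alpha", "receptor_beta", "other")
    if (!all(chain_roles %in% ok))
      stop("unknown chain role(s): ",
           paste(setdiff(chain_roles, ok), collapse = ", "))
    known <- intersect(names(chain_roles), chains)
    roles[known] <- chain_roles[known]
  }

  top <- structure(
    list(atoms = atoms, chains = roles,
         charged_groups = .build_charged_groups(atoms, catalog),
         catalog = catalog),
    class = "topology")
  top
}

# Scan the atom table for residues matching the catalog; each hit records the
# indices of the member atoms actually present.
.build_charged_groups <- function(atoms, catalog) {
  groups <- list()
  res_key <- paste(atoms$chain_id, atoms$residue_id)
  for (k in seq_len(nrow(catalog))) {
    members <- strsplit(catalog$atoms[k], ",")[[1]]
    hit <- which(atoms$residue_name == catalog$resname[k] &
                   atoms$atom_name %in% members & atoms$is_atom)
    if (!length(hit)) next
    for (rk in unique(res_key[hit])) {
      idx <- hit[res_key[hit] == rk]
      groups[[length(groups) + 1L]] <- list(
        chain = atoms$chain_id[idx[1]],
        residue_id = atoms$residue_id[idx[1]],
        resname = catalog$resname[k],
        polarity = catalog$polarity[k],
        atom_idx = idx,
        atom_names = atoms$atom_name[idx])
    }
  }
  if (!length(groups)) return(groups)
  ord <- order(vapply(groups, `[[`, "", "chain"),
               vapply(groups, `[[`, 0L, "residue_id"))
  groups[ord]
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain_id, x$atoms$residue_id))), "residues,",
      length(x$chains), "chains\n")
  cat("  roles:", paste(names(x$chains), x$chains, sep = "=", collapse = " "),
      "\n")
  cat("  charged groups:", length(x$charged_groups), "\n")
  invisible(x)
}

#' Construct an ensemble
#'
#' An ensemble is a stack of T frames of N atoms bound to a topology.
#' Coordinates are in Angstrom throughout the package.
#'
#' @param topology a [topology()].
#' @param coords numeric array T x N x 3 (Angstrom).
#' @param frame_interval time between frames in ps (default 1, the typical
#'   snapshot save interval of production MD).
#' @param label free-text tag identifying the species/trajectory.
#' @return object of class `ensemble`.
#' @export
ensemble <- function(topology, coords, frame_interval = 1, label = "") {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be a T x N x 3 array")
  if (dim(coords)[2] != nrow(topology$atoms))
    stop("coords atom count (", dim(coords)[2],
         ") does not match topology (", nrow(topology$atoms), ")")
  if (dim(coords)[1] < 1) stop("ensemble needs at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in ensemble")
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval, label = label),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat("ensemble", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      ":", d[1], "frames x", d[2], "atoms,",
      x$frame_interval, "ps/frame\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an [ensemble()].
#' @return integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' Extract one frame as an N x 3 coordinate matrix
#' @param ens an [ensemble()].
#' @param frame frame index (1-based).
#' @return N x 3 numeric matrix (Angstrom).
#' @export
frame_coords <- function(ens, frame = 1) {
  T <- n_frames(ens)
  if (frame < 1 || frame > T) stop("frame index out of range 1..", T)
  x <- ens$coords[frame, , , drop = TRUE]
  dim(x) <- c(dim(ens$coords)[2], 3)
  x
}

#' Build an atom selection
#'
#' @param indices strictly increasing 1-based atom indices.
#' @param descriptor free-text description of the selection.
#' @param n_atoms optional total atom count for bound checking.
#' @return integer vector of class `selection`.
#' @export
selection <- function(indices, descriptor = "", n_atoms = NULL) {
  idx <- as.integer(indices)
  if (length(idx) && (any(diff(idx) <= 0) || idx[1] < 1))
    stop("selection indices must be strictly increasing and >= 1")
  if (!is.null(n_atoms) && length(idx) && idx[length(idx)] > n_atoms)
    stop("selection index exceeds atom count ", n_atoms)
  structure(idx, descriptor = descriptor, class = "selection")
}

.backbone_names <- c("N", "CA", "C", "O")

#' Select atoms from a topology
#'
#' Convenience selector over scope and chains.  "backbone" selects the
#' main-chain atoms N, CA, C, O.
#'
#' @param top a [topology()].
#' @param scope one of "all", "backbone".
#' @param chains optional chain ids to restrict to.
#' @param roles optional chain roles to restrict to (e.g. "presenter").
#' @return a [selection()].
#' @export
select_atoms <- function(top, scope = c("all", "backbone"), chains = NULL,
                         roles = NULL) {
  scope <- match.arg(scope)
  keep <- top$atoms$is_atom
  if (scope == "backbone") keep <- keep & top$atoms$atom_name %in% .backbone_names
  if (!is.null(roles)) chains <- union(chains, names(top$chains)[top$chains %in% roles])
  if (!is.null(chains)) keep <- keep & top$atoms$chain_id %in% chains
  desc <- paste0(scope,
                 if (!is.null(chains)) paste0(" [", paste(chains, collapse = ","), "]"))
  selection(which(keep), descriptor = desc, n_atoms = nrow(top$atoms))
}

# Residue-level bookkeeping: unique (chain, resid) keys in atom order.
.residue_table <- function(top, idx = seq_len(nrow(top$atoms))) {
  a <- top$atoms[idx, , drop = FALSE]
  key <- paste(a$chain_id, a$residue_id)
  first <- !duplicated(key)
  data.frame(chain = a$chain_id[first], residue_id = a$residue_id[first],
             resname = a$residue_name[first], stringsAsFactors = FALSE)
}

# Label convention for charged residues: "ASP61.A" (resname, author residue
# number, chain after the dot).  Used for matrix row/column names.
.residue_label <- function(resname, residue_id, chain) {
  paste0(resname, residue_id, ".", chain)
}

.parse_residue_label <- function(label) {
  chain <- sub("^.*\\.", "", label)
  body <- sub("\\.[^.]*$", "", label)
  resname <- sub("[0-9-]+$", "", body)
  resid <- as.integer(sub("^[A-Za-z]+", "", body))
  data.frame(label = label, resname = resname, residue_id = resid,
             chain = chain, stringsAsFactors = FALSE)
}
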