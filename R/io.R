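# Structure / trajectory / matrix I/O.  PDB and DCD parsing is delegated to
# bio3d; this layer builds the package's containers and enforces contracts.

#' Read a (possibly multi-model) PDB structure
#'
#' Each MODEL block becomes one ensemble frame.  HETATM records are dropped by
#' default (solvent and ions take no part in any analysis here); alternate
#' locations other than '' or 'A' are dropped for deterministic parsing.
#' Masses are assigned from the element (standard atomic weights); the element
#' is taken from columns 77-78 when present, otherwise inferred from the atom
#' name.
#'
#' @param path PDB file path.
#' @param chain_roles named character vector chain id -> role (see
#'   [topology()]).
#' @param keep_hetatm keep HETATM records (default FALSE).
#' @param catalog charged-group catalog.
#' @param frame_interval ps per frame for the resulting ensemble.
#' @param label ensemble label (defaults to file name).
#' @return an [ensemble()]; its `$topology` holds the parsed topology.
#' @export
read_structure <- function(path, chain_roles = NULL, keep_hetatm = FALSE,
                           catalog = default_charged_catalog(),
                           frame_interval = 1, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom

  keep <- at$type == "ATOM" | keep_hetatm
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  if (!any(keep)) stop("no usable ATOM records in ", path)

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_all <- nrow(at)
  cols <- as.vector(rbind(3 * (which(keep)) - 2, 3 * which(keep) - 1,
                          3 * which(keep)))
  xyz <- xyz[, cols, drop = FALSE]
  at <- at[keep, , drop = FALSE]

  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- .element_from_name(at$elety[blank])
  elem <- toupper(trimws(elem))
  bad <- !(elem %in% names(.atomic_masses))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown element for atom serial ", at$eleno[i], " (", at$elety[i],
         " ", at$resid[i], at$resno[i], ")")
  }

  chain <- at$chain
  chain[is.na(chain) | !nzchar(chain)] <- " "
  atoms <- data.frame(
    serial = at$eleno, atom_name = trimws(at$elety),
    residue_name = trimws(at$resid), residue_id = at$resno,
    chain_id = chain, element = elem, mass = element_mass(elem),
    is_atom = at$type == "ATOM", stringsAsFactors = FALSE)

  top <- topology(atoms, chain_roles = chain_roles, catalog = catalog)
  T <- nrow(xyz)
  coords <- array(NA_real_, c(T, nrow(atoms), 3))
  for (t in seq_len(T)) coords[t, , ] <- matrix(xyz[t, ], ncol = 3, byrow = TRUE)
  ensemble(top, coords, frame_interval = frame_interval,
           label = if (is.null(label)) basename(path) else label)
}

# Light pre-validation of ATOM/HETATM fixed columns so that malformed lines
# are reported with their line number rather than surfacing as NA downstream.
.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM line ", i, " in ", path, ": too short")
    flds <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(flds))))
      stop("malformed ATOM/HETATM line ", i, " in ", path,
           ": non-numeric coordinate field")
  }
  invisible(TRUE)
}

# PDB atom-name -> element heuristic: strip digits, take leading letters;
# 4-character names starting with a digit (e.g. "1HB1") are hydrogens.
.element_from_name <- function(name) {
  nm <- trimws(name)
  vapply(nm, function(x) {
    if (grepl("^[0-9]", x)) return("H")
    letters_only <- gsub("[^A-Za-z]", "", x)
    two <- toupper(substr(letters_only, 1, 2))
    if (two %in% c("FE", "ZN", "MG", "MN", "CU", "SE", "CL", "NA"))
      return(two)
    toupper(substr(letters_only, 1, 1))
  }, "", USE.NAMES = FALSE)
}

#' Read a trajectory against a topology
#'
#' Accepts a multi-model PDB (routed through [read_structure()]) or a binary
#' DCD trajectory (read through bio3d) paired with a single-frame PDB
#' topology.  Coordinates are returned in Angstrom.
#'
#' @param topology_path single-frame PDB defining the topology.
#' @param traj_path trajectory file (.pdb multi-model or .dcd).
#' @param ... passed to [read_structure()] (chain roles, catalog, ...).
#' @return an [ensemble()].
#' @export
read_trajectory <- function(topology_path, traj_path, ...) {
  ref <- read_structure(topology_path, ...)
  ext <- tolower(tools::file_ext(traj_path))
  if (ext %in% c("pdb", "ent")) {
    ens <- read_structure(traj_path, ...)
    if (dim(ens$coords)[2] != nrow(ref$topology$atoms))
      stop("trajectory atom count ", dim(ens$coords)[2],
           " does not match topology atom count ", nrow(ref$topology$atoms))
    return(ensemble(ref$topology, ens$coords,
                    frame_interval = ens$frame_interval,
                    label = basename(traj_path)))
  }
  if (ext == "dcd") {
    before <- rownames(showConnections())
    xyz <- tryCatch(bio3d::read.dcd(traj_path, verbose = FALSE),
                    error = function(e) {
                      # the reader leaves its connection open on a mid-file
                      # failure (e.g. truncated trajectory)
                      leaked <- setdiff(rownames(showConnections()), before)
                      for (i in leaked)
                        try(close(getConnection(as.integer(i))), silent = TRUE)
                      stop("cannot read DCD ", traj_path, ": ",
                           conditionMessage(e))
                    })
    n <- ncol(xyz) / 3
    n_top <- nrow(ref$topology$atoms)
    if (n != n_top)
      stop("trajectory atom count ", n, " does not match topology atom count ",
           n_top)
    T <- nrow(xyz)
    coords <- array(NA_real_, c(T, n, 3))
    for (t in seq_len(T)) coords[t, , ] <- matrix(xyz[t, ], ncol = 3,
                                                  byrow = TRUE)
    return(ensemble(ref$topology, coords, label = basename(traj_path)))
  }
  stop("unsupported trajectory format: .", ext)
}

#' Write an ensemble as a multi-model PDB
#'
#' @param ens an [ensemble()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_ensemble_pdb <- function(ens, path) {
  a <- ens$topology$atoms
  T <- n_frames(ens)
  xyz <- matrix(NA_real_, T, nrow(a) * 3)
  for (t in seq_len(T)) xyz[t, ] <- t(frame_coords(ens, t))
  bio3d::write.pdb(file = path, xyz = xyz, eleno = a$serial,
                   elety = a$atom_name, resid = a$residue_name,
                   resno = a$residue_id, chain = a$chain_id,
                   elesy = substr(a$element, 1, 2))
  invisible(path)
}

#' Write a labeled matrix as CSV
#'
#' One header row of column labels and one leading column of row labels;
#' values at 6 significant digits.  [read_matrix()] reproduces labels and
#' values.
#'
#' @param m numeric matrix with unique rownames and colnames (a 0 x 0 matrix
#'   is allowed and yields a header-only file).
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  if (nrow(m) > 0 && ncol(m) > 0) {
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("matrix must have row and column labels")
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
      stop("matrix labels must be unique")
  }
  ok <- tryCatch({
    if (nrow(m) == 0) {
      writeLines(paste(c("\"label\"", colnames(m)), collapse = ","), path)
    } else {
      df <- as.data.frame(signif(m, 6))
      utils::write.csv(cbind(label = rownames(m), df), path,
                       row.names = FALSE, quote = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write matrix to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a labeled matrix written by [write_matrix()]
#'
#' @param path CSV path.
#' @return numeric matrix with row/column labels.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) <= 1) {
    hdr <- setdiff(scan(text = lines[1], what = "", sep = ",", quiet = TRUE),
                   "label")
    m <- matrix(numeric(0), 0, length(hdr))
    colnames(m) <- hdr
    return(m)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    m <- matrix(numeric(0), 0, max(0, ncol(df) - 1))
    colnames(m) <- setdiff(names(df), "label")
    return(m)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label
  storage.mode(m) <- "double"
  m
}

#' Write a JSON report
#'
#' @param x list to serialize.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
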