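# Structure models, atom selections and trajectory I/O.
#
# Coordinates are in angstrom throughout.  Trajectories are assumed to be
# whole/unwrapped: no periodic-boundary treatment is applied, so inputs
# must already have the molecule re-imaged into one periodic cell.

# Monoisotopic-ish standard atomic weights (Da) for elements common in
# protein/dye structures.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904,
  I = 126.904, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  "NA" = 22.99, K = 39.098
)

#' Look up the atomic mass of an element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in Da.
#' @export
element_mass <- function(element) {
  m <- .element_masses[toupper(trimws(element))]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Construct a structure model
#'
#' A structure model is the topology plus one set of coordinates: a data
#' frame of atoms with names, elements, masses, residue labels/numbers,
#' chain ids and xyz coordinates in angstrom.
#'
#' @param atoms data.frame with columns \code{atom}, \code{element},
#'   \code{mass}, \code{resid}, \code{resno}, \code{chain}, \code{x},
#'   \code{y}, \code{z}.  \code{mass} may be omitted, in which case it is
#'   looked up from \code{element}.
#' @return an object of class \code{structure_model} (a validated
#'   data.frame).
#' @export
structure_model <- function(atoms) {
  req <- c("atom", "element", "resid", "resno", "chain", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!"mass" %in% names(atoms)) atoms$mass <- element_mass(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  if (!all(atoms$mass > 0)) stop("all masses must be > 0")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key)) {
    stop("(chain, resno, atom) must be unique; duplicated: ",
         paste(head(unique(key[duplicated(key)]), 3), collapse = "; "))
  }
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' Parse an atom-selection string
#'
#' Selections are written \code{"chain:resnum"} or
#' \code{"chain:resnum:atomname"}, e.g. \code{"A:101"} selects all atoms
#' of residue 101 on chain A and \code{"A:101:CA"} a single atom.
#'
#' @param selector selection string.
#' @return list with fields \code{chain}, \code{resno}, \code{atom}
#'   (NA when not given).
#' @export
parse_selection <- function(selector) {
  parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2 || length(parts) > 3) {
    stop("selector must be 'chain:resnum' or 'chain:resnum:atomname', got '",
         selector, "'")
  }
  resno <- suppressWarnings(as.integer(parts[2]))
  if (is.na(resno)) stop("non-integer residue number in selector '", selector, "'")
  list(chain = parts[1], resno = resno,
       atom = if (length(parts) == 3) parts[3] else NA_character_)
}

#' Resolve a selection to atom indices
#'
#' @param model a \code{structure_model}.
#' @param selector a selection string (see \code{\link{parse_selection}}),
#'   a logical vector, or an integer index vector.
#' @param heavy_only drop hydrogens.
#' @param sidechain_only drop protein backbone atoms (N, CA, C, O).
#' @return integer vector of atom indices (>= 1 atom, or an error naming
#'   the selector).
#' @export
select_atoms <- function(model, selector, heavy_only = FALSE,
                         sidechain_only = FALSE) {
  if (is.character(selector)) {
    sel <- parse_selection(selector)
    idx <- which(model$chain == sel$chain & model$resno == sel$resno &
                   (is.na(sel$atom) | model$atom == sel$atom))
  } else if (is.logical(selector)) {
    idx <- which(selector)
  } else {
    idx <- as.integer(selector)
  }
  if (heavy_only) idx <- idx[toupper(model$element[idx]) != "H"]
  if (sidechain_only) {
    idx <- idx[!model$atom[idx] %in% c("N", "CA", "C", "O")]
  }
  if (!length(idx)) {
    stop("selection '",
         if (is.character(selector)) selector else "<index/logical>",
         "' matches no atoms")
  }
  idx
}

#' Mass-weighted centre of mass
#'
#' @param model a \code{structure_model}.
#' @param selector selection resolved by \code{\link{select_atoms}};
#'   default all atoms.
#' @param coords optional n_atoms x 3 coordinate matrix overriding the
#'   model's own coordinates (used for trajectory frames).
#' @inheritParams select_atoms
#' @return length-3 numeric xyz in angstrom.
#' @export
center_of_mass <- function(model, selector = NULL, coords = NULL,
                           heavy_only = FALSE, sidechain_only = FALSE) {
  idx <- if (is.null(selector)) seq_len(nrow(model)) else {
    select_atoms(model, selector, heavy_only, sidechain_only)
  }
  if (is.null(coords)) coords <- as.matrix(model[, c("x", "y", "z")])
  m <- model$mass[idx]
  unname(drop(m %*% coords[idx, , drop = FALSE]) / sum(m))
}

#' Construct a trajectory ensemble
#'
#' An ordered set of coordinate frames for one state (apo or
#' antigen-bound), possibly over several independent replicates.  All
#' frames share the topology of \code{model}.
#'
#' @param model \code{structure_model} giving the shared topology (its
#'   own coordinates are ignored unless they are the only frame).
#' @param replicates list of coordinate arrays, one per replicate, each
#'   with dim \code{c(n_atoms, 3, n_frames)}.
#' @param state \code{"apo"} or \code{"bound"}.
#' @param frame_interval time between saved frames, ps.
#' @return object of class \code{trajectory_ensemble}.
#' @export
trajectory_ensemble <- function(model, replicates, state = c("apo", "bound"),
                                frame_interval = 100) {
  state <- match.arg(state)
  stopifnot(inherits(model, "structure_model"))
  if (!length(replicates)) stop("need >= 1 replicate")
  n_atoms <- nrow(model)
  for (r in seq_along(replicates)) {
    d <- dim(replicates[[r]])
    if (length(d) != 3 || d[1] != n_atoms || d[2] != 3 || d[3] < 1) {
      stop("replicate ", r, " must be an array [", n_atoms,
           " x 3 x n_frames>=1]")
    }
    if (!all(is.finite(replicates[[r]]))) {
      stop("replicate ", r, " contains non-finite coordinates")
    }
  }
  structure(list(model = model, replicates = replicates, state = state,
                 frame_interval = frame_interval),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$replicates, function(a) dim(a)[3], integer(1))
  cat("trajectory_ensemble:", x$state, "state,", nrow(x$model), "atoms,",
      length(x$replicates), "replicate(s) with",
      paste(nf, collapse = "/"), "frames,",
      x$frame_interval, "ps/frame\n")
  invisible(x)
}

.bio3d_element <- function(pdb_atom) {
  el <- toupper(trimws(pdb_atom$elesy))
  bad <- is.na(el) | el == ""
  # fall back to the first letter of the atom name (PDB convention for
  # standard organic elements)
  el[bad] <- substr(gsub("[0-9']", "", toupper(trimws(pdb_atom$elety[bad]))), 1, 1)
  el
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame; the topology (atom names,
#' residues, chains, elements) is taken from the first model.  One file
#' is one replicate; pass several files for replicate ensembles.
#'
#' @param paths character vector of PDB file paths, one per replicate.
#' @inheritParams trajectory_ensemble
#' @return \code{trajectory_ensemble}.
#' @export
read_pdb_trajectory <- function(paths, state = c("apo", "bound"),
                                frame_interval = 100) {
  state <- match.arg(state)
  reps <- vector("list", length(paths))
  model <- NULL
  for (i in seq_along(paths)) {
    pdb <- bio3d::read.pdb(paths[i], multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    if (is.null(model)) {
      model <- structure_model(data.frame(
        atom = trimws(at$elety), element = .bio3d_element(at),
        resid = trimws(at$resid), resno = at$resno,
        chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
        x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
    } else if (nrow(at) != nrow(model)) {
      stop("file ", paths[i], " has a different atom count than the first file")
    }
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    n_frames <- nrow(xyz)
    a <- array(NA_real_, c(nrow(model), 3, n_frames))
    for (f in seq_len(n_frames)) {
      a[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    }
    reps[[i]] <- a
  }
  trajectory_ensemble(model, reps, state, frame_interval)
}

#' Write a trajectory ensemble as multi-model PDB file(s)
#'
#' Replicates are written to separate files (suffix \code{_repN} when
#' there is more than one).
#'
#' @param traj \code{trajectory_ensemble}.
#' @param path output path for a single replicate, or base path.
#' @return invisibly, the written file paths.
#' @export
write_pdb_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  n_rep <- length(traj$replicates)
  paths <- if (n_rep == 1) path else {
    paste0(sub("\\.pdb$", "", path), "_rep", seq_len(n_rep), ".pdb")
  }
  m <- traj$model
  for (r in seq_len(n_rep)) {
    a <- traj$replicates[[r]]
    xyz <- t(apply(a, 3, function(fr) as.vector(t(fr))))
    if (dim(a)[3] == 1) xyz <- matrix(xyz, nrow = 1)
    bio3d::write.pdb(file = paths[r], xyz = xyz, resno = m$resno,
                     resid = m$resid, eleno = seq_len(nrow(m)),
                     elety = m$atom, chain = m$chain)
  }
  invisible(paths)
}

#' Read a whitespace-delimited XYZ trajectory
#'
#' Standard XYZ format: each frame is an atom count line, a comment
#' line, then one \code{element x y z} line per atom.  XYZ carries no
#' residue information, so a topology may be supplied; by default each
#' atom becomes its own single-atom residue on chain A.
#'
#' @param path XYZ file (one replicate).
#' @param model optional \code{structure_model} supplying residue/chain
#'   annotation (atom count must match).
#' @inheritParams trajectory_ensemble
#' @return \code{trajectory_ensemble} with one replicate.
#' @export
read_xyz_trajectory <- function(path, model = NULL,
                                state = c("apo", "bound"),
                                frame_interval = 100) {
  state <- match.arg(state)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("malformed XYZ atom-count line at line ", i)
    if (i + 1 + n > length(lines)) stop("truncated XYZ frame at line ", i)
    block <- lines[(i + 2):(i + 1 + n)]
    tok <- do.call(rbind, strsplit(trimws(block), "[[:space:]]+"))
    if (ncol(tok) < 4) stop("malformed XYZ atom line in frame starting line ", i)
    frames[[length(frames) + 1]] <- list(
      element = tok[, 1],
      xyz = matrix(as.numeric(tok[, 2:4]), ncol = 3))
    i <- i + 2 + n
  }
  el <- frames[[1]]$element
  if (is.null(model)) {
    model <- structure_model(data.frame(
      atom = paste0(el, seq_along(el)), element = el,
      resid = "UNK", resno = seq_along(el), chain = "A",
      x = frames[[1]]$xyz[, 1], y = frames[[1]]$xyz[, 2],
      z = frames[[1]]$xyz[, 3], stringsAsFactors = FALSE))
  } else if (nrow(model) != length(el)) {
    stop("supplied model has ", nrow(model), " atoms but XYZ frames have ",
         length(el))
  }
  a <- array(NA_real_, c(nrow(model), 3, length(frames)))
  for (f in seq_along(frames)) a[, , f] <- frames[[f]]$xyz
  trajectory_ensemble(model, list(a), state, frame_interval)
}
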