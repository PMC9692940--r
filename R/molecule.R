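#' Construct a molecule
#'
#' A molecule bundles the atom table (element, mass, partial charge,
#' gyromagnetic ratio, label), current Cartesian coordinates (A) and the bond
#' graph. Angles, torsions and nonbonded exclusion sets are derived from the
#' bond list alone (1-2 and 1-3 pairs excluded, 1-4 pairs flagged for scaling).
#'
#' @param elements character vector of element symbols
#' @param xyz numeric n x 3 matrix of coordinates (A)
#' @param bonds integer m x 2 matrix of bonded atom index pairs (1-based)
#' @param labels atom labels (default element + index, e.g. "C2", "H11a" style)
#' @param charges partial charges (e), recycled
#' @param masses atomic masses (amu); defaults from the element table
#' @return object of class \code{mdoc_molecule}
#' @export
molecule <- function(elements, xyz, bonds = NULL, labels = NULL,
                     charges = 0, masses = NULL) {
  xyz <- as_xyz_matrix(xyz)
  n <- nrow(xyz)
  if (length(elements) != n) stop("length(elements) != nrow(xyz)")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(masses)) masses <- element_mass(elements)
  if (any(masses <= 0)) stop("atomic masses must be positive")
  if (is.null(labels)) labels <- paste0(elements, seq_len(n))
  if (anyDuplicated(labels)) stop("atom labels must be unique")
  charges <- rep_len(charges, n)
  atoms <- data.frame(
    label = as.character(labels), element = as.character(elements),
    mass = as.numeric(masses), charge = as.numeric(charges),
    gamma = gyromagnetic_ratio(elements), stringsAsFactors = FALSE
  )
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  bonds <- normalize_bonds(bonds, n)
  structure(
    list(atoms = atoms, xyz = xyz, bonds = bonds,
         topology = derive_topology(bonds, n)),
    class = "mdoc_molecule"
  )
}

as_xyz_matrix <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("coordinates must be an n x 3 matrix")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  xyz
}

normalize_bonds <- function(bonds, n) {
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1 | bonds > n)) stop("bond index out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond")
    bonds <- t(apply(bonds, 1, sort))
    bonds <- unique(bonds)
  }
  dimnames(bonds) <- NULL
  bonds
}

#' @export
print.mdoc_molecule <- function(x, ...) {
  cat(sprintf("mdoc_molecule: %d atoms (%s), %d bonds\n",
              nrow(x$atoms),
              paste(names(sort(table(x$atoms$element), decreasing = TRUE)),
                    collapse = ""),
              nrow(x$bonds)))
  cat(sprintf("  angles: %d, torsions: %d, nonbonded pairs: %d (of which 1-4: %d)\n",
              nrow(x$topology$angles), nrow(x$topology$torsions),
              nrow(x$topology$nb_pairs), sum(x$topology$nb_pairs[, 3] == 1)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol an \code{mdoc_molecule}
#' @return integer atom count
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Look up atom indices by label
#' @param mol an \code{mdoc_molecule}
#' @param labels character vector of atom labels
#' @return integer vector of 1-based indices
#' @export
atom_index <- function(mol, labels) {
  idx <- match(labels, mol$atoms$label)
  if (anyNA(idx)) {
    stop("unknown atom label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}

# Angles, proper torsions and nonbonded pair lists from the bond graph.
# nb_pairs has columns (i, j, is14): all pairs except 1-2/1-3; 1-4 flagged.
derive_topology <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  angles <- list()
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      angles[[length(angles) + 1]] <- cbind(cmb[1, ], j, cmb[2, ])
    }
  }
  angles <- if (length(angles)) do.call(rbind, angles) else matrix(integer(0), 0, 3)

  torsions <- list()
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      j <- bonds[r, 1]; k <- bonds[r, 2]
      for (i in setdiff(adj[[j]], k)) {
        for (l in setdiff(adj[[k]], j)) {
          if (i != l) torsions[[length(torsions) + 1]] <- c(i, j, k, l)
        }
      }
    }
  }
  torsions <- if (length(torsions)) do.call(rbind, torsions) else matrix(integer(0), 0, 4)
  # keep one orientation per quadruple (i,j,k,l) == (l,k,j,i)
  if (nrow(torsions) > 0) {
    flip <- torsions[, 2] > torsions[, 3] |
      (torsions[, 2] == torsions[, 3] & torsions[, 1] > torsions[, 4])
    torsions[flip, ] <- torsions[flip, 4:1]
    torsions <- unique(torsions)
  }

  key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  excl <- unique(c(
    if (nrow(bonds) > 0) key(bonds[, 1], bonds[, 2]),
    if (nrow(angles) > 0) key(angles[, 1], angles[, 3])
  ))
  k14 <- if (nrow(torsions) > 0) {
    setdiff(unique(key(torsions[, 1], torsions[, 4])), excl)
  } else integer(0)

  if (n >= 2) {
    cmb <- utils::combn(n, 2)
    allk <- key(cmb[1, ], cmb[2, ])
    keep <- !(allk %in% excl)
    nb_pairs <- cbind(cmb[1, keep], cmb[2, keep],
                      as.integer(allk[keep] %in% k14))
  } else {
    nb_pairs <- matrix(integer(0), 0, 3)
  }
  dimnames(angles) <- dimnames(torsions) <- dimnames(nb_pairs) <- NULL
  list(angles = angles, torsions = torsions, nb_pairs = nb_pairs)
}

#' Guess covalent connectivity from interatomic distances
#'
#' Two atoms are bonded if their distance is below scale * (r_cov_i + r_cov_j).
#' Only connectivity is produced, never bond orders.
#'
#' @param elements element symbols
#' @param xyz n x 3 coordinates (A)
#' @param scale tolerance factor (default 1.2)
#' @return integer m x 2 bond matrix
#' @export
guess_bonds <- function(elements, xyz, scale = 1.2) {
  rcov <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
            P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20)
  r <- rcov[elements]
  r[is.na(r)] <- 0.8
  xyz <- as_xyz_matrix(xyz)
  n <- nrow(xyz)
  out <- list()
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < scale * (r[i] + r[j])) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 2)
}

#' Read an XYZ coordinate file
#'
#' Standard XYZ: atom count, comment line, then one "element x y z" record per
#' atom. Elements are mapped to default masses and gyromagnetic ratios (1H,
#' 13C, 15N populated). Bonds are guessed from covalent radii unless
#' \code{guess = FALSE}.
#'
#' @param path file path
#' @param guess guess bonds from distances (default TRUE)
#' @return an \code{mdoc_molecule}
#' @export
read_xyz <- function(path, guess = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("XYZ parse error: file too short")
  count <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(count) || count < 1) stop("XYZ parse error at line 1: bad atom count")
  if (length(lines) < 2 + count) {
    stop(sprintf("XYZ parse error: header declares %d atoms but only %d records present",
                 count, max(length(lines) - 2, 0)))
  }
  elements <- character(count)
  xyz <- matrix(NA_real_, count, 3)
  for (i in seq_len(count)) {
    ln <- 2 + i
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4) stop(sprintf("XYZ parse error at line %d: expected 'element x y z'", ln))
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(v)) stop(sprintf("XYZ parse error at line %d: non-numeric coordinate", ln))
    elements[i] <- tok[1]
    xyz[i, ] <- v
  }
  element_mass(elements) # errors on unknown elements
  bonds <- if (guess) guess_bonds(elements, xyz) else NULL
  molecule(elements, xyz, bonds = bonds)
}

#' Write an XYZ coordinate file
#'
#' @param mol an \code{mdoc_molecule} (or anything with \code{$atoms$element})
#' @param path output path
#' @param xyz optional coordinate matrix overriding \code{mol$xyz}
#' @param comment comment line
#' @return invisibly, the path
#' @export
write_xyz <- function(mol, path, xyz = NULL, comment = "generated by mdoc") {
  if (is.null(xyz)) xyz <- mol$xyz
  xyz <- as_xyz_matrix(xyz)
  lines <- c(
    sprintf("%d", nrow(xyz)), comment,
    sprintf("%-3s %14.8f %14.8f %14.8f", mol$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Minimal PDB reader (ATOM/HETATM coordinates and element only)
#'
#' Reads coordinates, atom names and elements from fixed-column ATOM/HETATM
#' records; everything else in the format is ignored.
#'
#' @param path file path
#' @param guess guess bonds from distances (default TRUE)
#' @return an \code{mdoc_molecule}
#' @export
read_pdb <- function(path, guess = TRUE) {
  lines <- readLines(path)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(rec)) stop("PDB parse error: no ATOM/HETATM records")
  xyz <- cbind(
    as.numeric(substr(rec, 31, 38)),
    as.numeric(substr(rec, 39, 46)),
    as.numeric(substr(rec, 47, 54))
  )
  if (anyNA(xyz)) stop("PDB parse error: non-numeric coordinates")
  name <- trimws(substr(rec, 13, 16))
  elem <- trimws(substr(rec, 77, 78))
  # fall back to the first letter of the atom name when the element column is blank
  blank <- elem == ""
  elem[blank] <- gsub("[^A-Za-z].*$", "", name[blank])
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 2)))
  elem <- sub(" $", "", elem)
  labels <- name
  if (anyDuplicated(labels)) labels <- paste0(labels, ".", seq_along(labels))
  bonds <- if (guess) guess_bonds(elem, xyz) else NULL
  molecule(elem, xyz, bonds = bonds, labels = labels)
}
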