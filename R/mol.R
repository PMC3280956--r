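#' @useDynLib rxndesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal molecule model
# -----------------------
# A molecule is a hydrogen-suppressed, *kekulized* graph:
#   atoms: data.frame(elem, charge, nH, arom, ring, ptype)
#   bonds: data.frame(a1, a2, order)   order in {1,2,3}
# Aromaticity is a derived flag (perceived from SSSR + pi counting), never a
# bond order, so implicit hydrogen counts stay well-defined after graph edits.

.ELEMENT_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.065, Cl = 35.453, Se = 78.971,
  Br = 79.904, I = 126.904,
  # a few off-whitelist elements so planted fixture violations still get a mass
  Fe = 55.845, As = 74.922, Ge = 72.630, Na = 22.990, K = 39.098,
  Li = 6.94, Mg = 24.305, Ca = 40.078, Zn = 65.38, Sn = 118.710, Hg = 200.592
)

# default valence by element; vectors = allowed expanded valences (smallest first)
.VALENCE <- list(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5), S = c(2, 4, 6),
  Cl = 1, Se = c(2, 4, 6), Br = 1, I = 1, H = 1
)

.new_mol <- function(atoms, bonds, source_id = NA_character_) {
  stopifnot(is.data.frame(atoms))
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  atoms$elem <- as.character(atoms$elem)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  mol <- structure(list(atoms = atoms, bonds = bonds, source_id = source_id),
                   class = "rxn_mol")
  perceive(mol)
}

n_atoms <- function(mol) nrow(mol$atoms)

#' @export
print.rxn_mol <- function(x, ...) {
  cat(sprintf("<rxn_mol %s: %d heavy atoms, %d bonds, mass %.2f>\n",
              ifelse(is.na(x$source_id), "", x$source_id),
              n_atoms(x), nrow(x$bonds), mol_mass(x)))
  invisible(x)
}

# adjacency list: integer indices of bonded neighbors per atom
mol_adjacency <- function(mol) {
  n <- n_atoms(mol)
  nb <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

# sum of bond orders incident to each atom
.bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  bs <- numeric(n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      bs[mol$bonds$a1[k]] <- bs[mol$bonds$a1[k]] + o
      bs[mol$bonds$a2[k]] <- bs[mol$bonds$a2[k]] + o
    }
  }
  bs
}

# effective default valence given formal charge
.effective_valence <- function(elem, charge, bondsum) {
  v <- .VALENCE[[elem]]
  if (is.null(v)) return(NA_real_)  # off-whitelist element: no H model
  v <- v[1]
  if (elem == "N") v <- v + max(min(charge, 1L), -1L)
  if (elem == "O") v <- v + max(min(charge, 1L), -1L)
  if (elem == "C" && charge != 0L) v <- 3
  if (elem == "S" && charge > 0L) v <- 3
  if (elem == "S" && charge < 0L) v <- 1
  if (elem %in% c("F", "Cl", "Br", "I") && charge < 0L) v <- 0
  # hypervalent S/P/Se: smallest allowed valence >= bond order sum
  if (elem %in% c("S", "P", "Se") && charge == 0L) {
    allowed <- .VALENCE[[elem]]
    fit <- allowed[allowed >= bondsum]
    v <- if (length(fit)) fit[1] else max(allowed)
  }
  v
}

.max_valence <- function(elem, charge) {
  v <- .VALENCE[[elem]]
  if (is.null(v)) return(Inf)
  vmax <- max(v)
  if (elem == "N" && charge > 0L) vmax <- 4
  if (elem == "O" && charge > 0L) vmax <- 3
  if (elem == "N" && charge < 0L) vmax <- 2
  if (elem == "O" && charge < 0L) vmax <- 1
  if (elem %in% c("F", "Cl", "Br", "I") && charge < 0L) vmax <- 0
  vmax
}

# Recompute implicit hydrogens, ring membership and aromaticity. Idempotent.
perceive <- function(mol) {
  n <- n_atoms(mol)
  bs <- .bond_order_sum(mol)
  nH <- integer(n)
  for (i in seq_len(n)) {
    v <- .effective_valence(mol$atoms$elem[i], mol$atoms$charge[i], bs[i])
    nH[i] <- if (is.na(v)) 0L else as.integer(max(0, v - bs[i]))
  }
  mol$atoms$nH <- nH
  mol$sssr <- .sssr(mol)
  mol <- .perceive_aromaticity(mol)
  mol
}

# TRUE unless some atom exceeds its maximum allowed valence
valences_ok <- function(mol) {
  bs <- .bond_order_sum(mol)
  for (i in seq_len(n_atoms(mol))) {
    if (bs[i] > .max_valence(mol$atoms$elem[i], mol$atoms$charge[i])) return(FALSE)
  }
  TRUE
}

# connected components; returns integer membership vector
mol_components <- function(mol) {
  n <- n_atoms(mol)
  comp <- integer(n)
  nb <- mol_adjacency(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# Smallest set of smallest rings: shortest cycle through each edge,
# then a GF(2)-independent subset of size E - V + C, smallest rings first.
.sssr <- function(mol) {
  m <- nrow(mol$bonds); n <- n_atoms(mol)
  if (m == 0) return(list())
  ncomp <- max(mol_components(mol))
  nring <- m - n + ncomp
  if (nring <= 0) return(list())
  nb <- mol_adjacency(mol)
  bond_id <- new.env(hash = TRUE)
  for (k in seq_len(m)) {
    key <- paste(sort(c(mol$bonds$a1[k], mol$bonds$a2[k])), collapse = "-")
    assign(key, k, envir = bond_id)
  }
  edge_of <- function(i, j) get(paste(sort(c(i, j)), collapse = "-"), envir = bond_id)

  candidates <- list()
  for (k in seq_len(m)) {
    u <- mol$bonds$a1[k]; v <- mol$bonds$a2[k]
    # BFS from u to v avoiding edge k
    prev <- rep(NA_integer_, n); seen <- logical(n)
    seen[u] <- TRUE; queue <- u
    while (length(queue) && !seen[v]) {
      x <- queue[1]; queue <- queue[-1]
      for (w in nb[[x]]) {
        if ((x == u && w == v) || (x == v && w == u)) next
        if (!seen[w]) { seen[w] <- TRUE; prev[w] <- x; queue <- c(queue, w) }
      }
    }
    if (!seen[v]) next
    path <- v
    while (path[1] != u) path <- c(prev[path[1]], path)
    candidates[[length(candidates) + 1L]] <- path  # cycle atoms in order
  }
  if (!length(candidates)) return(list())
  sizes <- vapply(candidates, length, 1L)
  ord <- order(sizes, vapply(candidates, function(p) paste(sort(p), collapse = ","), ""))
  candidates <- candidates[ord]

  basis <- matrix(FALSE, nrow = 0, ncol = m)
  pivots <- integer(0)
  rings <- list()
  for (cyc in candidates) {
    if (length(rings) >= nring) break
    vec <- rep(FALSE, m)
    cyc_cl <- c(cyc, cyc[1])
    for (t in seq_len(length(cyc))) vec[edge_of(cyc_cl[t], cyc_cl[t + 1])] <- TRUE
    red <- vec
    for (r in seq_along(pivots)) if (red[pivots[r]]) red <- xor(red, basis[r, ])
    if (any(red)) {
      basis <- rbind(basis, red)
      pivots <- c(pivots, which(red)[1])
      rings[[length(rings) + 1L]] <- cyc
    }
  }
  rings
}

# Simplified Hueckel perception on SSSR rings (see vignette for the pi-count
# rules); sets atoms$arom/atoms$ring and bonds$arom.
.perceive_aromaticity <- function(mol) {
  n <- n_atoms(mol)
  rings <- mol$sssr
  atoms_ring <- logical(n)
  for (r in rings) atoms_ring[r] <- TRUE
  mol$atoms$ring <- atoms_ring

  nb <- mol_adjacency(mol)
  bo <- function(i, j) {
    k <- which((mol$bonds$a1 == i & mol$bonds$a2 == j) | (mol$bonds$a1 == j & mol$bonds$a2 == i))
    mol$bonds$order[k[1]]
  }
  arom_atom <- logical(n)
  arom_ring <- logical(length(rings))
  for (ri in seq_along(rings)) {
    r <- rings[[ri]]
    ok <- TRUE; pi_e <- 0L
    for (a in r) {
      el <- mol$atoms$elem[a]
      if (!el %in% c("C", "N", "O", "S", "Se")) { ok <- FALSE; break }
      nbrs <- nb[[a]]
      orders <- vapply(nbrs, function(x) bo(a, x), 1)
      if (any(orders == 3)) { ok <- FALSE; break }
      if (length(nbrs) + mol$atoms$nH[a] > 3) { ok <- FALSE; break }
      dbl <- nbrs[orders == 2]
      if (length(dbl)) {
        if (any(dbl %in% r) || any(atoms_ring[dbl])) {
          pi_e <- pi_e + 1L            # in-ring or fused-ring double bond
        } else { ok <- FALSE; break }  # exocyclic double bond (e.g. quinone)
      } else if (el %in% c("N", "O", "S", "Se") && mol$atoms$charge[a] <= 0L) {
        pi_e <- pi_e + 2L              # lone-pair contributor (pyrrole-type)
      } else { ok <- FALSE; break }    # saturated carbon breaks the ring
    }
    arom_ring[ri] <- ok && (pi_e %% 4L == 2L)
    if (arom_ring[ri]) arom_atom[r] <- TRUE
  }
  mol$atoms$arom <- arom_atom

  if (nrow(mol$bonds)) {
    barom <- logical(nrow(mol$bonds))
    for (ri in which(arom_ring)) {
      r <- rings[[ri]]
      rc <- c(r, r[1])
      for (t in seq_len(length(r))) {
        i <- rc[t]; j <- rc[t + 1]
        k <- which((mol$bonds$a1 == i & mol$bonds$a2 == j) | (mol$bonds$a1 == j & mol$bonds$a2 == i))
        barom[k] <- TRUE
      }
    }
    mol$bonds$arom <- barom
  } else {
    mol$bonds$arom <- logical(0)
  }
  mol$arom_rings <- arom_ring
  mol
}

#' Molecular mass of a hydrogen-suppressed molecule
#'
#' Average atomic masses including implicit hydrogens.
#'
#' @param mol an internal molecule object as returned by [parse_smiles()]
#' @return mass in Da
#' @export
mol_mass <- function(mol) {
  if (n_atoms(mol) == 0) return(0)
  em <- .ELEMENT_MASS[mol$atoms$elem]
  em[is.na(em)] <- 0
  sum(em) + sum(mol$atoms$nH) * .ELEMENT_MASS[["H"]]
}

# ---------------------------------------------------------------------------
# I/O through Open Babel (ChemmineOB) + ChemmineR
# ---------------------------------------------------------------------------

# old-style SDF atom block charge codes
.SDF_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# Build an rxn_mol from one ChemmineR SDF object (+ optional raw record lines
# for 'M  CHG' properties, which override atom-block charge codes).
sdf_to_mol <- function(sdf, id = NA_character_, raw_lines = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_.*$", "", rownames(ab))
  nA <- nrow(ab)
  charge <- rep(0L, nA)
  if (ncol(ab) >= 5) {
    code <- as.character(ab[, 5])
    known <- code %in% names(.SDF_CHARGE)
    charge[known] <- .SDF_CHARGE[code[known]]
  }
  if (!is.null(raw_lines)) {
    chg_lines <- grep("^M  CHG", raw_lines, value = TRUE)
    if (length(chg_lines)) {
      charge <- rep(0L, nA)
      for (ln in chg_lines) {
        f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
        cnt <- f[1]
        for (t in seq_len(cnt)) charge[f[2 * t]] <- f[2 * t + 1]
      }
    }
  }
  atoms <- data.frame(elem = elems, charge = charge, stringsAsFactors = FALSE)
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- NULL
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    if (any(bonds$order == 4)) {
      stop("aromatic (type 4) SDF bonds are not supported; supply kekulized records")
    }
  }
  # drop explicit hydrogens (the representation is hydrogen-suppressed)
  keepH <- elems != "H"
  if (!all(keepH)) {
    idx_map <- cumsum(keepH)
    atoms <- atoms[keepH, , drop = FALSE]
    if (!is.null(bonds)) {
      keep_b <- keepH[bonds$a1] & keepH[bonds$a2]
      bonds <- bonds[keep_b, , drop = FALSE]
      bonds$a1 <- idx_map[bonds$a1]; bonds$a2 <- idx_map[bonds$a2]
    }
    rownames(atoms) <- NULL
  }
  .new_mol(atoms, bonds, source_id = id)
}

# minimal fallback for bond-free CTABs, which ChemmineR's SDF class rejects
.mol_from_ctab_nobonds <- function(lines, id) {
  nA <- as.integer(substr(lines[4], 1, 3))
  elems <- vapply(seq_len(nA), function(i) {
    trimws(substr(lines[4 + i], 32, 34))
  }, "")
  charge <- rep(0L, nA)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    for (t in seq_len(f[1])) charge[f[2 * t]] <- f[2 * t + 1]
  }
  keep <- elems != "H"
  .new_mol(data.frame(elem = elems[keep], charge = charge[keep]), NULL, source_id = id)
}

#' Parse a SMILES string into a molecule
#'
#' Parsing and kekulization are delegated to Open Babel; the result is a
#' hydrogen-suppressed graph with perceived rings and aromaticity.
#'
#' @param smiles a single SMILES string
#' @param id source identifier carried through to outputs
#' @return an `rxn_mol` object
#' @export
parse_smiles <- function(smiles, id = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))),
    error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("unparsable SMILES: ", smiles)
  counts <- substr(lines[4], 1, 6)
  nA <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(nA) || nA == 0) stop("unparsable SMILES: ", smiles)
  nB <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (!is.na(nB) && nB == 0) return(.mol_from_ctab_nobonds(lines, id))
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines)))
  sdf_to_mol(sdfset[[1]], id = id, raw_lines = lines)
}

# V2000 writer (kekulized; charges as M CHG lines)
mol_to_sdf <- function(mol, id = NULL) {
  if (is.null(id)) id <- ifelse(is.na(mol$source_id), "mol", mol$source_id)
  nA <- n_atoms(mol); nB <- nrow(mol$bonds)
  header <- c(id, "  rxndesign 2D", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nA, nB))
  atom_lines <- vapply(seq_len(nA), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, mol$atoms$elem[i])
  }, "")
  bond_lines <- if (nB) vapply(seq_len(nB), function(k) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1[k], mol$bonds$a2[k], mol$bonds$order[k])
  }, "") else character(0)
  chg_idx <- which(mol$atoms$charge != 0L)
  chg_lines <- character(0)
  if (length(chg_idx)) {
    for (grp in split(chg_idx, ceiling(seq_along(chg_idx) / 8))) {
      chg_lines <- c(chg_lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(vapply(grp, function(i) sprintf("%4d%4d", i, mol$atoms$charge[i]), ""),
               collapse = "")))
    }
  }
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END", "$$$$"), collapse = "\n")
}

.smiles_cache <- new.env(parent = emptyenv())

#' Canonical SMILES of a molecule
#'
#' Serializes through Open Babel's canonical SMILES writer; used everywhere
#' molecules are compared, deduplicated or written out.
#'
#' @param mol an `rxn_mol` object
#' @return a single SMILES string
#' @export
canonical_smiles <- function(mol) {
  sdftxt <- mol_to_sdf(mol, id = "m")
  key <- paste(c(mol$atoms$elem, mol$atoms$charge, t(as.matrix(mol$bonds[, 1:3]))),
               collapse = ",")
  hit <- .smiles_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", paste0(sdftxt, "\n")))
  smi <- strsplit(out, "[\t\n]")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) stop("canonical SMILES generation failed")
  .smiles_cache[[key]] <- smi
  smi
}

# disjoint union of two molecules; returns list(mol, offset of second)
combine_mols <- function(m1, m2) {
  off <- n_atoms(m1)
  atoms <- rbind(m1$atoms[, c("elem", "charge")], m2$atoms[, c("elem", "charge")])
  rownames(atoms) <- NULL
  b2 <- m2$bonds
  if (nrow(b2)) { b2$a1 <- b2$a1 + off; b2$a2 <- b2$a2 + off }
  bonds <- rbind(m1$bonds[, c("a1", "a2", "order")], b2[, c("a1", "a2", "order")])
  list(mol = .new_mol(atoms, bonds), offset = off)
}
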