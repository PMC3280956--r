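# Pharmacophore typing of the molecular graph
# -------------------------------------------
# Every heavy atom receives exactly one of eight types:
#   A acceptor, D donor, E donor+acceptor, P positive, N negative,
#   R aromatic, L lipophilic, 0 no type.
# Types are assigned by a fixed priority cascade (P > N > E > D > A > R > L > 0)
# so typing is single-valued and idempotent; the individual donor/acceptor/
# basicity rules are documented in the methods vignette.

.PTYPES <- c("A", "D", "E", "P", "N", "R", "L", "0")

# neutral aliphatic amine nitrogen that the standardizer would protonate:
# sp3 N bonded only to carbon, none of which is aromatic or a carbonyl/
# sulfonyl/imine carbon, and not part of N-N / N-O motifs
.is_basic_amine <- function(mol, i, nb, bsum) {
  at <- mol$atoms
  if (at$elem[i] != "N" || at$arom[i] || at$charge[i] != 0L) return(FALSE)
  deg <- length(nb[[i]])
  if (bsum[i] != deg) return(FALSE)          # double/triple bond at N
  if (deg + at$nH[i] != 3L) return(FALSE)    # not a simple amine
  for (j in nb[[i]]) {
    if (at$elem[j] != "C") return(FALSE)     # N-N, N-O, N-S excluded
    if (at$arom[j]) return(FALSE)            # anilines are not basic
    # carbon double-bonded to a heteroatom (amide, amidine, thioamide ...)
    for (k in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[k, ]
      if ((b$a1 == j || b$a2 == j) && b$order >= 2) {
        other <- ifelse(b$a1 == j, b$a2, b$a1)
        if (mol$atoms$elem[other] %in% c("O", "N", "S")) return(FALSE)
      }
    }
  }
  TRUE
}

.has_adjacent_pi_acid <- function(mol, i, nb) {
  # neighbor C or S that carries a double bond to O/N/S (amide-like context)
  at <- mol$atoms
  for (j in nb[[i]]) {
    if (!at$elem[j] %in% c("C", "S")) next
    for (k in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[k, ]
      if ((b$a1 == j || b$a2 == j) && b$order >= 2) {
        other <- ifelse(b$a1 == j, b$a2, b$a1)
        if (other != i && at$elem[other] %in% c("O", "N", "S")) return(TRUE)
      }
    }
  }
  FALSE
}

.is_donor <- function(mol, i) {
  mol$atoms$elem[i] %in% c("N", "O", "S") && mol$atoms$nH[i] >= 1L
}

.is_acceptor <- function(mol, i, nb, bsum) {
  at <- mol$atoms
  el <- at$elem[i]
  if (at$charge[i] != 0L) return(FALSE)
  if (el == "O") return(!at$arom[i])                   # furan-type O excluded
  if (el == "N") {
    if (at$arom[i]) return(at$nH[i] == 0L)             # pyridine-type
    deg <- length(nb[[i]])
    if (bsum[i] != deg) return(FALSE)                  # nitrile/imine excluded
    if (.has_adjacent_pi_acid(mol, i, nb)) return(FALSE)  # amide N excluded
    return(TRUE)
  }
  FALSE
}

#' Assign pharmacophore types to every atom
#'
#' Pure, deterministic and idempotent: the type is a function of the molecule
#' only. See the methods vignette for the full rule cascade.
#'
#' @param mol an `rxn_mol`
#' @return the molecule with an added `ptype` atom column
#' @export
assign_pharmacophore_types <- function(mol) {
  n <- n_atoms(mol)
  nb <- mol_adjacency(mol)
  bsum <- .bond_order_sum(mol)
  at <- mol$atoms
  ptype <- character(n)
  for (i in seq_len(n)) {
    don <- .is_donor(mol, i)
    acc <- .is_acceptor(mol, i, nb, bsum)
    lip <- (at$elem[i] == "C" && !at$arom[i] &&
              all(at$elem[nb[[i]]] %in% c("C", "F", "Cl", "Br", "I"))) ||
           at$elem[i] %in% c("F", "Cl", "Br", "I")
    ptype[i] <-
      if (at$charge[i] > 0L || .is_basic_amine(mol, i, nb, bsum)) "P"
      else if (at$charge[i] < 0L) "N"
      else if (don && acc) "E"
      else if (don) "D"
      else if (acc) "A"
      else if (at$arom[i]) "R"
      else if (lip) "L"
      else "0"
  }
  mol$atoms$ptype <- ptype
  mol
}

# ---------------------------------------------------------------------------
# Loading molecule files
# ---------------------------------------------------------------------------

#' Load molecules from a SMILES table or SDF file
#'
#' SMILES tables are whitespace- or tab-delimited with columns SMILES and
#' optional ID; lines starting with `#` are comments. SDF files must be V2000.
#' Invalid records are skipped with a warning and counted; pharmacophore types
#' are assigned to every loaded molecule.
#'
#' @param path input file; format chosen by extension (`.sdf` vs table)
#' @return list of typed `rxn_mol` objects with attribute `n_skipped`
#' @export
load_molecules <- function(path) {
  if (!file.exists(path)) stop("cannot read molecule file: ", path)
  ext <- tolower(tools::file_ext(path))
  mols <- list()
  skipped <- 0L
  if (ext == "sdf") {
    lines <- readLines(path, warn = FALSE)
    rec_ends <- grep("^\\${4}", lines)
    start <- 1L
    rec_i <- 0L
    for (e in rec_ends) {
      rec <- lines[start:e]
      start <- e + 1L
      rec_i <- rec_i + 1L
      id <- trimws(rec[1])
      if (!nzchar(id)) id <- sprintf("MOL%04d", rec_i)
      m <- tryCatch({
        sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(rec))
        sdf_to_mol(sdfset[[1]], id = id, raw_lines = rec)
      }, error = function(err) NULL)
      if (is.null(m) || n_atoms(m) == 0) {
        warning("skipping invalid SDF record ", rec_i, " (", id, ")")
        skipped <- skipped + 1L
      } else {
        mols[[length(mols) + 1L]] <- assign_pharmacophore_types(m)
      }
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (li in seq_along(lines)) {
      fields <- strsplit(trimws(lines[li]), "\\s+")[[1]]
      smi <- fields[1]
      id <- if (length(fields) >= 2) fields[2] else sprintf("MOL%04d", li)
      m <- tryCatch(parse_smiles(smi, id = id), error = function(err) NULL)
      if (is.null(m)) {
        warning("skipping unparsable SMILES record ", li, ": ", smi)
        skipped <- skipped + 1L
      } else {
        mols[[length(mols) + 1L]] <- assign_pharmacophore_types(m)
      }
    }
  }
  if (!length(mols)) stop("no valid records in ", path)
  ids <- vapply(mols, function(m) m$source_id, "")
  if (anyDuplicated(ids)) {
    dup <- duplicated(ids)
    for (w in which(dup)) mols[[w]]$source_id <- paste0(ids[w], "_", w)
  }
  attr(mols, "n_skipped") <- skipped
  mols
}
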