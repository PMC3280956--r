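# SMARTS-subset pattern language
# ------------------------------
# Reaction centers and structural alerts are written in a documented subset of
# SMARTS (see the methods vignette): bracket atoms support element symbols,
# #<atomic number>, a/A, * , charge (+, -, +0, +2 ...), H<n>, X<n>, D<n>,
# R / R0, ! negation, with ',' (OR) binding tighter than ';' (AND), plus an
# atom map ':<n>'. Bonds: default (single-or-aromatic), - = # : ~. Branches and
# ring closures as in SMILES. Recursive SMARTS is deliberately not supported;
# environment exclusions are expressed through per-component 'forbid' patterns
# anchored at the first pattern atom.

.ELEMENT_NUM <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                  S = 16, Cl = 17, Se = 34, Br = 35, I = 53)

.pattern_cache <- new.env(parent = emptyenv())

#' Compile a pattern string
#'
#' @param smarts pattern in the package's SMARTS subset
#' @return a compiled pattern object (`rxn_pattern`)
#' @export
parse_pattern <- function(smarts) {
  hit <- .pattern_cache[[smarts]]
  if (!is.null(hit)) return(hit)
  p <- .parse_pattern_impl(smarts)
  .pattern_cache[[smarts]] <- p
  p
}

.parse_bracket <- function(content, smarts) {
  map <- NA_integer_
  m <- regmatches(content, regexpr(":[0-9]+$", content))
  if (length(m) && nzchar(m)) {
    map <- as.integer(substring(m, 2))
    content <- sub(":[0-9]+$", "", content)
  }
  if (!nzchar(content)) stop("empty bracket atom in pattern: ", smarts)
  terms <- strsplit(content, ";", fixed = TRUE)[[1]]
  parsed_terms <- lapply(terms, function(term) {
    alts <- strsplit(term, ",", fixed = TRUE)[[1]]
    lapply(alts, .parse_primitive_seq, smarts = smarts)
  })
  list(terms = parsed_terms, map = map)
}

.parse_primitive_seq <- function(seq, smarts) {
  prims <- list()
  i <- 1; n <- nchar(seq)
  while (i <= n) {
    neg <- FALSE
    ch <- substr(seq, i, i)
    if (ch == "!") { neg <- TRUE; i <- i + 1; ch <- substr(seq, i, i) }
    two <- substr(seq, i, i + 1)
    grab_num <- function(j) {
      k <- j
      while (k <= n && grepl("[0-9]", substr(seq, k, k))) k <- k + 1
      list(num = if (k > j) as.integer(substr(seq, j, k - 1)) else NA_integer_, nxt = k)
    }
    if (ch == "#") {
      g <- grab_num(i + 1)
      if (is.na(g$num)) stop("bad #n primitive in: ", smarts)
      prims[[length(prims) + 1]] <- list(kind = "elem", neg = neg,
        elem = names(.ELEMENT_NUM)[match(g$num, .ELEMENT_NUM)], arom = NA)
      i <- g$nxt
    } else if (two %in% c("Cl", "Br", "Si", "Se")) {
      prims[[length(prims) + 1]] <- list(kind = "elem", neg = neg, elem = two, arom = FALSE)
      i <- i + 2
    } else if (two == "se") {
      prims[[length(prims) + 1]] <- list(kind = "elem", neg = neg, elem = "Se", arom = TRUE)
      i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "S", "P", "F", "I")) {
      prims[[length(prims) + 1]] <- list(kind = "elem", neg = neg, elem = ch, arom = FALSE)
      i <- i + 1
    } else if (ch %in% c("c", "n", "o", "s", "p")) {
      prims[[length(prims) + 1]] <- list(kind = "elem", neg = neg, elem = toupper(ch), arom = TRUE)
      i <- i + 1
    } else if (ch == "a") {
      prims[[length(prims) + 1]] <- list(kind = "arom", neg = neg, value = TRUE); i <- i + 1
    } else if (ch == "A") {
      prims[[length(prims) + 1]] <- list(kind = "arom", neg = neg, value = FALSE); i <- i + 1
    } else if (ch == "*") {
      prims[[length(prims) + 1]] <- list(kind = "any", neg = neg); i <- i + 1
    } else if (ch == "H") {
      g <- grab_num(i + 1)
      prims[[length(prims) + 1]] <- list(kind = "H", neg = neg,
                                         value = ifelse(is.na(g$num), 1L, g$num))
      i <- g$nxt
    } else if (ch == "X") {
      g <- grab_num(i + 1)
      if (is.na(g$num)) stop("X needs a number in: ", smarts)
      prims[[length(prims) + 1]] <- list(kind = "X", neg = neg, value = g$num); i <- g$nxt
    } else if (ch == "D") {
      g <- grab_num(i + 1)
      if (is.na(g$num)) stop("D needs a number in: ", smarts)
      prims[[length(prims) + 1]] <- list(kind = "D", neg = neg, value = g$num); i <- g$nxt
    } else if (ch == "R") {
      g <- grab_num(i + 1)
      inring <- if (!is.na(g$num) && g$num == 0L) FALSE else TRUE
      prims[[length(prims) + 1]] <- list(kind = "ring", neg = neg, value = inring); i <- g$nxt
    } else if (ch == "+" || ch == "-") {
      g <- grab_num(i + 1)
      val <- ifelse(is.na(g$num), 1L, g$num)
      if (ch == "-") val <- -val
      prims[[length(prims) + 1]] <- list(kind = "charge", neg = neg, value = as.integer(val))
      i <- g$nxt
    } else {
      stop("unsupported primitive '", ch, "' in pattern: ", smarts)
    }
  }
  prims
}

.parse_pattern_impl <- function(smarts) {
  atoms <- list()
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), sym = character(0),
                      stringsAsFactors = FALSE)
  prev <- NA_integer_          # previous atom for chain bonds
  stack <- integer(0)          # branch stack
  pending_bond <- ""           # bond symbol awaiting next atom
  ring_open <- list()          # closure digit -> list(atom, sym)
  i <- 1; n <- nchar(smarts)
  add_atom <- function(parsed) {
    atoms[[length(atoms) + 1]] <<- parsed
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[nrow(bonds) + 1, ] <<- list(prev, idx, pending_bond)
    }
    prev <<- idx
    pending_bond <<- ""
  }
  while (i <= n) {
    ch <- substr(smarts, i, i)
    two <- substr(smarts, i, i + 1)
    if (ch == "[") {
      j <- regexpr("]", substring(smarts, i), fixed = TRUE)
      if (j < 0) stop("unclosed bracket in pattern: ", smarts)
      add_atom(.parse_bracket(substr(smarts, i + 1, i + j - 2), smarts))
      i <- i + j
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending_bond <- ch; i <- i + 1
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") { key <- substr(smarts, i + 1, i + 2); i <- i + 3 }
      else { key <- ch; i <- i + 1 }
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        sym <- if (nzchar(pending_bond)) pending_bond else op$sym
        bonds[nrow(bonds) + 1, ] <- list(op$atom, prev, sym)
        ring_open[[key]] <- NULL
        pending_bond <- ""
      } else {
        ring_open[[key]] <- list(atom = prev, sym = pending_bond)
        pending_bond <- ""
      }
    } else if (two %in% c("Cl", "Br")) {
      add_atom(list(terms = list(list(list(list(kind = "elem", neg = FALSE,
        elem = two, arom = FALSE)))), map = NA_integer_))
      i <- i + 2
    } else if (ch %in% c("B", "C", "N", "O", "S", "P", "F", "I")) {
      add_atom(list(terms = list(list(list(list(kind = "elem", neg = FALSE,
        elem = ch, arom = FALSE)))), map = NA_integer_))
      i <- i + 1
    } else if (ch %in% c("c", "n", "o", "s", "p")) {
      add_atom(list(terms = list(list(list(list(kind = "elem", neg = FALSE,
        elem = toupper(ch), arom = TRUE)))), map = NA_integer_))
      i <- i + 1
    } else if (ch == "*") {
      add_atom(list(terms = list(list(list(list(kind = "any", neg = FALSE)))),
                    map = NA_integer_))
      i <- i + 1
    } else if (ch == ".") {
      stop("disconnected patterns are not supported (component patterns are separate): ", smarts)
    } else {
      stop("unsupported character '", ch, "' in pattern: ", smarts)
    }
  }
  if (length(ring_open)) stop("unclosed ring bond in pattern: ", smarts)
  if (!length(atoms)) stop("empty pattern: ", smarts)
  structure(list(atoms = atoms, bonds = bonds, smarts = smarts), class = "rxn_pattern")
}

# ---------------------------------------------------------------------------
# Matching
# ---------------------------------------------------------------------------

.prim_matches <- function(prim, mol, i, deg) {
  val <- switch(prim$kind,
    any    = TRUE,
    elem   = (mol$atoms$elem[i] == prim$elem) &&
             (is.na(prim$arom) || mol$atoms$arom[i] == prim$arom),
    arom   = mol$atoms$arom[i] == prim$value,
    H      = mol$atoms$nH[i] == prim$value,
    X      = (deg[i] + mol$atoms$nH[i]) == prim$value,
    D      = deg[i] == prim$value,
    ring   = mol$atoms$ring[i] == prim$value,
    charge = mol$atoms$charge[i] == prim$value,
    stop("unknown primitive kind ", prim$kind))
  if (prim$neg) !val else val
}

.atom_matches <- function(pat_atom, mol, i, deg) {
  for (term in pat_atom$terms) {      # AND over ';' terms
    term_ok <- FALSE
    for (alt in term) {               # OR over ',' alternatives
      ok <- TRUE
      for (prim in alt) {
        if (!.prim_matches(prim, mol, i, deg)) { ok <- FALSE; break }
      }
      if (ok) { term_ok <- TRUE; break }
    }
    if (!term_ok) return(FALSE)
  }
  TRUE
}

.bond_matches <- function(sym, order, arom) {
  switch(sym,
    "-" = order == 1 && !arom,
    "=" = order == 2 && !arom,
    "#" = order == 3,
    ":" = arom,
    "~" = TRUE,
    (order == 1 && !arom) || arom)   # default: single or aromatic
}

# bond lookup table keyed "i-j" (i<j) -> c(order, arom)
.bond_table <- function(mol) {
  tb <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      key <- paste(sort(c(mol$bonds$a1[k], mol$bonds$a2[k])), collapse = "-")
      assign(key, c(mol$bonds$order[k], as.integer(isTRUE(mol$bonds$arom[k]))), envir = tb)
    }
  }
  tb
}

#' Find substructure matches of a pattern in a molecule
#'
#' Backtracking subgraph search over the hydrogen-suppressed graph. SMARTS
#' semantics: extra bonds of the molecule beyond the pattern are allowed.
#'
#' @param pattern a compiled pattern or pattern string
#' @param mol an `rxn_mol`
#' @param reduce collapse symmetry-equivalent mappings that cover the same
#'   atom set to a single match (default `TRUE`)
#' @param anchor if not `NULL`, the first pattern atom is constrained to this
#'   molecule atom index
#' @return list of integer vectors (pattern atom -> molecule atom)
#' @export
match_pattern <- function(pattern, mol, reduce = TRUE, anchor = NULL) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  np <- length(pattern$atoms)
  nm <- n_atoms(mol)
  if (nm == 0 || np > nm) return(list())
  nb <- mol_adjacency(mol)
  deg <- lengths(nb)
  bt <- .bond_table(mol)
  get_bond <- function(i, j) {
    key <- paste(sort(c(i, j)), collapse = "-")
    if (exists(key, envir = bt, inherits = FALSE)) get(key, envir = bt) else NULL
  }

  # search order: pattern atom 1 first, then atoms adjacent to placed ones
  order_idx <- 1L
  placed <- c(TRUE, rep(FALSE, np - 1))
  pb <- pattern$bonds
  while (length(order_idx) < np) {
    nxt <- NA_integer_
    for (k in seq_len(nrow(pb))) {
      if (placed[pb$a1[k]] && !placed[pb$a2[k]]) { nxt <- pb$a2[k]; break }
      if (placed[pb$a2[k]] && !placed[pb$a1[k]]) { nxt <- pb$a1[k]; break }
    }
    if (is.na(nxt)) stop("pattern must be connected: ", pattern$smarts)
    placed[nxt] <- TRUE
    order_idx <- c(order_idx, nxt)
  }

  matches <- list()
  map <- rep(NA_integer_, np)
  used <- rep(FALSE, nm)

  extend <- function(pos) {
    if (pos > np) {
      matches[[length(matches) + 1L]] <<- map
      return(invisible(NULL))
    }
    pa <- order_idx[pos]
    # candidates: neighbors of an already-placed pattern neighbor, or all atoms
    cand <- NULL
    for (k in seq_len(nrow(pb))) {
      other <- NA_integer_
      if (pb$a1[k] == pa && !is.na(map[pb$a2[k]])) other <- pb$a2[k]
      if (pb$a2[k] == pa && !is.na(map[pb$a1[k]])) other <- pb$a1[k]
      if (!is.na(other)) { cand <- nb[[map[other]]]; break }
    }
    if (is.null(cand)) cand <- seq_len(nm)
    if (pos == 1L && !is.null(anchor)) cand <- intersect(cand, anchor)
    for (mi in cand) {
      if (used[mi]) next
      if (!.atom_matches(pattern$atoms[[pa]], mol, mi, deg)) next
      ok <- TRUE
      for (k in seq_len(nrow(pb))) {
        qa <- NA_integer_
        if (pb$a1[k] == pa) qa <- pb$a2[k]
        if (pb$a2[k] == pa) qa <- pb$a1[k]
        if (is.na(qa) || is.na(map[qa])) next
        b <- get_bond(mi, map[qa])
        if (is.null(b) || !.bond_matches(pb$sym[k], b[1], b[2] == 1L)) { ok <- FALSE; break }
      }
      if (!ok) next
      map[pa] <<- mi; used[mi] <<- TRUE
      extend(pos + 1L)
      map[pa] <<- NA_integer_; used[mi] <<- FALSE
    }
    invisible(NULL)
  }
  extend(1L)

  if (reduce && length(matches) > 1) {
    keys <- vapply(matches, function(m) paste(sort(m), collapse = ","), "")
    matches <- matches[!duplicated(keys)]
  }
  matches
}

#' Count symmetry-reduced matches of a pattern
#' @inheritParams match_pattern
#' @return integer match count
#' @export
count_matches <- function(pattern, mol) length(match_pattern(pattern, mol, reduce = TRUE))
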