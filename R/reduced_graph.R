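# Reduced feature-graph representation
# ------------------------------------
# Rings (SSSR) collapse to one vertex each; fused systems with an atom in more
# than two SSSR rings ("amalgamated") collapse to a single vertex; maximal
# clusters of acyclic lipophilic/untyped atoms collapse to one vertex; every
# other acyclic atom is its own vertex. Vertices carry a 10-bit label (8
# pharmacophore types + ring + amalgamated-ring) and an atom count. Fused
# rings are connected by an edge of order 2, everything else by order 1.

.BIT_NAMES <- c("A", "D", "E", "P", "N", "R", "L", "0", "ring", "amalg")

#' Build the reduced graph of a typed molecule
#'
#' @param mol a typed `rxn_mol` (types are assigned if missing)
#' @return an `rxn_reduced_graph`: list of vertices (`bits`, `ac`,
#'   `member_atoms`, `ring_atoms`), an edge table with orders 1/2, and a
#'   `valid` flag that is `FALSE` when some vertex has more than six
#'   neighbors (such molecules must be discarded by the caller)
#' @export
build_reduced_graph <- function(mol) {
  if (is.null(mol$atoms$ptype)) mol <- assign_pharmacophore_types(mol)
  n <- n_atoms(mol)
  rings <- mol$sssr
  # canonical ring order: size, then sorted atom indices
  if (length(rings)) {
    ord <- order(lengths(rings),
                 vapply(rings, function(r) paste(sprintf("%04d", sort(r)), collapse = ","), ""))
    rings <- rings[ord]
  }
  ring_count <- integer(n)
  for (r in rings) ring_count[r] <- ring_count[r] + 1L

  # ring systems: connected components of rings sharing at least one atom
  nr <- length(rings)
  sys_id <- seq_len(nr)
  if (nr > 1) {
    repeat {
      changed <- FALSE
      for (i in seq_len(nr - 1)) for (j in seq(i + 1, nr)) {
        if (sys_id[i] != sys_id[j] && length(intersect(rings[[i]], rings[[j]]))) {
          tgt <- min(sys_id[i], sys_id[j])
          sys_id[sys_id %in% c(sys_id[i], sys_id[j])] <- tgt
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  vertices <- list()
  assign_of <- rep(NA_integer_, n)   # atom -> vertex
  add_vertex <- function(members, ring_atoms, is_ring, is_amalg) {
    vertices[[length(vertices) + 1L]] <<- list(
      member_atoms = sort(members), ring_atoms = sort(ring_atoms),
      is_ring = is_ring, is_amalg = is_amalg)
    assign_of[members] <<- length(vertices)
    invisible(NULL)
  }

  for (sid in unique(sys_id)) {
    sys_rings <- rings[sys_id == sid]
    sys_atoms <- sort(unique(unlist(sys_rings)))
    if (any(ring_count[sys_atoms] > 2L)) {
      add_vertex(sys_atoms, sys_atoms, TRUE, TRUE)
    } else {
      for (r in sys_rings) {
        members <- r[is.na(assign_of[r])]   # shared atoms go to the earlier ring
        add_vertex(members, r, TRUE, FALSE)
      }
    }
  }

  # acyclic atoms: clusters of L/0, singletons otherwise
  nb <- mol_adjacency(mol)
  acyclic <- which(is.na(assign_of))
  lipo <- acyclic[mol$atoms$ptype[acyclic] %in% c("L", "0")]
  in_lipo <- rep(FALSE, n); in_lipo[lipo] <- TRUE
  seen <- rep(FALSE, n)
  for (s in sort(lipo)) {
    if (seen[s]) next
    cluster <- s; seen[s] <- TRUE; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) if (in_lipo[w] && !seen[w]) {
        seen[w] <- TRUE; cluster <- c(cluster, w); queue <- c(queue, w)
      }
    }
    add_vertex(cluster, integer(0), FALSE, FALSE)
  }
  for (a in sort(acyclic[!acyclic %in% lipo])) add_vertex(a, integer(0), FALSE, FALSE)

  # deterministic vertex order by smallest member atom
  vord <- order(vapply(vertices, function(v) min(v$member_atoms), 1L))
  vertices <- vertices[vord]
  for (vi in seq_along(vertices)) assign_of[vertices[[vi]]$member_atoms] <- vi

  # bit vectors and atom counts
  for (vi in seq_along(vertices)) {
    v <- vertices[[vi]]
    bits <- stats::setNames(rep(FALSE, 10L), .BIT_NAMES)
    for (tp in unique(mol$atoms$ptype[v$member_atoms])) bits[[tp]] <- TRUE
    bits[["ring"]] <- v$is_ring
    bits[["amalg"]] <- v$is_amalg
    vertices[[vi]]$bits <- bits
    vertices[[vi]]$ac <- length(v$member_atoms)
  }

  # edges between vertices whose member sets are bonded
  e1 <- integer(0); e2 <- integer(0)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      u <- assign_of[mol$bonds$a1[k]]; v <- assign_of[mol$bonds$a2[k]]
      if (u != v) { e1 <- c(e1, min(u, v)); e2 <- c(e2, max(u, v)) }
    }
  }
  edges <- unique(data.frame(v1 = e1, v2 = e2))
  if (nrow(edges)) {
    edges <- edges[order(edges$v1, edges$v2), , drop = FALSE]
    rownames(edges) <- NULL
    edges$order <- 1L
    for (k in seq_len(nrow(edges))) {
      a <- vertices[[edges$v1[k]]]; b <- vertices[[edges$v2[k]]]
      if (a$is_ring && b$is_ring && length(intersect(a$ring_atoms, b$ring_atoms))) {
        edges$order[k] <- 2L   # fused rings
      }
    }
  } else {
    edges <- data.frame(v1 = integer(0), v2 = integer(0), order = integer(0))
  }

  deg <- tabulate(c(edges$v1, edges$v2), nbins = length(vertices))
  valid <- all(deg <= 6L)
  structure(list(vertices = vertices, edges = edges, valid = valid,
                 max_degree = if (length(deg)) max(deg) else 0L,
                 source_id = mol$source_id,
                 heavy_atom_count = n),
            class = "rxn_reduced_graph")
}

#' @export
print.rxn_reduced_graph <- function(x, ...) {
  cat(sprintf("<reduced graph %s: %d vertices, %d edges%s>\n",
              ifelse(is.na(x$source_id), "", x$source_id),
              length(x$vertices), nrow(x$edges),
              ifelse(x$valid, "", " [REJECTED: vertex degree > 6]")))
  invisible(x)
}

#' Tanimoto similarity of two bit vectors
#'
#' `c / (a + b - c)` with `a`, `b` the set-bit counts and `c` the common bits.
#'
#' @param bv_a,bv_b logical vectors of equal length, not both all-`FALSE`
#' @return similarity in \[0, 1\]
#' @export
tanimoto_bits <- function(bv_a, bv_b) {
  a <- sum(bv_a); b <- sum(bv_b); cc <- sum(bv_a & bv_b)
  if (a + b == 0) return(0)
  cc / (a + b - cc)
}

#' Atom-count difference penalty
#'
#' 1 at equal counts, linear decay, 0 once the difference exceeds five.
#'
#' @param ac_a,ac_b vertex atom counts (>= 1)
#' @return penalty in \[0, 1\]
#' @export
sd_factor <- function(ac_a, ac_b) {
  max(0, 1 - abs(ac_a - ac_b) / 6)
}

#' Similarity of two reduced-graph vertices
#'
#' The product of the atom-count penalty and the bit-vector Tanimoto index.
#'
#' @param v_a,v_b reduced-graph vertices (elements of
#'   `rxn_reduced_graph$vertices`)
#' @return similarity in \[0, 1\]
#' @export
vertex_similarity <- function(v_a, v_b) {
  sd_factor(v_a$ac, v_b$ac) * tanimoto_bits(v_a$bits, v_b$bits)
}

#' Write a reduced graph for inspection
#'
#' GraphML (via igraph) plus a human-readable vertex table.
#'
#' @param rg an `rxn_reduced_graph`
#' @param graphml_path,table_path output paths (either may be `NULL`)
#' @return the vertex table, invisibly
#' @export
write_reduced_graph <- function(rg, graphml_path = NULL, table_path = NULL) {
  tab <- data.frame(
    vertex = seq_along(rg$vertices),
    bits = vapply(rg$vertices, function(v) paste(.BIT_NAMES[v$bits], collapse = "|"), ""),
    ac = vapply(rg$vertices, function(v) v$ac, 1L),
    atoms = vapply(rg$vertices, function(v) paste(v$member_atoms, collapse = ","), ""))
  if (!is.null(graphml_path)) {
    g <- if (nrow(rg$edges)) {
      igraph::graph_from_data_frame(
        rg$edges[, c("v1", "v2", "order")], directed = FALSE,
        vertices = data.frame(name = tab$vertex, bits = tab$bits, ac = tab$ac))
    } else {
      igraph::make_empty_graph(n = length(rg$vertices), directed = FALSE)
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(table_path)) {
    utils::write.table(tab, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}
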