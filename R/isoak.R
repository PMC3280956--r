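# Iterative optimal-assignment graph-kernel similarity
# ----------------------------------------------------
# "Two vertices are similar if their neighbors are similar": vertex-pair
# similarities are iterated to a fixed point of
#   s(u,v) = (1 - alpha) * base(u,v) + alpha * neighbor_term(u,v)
# where neighbor_term is a maximum-weight one-to-one matching of the two
# neighbor lists (pair weight = edge-label compatibility x current s),
# normalized by the larger neighbor count. The final score is the value of a
# maximum-weight assignment of the smaller graph's vertices onto the larger
# graph, scaled by the larger vertex count, so self-similarity is exactly 1.

#' Kernel parameters
#'
#' @param representation `"molgraph"` (pharmacophore-typed molecular graph,
#'   default alpha 0.875) or `"reduced"` (reduced feature graph, default
#'   alpha 0.4)
#' @param alpha neighborhood weight in `[0, 1)`; `NULL` picks the
#'   representation default
#' @param tol convergence tolerance on the max entry change
#' @param max_iter iteration cap
#' @return a `kernel_params` list
#' @export
kernel_params <- function(representation = c("molgraph", "reduced"),
                          alpha = NULL, tol = 1e-6, max_iter = 100L) {
  representation <- match.arg(representation)
  if (is.null(alpha)) alpha <- if (representation == "molgraph") 0.875 else 0.4
  stopifnot(alpha >= 0, alpha < 1, tol > 0, max_iter >= 1)
  structure(list(representation = representation, alpha = alpha,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "kernel_params")
}

# Uniform view of a graph for the kernel: vertex count, 1-based adjacency,
# integer edge labels (molecular: bond order with aromatic as its own label 4;
# reduced: edge order 1/2), and the data needed for base similarities.
kernel_view <- function(x) {
  if (inherits(x, "rxn_mol")) {
    if (is.null(x$atoms$ptype)) x <- assign_pharmacophore_types(x)
    n <- n_atoms(x)
    adj <- rep(list(integer(0)), n)
    lab <- rep(list(integer(0)), n)
    if (nrow(x$bonds)) {
      el <- ifelse(isTRUE_vec(x$bonds$arom), 4L, x$bonds$order)
      for (k in seq_len(nrow(x$bonds))) {
        i <- x$bonds$a1[k]; j <- x$bonds$a2[k]
        adj[[i]] <- c(adj[[i]], j); lab[[i]] <- c(lab[[i]], el[k])
        adj[[j]] <- c(adj[[j]], i); lab[[j]] <- c(lab[[j]], el[k])
      }
    }
    list(mode = "molecular", n = n, adj = adj, elab = lab, types = x$atoms$ptype)
  } else if (inherits(x, "rxn_reduced_graph")) {
    n <- length(x$vertices)
    adj <- rep(list(integer(0)), n)
    lab <- rep(list(integer(0)), n)
    if (nrow(x$edges)) {
      for (k in seq_len(nrow(x$edges))) {
        i <- x$edges$v1[k]; j <- x$edges$v2[k]; o <- x$edges$order[k]
        adj[[i]] <- c(adj[[i]], j); lab[[i]] <- c(lab[[i]], o)
        adj[[j]] <- c(adj[[j]], i); lab[[j]] <- c(lab[[j]], o)
      }
    }
    list(mode = "reduced", n = n, adj = adj, elab = lab, vertices = x$vertices)
  } else {
    stop("kernel input must be an rxn_mol or rxn_reduced_graph")
  }
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Base similarity of two vertices
#'
#' Molecular mode: 1 if the pharmacophore types are equal, else 0. Reduced
#' mode: [vertex_similarity()] (atom-count penalty times bit Tanimoto).
#'
#' @param u,v vertices: pharmacophore type strings (molecular) or
#'   reduced-graph vertex lists (reduced)
#' @param mode `"molecular"` or `"reduced"`
#' @return similarity in \[0, 1\]
#' @export
base_vertex_similarity <- function(u, v, mode = c("molecular", "reduced")) {
  mode <- match.arg(mode)
  if (mode == "molecular") {
    if (!is.character(u) || !is.character(v)) stop("molecular mode expects type labels")
    as.numeric(u == v)
  } else {
    if (is.character(u) || is.character(v)) stop("reduced mode expects reduced-graph vertices")
    vertex_similarity(u, v)
  }
}

.base_matrix <- function(va, vb) {
  if (va$mode != vb$mode) stop("cannot compare graphs of different representations")
  if (va$mode == "molecular") {
    outer(va$types, vb$types, function(a, b) as.numeric(a == b))
  } else {
    m <- matrix(0, va$n, vb$n)
    for (i in seq_len(va$n)) for (j in seq_len(vb$n)) {
      m[i, j] <- vertex_similarity(va$vertices[[i]], vb$vertices[[j]])
    }
    m
  }
}

.check_degree <- function(v) {
  if (any(lengths(v$adj) > 6L)) {
    stop("kernel requires maximum vertex degree 6 (got ", max(lengths(v$adj)), ")")
  }
}

#' Iterate vertex-pair similarities to convergence
#'
#' @param g_a,g_b two graphs of the same representation (`rxn_mol` or
#'   `rxn_reduced_graph`)
#' @param params a [kernel_params()] object
#' @return matrix of vertex-pair similarities with attributes `iterations`
#'   and `converged`
#' @export
iterate_similarity <- function(g_a, g_b, params = kernel_params()) {
  va <- kernel_view(g_a); vb <- kernel_view(g_b)
  if (va$n == 0 || vb$n == 0) stop("cannot compare empty graphs")
  .check_degree(va); .check_degree(vb)
  base <- .base_matrix(va, vb)
  s <- isoak_iterate_cpp(base, va$adj, vb$adj, va$elab, vb$elab,
                         params$alpha, params$tol, params$max_iter)
  if (!attr(s, "converged")) {
    warning("similarity iteration did not converge within ", params$max_iter,
            " iterations")
  }
  s
}

#' Graph-kernel similarity score of two molecules
#'
#' Maximum-weight one-to-one assignment over the converged vertex-pair
#' similarities, scaled by the larger vertex count. Symmetric, bounded in
#' \[0, 1\], and exactly 1 for a graph against itself.
#'
#' @inheritParams iterate_similarity
#' @return a similarity score in \[0, 1\]
#' @export
molecule_similarity <- function(g_a, g_b, params = kernel_params()) {
  s <- iterate_similarity(g_a, g_b, params)
  res <- hungarian_max_cpp(s)
  res$value / max(nrow(s), ncol(s))
}

#' Rank a set of molecules by similarity to a reference
#'
#' The scoring front end used for start-fragment selection and the `score`
#' command-line subcommand.
#'
#' @param reference a typed `rxn_mol`
#' @param queries list of typed `rxn_mol` objects
#' @param params a [kernel_params()] object; reduced representation converts
#'   both sides with [build_reduced_graph()] and drops molecules whose reduced
#'   graph exceeds the degree-6 limit
#' @return data.frame (id, score) sorted by score descending, ties broken by
#'   canonical SMILES then id
#' @export
score_molecules <- function(reference, queries, params = kernel_params()) {
  ref_g <- if (params$representation == "reduced") build_reduced_graph(reference) else reference
  if (params$representation == "reduced" && !ref_g$valid) {
    stop("reference reduced graph exceeds the degree-6 limit")
  }
  ids <- vapply(queries, function(m) m$source_id, "")
  scores <- rep(NA_real_, length(queries))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    qg <- if (params$representation == "reduced") build_reduced_graph(q) else q
    if (params$representation == "reduced" && !qg$valid) next
    scores[i] <- molecule_similarity(ref_g, qg, params)
  }
  smis <- vapply(queries, canonical_smiles, "")
  out <- data.frame(id = ids, score = scores, smiles = smis,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$score), , drop = FALSE]
  out[order(-out$score, out$smiles, out$id), , drop = FALSE]
}
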