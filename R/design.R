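# Deterministic greedy/beam construction
# --------------------------------------
# Start fragments are the catalog blocks ranked by kernel similarity to the
# reference. Each extension cycle (i) scores every applicable reaction via
# its minimal-dummy-fragment product and keeps the top-scoring reaction(s),
# (ii) enumerates all catalog partners of the chosen reaction(s), scores the
# real products and carries the top-scoring one(s) forward, never more than
# `beam_width` states per round. Growth below the lower mass bound is
# unconditional; above it, a step must strictly improve the score and stay
# under the upper mass bound, otherwise the previous intermediate is
# finalized. The step cap finalizes unconditionally. No randomness anywhere:
# ties break by score, then canonical SMILES, then block id.

.SCORE_EPS <- 1e-9

#' Design run configuration
#'
#' @param n_starts number of start fragments that must yield at least one
#'   product each (dead starts are skipped and replaced)
#' @param beam_width maximum intermediate products carried per round
#' @param max_steps maximum synthesis steps per pathway
#' @param mass_low_frac,mass_high_frac mass window relative to the reference
#' @param representation,alpha,tol,max_iter kernel settings (see
#'   [kernel_params()])
#' @return a `design_config` list
#' @export
design_config <- function(n_starts = 200L, beam_width = 10L, max_steps = 4L,
                          mass_low_frac = 0.70, mass_high_frac = 1.30,
                          representation = c("molgraph", "reduced"),
                          alpha = NULL, tol = 1e-6, max_iter = 100L) {
  representation <- match.arg(representation)
  stopifnot(mass_low_frac > 0, mass_low_frac < 1, mass_high_frac > 1,
            beam_width >= 1, max_steps >= 1, n_starts >= 1)
  structure(list(n_starts = as.integer(n_starts), beam_width = as.integer(beam_width),
                 max_steps = as.integer(max_steps), mass_low_frac = mass_low_frac,
                 mass_high_frac = mass_high_frac,
                 kernel = kernel_params(representation, alpha, tol, max_iter)),
            class = "design_config")
}

# similarity scorer against a fixed reference with a canonical-SMILES cache;
# returns NA for molecules whose reduced graph violates the degree-6 limit
make_scorer <- function(reference, config) {
  kp <- config$kernel
  ref_g <- if (kp$representation == "reduced") build_reduced_graph(reference) else reference
  if (kp$representation == "reduced" && !ref_g$valid) {
    stop("reference reduced graph exceeds the degree-6 limit")
  }
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(mol) {
    key <- canonical_smiles(mol)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    g <- if (kp$representation == "reduced") build_reduced_graph(mol) else mol
    val <- if (kp$representation == "reduced" && !g$valid) NA_real_
           else molecule_similarity(ref_g, g, kp)
    cache[[key]] <- val
    val
  }
}

.new_state <- function(mol, score, steps, route) {
  list(mol = mol, score = score, mass = mol_mass(mol), steps = steps,
       smiles = canonical_smiles(mol), route = route)
}

#' Rank catalog blocks as start fragments
#'
#' Blocks with at least one reaction annotation, ranked by similarity to the
#' reference; ties break by canonical SMILES then block id.
#'
#' @param catalog an `rxn_catalog`
#' @param reference a typed `rxn_mol`
#' @param config a [design_config()]
#' @param n how many to return (default `config$n_starts`; capped at the
#'   catalog size with a warning)
#' @return ordered list of blocks
#' @export
select_start_fragments <- function(catalog, reference, config = design_config(),
                                   n = config$n_starts) {
  usable <- catalog$blocks[catalog$table$usable]
  if (!length(usable)) stop("catalog has no usable (annotated) blocks")
  scorer <- make_scorer(reference, config)
  scores <- vapply(usable, function(b) scorer(b) %||% NA_real_, 1)
  smis <- vapply(usable, canonical_smiles, "")
  ids <- vapply(usable, function(b) b$source_id, "")
  keep <- !is.na(scores)
  ord <- order(-scores[keep], smis[keep], ids[keep])
  ranked <- usable[keep][ord]
  attr(ranked, "scores") <- scores[keep][ord]
  if (n > length(ranked)) {
    warning("requested ", n, " start fragments but only ", length(ranked),
            " scorable blocks are available")
    n <- length(ranked)
  }
  out <- ranked[seq_len(n)]
  attr(out, "scores") <- attr(ranked, "scores")[seq_len(n)]
  out
}

#' One extension cycle of the growing molecule
#'
#' Step 1 ranks the applicable reactions by their dummy products (one dummy
#' product per reaction; one-component reactions compete with their actual
#' product); all top-tied reactions proceed. Step 2 enumerates every
#' annotated catalog partner of the selected reactions and returns the
#' top-tied products, at most `beam_width` states.
#'
#' @param state a design state (`mol`, `score`, `mass`, `steps`, `route`)
#' @param catalog an `rxn_catalog`
#' @param library coupling templates
#' @param reference the reference molecule (used via `scorer`)
#' @param config a [design_config()]
#' @param scorer optional prebuilt scorer from [make_scorer()]
#' @return list of extended states (possibly empty: the pathway dies)
#' @export
extension_cycle <- function(state, catalog, library, reference,
                            config = design_config(), scorer = NULL) {
  if (is.null(scorer)) scorer <- make_scorer(reference, config)
  hits <- find_applicable_reactions(state$mol, library)
  if (!length(hits)) return(list())

  # Step 1: score each reaction through its dummy product
  step1 <- list()
  for (h in hits) {
    tmpl <- h$template
    prod <- tryCatch({
      if (tmpl$n_components == 1L) {
        apply_reaction(tmpl, list(state$mol))
      } else {
        other <- 3L - h$component
        dummy <- minimal_dummy_fragment(tmpl, other)
        reactants <- if (h$component == 1L) list(state$mol, dummy) else list(dummy, state$mol)
        apply_reaction(tmpl, reactants)
      }
    }, rxn_reaction_error = function(e) NULL, error = function(e) NULL)
    if (is.null(prod)) next
    sc <- scorer(prod)
    if (is.na(sc)) next
    step1[[length(step1) + 1L]] <- list(hit = h, dummy_score = sc, dummy_product = prod)
  }
  if (!length(step1)) return(list())
  top1 <- max(vapply(step1, function(x) x$dummy_score, 1))
  selected <- Filter(function(x) x$dummy_score >= top1 - .SCORE_EPS, step1)

  # Step 2: enumerate partners of the selected reaction(s)
  cands <- list()
  add_cand <- function(prod, sc, tmpl, component_of_Z, partner) {
    step <- list(
      reaction_id = tmpl$id, reaction_name = tmpl$name,
      reference = tmpl$reference,
      z_component = component_of_Z,
      partner_id = if (is.null(partner)) NA_character_ else partner$source_id,
      partner_parent = if (is.null(partner)) NA_character_ else partner$parent_id %||% NA_character_,
      partner_preprocessing = if (is.null(partner)) NA_character_
                              else partner$preprocessing_id %||% NA_character_,
      product = canonical_smiles(prod))
    cands[[length(cands) + 1L]] <<- .new_state(prod, sc, state$steps + 1L,
                                               c(state$route, list(step)))
    invisible(NULL)
  }
  for (sel in selected) {
    tmpl <- sel$hit$template
    if (tmpl$n_components == 1L) {
      add_cand(sel$dummy_product, sel$dummy_score, tmpl, 1L, NULL)
      next
    }
    other <- 3L - sel$hit$component
    for (partner in catalog_partners(catalog, tmpl$id, other)) {
      prod <- tryCatch({
        reactants <- if (sel$hit$component == 1L) list(state$mol, partner)
                     else list(partner, state$mol)
        apply_reaction(tmpl, reactants)
      }, rxn_reaction_error = function(e) NULL, error = function(e) NULL)
      if (is.null(prod)) next
      sc <- scorer(prod)
      if (is.na(sc)) next
      add_cand(prod, sc, tmpl, sel$hit$component, partner)
    }
  }
  if (!length(cands)) return(list())
  top2 <- max(vapply(cands, function(x) x$score, 1))
  tied <- Filter(function(x) x$score >= top2 - .SCORE_EPS, cands)
  ord <- order(vapply(tied, function(x) x$smiles, ""),
               vapply(tied, function(x) x$route[[length(x$route)]]$partner_id %||% "", ""))
  tied <- tied[ord]
  tied[seq_len(min(length(tied), config$beam_width))]
}

#' Stop-criterion decision for one extension step
#'
#' Below the lower mass bound every extension is accepted (even a score
#' decrease). At or above it, the step must strictly improve the score. A
#' step may never push the mass over the upper bound. Pathways at the step
#' cap are finalized unconditionally (handled by the run loop).
#'
#' @param prev,nxt the previous and extended design states
#' @param reference_mass mass of the reference ligand (Da)
#' @param config a [design_config()]
#' @return `"accept"` or `"finalize_prev"`
#' @export
check_stop <- function(prev, nxt, reference_mass, config = design_config()) {
  if (nxt$mass > config$mass_high_frac * reference_mass) return("finalize_prev")
  if (prev$mass < config$mass_low_frac * reference_mass) return("accept")
  if (nxt$score > prev$score) "accept" else "finalize_prev"
}

.finalize <- function(state, reason, ref_mass, config) {
  list(final_smiles = state$smiles, final_score = state$score,
       final_mass = state$mass, n_steps = state$steps,
       start_block = state$route[[1]]$start_block %||% NA_character_,
       steps = state$route, finalized_by = reason,
       below_mass_window = state$mass < config$mass_low_frac * ref_mass)
}

# grow one start fragment to its list of finalized routes
.grow_start <- function(blk, blk_score, catalog, library, reference, config, scorer,
                        ref_mass) {
  start_step_tag <- blk$source_id
  st0 <- .new_state(blk, blk_score, 0L, list())
  frontier <- list(st0)
  finals <- list()
  while (length(frontier)) {
    nxt_frontier <- list()
    for (state in frontier) {
      if (state$steps >= config$max_steps) {
        if (state$steps > 0L) finals[[length(finals) + 1L]] <-
            .finalize(state, "step_cap", ref_mass, config)
        next
      }
      cands <- extension_cycle(state, catalog, library, reference, config, scorer)
      accepted <- list()
      for (cand in cands) {
        if (check_stop(state, cand, ref_mass, config) == "accept") {
          accepted[[length(accepted) + 1L]] <- cand
        }
      }
      if (!length(accepted)) {
        # dead end or rejected extension: previous intermediate is the product
        if (state$steps > 0L) {
          reason <- if (length(cands)) "score" else "dead_end"
          finals[[length(finals) + 1L]] <- .finalize(state, reason, ref_mass, config)
        }
        next
      }
      nxt_frontier <- c(nxt_frontier, accepted)
    }
    if (length(nxt_frontier) > config$beam_width) {
      ord <- order(-vapply(nxt_frontier, function(x) x$score, 1),
                   vapply(nxt_frontier, function(x) x$smiles, ""))
      nxt_frontier <- nxt_frontier[ord][seq_len(config$beam_width)]
    }
    frontier <- nxt_frontier
  }
  for (i in seq_along(finals)) finals[[i]]$start_block <- start_step_tag
  finals
}

#' Run the full design algorithm
#'
#' Grows at least `n_starts` pathways (dead starts are skipped with the next
#' ranked block taking their place), collapses duplicate final products while
#' retaining all routes, and sorts by final score then canonical SMILES.
#' The run is deterministic: identical inputs give byte-identical output.
#'
#' @param catalog an `rxn_catalog`
#' @param reference a typed `rxn_mol` reference ligand
#' @param library coupling templates
#' @param config a [design_config()]
#' @return an `rxn_designs` object: `summary` data.frame (one row per unique
#'   product) and `routes` (all finalized routes per product)
#' @export
run_design <- function(catalog, reference, library, config = design_config()) {
  scorer <- make_scorer(reference, config)
  ref_mass <- mol_mass(reference)
  ranked <- select_start_fragments(catalog, reference, config,
                                   n = sum(catalog$table$usable))
  scores <- attr(ranked, "scores")
  all_routes <- list()
  productive <- 0L
  i <- 0L
  while (i < length(ranked) && productive < config$n_starts) {
    i <- i + 1L
    finals <- .grow_start(ranked[[i]], scores[i], catalog, library, reference,
                          config, scorer, ref_mass)
    if (length(finals)) {
      productive <- productive + 1L
      all_routes <- c(all_routes, finals)
    }
  }
  if (!length(all_routes)) {
    stop("design produced no routes: no start fragment could complete a single ",
         "reaction step (catalog size ", length(ranked), ", reference mass ",
         round(ref_mass, 1), " Da)")
  }
  if (productive < config$n_starts) {
    warning("catalog exhausted after ", productive, " productive starts (",
            config$n_starts, " requested)")
  }

  # collapse duplicate products, keep every route
  key <- vapply(all_routes, function(r) r$final_smiles, "")
  groups <- split(seq_along(all_routes), key)
  uniq <- lapply(groups, function(idx) {
    r0 <- all_routes[[idx[1]]]
    list(smiles = r0$final_smiles, score = r0$final_score, mass = r0$final_mass,
         below_mass_window = r0$below_mass_window,
         routes = all_routes[idx])
  })
  ord <- order(-vapply(uniq, function(u) u$score, 1),
               vapply(uniq, function(u) u$smiles, ""))
  uniq <- uniq[ord]
  summary <- data.frame(
    rank = seq_along(uniq),
    smiles = vapply(uniq, function(u) u$smiles, ""),
    score = vapply(uniq, function(u) u$score, 1),
    mass = vapply(uniq, function(u) u$mass, 1),
    n_routes = vapply(uniq, function(u) length(u$routes), 1L),
    n_steps = vapply(uniq, function(u) u$routes[[1]]$n_steps, 1L),
    start_block = vapply(uniq, function(u) u$routes[[1]]$start_block, ""),
    below_mass_window = vapply(uniq, function(u) u$below_mass_window, TRUE),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, products = uniq,
                 reference_mass = ref_mass, config = config,
                 n_productive_starts = productive),
            class = "rxn_designs")
}

#' @export
print.rxn_designs <- function(x, ...) {
  cat(sprintf("<design run: %d unique products from %d productive starts>\n",
              nrow(x$summary), x$n_productive_starts))
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Replay a synthesis route
#'
#' Re-applies every recorded step through the reaction engine and returns the
#' canonical SMILES of the rebuilt product; used to verify that each emitted
#' route reproduces its final product exactly.
#'
#' @param route one route object from an `rxn_designs`
#' @param catalog the catalog used in the run
#' @param library the reaction library used in the run
#' @return canonical SMILES of the replayed product
#' @export
replay_route <- function(route, catalog, library) {
  ids <- vapply(catalog$blocks, function(b) b$source_id, "")
  z <- catalog$blocks[[match(route$start_block, ids)]]
  for (step in route$steps) {
    tmpl <- library[[step$reaction_id]]
    if (tmpl$n_components == 1L) {
      z <- apply_reaction(tmpl, list(z))
    } else {
      partner <- catalog$blocks[[match(step$partner_id, ids)]]
      reactants <- if (step$z_component == 1L) list(z, partner) else list(partner, z)
      z <- apply_reaction(tmpl, reactants)
    }
  }
  canonical_smiles(z)
}

#' Write design outputs
#'
#' SDF of the designed molecules (score/mass/flags as data fields), one JSON
#' route file, and a TSV summary — all deterministic.
#'
#' @param designs an `rxn_designs`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_designs <- function(designs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(designs$summary, file.path(dir, "designs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sdf <- vapply(seq_along(designs$products), function(i) {
    u <- designs$products[[i]]
    mol <- parse_smiles(u$smiles, id = sprintf("DESIGN%04d", i))
    body <- mol_to_sdf(mol, id = sprintf("DESIGN%04d", i))
    props <- sprintf("> <%s>\n%s\n", c("score", "mass", "n_routes", "below_mass_window"),
                     c(format(u$score, digits = 10), format(u$mass, digits = 8),
                       length(u$routes), tolower(as.character(u$below_mass_window))))
    sub("\\$\\$\\$\\$$", paste0(paste(props, collapse = "\n"), "\n$$$$"), body)
  }, "")
  writeLines(sdf, file.path(dir, "designs.sdf"))
  routes <- list(version = "1.0",
                 products = lapply(designs$products, function(u) {
                   list(smiles = u$smiles, score = u$score, mass = u$mass,
                        routes = u$routes)
                 }))
  jsonlite::write_json(routes, file.path(dir, "routes.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}
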