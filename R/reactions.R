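# Reaction templates and virtual synthesis
# ----------------------------------------
# A template couples one or two reactants into exactly one product. Reactant
# sides are reaction centers in the package's SMARTS subset with atom maps;
# the product side is a kekulized mapped pattern interpreted as graph edits:
#   - matched-but-unmapped reactant atoms are deleted (the leaving group),
#   - bonds between two matched atoms exist in the product only if the
#     product side draws them (explicit -/=/# orders override; a default bond
#     keeps an existing bond's order, a new default bond is single),
#   - unmapped product atoms are added as new atoms,
#   - implicit hydrogens are recomputed from valence, aromaticity re-perceived.
# Environment exclusions (e.g. "this N must not be an amide N") are 'forbid'
# patterns whose first atom is anchored on the component's first matched atom.

#' Load a reaction library
#'
#' Reads a YAML template file (see `inst/extdata/coupling_reactions.yaml` for
#' the schema), compiles all patterns, and self-tests every template by
#' applying it to its declared minimal dummy fragments.
#'
#' @param path YAML file of reaction templates
#' @param self_test run the dummy-fragment round-trip validation (default TRUE)
#' @return list of `rxn_template` objects
#' @export
load_reaction_library <- function(path, self_test = TRUE) {
  if (!file.exists(path)) stop("cannot read reaction library: ", path)
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("reaction library is empty: ", path)
  ids <- vapply(raw, function(r) as.character(r$id), "")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  templates <- lapply(raw, function(r) {
    tmpl <- tryCatch(.compile_template(r), error = function(e) {
      stop("invalid reaction template '", r$id, "': ", conditionMessage(e))
    })
    tmpl
  })
  names(templates) <- ids
  if (self_test) {
    for (tmpl in templates) .template_self_test(tmpl)
  }
  templates
}

.compile_template <- function(r) {
  stopifnot(!is.null(r$id), !is.null(r$components), !is.null(r$product))
  comps <- lapply(r$components, function(cc) {
    list(pattern = parse_pattern(cc$pattern),
         dummy = cc$dummy,
         forbid = lapply(cc$forbid %||% list(), parse_pattern))
  })
  n_comp <- length(comps)
  if (!n_comp %in% 1:2) stop("a template needs 1 or 2 components")
  product <- parse_pattern(r$product)
  # product atoms: mapped (existing) or concrete new atoms
  for (pa in product$atoms) {
    if (!is.na(pa$map)) next
    if (is.null(.concrete_atom(pa))) {
      stop("unmapped product atom must be a concrete element in '", r$id, "'")
    }
  }
  maps_in <- sort(unlist(lapply(comps, function(cc) {
    m <- vapply(cc$pattern$atoms, function(a) a$map, 1L)
    m[!is.na(m)]
  })))
  if (anyDuplicated(maps_in)) stop("duplicate atom map on the reactant side")
  maps_out <- vapply(product$atoms, function(a) a$map, 1L)
  maps_out <- maps_out[!is.na(maps_out)]
  if (!all(maps_out %in% maps_in)) stop("product references unknown atom map")
  structure(list(
    id = as.character(r$id),
    name = r$name %||% as.character(r$id),
    n_components = n_comp,
    components = comps,
    product = product,
    ring_forming = isTRUE(r$ring_forming),
    regioisomer_group = r$regioisomer_group %||% NA_character_,
    leaving_group = r$leaving_group %||% "none",
    leaving_mass = as.numeric(r$leaving_mass %||% NA_real_),
    reference = r$reference %||% NA_character_
  ), class = "rxn_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.concrete_atom <- function(pat_atom) {
  # a product-side atom spec: element from the first positive elem primitive,
  # charge from an explicit charge primitive (NA = keep/default)
  elem <- NULL; charge <- NA_integer_
  for (term in pat_atom$terms) {
    if (length(term) != 1) next  # OR groups are not concrete
    for (prim in term[[1]]) {
      if (prim$neg) next
      if (prim$kind == "elem" && is.null(elem)) elem <- prim$elem
      if (prim$kind == "charge") charge <- prim$value
    }
  }
  if (is.null(elem)) return(NULL)
  list(elem = elem, charge = charge)
}

#' @export
print.rxn_template <- function(x, ...) {
  cat(sprintf("<reaction %s (%s): %d component(s)%s>\n", x$id, x$name,
              x$n_components, ifelse(x$ring_forming, ", ring-forming", "")))
  invisible(x)
}

#' Minimal dummy fragment of a template component
#'
#' The smallest molecule satisfying the component's reaction center, used to
#' estimate the smallest structural change the reaction introduces.
#' One-component templates define none.
#'
#' @param template an `rxn_template`
#' @param component component index (1 or 2)
#' @return a typed `rxn_mol`, or `NULL` for one-component templates
#' @export
minimal_dummy_fragment <- function(template, component) {
  if (template$n_components == 1L) return(NULL)
  stopifnot(component %in% seq_len(template$n_components))
  smi <- template$components[[component]]$dummy
  if (is.null(smi)) stop("template '", template$id, "' lacks a dummy for component ", component)
  assign_pharmacophore_types(
    parse_smiles(smi, id = paste0("dummy:", template$id, ":", component)))
}

# matches of one component in a molecule after forbid filtering
.component_matches <- function(comp, mol) {
  ms <- match_pattern(comp$pattern, mol, reduce = TRUE)
  if (!length(ms) || !length(comp$forbid)) return(ms)
  keep <- vapply(ms, function(m) {
    for (fb in comp$forbid) {
      if (length(match_pattern(fb, mol, reduce = TRUE, anchor = m[1]))) return(FALSE)
    }
    TRUE
  }, TRUE)
  ms[keep]
}

#' Find reactions applicable to a molecule
#'
#' A (template, component) pair applies when the component's reaction center
#' matches the molecule exactly once (on symmetry-reduced matches, after
#' forbid filtering) — multiple occurrences of the same functional group
#' disqualify a reactant.
#'
#' @param mol a typed `rxn_mol`
#' @param library list of `rxn_template`s from [load_reaction_library()]
#' @return list of hits: `list(template, component, match)`
#' @export
find_applicable_reactions <- function(mol, library) {
  hits <- list()
  for (tmpl in library) {
    for (ci in seq_len(tmpl$n_components)) {
      ms <- .component_matches(tmpl$components[[ci]], mol)
      if (length(ms) == 1L) {
        hits[[length(hits) + 1L]] <- list(template = tmpl, component = ci,
                                          match = ms[[1]])
      }
    }
  }
  hits
}

.reaction_error <- function(template, msg) {
  structure(class = c("rxn_reaction_error", "error", "condition"),
            list(message = paste0("reaction '", template$id, "': ", msg),
                 call = NULL, template_id = template$id))
}

#' Apply a reaction template to its reactants
#'
#' Each reactant must match its component pattern exactly once. Produces a
#' single sanitized product with per-atom provenance (`from_component`).
#'
#' @param template an `rxn_template`
#' @param reactants list of 1 or 2 typed `rxn_mol`s, in component order
#' @return the product `rxn_mol`
#' @export
apply_reaction <- function(template, reactants) {
  if (!is.list(reactants) || inherits(reactants, "rxn_mol")) reactants <- list(reactants)
  if (length(reactants) != template$n_components) {
    stop(.reaction_error(template, "wrong number of reactants"))
  }
  matches <- vector("list", template$n_components)
  for (ci in seq_len(template$n_components)) {
    ms <- .component_matches(template$components[[ci]], reactants[[ci]])
    if (length(ms) != 1L) {
      stop(.reaction_error(template, sprintf(
        "component %d must match exactly once (found %d)", ci, length(ms))))
    }
    matches[[ci]] <- ms[[1]]
  }

  # combined atom table
  offsets <- c(0L, if (template$n_components == 2L) n_atoms(reactants[[1]]))
  atoms <- do.call(rbind, lapply(reactants, function(m) m$atoms[, c("elem", "charge")]))
  rownames(atoms) <- NULL
  from_component <- unlist(lapply(seq_along(reactants),
                                  function(i) rep(i, n_atoms(reactants[[i]]))))
  all_bonds <- do.call(rbind, lapply(seq_along(reactants), function(i) {
    b <- reactants[[i]]$bonds[, c("a1", "a2", "order")]
    if (nrow(b)) { b$a1 <- b$a1 + offsets[i]; b$a2 <- b$a2 + offsets[i] }
    b
  }))

  # map number -> combined atom index; matched set
  map_of <- integer(0)
  matched <- integer(0)
  for (ci in seq_len(template$n_components)) {
    pat <- template$components[[ci]]$pattern
    mvec <- matches[[ci]] + offsets[ci]
    matched <- c(matched, mvec)
    for (k in seq_along(pat$atoms)) {
      mp <- pat$atoms[[k]]$map
      if (!is.na(mp)) map_of[as.character(mp)] <- mvec[k]
    }
  }
  mapped_atoms <- unname(map_of)
  deleted <- setdiff(matched, mapped_atoms)
  # leaving atoms must not carry non-matched substituents (would fragment)
  for (d in deleted) {
    nbrs <- c(all_bonds$a2[all_bonds$a1 == d], all_bonds$a1[all_bonds$a2 == d])
    if (any(!nbrs %in% matched)) {
      stop(.reaction_error(template, "leaving-group atom carries a variable substituent"))
    }
  }

  survivors <- setdiff(seq_len(nrow(atoms)), deleted)
  new_idx <- integer(nrow(atoms)); new_idx[survivors] <- seq_along(survivors)
  prod_atoms <- atoms[survivors, , drop = FALSE]
  prod_from <- from_component[survivors]
  rownames(prod_atoms) <- NULL

  # original bonds: keep those not fully inside the matched set
  keep <- logical(nrow(all_bonds))
  orig_order <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(all_bonds)) for (k in seq_len(nrow(all_bonds))) {
    u <- all_bonds$a1[k]; v <- all_bonds$a2[k]
    assign(paste(sort(c(u, v)), collapse = "-"), all_bonds$order[k], envir = orig_order)
    keep[k] <- !(u %in% matched && v %in% matched) && u %in% survivors && v %in% survivors
  }
  prod_bonds <- all_bonds[keep, , drop = FALSE]
  if (nrow(prod_bonds)) {
    prod_bonds$a1 <- new_idx[prod_bonds$a1]
    prod_bonds$a2 <- new_idx[prod_bonds$a2]
  }

  # product-side atoms and bonds
  ppat <- template$product
  prod_atom_idx <- integer(length(ppat$atoms))   # product pattern atom -> new atom index
  for (k in seq_along(ppat$atoms)) {
    pa <- ppat$atoms[[k]]
    if (!is.na(pa$map)) {
      comb <- map_of[as.character(pa$map)]
      prod_atom_idx[k] <- new_idx[comb]
      conc <- .concrete_atom(pa)
      if (!is.null(conc) && !is.na(conc$charge)) {
        prod_atoms$charge[prod_atom_idx[k]] <- conc$charge
      }
    } else {
      conc <- .concrete_atom(pa)
      prod_atoms <- rbind(prod_atoms, data.frame(
        elem = conc$elem, charge = ifelse(is.na(conc$charge), 0L, conc$charge)))
      prod_from <- c(prod_from, 0L)   # contributed by the reaction itself
      prod_atom_idx[k] <- nrow(prod_atoms)
    }
  }
  if (nrow(ppat$bonds)) for (k in seq_len(nrow(ppat$bonds))) {
    pa <- ppat$bonds$a1[k]; pb <- ppat$bonds$a2[k]; sym <- ppat$bonds$sym[k]
    u <- prod_atom_idx[pa]; v <- prod_atom_idx[pb]
    ord <- switch(sym, "-" = 1L, "=" = 2L, "#" = 3L,
                  ":" = stop(.reaction_error(template, "aromatic product bonds not allowed; write kekulized")),
                  NULL)
    if (is.null(ord)) {   # default: keep an existing bond's order, else single
      ma <- ppat$atoms[[pa]]$map; mb <- ppat$atoms[[pb]]$map
      ord <- 1L
      if (!is.na(ma) && !is.na(mb)) {
        key <- paste(sort(c(map_of[as.character(ma)], map_of[as.character(mb)])), collapse = "-")
        if (exists(key, envir = orig_order, inherits = FALSE)) {
          ord <- get(key, envir = orig_order)
        }
      }
    }
    prod_bonds <- rbind(prod_bonds, data.frame(a1 = u, a2 = v, order = ord))
  }

  product <- tryCatch(.new_mol(prod_atoms, prod_bonds), error = function(e) NULL)
  if (is.null(product)) stop(.reaction_error(template, "product construction failed"))
  if (!valences_ok(product)) stop(.reaction_error(template, "product has invalid valences"))
  if (max(mol_components(product)) != 1L) {
    stop(.reaction_error(template, "product is not a single connected molecule"))
  }
  product$atoms$from_component <- prod_from
  product$source_id <- paste0(template$id, "(",
    paste(vapply(reactants, function(m) ifelse(is.na(m$source_id), "?", m$source_id), ""),
          collapse = ","), ")")
  assign_pharmacophore_types(product)
}

# load-time validation: dummies match exactly once and react to one product
.template_self_test <- function(template) {
  if (template$n_components == 1L) {
    d <- template$components[[1]]$dummy
    if (is.null(d)) return(invisible(TRUE))  # nothing to validate against
    mol <- assign_pharmacophore_types(parse_smiles(d))
    ms <- .component_matches(template$components[[1]], mol)
    if (length(ms) != 1L) {
      stop("template '", template$id, "' self-test: dummy matches ", length(ms), " times")
    }
    prod <- apply_reaction(template, list(mol))
  } else {
    dummies <- lapply(1:2, function(ci) minimal_dummy_fragment(template, ci))
    for (ci in 1:2) {
      ms <- .component_matches(template$components[[ci]], dummies[[ci]])
      if (length(ms) != 1L) {
        stop("template '", template$id, "' self-test: dummy ", ci,
             " matches ", length(ms), " times")
      }
    }
    prod <- apply_reaction(template, dummies)
  }
  invisible(TRUE)
}
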