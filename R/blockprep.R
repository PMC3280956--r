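# Building-block catalog preparation
# ----------------------------------
# Three stages: (1) standardize + filter, (2) functional-group addition /
# interconversion (FGA/FGI) preprocessing with originals kept, (3) annotation
# of reactive substructures (which block can serve which reaction component;
# a center must occur exactly once). The persisted store is a deterministic
# TSV plus a JSON report of per-rule rejection and per-reaction annotation
# counts.

.FILTER_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si", "Se")
.FILTER_RULE_ORDER <- c("mass", "rings", "element", "fluorine", "valence", "alert", "duplicate")

#' Standardize a building block
#'
#' Keeps the largest fragment, deprotonates carboxylic acids, protonates
#' basic aliphatic amines, and re-perceives the graph.
#'
#' @param mol an `rxn_mol`
#' @return the standardized, typed `rxn_mol`
#' @export
standardize <- function(mol) {
  comp <- mol_components(mol)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    keep_comp <- which.max(sizes)          # deterministic: first largest
    keep <- which(comp == keep_comp)
    idx <- integer(n_atoms(mol)); idx[keep] <- seq_along(keep)
    atoms <- mol$atoms[keep, c("elem", "charge"), drop = FALSE]
    rownames(atoms) <- NULL
    b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
    if (nrow(b)) { b$a1 <- idx[b$a1]; b$a2 <- idx[b$a2] }
    mol <- .new_mol(atoms, b[, c("a1", "a2", "order")], source_id = mol$source_id)
  }
  # deprotonate carboxylic acids
  for (m in match_pattern("[CX3](=[OX1])[OX2H1]", mol)) {
    mol$atoms$charge[m[3]] <- -1L
  }
  mol <- perceive(mol)
  # protonate basic aliphatic amines
  nb <- mol_adjacency(mol)
  bsum <- .bond_order_sum(mol)
  for (i in seq_len(n_atoms(mol))) {
    if (.is_basic_amine(mol, i, nb, bsum)) mol$atoms$charge[i] <- 1L
  }
  mol <- perceive(mol)
  assign_pharmacophore_types(mol)
}

#' Load a structural-alert list
#'
#' @param path YAML alert file (name, pattern, optional `unless` exceptions)
#' @return compiled alert list
#' @export
load_alerts <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(a) list(
    name = a$name,
    pattern = parse_pattern(a$pattern),
    unless = lapply(a$unless %||% list(), parse_pattern)))
}

# names of alerts triggered by a molecule
alert_hits <- function(mol, alerts) {
  hits <- character(0)
  for (a in alerts) {
    ms <- match_pattern(a$pattern, mol, reduce = TRUE)
    if (!length(ms)) next
    excused <- vapply(ms, function(m) {
      for (u in a$unless) {
        if (length(match_pattern(u, mol, reduce = TRUE, anchor = m[1]))) return(TRUE)
      }
      FALSE
    }, TRUE)
    if (any(!excused)) hits <- c(hits, a$name)
  }
  hits
}

#' Filter a standardized building block
#'
#' Rules: mass in \[30, 300\] Da; at most 4 SSSR rings; elements restricted to
#' C, N, O, S, P, F, Cl, Br, I, B, Si, Se; at most 3 fluorines; valid
#' valences; no structural alert; no duplicate of an earlier block. All rules
#' are evaluated; the reason code names the first failing rule.
#'
#' @param mol a standardized `rxn_mol`
#' @param alerts compiled alert list from [load_alerts()] (or `list()`)
#' @param seen environment used as the canonical-SMILES duplicate set (or
#'   `NULL` to skip the duplicate rule)
#' @return list(accept, reason, failures)
#' @export
filter_block <- function(mol, alerts = list(), seen = NULL) {
  failures <- character(0)
  m <- mol_mass(mol)
  if (m < 30 || m > 300) failures <- c(failures, "mass")
  if (length(mol$sssr) > 4L) failures <- c(failures, "rings")
  if (!all(mol$atoms$elem %in% .FILTER_ELEMENTS)) failures <- c(failures, "element")
  if (sum(mol$atoms$elem == "F") > 3L) failures <- c(failures, "fluorine")
  if (!valences_ok(mol)) failures <- c(failures, "valence")
  ah <- alert_hits(mol, alerts)
  if (length(ah)) failures <- c(failures, paste0("alert:", ah[1]))
  smi <- tryCatch(canonical_smiles(mol), error = function(e) NA_character_)
  if (is.na(smi)) failures <- c(failures, "valence")
  if (!is.null(seen) && !is.na(smi)) {
    if (!is.null(seen[[smi]])) failures <- c(failures, "duplicate")
    else if (!length(failures)) seen[[smi]] <- TRUE
  }
  list(accept = !length(failures),
       reason = if (length(failures)) failures[1] else NA_character_,
       failures = failures, smiles = smi)
}

#' Expand a block set with FGA/FGI preprocessing reactions
#'
#' Every applicable one-component template is applied once per block; the
#' original block is always kept and converted blocks are not preprocessed
#' again.
#'
#' @param blocks list of standardized typed `rxn_mol`s
#' @param fga_fgi one-component `rxn_template` list
#' @return list of new blocks only (each with `parent_id` and
#'   `preprocessing_id` fields set); the caller appends them
#' @export
apply_preprocessing_reactions <- function(blocks, fga_fgi) {
  stopifnot(all(vapply(fga_fgi, function(t) t$n_components == 1L, TRUE)))
  out <- list()
  for (blk in blocks) {
    for (tmpl in fga_fgi) {
      ms <- .component_matches(tmpl$components[[1]], blk)
      if (length(ms) != 1L) next
      prod <- tryCatch(apply_reaction(tmpl, list(blk)),
                       error = function(e) { warning(conditionMessage(e)); NULL })
      if (is.null(prod)) next
      prod$source_id <- paste0(blk$source_id, ":", tmpl$id)
      prod$parent_id <- blk$source_id
      prod$preprocessing_id <- tmpl$id
      out[[length(out) + 1L]] <- prod
    }
  }
  out
}

# annotations of one block: data.frame(reaction_id, component)
annotate_block <- function(mol, coupling) {
  hits <- find_applicable_reactions(mol, coupling)
  if (!length(hits)) {
    return(data.frame(reaction_id = character(0), component = integer(0)))
  }
  data.frame(
    reaction_id = vapply(hits, function(h) h$template$id, ""),
    component = vapply(hits, function(h) h$component, 1L))
}

#' Build an annotated building-block catalog
#'
#' Runs the full three-stage preparation protocol over an input catalog and
#' optionally persists the result (TSV store + JSON report). Blocks without
#' any reaction annotation are kept but flagged unusable.
#'
#' @param input path to an SDF or SMILES-table catalog
#' @param coupling coupling-reaction templates ([load_reaction_library()])
#' @param fga_fgi preprocessing templates (may be `list()`)
#' @param alerts compiled alert list (may be `list()`)
#' @param out optional TSV store path
#' @param report optional JSON report path
#' @return an `rxn_catalog`: list(blocks, table, report)
#' @export
build_catalog <- function(input, coupling, fga_fgi = list(), alerts = list(),
                          out = NULL, report = NULL) {
  raw <- load_molecules(input)
  n_skipped <- attr(raw, "n_skipped")

  seen <- new.env(hash = TRUE, parent = emptyenv())
  rejections <- list()
  accepted <- list()
  consider <- function(mol, parent_id = NA_character_, prep_id = NA_character_) {
    std <- tryCatch(standardize(mol), error = function(e) NULL)
    if (is.null(std)) {
      rejections[[length(rejections) + 1L]] <<- list(id = mol$source_id, reason = "sanitize")
      return(invisible(NULL))
    }
    res <- filter_block(std, alerts, seen)
    if (!res$accept) {
      rejections[[length(rejections) + 1L]] <<- list(id = mol$source_id, reason = res$reason,
                                                     failures = res$failures)
    } else {
      std$parent_id <- parent_id
      std$preprocessing_id <- prep_id
      std$canonical <- res$smiles
      accepted[[length(accepted) + 1L]] <<- std
    }
    invisible(NULL)
  }
  for (mol in raw) consider(mol)

  n_before_prep <- length(accepted)
  converted <- apply_preprocessing_reactions(accepted, fga_fgi)
  for (mol in converted) consider(mol, parent_id = mol$parent_id,
                                  prep_id = mol$preprocessing_id)
  n_fga_added <- length(accepted) - n_before_prep

  if (!length(accepted)) stop("no building blocks survived catalog preparation")

  ann_list <- lapply(accepted, annotate_block, coupling = coupling)
  tab <- data.frame(
    id = vapply(accepted, function(b) b$source_id, ""),
    smiles = vapply(accepted, function(b) b$canonical, ""),
    mass = round(vapply(accepted, mol_mass, 1), 3),
    parent_id = vapply(accepted, function(b) b$parent_id %||% NA_character_, ""),
    preprocessing_id = vapply(accepted, function(b) b$preprocessing_id %||% NA_character_, ""),
    n_annotations = vapply(ann_list, nrow, 1L),
    annotations = vapply(ann_list, function(a) {
      if (!nrow(a)) return("")
      paste(paste0(a$reaction_id, "/", a$component), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE)
  tab$usable <- tab$n_annotations > 0L

  reason_codes <- vapply(rejections, function(r) r$reason, "")
  rep_obj <- list(
    n_input = length(raw) + n_skipped,
    n_unparsable = n_skipped,
    n_rejected = length(rejections),
    n_accepted = length(accepted),
    n_fga_added = n_fga_added,
    rejections_by_rule = as.list(table(reason_codes)),
    rejected_ids = stats::setNames(as.list(reason_codes),
                                   vapply(rejections, function(r) r$id, "")),
    annotations_by_reaction = as.list(table(unlist(lapply(ann_list, function(a)
      if (nrow(a)) paste0(a$reaction_id, "/", a$component) else character(0))))),
    n_unusable = sum(!tab$usable))

  catalog <- structure(list(blocks = accepted, annotations = ann_list,
                            table = tab, report = rep_obj),
                       class = "rxn_catalog")
  if (!is.null(out)) write_catalog(catalog, out)
  if (!is.null(report)) {
    jsonlite::write_json(rep_obj, report, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  catalog
}

#' @export
print.rxn_catalog <- function(x, ...) {
  cat(sprintf("<building-block catalog: %d blocks (%d usable), %d rejected>\n",
              nrow(x$table), sum(x$table$usable), x$report$n_rejected))
  invisible(x)
}

#' Write a catalog store (deterministic TSV)
#' @param catalog an `rxn_catalog`
#' @param path output TSV path
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a catalog store written by [write_catalog()]
#'
#' Re-parses the stored canonical SMILES and re-derives annotations against
#' the supplied reaction library (annotation soundness is re-checkable).
#'
#' @param path TSV store
#' @param coupling reaction templates used to restore annotations
#' @return an `rxn_catalog`
#' @export
read_catalog <- function(path, coupling) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", colClasses = "character")
  tab$mass <- as.numeric(tab$mass)
  tab$n_annotations <- as.integer(tab$n_annotations)
  tab$usable <- as.logical(tab$usable)
  blocks <- lapply(seq_len(nrow(tab)), function(i) {
    m <- assign_pharmacophore_types(parse_smiles(tab$smiles[i], id = tab$id[i]))
    m$canonical <- tab$smiles[i]
    m
  })
  ann_list <- lapply(blocks, annotate_block, coupling = coupling)
  structure(list(blocks = blocks, annotations = ann_list, table = tab,
                 report = NULL), class = "rxn_catalog")
}

# blocks annotated for (reaction_id, component), in catalog order
catalog_partners <- function(catalog, reaction_id, component) {
  idx <- which(vapply(catalog$annotations, function(a) {
    any(a$reaction_id == reaction_id & a$component == component)
  }, TRUE))
  catalog$blocks[idx]
}
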