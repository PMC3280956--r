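# Deterministic synthetic building-block catalog
# ----------------------------------------------
# Scaffold x functional-group enumeration, one reactive group per block, so
# the exactly-once annotation rule is exercised from both sides; planted
# violations (one per filter rule) and a terephthalic-type diacid make the
# rejection paths testable. A manifest records the expected outcome and
# expected annotations of every record *by construction* — blockprep output
# is compared against it, not the other way round.

.FIX_SCAFFOLDS <- list(
  ph  = "c1ccccc1",
  tol = "c1ccc(C)cc1",
  pyr = "c1ccncc1",
  chx = "C1CCCCC1",
  prp = "CCC",
  meo = "CCOC")

# group -> list(tpl = sprintf template, scaffolds, annotations by construction)
.AMINE_ANN <- c("amide_coupling_1/2", "sulfonamide_1/2", "buchwald_amination/2",
                "n_alkylation/2", "reductive_amination_1/2", "reductive_amination_2/2",
                "urea_coupling/1", "urea_coupling/2", "carbamate_formation/2",
                "paal_knorr_pyrrole/2")

.FIX_GROUPS <- list(
  acid = list(tpl = "OC(=O)%s", scaffolds = c("ph", "tol", "pyr", "chx", "prp", "meo"),
              ann = c("amide_coupling_1/1", "amide_coupling_2/1", "ester_formation/1")),
  amine = list(tpl = "N%s", scaffolds = c("tol", "chx", "prp", "meo"), ann = .AMINE_ANN),
  secamine = list(tpl = "CN%s", scaffolds = c("ph", "chx", "prp"),
                  ann = c("amide_coupling_2/2", "sulfonamide_2/2")),
  alcohol = list(tpl = "OC%s", scaffolds = c("ph", "tol", "prp"),
                 ann = c("ester_formation/2", "williamson_ether/2")),
  boronic = list(tpl = "OB(O)%s", scaffolds = c("ph", "tol", "pyr"),
                 ann = "suzuki_coupling/2"),
  arylbr = list(tpl = "Br%s", scaffolds = c("ph", "tol", "pyr"),
                ann = c("suzuki_coupling/1", "buchwald_amination/1", "sonogashira_coupling/1")),
  bnzbr = list(tpl = "BrC%s", scaffolds = c("ph", "tol"),
               ann = c("n_alkylation/1", "williamson_ether/1")),
  so2cl = list(tpl = "ClS(=O)(=O)%s", scaffolds = c("ph", "tol", "prp"),
               ann = c("sulfonamide_1/1", "sulfonamide_2/1")),
  dione14 = list(tpl = "CC(=O)CCC(=O)%s", scaffolds = c("ph", "prp"),
                 ann = c("paal_knorr_pyrrole/1", "paal_knorr_furan/1", "paal_knorr_thiophene/1")),
  dione13 = list(tpl = "CC(=O)CC(=O)%s", scaffolds = c("ph", "prp"),
                 ann = c("pyrazole_synthesis_a/1", "pyrazole_synthesis_b/1",
                         "knoevenagel_condensation/2")),
  azide = list(tpl = "N(=[N+]=[N-])%s", scaffolds = c("ph", "prp"),
               ann = c("huisgen_triazole_14/1", "huisgen_triazole_15/1")),
  alkyne = list(tpl = "C#C%s", scaffolds = c("ph", "prp"),
                ann = c("sonogashira_coupling/2", "huisgen_triazole_14/2",
                        "huisgen_triazole_15/2")),
  aldehyde = list(tpl = "O=C%s", scaffolds = c("ph", "tol", "prp"),
                  ann = c("reductive_amination_1/1", "knoevenagel_condensation/1",
                          "benzimidazole_synthesis/2")),
  ketone = list(tpl = "CC(=O)%s", scaffolds = c("ph", "prp"),
                ann = "reductive_amination_2/1"),
  thioamide = list(tpl = "NC(=S)%s", scaffolds = c("ph", "prp"),
                   ann = "hantzsch_thiazole/2"),
  hydrazine = list(tpl = "NN%s", scaffolds = c("ph", "prp"),
                   ann = c("pyrazole_synthesis_a/2", "pyrazole_synthesis_b/2")),
  bromoketone = list(tpl = "BrCC(=O)%s", scaffolds = c("ph", "prp"),
                     ann = c("hantzsch_thiazole/1", "n_alkylation/1",
                             "williamson_ether/1", "reductive_amination_2/1")),
  chloroformate = list(tpl = "ClC(=O)OC%s", scaffolds = c("ph", "prp"),
                       ann = "carbamate_formation/1"),
  odiamine = list(tpl = "N%s", scaffolds = c("ph", "tol"),
                  smiles = c(ph = "Nc1ccccc1N", tol = "Cc1ccc(N)c(N)c1"),
                  ann = "benzimidazole_synthesis/1"),
  nitro = list(tpl = "O=[N+]([O-])%s", scaffolds = "ph", ann = character(0)),
  nitrile = list(tpl = "N#C%s", scaffolds = "ph", ann = character(0)),
  mester = list(tpl = "COC(=O)%s", scaffolds = "tol", ann = character(0)))

.FIX_VIOLATIONS <- list(
  list(id = "V01_masslow",   smiles = "C",                          expect = "reject", reason = "mass"),
  list(id = "V02_masshigh",  smiles = strrep("C", 24),              expect = "reject", reason = "mass"),
  list(id = "V03_rings",     smiles = "C1CC1C1CC1C1CC1C1CC1C1CC1",  expect = "reject", reason = "rings"),
  list(id = "V04_element",   smiles = "C[As](C)C",                  expect = "reject", reason = "element"),
  list(id = "V05_fluorine",  smiles = "FC(F)(F)C(F)(F)F",           expect = "reject", reason = "fluorine"),
  list(id = "V06_valence",   smiles = "CC(C)(C)(C)C",               expect = "reject", reason = "valence"),
  list(id = "V07_alert",     smiles = "CCOOCC",                     expect = "reject", reason = "alert:peroxide"),
  list(id = "V08_duplicate", smiles = "OC(=O)c1ccccc1",             expect = "reject", reason = "duplicate"),
  list(id = "V09_broken",    smiles = "C1CC",                       expect = "unparsable", reason = "unparsable"))

# derived (FGA/FGI) expectations by construction; {id} = parent id
.FIX_DERIVED <- list(
  list(parent_group = "nitro", via = "fgi_nitro_to_amine", expect = "accept",
       ann = .AMINE_ANN),
  list(parent_group = "nitrile", via = "fgi_nitrile_to_amine", expect = "accept",
       ann = .AMINE_ANN),
  list(parent_group = "mester", via = "fgi_methyl_ester_to_acid", expect = "reject",
       reason = "duplicate"),   # saponified ester == acid/tol block
  list(parent_group = "arylbr", via = "fga_aryl_halide_to_boronic_acid",
       expect = "reject", reason = "duplicate"),  # borylation products == boronic blocks
  list(parent_group = "alcohol", scaffolds = c("ph", "tol"),
       via = "fgi_primary_alcohol_to_bromide", expect = "reject", reason = "duplicate"),
  list(parent_group = "alcohol", scaffolds = "prp",
       via = "fgi_primary_alcohol_to_bromide", expect = "reject",
       reason = "alert:alkyl_halide_nonactivated"))

#' Specification for the synthetic catalog generator
#'
#' @param seed integer; controls the record order of the written catalog
#' @param n_blocks number of valid scaffold-x-group blocks (default: all)
#' @param plant_violations include the planted filter violations
#' @return a `fixture_spec` list
#' @export
fixture_spec <- function(seed = 1L, n_blocks = NULL, plant_violations = TRUE) {
  structure(list(seed = as.integer(seed), n_blocks = n_blocks,
                 plant_violations = isTRUE(plant_violations)),
            class = "fixture_spec")
}

#' Generate the synthetic building-block catalog and its manifest
#'
#' Deterministic for a given seed. The SMILES table and a JSON manifest of
#' expected accept/reject outcomes and expected reaction annotations (derived
#' from the construction, not from running the preparation pipeline) are
#' written side by side.
#'
#' @param spec a [fixture_spec()]
#' @param catalog_path output SMILES table path
#' @param manifest_path output JSON manifest path
#' @return the manifest, invisibly
#' @export
generate_catalog <- function(spec = fixture_spec(),
                             catalog_path = "catalog.smi",
                             manifest_path = "manifest.json") {
  records <- list()
  for (gname in names(.FIX_GROUPS)) {
    g <- .FIX_GROUPS[[gname]]
    for (sc in g$scaffolds) {
      smi <- if (!is.null(g$smiles)) g$smiles[[sc]]
             else sprintf(g$tpl, .FIX_SCAFFOLDS[[sc]])
      records[[length(records) + 1L]] <- list(
        id = sprintf("BB_%s_%s", gname, sc), smiles = smi, group = gname,
        scaffold = sc, expect = "accept", reason = NA_character_,
        annotations = as.list(g$ann))
    }
  }
  # diacid: passes all filters but the exactly-once rule blanks its annotations
  records[[length(records) + 1L]] <- list(
    id = "BB_diacid_ph", smiles = "OC(=O)c1ccc(C(=O)O)cc1", group = "diacid",
    scaffold = "ph", expect = "accept", reason = NA_character_,
    annotations = list())

  if (!is.null(spec$n_blocks)) {
    if (spec$n_blocks < length(records)) {
      stop("n_blocks below the full enumeration would break reaction coverage; ",
           "the generator ships ", length(records), " valid blocks")
    }
  }
  violations <- list()
  if (spec$plant_violations) {
    violations <- lapply(.FIX_VIOLATIONS, function(v) {
      c(v[c("id", "smiles", "expect", "reason")],
        list(group = "violation", scaffold = NA, annotations = list()))
    })
  }

  # coverage: every two-component coupling component must have >= 2 blocks
  cov <- table(unlist(lapply(records, function(r) unlist(r$annotations))))
  # (asserted again in tests; fatal here if construction is inconsistent)
  if (length(cov) && any(cov < 2)) {
    stop("fixture coverage broken for: ",
         paste(names(cov)[cov < 2], collapse = ", "))
  }

  derived <- list()
  for (d in .FIX_DERIVED) {
    g <- .FIX_GROUPS[[d$parent_group]]
    scs <- d$scaffolds %||% g$scaffolds
    for (sc in scs) {
      derived[[length(derived) + 1L]] <- list(
        id = sprintf("BB_%s_%s:%s", d$parent_group, sc, d$via),
        parent = sprintf("BB_%s_%s", d$parent_group, sc),
        via = d$via, expect = d$expect, reason = d$reason %||% NA_character_,
        annotations = as.list(d$ann %||% character(0)))
    }
  }

  # shuffle the valid blocks only; planted violations stay at the end so the
  # duplicate rule deterministically rejects the *second* occurrence
  set.seed(spec$seed)
  ord <- sample.int(length(records))
  records <- c(records[ord], violations)

  lines <- c("# synthetic building-block catalog (generated fixture)",
             sprintf("# seed %d, %d records", spec$seed, length(records)),
             vapply(records, function(r) paste(r$smiles, r$id, sep = "\t"), ""))
  writeLines(lines, catalog_path)

  manifest <- list(seed = spec$seed, n_records = length(records),
                   records = records, derived = derived)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(manifest)
}
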