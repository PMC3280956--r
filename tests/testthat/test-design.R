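test_that("start fragments are ranked exactly by brute-force scoring", {
  tiny <- tiny_design_world()
  cfg <- design_config(n_starts = 3, representation = "molgraph")
  ranked <- select_start_fragments(tiny$catalog, tiny$reference, cfg,
                                   n = sum(tiny$catalog$table$usable))
  kp <- cfg$kernel
  ref <- tiny$reference
  brute <- lapply(tiny$catalog$blocks[tiny$catalog$table$usable], function(b)
    list(id = b$source_id, smi = canonical_smiles(b),
         score = molecule_similarity(ref, b, kp)))
  ord <- order(-vapply(brute, function(x) x$score, 1),
               vapply(brute, function(x) x$smi, ""),
               vapply(brute, function(x) x$id, ""))
  expect_identical(vapply(ranked, function(b) b$source_id, ""),
                   vapply(brute[ord], function(x) x$id, ""))
  # a catalog containing the reference itself ranks it first with score 1
  d <- tempdir(); f <- file.path(d, "withref.smi")
  writeLines(c("OC(=O)c1ccccc1\trefblock", "CCCN\tamine", "OCc1ccccc1\talcohol"), f)
  cat2 <- suppressWarnings(build_catalog(f, tiny$library))
  acid_ref <- standardize(parse_smiles("OC(=O)c1ccccc1", "acidref"))
  r2 <- select_start_fragments(cat2, acid_ref, cfg, n = 1)
  expect_equal(r2[[1]]$source_id, "refblock")
  expect_equal(attr(r2, "scores")[1], 1)
  expect_warning(select_start_fragments(cat2, acid_ref, cfg, n = 99), "only")
})

test_that("the stop criterion follows the mass-window and improvement rules", {
  cfg <- design_config()
  ref_mass <- 300
  st <- function(mass, score, steps = 1L) list(mass = mass, score = score, steps = steps)
  # below the lower bound: accept even when the score drops
  expect_equal(check_stop(st(180, 0.5), st(230, 0.4), ref_mass, cfg), "accept")
  # at/above the lower bound: only strict improvement passes
  expect_equal(check_stop(st(240, 0.5), st(280, 0.4), ref_mass, cfg), "finalize_prev")
  expect_equal(check_stop(st(240, 0.5), st(280, 0.5), ref_mass, cfg), "finalize_prev")
  expect_equal(check_stop(st(240, 0.5), st(280, 0.6), ref_mass, cfg), "accept")
  # the upper mass bound is never crossed
  expect_equal(check_stop(st(180, 0.3), st(405, 0.9), ref_mass, cfg), "finalize_prev")
})

test_that("an extension cycle enumerates only the winning reaction's partners", {
  tiny <- tiny_design_world()
  cfg <- design_config(representation = "molgraph")
  scorer <- rxndesign:::make_scorer(tiny$reference, cfg)
  acid <- tiny$catalog$blocks[[which(tiny$catalog$table$id == "acid_ph")]]
  st <- rxndesign:::.new_state(acid, scorer(acid), 0L, list())
  out <- extension_cycle(st, tiny$catalog, tiny$library, tiny$reference, cfg, scorer)
  expect_gt(length(out), 0)
  expect_lte(length(out), cfg$beam_width)
  # all returned states are tied at the top score
  scores <- vapply(out, function(x) x$score, 1)
  expect_true(all(abs(scores - max(scores)) < 1e-9))
  # each carries a one-step route with provenance
  for (x in out) {
    expect_equal(x$steps, 1L)
    expect_length(x$route, 1)
    expect_true(x$route[[1]]$reaction_id %in% names(tiny$library))
  }
  # a molecule with no applicable reaction dies
  dead <- rxndesign:::.new_state(typed_mol("c1ccccc1"), 0.1, 0L, list())
  expect_length(extension_cycle(dead, tiny$catalog, tiny$library,
                                tiny$reference, cfg, scorer), 0)
})

test_that("the full run matches an independent exhaustive-tree oracle", {
  tiny <- tiny_design_world()
  cfg <- design_config(n_starts = 3, beam_width = 10, max_steps = 4,
                       representation = "molgraph")
  designs <- run_design(tiny$catalog, tiny$reference, tiny$library, cfg)
  oracle <- oracle_design(tiny$catalog, tiny$reference, tiny$library, cfg)
  expect_identical(designs$summary$smiles, oracle$smiles)
  expect_equal(designs$summary$score, oracle$score, tolerance = 1e-9)
  expect_equal(designs$summary$mass, oracle$mass, tolerance = 1e-9)
})

test_that("run invariants hold: replay, mass window, monotonicity, beam", {
  fx <- fixture_catalog()
  ref <- design_reference()
  lib <- coupling_lib()
  cfg <- design_config(n_starts = 4, representation = "molgraph")
  designs <- suppressWarnings(run_design(fx$catalog, ref, lib, cfg))
  expect_gte(designs$n_productive_starts, 1)
  low <- cfg$mass_low_frac * designs$reference_mass
  high <- cfg$mass_high_frac * designs$reference_mass
  for (u in designs$products) {
    for (r in u$routes) {
      # route replay reproduces the final product exactly
      expect_identical(replay_route(r, fx$catalog, lib), r$final_smiles)
      expect_equal(r$n_steps, length(r$steps))
      expect_lte(r$n_steps, cfg$max_steps)
      # score-finalized products sit inside the mass window
      if (r$finalized_by == "score") {
        expect_gte(r$final_mass, low); expect_lte(r$final_mass, high)
        expect_false(r$below_mass_window)
      }
      expect_lte(r$final_mass, high)
    }
  }
})

test_that("two identical runs produce byte-identical output", {
  fx <- fixture_catalog()
  ref <- design_reference()
  cfg <- design_config(n_starts = 3, representation = "reduced")
  d1 <- suppressWarnings(run_design(fx$catalog, ref, coupling_lib(), cfg))
  d2 <- suppressWarnings(run_design(fx$catalog, ref, coupling_lib(), cfg))
  o1 <- file.path(tempdir(), "dz1"); o2 <- file.path(tempdir(), "dz2")
  write_designs(d1, o1); write_designs(d2, o2)
  for (f in c("designs.tsv", "designs.sdf", "routes.json")) {
    expect_identical(readLines(file.path(o1, f)), readLines(file.path(o2, f)),
                     info = f)
  }
})

test_that("a hopeless mass window yields a clear failure", {
  tiny <- tiny_design_world()
  small_ref <- typed_mol("C=O", "tinyref")    # 30 Da: every product overshoots
  cfg <- design_config(n_starts = 2)
  expect_error(suppressWarnings(
    run_design(tiny$catalog, small_ref, tiny$library, cfg)),
    "no routes")
})
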