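test_that("standardization sets charges the way the protocol prescribes", {
  expect_equal(canonical_smiles(standardize(parse_smiles("CC(=O)O"))),
               canonical_smiles(parse_smiles("CC(=O)[O-]")))
  expect_equal(canonical_smiles(standardize(parse_smiles("CCCN"))),
               canonical_smiles(parse_smiles("CCC[NH3+]")))
  # amides are not basic amines
  benzamide <- standardize(parse_smiles("NC(=O)c1ccccc1"))
  expect_true(all(benzamide$atoms$charge == 0L))
  # anilines stay neutral too
  aniline <- standardize(parse_smiles("Nc1ccccc1"))
  expect_true(all(aniline$atoms$charge == 0L))
  # largest organic fragment is kept
  salt <- standardize(parse_smiles("CC(=O)O.CCCCCCCC"))
  expect_equal(rxndesign:::n_atoms(salt), 8L)
})

test_that("filter rules fire individually with the right reason codes", {
  alerts <- alert_list()
  seen <- new.env()
  fb <- function(smi) filter_block(standardize(parse_smiles(smi)), alerts, seen)
  expect_true(fb("C=O")$accept)                      # formaldehyde, 30.03 Da
  expect_equal(fb("C")$reason, "mass")               # methane, 16 Da
  expect_equal(fb(strrep("C", 24))$reason, "mass")   # 338 Da
  expect_equal(fb("C1CC1C1CC1C1CC1C1CC1C1CC1")$reason, "rings")
  expect_equal(fb("C[As](C)C")$reason, "element")
  expect_equal(fb("FC(F)(F)C(F)(F)F")$reason, "fluorine")
  expect_equal(fb("CC(C)(C)(C)C")$reason, "valence")
  expect_equal(fb("CCOOCC")$reason, "alert:peroxide")
  expect_true(fb("OC(=O)c1ccccc1")$accept)
  expect_equal(fb("OC(=O)c1ccccc1")$reason, "duplicate")   # second occurrence
  # activated halides are excused, plain alkyl halides are not
  expect_true(fb("BrCc1ccccc1")$accept)
  expect_equal(fb("CCCCBr")$reason, "alert:alkyl_halide_nonactivated")
})

test_that("preparation output agrees with the generator manifest on all records", {
  fx <- fixture_catalog()
  tab <- fx$catalog$table
  rejected <- fx$catalog$report$rejected_ids
  check <- function(rec) {
    if (rec$expect == "unparsable") {
      expect_false(rec$id %in% tab$id, info = rec$id)
      return(invisible(NULL))
    }
    if (rec$expect == "accept") {
      expect_true(rec$id %in% tab$id, info = rec$id)
      got <- sort(strsplit(tab$annotations[tab$id == rec$id], ";")[[1]])
      expect_identical(got, sort(as.character(unlist(rec$annotations))), info = rec$id)
    } else {
      expect_false(rec$id %in% tab$id, info = rec$id)
      expect_identical(unname(unlist(rejected[rec$id])), rec$reason, info = rec$id)
    }
    invisible(NULL)
  }
  for (rec in fx$manifest$records) check(rec)
  for (rec in fx$manifest$derived) check(rec)
})

test_that("the exactly-once rule blanks annotations of the planted diacid", {
  fx <- fixture_catalog()
  tab <- fx$catalog$table
  row <- tab[tab$id == "BB_diacid_ph", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$n_annotations, 0L)
  expect_false(row$usable)
})

test_that("stored blocks re-check against every filter and annotation", {
  fx <- fixture_catalog()
  alerts <- alert_list()
  lib <- coupling_lib()
  for (i in seq_len(nrow(fx$catalog$table))) {
    blk <- fx$catalog$blocks[[i]]
    res <- filter_block(blk, alerts, seen = NULL)
    expect_true(res$accept, info = blk$source_id)
    ann <- fx$catalog$annotations[[i]]
    for (k in seq_len(nrow(ann))) {
      tmpl <- lib[[ann$reaction_id[k]]]
      ms <- rxndesign:::.component_matches(tmpl$components[[ann$component[k]]], blk)
      expect_length(ms, 1)
    }
  }
})

test_that("FGA/FGI preprocessing only ever adds blocks", {
  fx <- fixture_catalog()
  bare <- suppressWarnings(build_catalog(fx$catalog_path, coupling_lib(),
                                         fga_fgi = list(), alerts = alert_list()))
  with_fga <- fx$catalog
  expect_true(all(bare$table$id %in% with_fga$table$id))
  expect_gt(nrow(with_fga$table), nrow(bare$table))
  # originals are kept alongside conversions
  expect_true("BB_nitro_ph" %in% with_fga$table$id)
  expect_true("BB_nitro_ph:fgi_nitro_to_amine" %in% with_fga$table$id)
})

test_that("the catalog store round-trips deterministically", {
  fx <- fixture_catalog()
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_catalog(fx$catalog, p1)
  rebuilt <- suppressWarnings(build_catalog(fx$catalog_path, coupling_lib(),
                                            fga_lib(), alert_list()))
  write_catalog(rebuilt, p2)
  expect_identical(readLines(p1), readLines(p2))
  restored <- read_catalog(p1, coupling_lib())
  expect_identical(restored$table$id, fx$catalog$table$id)
  expect_identical(
    vapply(restored$annotations, function(a) paste(a$reaction_id, a$component,
                                                   collapse = ";"), ""),
    vapply(fx$catalog$annotations, function(a) paste(a$reaction_id, a$component,
                                                     collapse = ";"), ""))
})
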