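test_that("molecule loading parses SMILES tables and skips broken records", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("# comment line",
               "c1ccccc1\tbenzene",
               "CC(=O)O\tacetic",
               "C1CC\tbroken",
               "CCO ethanol"), f)
  expect_warning(mols <- load_molecules(f), "unparsable")
  expect_length(mols, 3)
  expect_equal(attr(mols, "n_skipped"), 1L)
  expect_equal(vapply(mols, rxndesign:::n_atoms, 1L), c(6L, 4L, 3L))

  # SDF round trip preserves heavy-atom count and canonical form
  sdf <- tempfile(fileext = ".sdf")
  writeLines(vapply(mols, rxndesign:::mol_to_sdf, ""), sdf)
  mols2 <- load_molecules(sdf)
  expect_equal(vapply(mols2, canonical_smiles, ""),
               vapply(mols, canonical_smiles, ""))

  expect_error(load_molecules(tempfile()), "cannot read")
  empty <- tempfile(); writeLines("# nothing", empty)
  expect_error(load_molecules(empty), "no valid records")
})

test_that("pharmacophore typing follows the documented cascade", {
  cases <- list(
    list(smi = "c1ccccc1",        atom = "C", type = "R"),   # aromatic carbon
    list(smi = "CC[NH3+]",        atom = "N", type = "P"),   # protonated amine
    list(smi = "CCCN",            atom = "N", type = "P"),   # protonatable amine
    list(smi = "CC(=O)[O-]",      atom = "O", type = NULL),  # handled below
    list(smi = "c1ccncc1",        atom = "N", type = "A"),   # pyridine N
    list(smi = "c1cc[nH]c1",      atom = "N", type = "D"),   # pyrrole NH
    list(smi = "CCO",             atom = "O", type = "E"),   # alcohol: donor+acceptor
    list(smi = "NC(=O)c1ccccc1",  atom = "N", type = "D"),   # amide NH2: donor only
    list(smi = "CCC",             atom = "C", type = "L"),   # plain alkane
    list(smi = "c1ccsc1",         atom = "S", type = "R"))   # thiophene S: aromatic
  for (cs in cases) {
    m <- typed_mol(cs$smi)
    if (is.null(cs$type)) next
    got <- m$atoms$ptype[m$atoms$elem == cs$atom]
    expect_true(cs$type %in% got, info = cs$smi)
  }
  # carboxylate oxygens: O- is negative, C=O is acceptor
  ac <- typed_mol("CC(=O)[O-]")
  expect_setequal(ac$atoms$ptype[ac$atoms$elem == "O"], c("A", "N"))
})

test_that("typing is idempotent, exclusive, and a pure function", {
  smis <- c("CC(=O)Nc1ccc(O)cc1", "O=[N+]([O-])c1ccccc1", "NCCO",
            "CC(=O)CCC(=O)C", "Brc1ccncc1", "NNc1ccccc1")
  for (smi in smis) {
    m1 <- typed_mol(smi)
    m2 <- assign_pharmacophore_types(m1)
    expect_identical(m1$atoms$ptype, m2$atoms$ptype, info = smi)
    expect_true(all(m1$atoms$ptype %in% c("A", "D", "E", "P", "N", "R", "L", "0")),
                info = smi)
    # exclusivity: donor+acceptor atoms carry E, never a bare A or D
    for (i in seq_len(rxndesign:::n_atoms(m1))) {
      nb <- rxndesign:::mol_adjacency(m1)
      bs <- rxndesign:::.bond_order_sum(m1)
      if (rxndesign:::.is_donor(m1, i) && rxndesign:::.is_acceptor(m1, i, nb, bs) &&
          m1$atoms$charge[i] == 0L &&
          !rxndesign:::.is_basic_amine(m1, i, nb, bs)) {
        expect_identical(m1$atoms$ptype[i], "E", info = paste(smi, i))
      }
    }
  }
})

test_that("substructure matching honors counts, symmetry reduction and anchors", {
  acid_pat <- "[CX3](=[OX1])[OX2H1,OX1-]"
  expect_equal(count_matches(acid_pat, typed_mol("CC(=O)O")), 1L)
  expect_equal(count_matches(acid_pat, typed_mol("OC(=O)c1ccc(C(=O)O)cc1")), 2L)
  expect_equal(count_matches(acid_pat, typed_mol("CC(=O)[O-]")), 1L)
  expect_equal(count_matches("c1ccccc1", typed_mol("c1ccccc1")), 1L)  # symmetry-reduced
  expect_equal(count_matches("[NX3H2]", typed_mol("C")), 0L)
  # anchored matching restricts the first pattern atom
  m <- typed_mol("NC(=O)c1ccccc1")
  nidx <- which(m$atoms$elem == "N")
  expect_length(match_pattern("[NX3][CX3]=[OX1]", m, anchor = nidx), 1)
  expect_length(match_pattern("[NX3][CX3]=[OX1]", m, anchor = nidx + 1L), 0)
})
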