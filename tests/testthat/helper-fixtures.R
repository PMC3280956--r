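# Shared fixtures: shipped libraries, a generated synthetic catalog (built
# once per test run), small molecules, and independent oracles.

.cache <- new.env(parent = emptyenv())

shipped_path <- function(f) system.file("extdata", f, package = "rxndesign")

coupling_lib <- function() {
  if (is.null(.cache$coupling)) {
    .cache$coupling <- load_reaction_library(shipped_path("coupling_reactions.yaml"),
                                             self_test = FALSE)
  }
  .cache$coupling
}

fga_lib <- function() {
  if (is.null(.cache$fga)) {
    .cache$fga <- load_reaction_library(shipped_path("preprocessing_reactions.yaml"),
                                        self_test = FALSE)
  }
  .cache$fga
}

alert_list <- function() {
  if (is.null(.cache$alerts)) .cache$alerts <- load_alerts(shipped_path("alerts.yaml"))
  .cache$alerts
}

# generated synthetic catalog + manifest + prepared store (seed 7)
fixture_catalog <- function() {
  if (is.null(.cache$fixture)) {
    dir <- file.path(tempdir(), "rxndesign-fixture")
    dir.create(dir, showWarnings = FALSE)
    cat_path <- file.path(dir, "catalog.smi")
    man_path <- file.path(dir, "manifest.json")
    manifest <- generate_catalog(fixture_spec(seed = 7), cat_path, man_path)
    catalog <- suppressWarnings(
      build_catalog(cat_path, coupling_lib(), fga_lib(), alert_list()))
    .cache$fixture <- list(dir = dir, catalog_path = cat_path,
                           manifest = manifest, catalog = catalog)
  }
  .cache$fixture
}

typed_mol <- function(smiles, id = NA_character_) {
  assign_pharmacophore_types(parse_smiles(smiles, id = id))
}

# reference ligand used for design-run tests (an N-aryl benzamide)
design_reference <- function() typed_mol("O=C(Nc1ccc(C)cc1)c1ccccc1", "ref")

# ---------------------------------------------------------------------------
# Independent oracles
# ---------------------------------------------------------------------------

# exhaustive maximum-weight one-to-one assignment over a weight matrix
brute_force_assignment <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  best <- 0
  if (nr <= nc) {
    idx <- seq_len(nc)
    rec <- function(i, used, acc) {
      if (i > nr) { best <<- max(best, acc); return(invisible(NULL)) }
      for (j in idx[!used]) {
        used[j] <- TRUE
        rec(i + 1L, used, acc + w[i, j])
        used[j] <- FALSE
      }
    }
    rec(1L, rep(FALSE, nc), 0)
  } else {
    return(brute_force_assignment(t(w)))
  }
  best
}

# random small typed graph for kernel tests: connected, degree <= 6
random_typed_graph <- function(n) {
  types <- sample(c("A", "D", "E", "P", "N", "R", "L", "0"), n, replace = TRUE)
  atoms <- data.frame(elem = "C", charge = 0L)
  atoms <- atoms[rep(1, n), , drop = FALSE]
  bonds <- NULL
  if (n > 1) {
    a1 <- integer(0); a2 <- integer(0)
    for (v in 2:n) { u <- sample(v - 1L, 1L); a1 <- c(a1, u); a2 <- c(a2, v) }
    extra <- sample(0:1, 1)
    if (extra && n >= 4) {
      u <- sample(n, 1L); v <- sample(setdiff(seq_len(n), u), 1L)
      if (!any((a1 == min(u, v)) & (a2 == max(u, v)))) {
        a1 <- c(a1, min(u, v)); a2 <- c(a2, max(u, v))
      }
    }
    bonds <- data.frame(a1 = a1, a2 = a2,
                        order = sample(1:2, length(a1), replace = TRUE))
  }
  g <- rxndesign:::.new_mol(atoms, bonds)
  g$atoms$ptype <- types
  g
}

# Independent re-implementation of the greedy/beam/stop search for tiny
# catalogs: plain recursive enumeration honoring (i) dummy-product reaction
# selection with ties, (ii) full partner enumeration with top-tie beam,
# (iii) the mass-window / score-improvement / step-cap stop rules.
oracle_design <- function(catalog, reference, library, config) {
  scorer <- rxndesign:::make_scorer(reference, config)
  ref_mass <- mol_mass(reference)
  finals <- list()

  grow <- function(states) {
    nxt <- list()
    for (st in states) {
      if (st$steps >= config$max_steps) {
        if (st$steps > 0) finals[[length(finals) + 1L]] <<- st
        next
      }
      hits <- find_applicable_reactions(st$mol, library)
      dummy_scored <- list()
      for (h in hits) {
        tmpl <- h$template
        dp <- tryCatch({
          if (tmpl$n_components == 1L) apply_reaction(tmpl, list(st$mol))
          else {
            dummy <- minimal_dummy_fragment(tmpl, 3L - h$component)
            rs <- if (h$component == 1L) list(st$mol, dummy) else list(dummy, st$mol)
            apply_reaction(tmpl, rs)
          }
        }, error = function(e) NULL)
        if (is.null(dp)) next
        s <- scorer(dp)
        if (!is.na(s)) dummy_scored[[length(dummy_scored) + 1L]] <- list(h = h, s = s, dp = dp)
      }
      if (!length(dummy_scored)) {
        if (st$steps > 0) finals[[length(finals) + 1L]] <<- st
        next
      }
      smax <- max(vapply(dummy_scored, function(x) x$s, 1))
      chosen <- Filter(function(x) x$s >= smax - 1e-9, dummy_scored)
      cands <- list()
      for (ch in chosen) {
        tmpl <- ch$h$template
        if (tmpl$n_components == 1L) {
          cands[[length(cands) + 1L]] <- list(mol = ch$dp, score = ch$s,
                                              smiles = canonical_smiles(ch$dp),
                                              partner = "")
        } else {
          other <- 3L - ch$h$component
          for (p in rxndesign:::catalog_partners(catalog, tmpl$id, other)) {
            pr <- tryCatch({
              rs <- if (ch$h$component == 1L) list(st$mol, p) else list(p, st$mol)
              apply_reaction(tmpl, rs)
            }, error = function(e) NULL)
            if (is.null(pr)) next
            s <- scorer(pr)
            if (!is.na(s)) cands[[length(cands) + 1L]] <-
                list(mol = pr, score = s, smiles = canonical_smiles(pr),
                     partner = p$source_id)
          }
        }
      }
      if (!length(cands)) {
        if (st$steps > 0) finals[[length(finals) + 1L]] <<- st
        next
      }
      cmax <- max(vapply(cands, function(x) x$score, 1))
      top <- Filter(function(x) x$score >= cmax - 1e-9, cands)
      top <- top[order(vapply(top, function(x) x$smiles, ""),
                       vapply(top, function(x) x$partner, ""))]
      top <- top[seq_len(min(length(top), config$beam_width))]
      accepted <- list()
      for (cand in cands_accept(st, top, ref_mass, config)) {
        accepted[[length(accepted) + 1L]] <- cand
      }
      if (!length(accepted)) {
        if (st$steps > 0) finals[[length(finals) + 1L]] <<- st
        next
      }
      nxt <- c(nxt, accepted)
    }
    if (length(nxt) > config$beam_width) {
      ord <- order(-vapply(nxt, function(x) x$score, 1),
                   vapply(nxt, function(x) x$smiles, ""))
      nxt <- nxt[ord][seq_len(config$beam_width)]
    }
    if (length(nxt)) grow(nxt)
  }

  cands_accept <- function(st, top, ref_mass, config) {
    out <- list()
    for (cand in top) {
      m <- mol_mass(cand$mol)
      ok <- m <= config$mass_high_frac * ref_mass &&
        (st$mass < config$mass_low_frac * ref_mass || cand$score > st$score)
      if (ok) out[[length(out) + 1L]] <-
          list(mol = cand$mol, score = cand$score, smiles = cand$smiles,
               mass = m, steps = st$steps + 1L)
    }
    out
  }

  ranked <- select_start_fragments(catalog, reference, config,
                                   n = sum(catalog$table$usable))
  scores <- attr(ranked, "scores")
  productive <- 0L
  for (i in seq_along(ranked)) {
    if (productive >= config$n_starts) break
    n0 <- length(finals)
    grow(list(list(mol = ranked[[i]], score = scores[i],
                   smiles = canonical_smiles(ranked[[i]]),
                   mass = mol_mass(ranked[[i]]), steps = 0L)))
    if (length(finals) > n0) productive <- productive + 1L
  }
  df <- data.frame(
    smiles = vapply(finals, function(f) f$smiles, ""),
    score = vapply(finals, function(f) f$score, 1),
    mass = vapply(finals, function(f) f$mass, 1))
  df <- unique(df)
  df[order(-df$score, df$smiles), , drop = FALSE]
}

# tiny 5-block / 2-reaction world for design-oracle comparisons
tiny_design_world <- function() {
  if (is.null(.cache$tiny)) {
    dir <- file.path(tempdir(), "rxndesign-tiny")
    dir.create(dir, showWarnings = FALSE)
    cat_path <- file.path(dir, "blocks.smi")
    writeLines(c("OC(=O)c1ccccc1\tacid_ph",
                 "CC(=O)O\tacid_me",
                 "NCCO\taminol",
                 "CCCN\tamine_pr",
                 "OCc1ccccc1\talcohol_bn"), cat_path)
    lib <- coupling_lib()[c("amide_coupling_1", "ester_formation")]
    catalog <- suppressWarnings(build_catalog(cat_path, lib))
    ref <- typed_mol("O=C(NCCOC(=O)c1ccccc1)c1ccccc1", "tinyref")
    .cache$tiny <- list(catalog = catalog, library = lib, reference = ref)
  }
  .cache$tiny
}
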