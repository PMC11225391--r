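# Unit tests for the SMILES string algebra: tokenization, attachment-point
# parsing, marker strip/reinsert bookkeeping, rooting, reversal and branch
# insertion.

test_that("tokenizer treats multi-character constructs as single tokens", {
  toks <- smiles_tokens("CCl")
  expect_equal(as.character(toks), c("C", "Cl"))
  toks <- smiles_tokens("c1cc[nH]c1")
  expect_true("[nH]" %in% toks)
  toks <- smiles_tokens("C%12CC%12")
  expect_equal(sum(attr(toks, "type") == "ring"), 2L)
  expect_error(smiles_tokens("C?C"), class = "smiles_parse_error")
})

test_that("attachment points parse with correct sites, cores and errors", {
  sp <- parse_attachment_points("c1c(*)cc(*)cc1")
  expect_equal(sp$n_sites, 2L)
  expect_equal(sp$sites, c(1L, 3L))
  expect_equal(canonicalize_smiles(sp$core_smiles), canonicalize_smiles("c1ccccc1"))

  sp <- parse_attachment_points("C1C(*)C1")
  expect_equal(sp$n_sites, 1L)
  expect_equal(canonicalize_smiles(sp$core_smiles), canonicalize_smiles("C1CC1"))

  sp <- parse_attachment_points("CCO")
  expect_equal(sp$n_sites, 0L)
  expect_equal(sp$core_smiles, "CCO")

  # bare terminal marker and leading marker both accepted
  expect_equal(parse_attachment_points("*CC")$sites, 0L)
  expect_equal(parse_attachment_points("n1(*)ccncc1")$sites, 0L)

  expect_error(parse_attachment_points("C1CC"), class = "smiles_parse_error")
  expect_error(parse_attachment_points("C(*)(F)(F)(F)F"),
               class = "smiles_valence_error")
})

test_that("strip/reinsert is an exact string inverse, stable under suffix edits", {
  s <- "c1c(*)cc(*)cc1"
  sl <- strip_markers(s)
  expect_equal(sl$core, "c1ccccc1")
  expect_equal(nrow(sl$ledger), 2L)
  expect_identical(reinsert_markers(sl$core, sl$ledger), s)

  # append a generated suffix: markers reappear at the original spans
  expect_identical(reinsert_markers(paste0(sl$core, "CC"), sl$ledger),
                   paste0("c1c(*)cc(*)cc1", "CC"))

  sl2 <- strip_markers("CCO")
  expect_equal(sl2$core, "CCO")
  expect_equal(nrow(sl2$ledger), 0L)
  expect_identical(reinsert_markers("CCO", sl2$ledger), "CCO")

  # corrupted ledger: position beyond the string
  expect_error(reinsert_markers("CC", sl$ledger), class = "ledger_corruption_error")
})

test_that("rooting places the chosen atom first and preserves the graph", {
  expect_equal(as.character(root_at_atom("CCO", 2L)), "OCC")
  expect_equal(as.character(root_at_atom("CCO", 0L)), "CCO")
  expect_error(root_at_atom("CCO", 5L), class = "smiles_index_error")
  r <- root_at_atom("c1cc(F)ccc1O", 3L)
  expect_equal(canonicalize_smiles(as.character(r)),
               canonicalize_smiles("c1cc(F)ccc1O"))
  expect_equal(attr(r, "atom_order")[1], 4L)
})

test_that("reversal makes the first atom last, including branch-at-root cases", {
  expect_equal(reverse_smiles("NCC"), "CCN")
  expect_equal(reverse_smiles("C"), "C")
  expect_equal(reverse_smiles("Oc1ccccc1"), "c1ccccc1O")
  for (s in c("C(C)C", "C(F)(Cl)Br", "C1(CC1)O", "c1ccccc1", "C(=O)CC")) {
    r <- reverse_smiles(s)
    expect_equal(canonicalize_smiles(r), canonicalize_smiles(s), info = s)
    # positional identity via the isotope-label oracle
    l_in <- label_atom(s, 0L)
    l_out <- label_atom(r, last_atom_ordinal(r))
    if (!is.na(l_in) && !is.na(l_out)) {
      expect_true(same_labeled_molecule(l_in, l_out), info = s)
    }
  }
})

test_that("reversed variants end at the site atom and deduplicate as strings", {
  v <- enumerate_reversed_variants("c1c(*)cc(*)cc1", site = 1L, k = 10L)
  expect_true(length(v) >= 1L)
  expect_true(all(canonicalize_smiles(v) == canonicalize_smiles("c1ccccc1")))
  expect_equal(anyDuplicated(v), 0L)

  expect_equal(parse_attachment_points("CC(F)CCO")$n_sites, 0L)
  # a real multi-variant case: asymmetric molecule, marker on the oxygen
  set.seed(4)
  v3 <- enumerate_reversed_variants("CC(F)CCO(*)", site = 1L, k = 8L)
  expect_true(length(v3) > 1L)
  lab <- vapply(v3, function(s) label_atom(s, last_atom_ordinal(s)), character(1))
  expect_equal(length(unique(canonicalize_smiles(lab))), 1L)
})

test_that("branch insertion joins fragments with renumbered ring digits", {
  tol <- insert_branch("c1ccccc1", 0L, "C")
  expect_equal(canonicalize_smiles(as.character(tol)), canonicalize_smiles("Cc1ccccc1"))

  ib <- insert_branch("CCCC", 1L, "C1CC1")
  expect_true(is_substructure(as.character(ib), "C1CC1"))
  expect_true(is_substructure(as.character(ib), "CCCC"))
  expect_equal(attr(ib, "frag_atoms"), 3:5)

  # digit collision: host already uses digit 1
  out <- insert_branch("C1CCCC1", 2L, "C1CC1")
  expect_true(smiles_valid(as.character(out)))
  expect_true(is_substructure(as.character(out), "C1CC1"))

  expect_error(insert_branch("C(F)(F)(F)F", 0L, "C"),
               class = "smiles_valence_error")
})

test_that("canonicalization is idempotent and substructure queries behave", {
  s <- canonicalize_smiles("OCC")
  expect_equal(canonicalize_smiles(s), s)
  expect_true(is.na(canonicalize_smiles("C1CC")))
  expect_true(is_substructure("c1ccccc1C", "c1ccccc1"))
  expect_false(is_substructure("CCO", "c1ccccc1"))
  # markers in the query act as wildcards
  expect_true(is_substructure("c1ccccc1CC", "c1ccc(*)cc1"))
})

test_that(".smi files round-trip with ids and comments", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("# header", "CCO\tmol1", "c1ccccc1", ""), f)
  d <- read_smi(f)
  expect_equal(d$smiles, c("CCO", "c1ccccc1"))
  expect_equal(d$id, c("mol1", NA))
  write_smi(d$smiles, f, id = c("a", "b"))
  expect_equal(read_smi(f)$id, c("a", "b"))
})
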