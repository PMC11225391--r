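# Property-style tests over generated molecules: rooting and reversal
# preserve graph isomorphism and satisfy their positional contracts; the
# marker ledger survives suffix-only edits.

test_that("rooting and reversal preserve isomorphism over random molecules", {
  mols <- generate_corpus(150, seed = 11)
  set.seed(99)
  atoms <- vapply(mols, function(s) {
    sample.int(asNamespace("promptclm")$parse_smiles_graph(s)$n, 1L) - 1L
  }, integer(1), USE.NAMES = FALSE)
  rooted <- mapply(function(s, a) as.character(root_at_atom(s, a)), mols, atoms)
  reversed <- vapply(rooted, function(s) reverse_smiles(s, verify = FALSE),
                     character(1), USE.NAMES = FALSE)
  c0 <- canonicalize_smiles(mols)
  c1 <- canonicalize_smiles(rooted)
  c2 <- canonicalize_smiles(reversed)
  expect_identical(c1, c0)
  expect_identical(c2, c0)
  # first-atom contract of rooting via the traversal map
  firsts <- mapply(function(s, a) {
    attr(root_at_atom(s, a), "atom_order")[1] == a + 1L
  }, mols, atoms)
  expect_true(all(firsts))
})

test_that("reversal puts the rooted atom last (isotope-label oracle)", {
  mols <- generate_corpus(40, seed = 13)
  set.seed(7)
  for (s in mols) {
    n <- asNamespace("promptclm")$parse_smiles_graph(s)$n
    a <- sample.int(n, 1L) - 1L
    rooted <- as.character(root_at_atom(s, a))
    rev <- reverse_smiles(rooted, verify = FALSE)
    l_in <- label_atom(rooted, 0L)
    l_out <- label_atom(rev, last_atom_ordinal(rev))
    if (is.na(l_in) || is.na(l_out)) next  # bracket atoms not labelable
    expect_true(same_labeled_molecule(l_in, l_out), info = paste(s, a))
  }
})

test_that("marker spans are stable under suffix-only edits across molecules", {
  mols <- generate_corpus(30, seed = 17)
  pe <- asNamespace("promptclm")
  set.seed(3)
  for (s in mols) {
    mol <- pe$parse_smiles_graph(s)
    fv <- pe$free_valence(mol)
    cand <- which(fv >= 1 & !mol$atoms$bracket)
    if (length(cand) == 0L) next
    a <- cand[sample.int(length(cand), 1L)]
    marked <- as.character(insert_branch(s, a - 1L, "*"))
    sl <- strip_markers(marked)
    expect_identical(reinsert_markers(sl$core, sl$ledger), marked)
    expect_identical(reinsert_markers(paste0(sl$core, "CC"), sl$ledger),
                     paste0(substr(marked, 1, nchar(marked)), "CC"))
  }
})
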