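# The synthetic corpus generator and the curated toy inputs.

test_that("generated corpora are valid, unique, seed-deterministic, small-vocab", {
  c1 <- generate_corpus(300, seed = 1)
  expect_length(c1, 300L)
  expect_equal(anyDuplicated(c1), 0L)
  expect_true(all(smiles_valid(c1)))
  expect_identical(generate_corpus(300, seed = 1), c1)
  expect_false(identical(generate_corpus(300, seed = 2), c1))
  toks <- unique(unlist(lapply(c1, function(s) as.character(smiles_tokens(s)))))
  expect_lte(length(toks), 40L)
  expect_length(generate_corpus(1, seed = 3), 1L)
  expect_error(generate_corpus(10, seed = 1, size_range = c(5L, 4L)),
               class = "corpus_spec_error")
})

test_that("toy cases have the documented attachment structure", {
  tc <- toy_cases()
  expect_equal(parse_attachment_points(tc$meta_benzene)$n_sites, 2L)
  expect_equal(parse_attachment_points(tc$single_site)$n_sites, 1L)
  expect_true(all(vapply(tc$pair, function(f)
    parse_attachment_points(f)$n_sites, integer(1)) == 1L))
  expect_length(tc$four, 4L)
  expect_true(all(vapply(tc$four, function(f)
    parse_attachment_points(f)$n_sites, integer(1)) == 1L))
})

test_that("the four-fragment witness contains all cores, pairwise disjoint", {
  tc <- toy_cases()
  pe <- asNamespace("promptclm")
  expect_true(smiles_valid(tc$four_target))
  hits <- lapply(tc$four, function(f) {
    sp <- parse_attachment_points(f)
    pe$match_substructure(tc$four_target, sp$core_smiles)
  })
  expect_true(all(vapply(hits, length, integer(1)) > 0L))
  # a pairwise-disjoint placement exists
  lp <- linker_props(tc$four_target, tc$four)
  expect_gte(lp$n_atoms, 1L)
})
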