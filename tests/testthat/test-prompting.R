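# The prompting algorithms under scripted (mock) CLMs: decoration loop
# mechanics, pair linking, insertion-based multi-linking, and the
# likelihood-selection operations against brute-force oracles.

test_that("attachment selection: canonical takes the first, shuffle is uniform", {
  expect_equal(select_attachment(2L, "canonical"), 1L)
  expect_equal(select_attachment(1L, "shuffle"), 1L)
  expect_error(select_attachment(0L, "canonical"), class = "sites_exhausted_error")
  set.seed(12)
  draws <- replicate(3000, select_attachment(3L, "shuffle"))
  freq <- tabulate(draws, 3) / 3000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("decoration with a scripted CLM substitutes both sites in order", {
  mock <- make_mock_clm(list("C", "O"))
  g <- decorate(mock, "c1c(*)cc(*)cc1", n = 1)
  expect_true(g$summary$valid)
  expect_equal(g$summary$iterations, 2L)
  expect_equal(canonicalize_smiles(g$summary$smiles),
               canonicalize_smiles("Cc1cccc(O)c1"))
  recs <- g$results[[1]]$records
  expect_equal(nrow(recs), 2L)
  expect_true(all(startsWith(recs$full, recs$prompt)))
})

test_that("immediate EOS hydrogen-caps sites; single site means one iteration", {
  g <- decorate(make_mock_clm(list("")), "c1c(*)cc(*)cc1", n = 1)
  expect_equal(canonicalize_smiles(g$summary$smiles), canonicalize_smiles("c1ccccc1"))
  g1 <- decorate(make_mock_clm(list("C")), toy_cases()$single_site, n = 1)
  expect_equal(g1$summary$iterations, 1L)
  expect_equal(canonicalize_smiles(g1$summary$smiles), canonicalize_smiles("Cc1ccccc1"))
  expect_error(decorate(make_mock_clm(list("C")), "CCO"),
               class = "no_attachment_points_error")
})

test_that("optimised prompt selection equals the brute-force argmin", {
  nll_fn <- function(smiles, eos = TRUE) {
    vapply(smiles, function(s) sum(utf8ToInt(s) * seq_len(nchar(s))) %% 101,
           numeric(1), USE.NAMES = FALSE)
  }
  mock <- make_mock_clm(list("C"), nll_fn = nll_fn)
  for (seed in 1:10) {
    w <- "c1c(*)cc(CC(F)O)cc1"
    set.seed(seed)
    bp <- build_prompt(w, 1L, model = mock, optimise = TRUE, k_variants = 8L)
    expect_equal(bp$prompt, bp$candidates[which.min(nll_fn(bp$candidates))])
  }
})

test_that("pair linking concatenates the second fragment head-first", {
  tc <- toy_cases()
  lp <- link_pair(make_mock_clm(list("CC")), tc$pair, n = 1)
  expect_true(lp$summary$valid)
  s <- lp$summary$smiles
  pe <- asNamespace("promptclm")
  expect_gt(length(pe$match_substructure(s, "C1CC1")), 0L)
  expect_gt(length(pe$match_substructure(s, "n1ccncc1")), 0L)
  # single-update sequence is fragment + linker, without the second fragment
  expect_equal(lp$results[[1]]$update_smiles,
               paste0(lp$results[[1]]$records$prompt[1], "CC"))

  # empty linker: direct bond between the two attachment atoms
  lp0 <- link_pair(make_mock_clm(list("")), tc$pair, n = 1)
  expect_true(lp0$summary$valid)
  expect_equal(canonicalize_smiles(lp0$summary$smiles),
               canonicalize_smiles("C1C(C1)n1ccncc1"))

  expect_error(link_pair(make_mock_clm(list("C")), list("CCO", "C(*)C")),
               class = "fragment_spec_error")
})

test_that("shuffle mixes fragment orders across a batch", {
  tc <- toy_cases()
  lp <- link_pair(make_mock_clm(list("CC")), tc$pair, n = 40,
                  strategy = "shuffle", seed = 8)
  orders <- vapply(lp$results, function(r) r$order[1], integer(1))
  expect_setequal(unique(orders), c(1L, 2L))
})

test_that("insertion-site selection equals the exhaustive argmin", {
  nll_fn <- function(smiles, eos = TRUE) {
    vapply(smiles, function(s) (sum(utf8ToInt(s)) * 31 + nchar(s)) %% 97,
           numeric(1), USE.NAMES = FALSE)
  }
  mock <- make_mock_clm(list("C"), nll_fn = nll_fn)
  pe <- asNamespace("promptclm")
  hosts <- generate_corpus(20, seed = 23)
  for (h in hosts) {
    mol <- pe$parse_smiles_graph(h)
    fv <- pe$free_valence(mol)
    cand <- which(fv >= 1) - 1L
    if (length(cand) == 0L) next
    sel <- select_insertion_site(h, "C1C(*)C1", model = mock)
    # oracle: exhaustive enumeration with the same scorer
    frag <- as.character(root_at_atom("C1CC1", 1L))
    best <- Inf; best_atom <- NA
    for (a in cand) {
      s <- tryCatch(as.character(insert_branch(h, a, frag)), error = function(e) NULL)
      if (is.null(s)) next
      v <- nll_fn(s)
      if (v < best) { best <- v; best_atom <- a }
    }
    expect_equal(sel$atom, best_atom, info = h)
    expect_equal(sel$nll, best, info = h)
  }
  expect_error(select_insertion_site("C(F)(F)(F)F", "C1C(*)C1", model = mock),
               class = "no_insertion_site_error")
})

test_that("multi-fragment linking inserts all cores with disjoint atom sets", {
  frags <- list("C1C(*)C1", "c1ccc(*)cc1", "OC(*)")
  mock <- make_mock_clm(list("CCCCC"))
  lm <- link_multi(mock, frags, n = 1)
  expect_true(lm$summary$valid)
  sets <- lm$results[[1]]$frag_atom_sets
  expect_length(sets, 3L)
  all_atoms <- unlist(sets)
  expect_equal(anyDuplicated(all_atoms), 0L)
  pe <- asNamespace("promptclm")
  for (f in frags) {
    sp <- parse_attachment_points(f)
    expect_gt(length(pe$match_substructure(lm$summary$smiles, sp$core_smiles)), 0L)
  }
})

test_that("multi-fragment linking skips fragments the CLM already generated", {
  frags <- list("C1C(*)C1", "c1ccc(*)cc1", "OC(*)")
  # the de novo completion already contains a benzene ring
  mock <- make_mock_clm(list("Cc1ccccc1"))
  lm <- link_multi(mock, frags, n = 1)
  expect_true(lm$summary$valid)
  pe <- asNamespace("promptclm")
  n_benzene <- length(pe$match_substructure(lm$summary$smiles, "c1ccccc1"))
  expect_equal(n_benzene, 12L)  # one ring: 12 automorphic matches
})

test_that("four fragments admit branched insertion topologies", {
  frags <- list("C1C(*)C1", "c1ccc(*)cc1", "OC(*)", "NC(*)=O")
  mock <- make_mock_clm(list("CCC"))
  lm <- link_multi(mock, frags, n = 1)
  expect_true(lm$summary$valid)
  sets <- lm$results[[1]]$frag_atom_sets
  expect_length(sets, 4L)
  expect_equal(anyDuplicated(unlist(sets)), 0L)
})

test_that("link_fragments dispatches on fragment count", {
  tc <- toy_cases()
  lp <- link_fragments(make_mock_clm(list("C")), tc$pair, n = 1)
  expect_equal(lp$task, "link_pair")
  lm <- link_fragments(make_mock_clm(list("CCCC")), as.list(tc$four[1:3]), n = 1)
  expect_equal(lm$task, "link_multi")
  expect_error(link_fragments(make_mock_clm(list("C")), list("C(*)C")),
               class = "fragment_spec_error")
})
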