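# Reward functions: binary valid+unique, Tanimoto with a set-arithmetic
# oracle, linker properties against hand-computed graphs, band rewards.

test_that("valid+unique reward is 1 for fresh valid molecules, else 0", {
  mem <- reward_memory()
  expect_equal(valid_unique_reward(c("CCO", "CCO"), mem), c(1, 0))
  expect_equal(valid_unique_reward("C1CC", mem), 0)       # invalid
  expect_equal(valid_unique_reward("OCC", mem), 0)        # same graph as CCO
  expect_equal(valid_unique_reward("c1ccccc1", mem), 1)
  # representation-invariance: uniqueness is on the canonical graph
  mem2 <- reward_memory()
  expect_equal(valid_unique_reward(c("C(C)O", "OC(C)", "CC"), mem2), c(1, 0, 1))
})

test_that("Tanimoto reward matches a fingerprint set-arithmetic oracle", {
  expect_equal(tanimoto_reward("CCO", "CCO"), 1)
  expect_equal(tanimoto_reward("C1CC", "CCO"), 0)  # invalid scores 0
  sim <- tanimoto_reward("Cc1ccccc1", "c1ccccc1")
  sdf <- ChemmineR::smiles2sdf(c(a = "c1ccccc1", b = "Cc1ccccc1"))
  m <- ChemmineR::fingerprintOB(sdf, "ECFP4")@fpma
  a <- m[1, ] > 0; b <- m[2, ] > 0
  expect_equal(sim, sum(a & b) / sum(a | b), tolerance = 1e-12)
  expect_gt(sim, 0); expect_lt(sim, 1)
})

test_that("linker properties match hand-computed graphs", {
  frags <- list("C1C(*)C1", "c1ccc(*)cc1")
  # unbranched CCCC linker
  lp <- linker_props("C1CC1CCCCc1ccccc1", frags)
  expect_equal(lp$n_atoms, 4L)
  expect_equal(lp$path_len, 4L)
  expect_equal(lp$linearity, 1)
  expect_equal(lp$flexibility, 1)  # all 3 internal bonds rotatable
  # branched CC(C)C linker: path 3 of 4 atoms; methyl bond not rotatable
  lp2 <- linker_props("C1CC1CC(C)Cc1ccccc1", frags)
  expect_equal(lp2$n_atoms, 4L)
  expect_equal(lp2$path_len, 3L)
  expect_equal(lp2$linearity, 0.75)
  expect_equal(lp2$flexibility, 2 / 3)
  # direct bond: degenerate conventions
  lp0 <- linker_props("C1CC1c1ccccc1", frags)
  expect_equal(lp0$n_atoms, 0L)
  expect_equal(lp0$linearity, 1)
  expect_equal(lp0$flexibility, 0)
  expect_error(linker_props("CCCCCC", frags), class = "containment_error")
})

test_that("linker properties are invariant to the SMILES representation", {
  frags <- list("C1C(*)C1", "c1ccc(*)cc1")
  s <- "C1CC1CC(C)Cc1ccccc1"
  alt <- as.character(root_at_atom(s, 7L))
  lp1 <- linker_props(s, frags)
  lp2 <- linker_props(alt, frags)
  expect_equal(lp1[c("n_atoms", "path_len", "linearity", "flexibility")],
               lp2[c("n_atoms", "path_len", "linearity", "flexibility")])
})

test_that("band reward is 1 inside, ramps linearly outside", {
  expect_equal(range_reward(0.5, 0.4, 0.6), 1)
  expect_equal(range_reward(c(0.4, 0.6), 0.4, 0.6), c(1, 1))  # closed edges
  expect_equal(range_reward(0.7, 0.4, 0.6, margin = 0.2), 0.5)
  expect_equal(range_reward(0.9, 0.4, 0.6, margin = 0.2), 0)
  expect_equal(range_reward(0.3, 0.4, 0.6, margin = 0.2), 0.5)
})

test_that("reward pipelines take the weighted mean and stay in [0,1]", {
  f <- reward_pipeline(list(
    list(fn = function(s) rep(1, length(s)), weight = 3),
    list(fn = function(s) rep(0, length(s)), weight = 1)
  ))
  expect_equal(f(c("CCO", "CC")), c(0.75, 0.75))
})
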