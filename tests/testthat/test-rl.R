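# Reinforcement learning: loss identities, fixed points, update-sequence
# assembly in single vs multi mode, prior immutability, and the diversity
# filter.

test_that("augmented-likelihood loss identities hold exactly", {
  expect_equal(reinvent_loss(20, 20, 0, 120), 0)
  expect_equal(reinvent_loss(20, 20, 1, 120), 120^2)
  expect_equal(reinvent_loss(20, 20 - 120 * 1, 1, 120), 0)
  expect_equal(reinvent_loss(c(10, 30), c(10, 30), c(0, 0), 50), 0)
  expect_equal(rl_config()$sigma, 120)
})

test_that("zero reward with agent == prior is a fixed point of the update", {
  m <- tiny_model()
  cfg <- rl_config(batch_size = 8, steps = 1, lr = 1e-4, seed = 9)
  st <- rl_step(m, m, rl_task_denovo(max_len = 40),
                function(s) numeric(length(s)), cfg)
  expect_equal(st$metrics$loss, 0)
  expect_equal(st$batch$agent_nll, st$batch$prior_nll)
})

test_that("multi mode emits one update sequence per decoration iteration", {
  m <- tiny_model()
  cfg <- rl_config(batch_size = 6, steps = 1, lr = 1e-4, seed = 4,
                   update_mode = "multi")
  set.seed(41)
  st <- rl_step(m, m, rl_task_decorate(toy_cases()$meta_benzene, max_len = 50),
                function(s) numeric(length(s)), cfg)
  # every fully decorated molecule contributes exactly 2 iteration records
  tab <- table(st$batch$mol)
  expect_true(all(tab <= 2))
  expect_equal(st$metrics$n_update, sum(tab))
  # sampler-reported NLLs agree with the scorer on the update sequences
  ok <- !is.na(st$batch$sampled_nll)
  if (any(ok)) {
    expect_lt(max(abs(st$batch$sampled_nll[ok] - st$batch$agent_nll[ok])), 1e-8)
  }
})

# a deterministic task whose every collected molecule is valid, so reward
# plumbing is exercised regardless of model quality
mock_task <- function(smiles = "CCO") {
  structure(list(name = "mock", collect = function(model, n) {
    lapply(seq_len(n), function(i) {
      list(smiles = smiles, valid = TRUE,
           records = data.frame(iteration = 1L, marker = NA_integer_,
                                prompt = "", completion = smiles,
                                full = smiles, nll = NA_real_,
                                terminated = TRUE, stringsAsFactors = FALSE),
           mode = "de_novo", update_smiles = smiles)
    })
  }), class = "rl_task")
}

test_that("the prior is immutable across RL steps and the agent moves", {
  m <- tiny_model()
  probe <- generate_corpus(20, seed = 31)
  before <- clm_nll(m, probe)
  cfg <- rl_config(batch_size = 8, steps = 3, lr = 5e-4, seed = 6)
  out <- rl_optimize(m, mock_task(), function(s) rep(1, length(s)), cfg)
  expect_identical(clm_nll(out$prior, probe), before)
  # nonzero reward with agent == prior is not a fixed point: the agent moves
  expect_false(identical(out$agent$params, m$params))
})

test_that("out-of-range rewards are rejected", {
  m <- tiny_model()
  cfg <- rl_config(batch_size = 4, steps = 1, seed = 2)
  expect_error(
    rl_step(m, m, mock_task(), function(s) rep(2, length(s)), cfg),
    class = "reward_contract_error")
})

test_that("diversity filter zeroes a bucket only after it overflows", {
  mem <- reward_memory()
  s <- "CC(C)Cc1ccccc1"
  hits <- vapply(1:4, function(i) diversity_penalty(mem, s, bucket = 3L), numeric(1))
  expect_equal(hits, c(1, 1, 1, 0))
  # a different framework is unaffected
  expect_equal(diversity_penalty(mem, "CCC1CCCC1", bucket = 3L), 1)
  # same framework, different decoration, shares the bucket
  mem2 <- reward_memory()
  for (i in 1:3) diversity_penalty(mem2, "CCc1ccccc1", bucket = 3L)
  expect_equal(diversity_penalty(mem2, "OCc1ccccc1", bucket = 3L), 0)
})
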