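# Language-model mechanics: vocabulary round trips, analytic likelihoods,
# training behaviour, prompted sampling, determinism, and exact agreement
# between the sampler's accumulated log-probabilities and the scorer.

test_that("encode/decode round-trips and flags unknown tokens", {
  v <- clm_vocab(c("CCl", "c1cc[nH]c1"))
  for (s in c("c1ccccc1", "CCl", "c1cc[nH]c1", "CC(=O)O")) {
    expect_identical(decode_ids(v, encode_smiles(v, s)), s)
  }
  expect_length(encode_smiles(v, "c1ccccc1"), 8L)
  expect_length(encode_smiles(v, "CCl"), 2L)   # Cl is one token
  expect_length(encode_smiles(v, "[nH]"), 1L)  # bracket atom is one token
  expect_error(encode_smiles(v, "C[Zn]C"), class = "vocabulary_error")
})

test_that("uniform logits give the analytic NLL L * ln(V)", {
  pe <- asNamespace("promptclm")
  V <- 30L
  set.seed(1)
  P <- pe$nn_init(V, emb = 4L, hidden = 4L, layers = 1L)
  P$Wout[] <- 0; P$bout[] <- 0
  X <- matrix(c(2L, rep(4L, 10L)), 1)  # GO + 10 tokens (no EOS target)
  expect_equal(pe$nn_forward(P, X, 1L)$nll, 10 * log(V), tolerance = 1e-9)
})

test_that("analytic gradients match numerical differentiation", {
  pe <- asNamespace("promptclm")
  set.seed(42)
  P <- pe$nn_init(8L, emb = 5L, hidden = 6L, layers = 2L)
  X <- rbind(c(2L, 4L, 5L, 6L, 3L, 1L), c(2L, 7L, 4L, 3L, 1L, 1L))
  sw <- c(0.7, -1.3)
  fw <- pe$nn_forward(P, X, 1L, want_cache = TRUE)
  G <- pe$nn_backward(P, fw, X, 1L, seq_w = sw)
  f <- function(P) sum(sw * pe$nn_forward(P, X, 1L)$nll)
  eps <- 1e-5
  check_slot <- function(get, set, ana) {
    for (k in 1:3) {
      P1 <- set(P, k, eps); P2 <- set(P, k, -eps)
      num <- (f(P1) - f(P2)) / (2 * eps)
      expect_equal(ana[k], num, tolerance = 1e-4)
    }
  }
  check_slot(NULL, function(P, k, e) { P$Emb[2, k] <- P$Emb[2, k] + e; P }, G$Emb[2, ])
  check_slot(NULL, function(P, k, e) { P$layers[[1]]$U[1, k] <- P$layers[[1]]$U[1, k] + e; P },
             G$layers[[1]]$U[1, ])
  check_slot(NULL, function(P, k, e) { P$Wout[1, k] <- P$Wout[1, k] + e; P }, G$Wout[1, ])
})

test_that("training reduces loss and memorizes a single-molecule corpus", {
  m <- tiny_model()
  expect_lt(tail(m$log$nll, 1), m$log$nll[1])

  memo <- clm(rep("CC(=O)Nc1ccccc1", 50), epochs = 40, batch_size = 16,
              lr = 5e-3, embedding = 16, hidden = 32, seed = 1)
  expect_lt(tail(memo$log$nll, 1), 0.1)  # per-token NLL approaches 0
  s <- clm_sample(memo, n = 20, max_len = 30, seed = 9)
  expect_gte(mean(s$smiles == "CC(=O)Nc1ccccc1"), 0.6)
})

test_that("training and sampling are seed-deterministic", {
  corp <- generate_corpus(100, seed = 21)
  m1 <- clm(corp, epochs = 1, embedding = 16, hidden = 24, seed = 77)
  m2 <- clm(corp, epochs = 1, embedding = 16, hidden = 24, seed = 77)
  expect_identical(m1$params, m2$params)
  s1 <- clm_sample(m1, n = 25, max_len = 40, seed = 5)
  s2 <- clm_sample(m2, n = 25, max_len = 40, seed = 5)
  expect_identical(s1, s2)
})

test_that("samples start with the prompt verbatim; forced prompts reproduce it", {
  m <- tiny_model()
  s <- clm_sample(m, n = 30, prompts = "CCC", max_len = 40, seed = 3)
  expect_true(all(startsWith(s$smiles, "CCC")))
  # fully forced prompt: a benzene ring continued into benzoic acid
  target <- "c1ccccc1C(=O)O"
  s2 <- clm_sample(m, n = 1, prompts = target, max_len = nchar(target), seed = 1)
  expect_identical(s2$smiles, target)
})

test_that("NLL accumulates monotonically and matches the sampler exactly", {
  m <- tiny_model()
  expect_gte(clm_nll(m, "CCCC", eos = FALSE), clm_nll(m, "CC", eos = FALSE))
  expect_gte(clm_nll(m, "CC", eos = TRUE), clm_nll(m, "CC", eos = FALSE))
  s <- clm_sample(m, n = 50, max_len = 50, seed = 31)
  term <- which(s$terminated)
  expect_gt(length(term), 0L)
  recomputed <- clm_nll(m, s$smiles[term], eos = TRUE)
  expect_lt(max(abs(s$nll[term] - recomputed)), 1e-8)
})

test_that("checkpoints reload to an identical model", {
  m <- tiny_model()
  f <- tempfile(fileext = ".rds")
  save_clm(m, f)
  m2 <- load_clm(f)
  expect_identical(m2$params, m$params)
  expect_identical(clm_sample(m2, n = 5, max_len = 30, seed = 2),
                   clm_sample(m, n = 5, max_len = 30, seed = 2))
})
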