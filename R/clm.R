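# The chemical language model: vocabulary, training, autoregressive
# sampling from an optional prompt, and sequence likelihoods — plus the
# two-callback interface consumed by the prompting layer.

.SPECIALS <- c(PAD = "<pad>", GO = "<go>", EOS = "<eos>")

#' Build a SMILES token vocabulary
#'
#' @param corpus Character vector of SMILES whose tokens must be covered.
#' @param extra Extra tokens to include beyond those observed.
#' @return An object of class `clm_vocab`: token table with special tokens
#'   `<pad>`, `<go>`, `<eos>` at ids 1..3.
#' @export
clm_vocab <- function(corpus = character(0), extra = character(0)) {
  base <- c("C", "N", "O", "F", "S", "c", "n", "o", "s", "Cl", "Br",
            "=", "#", "-", "(", ")", ".", as.character(1:9), "%10", "%11")
  toks <- unique(c(base, extra,
                   unlist(lapply(corpus, function(s) as.character(smiles_tokens(s))))))
  tokens <- c(unname(.SPECIALS), toks)
  structure(list(tokens = tokens,
                 id = stats::setNames(seq_along(tokens), tokens),
                 pad = 1L, go = 2L, eos = 3L),
            class = "clm_vocab")
}

#' @export
print.clm_vocab <- function(x, ...) {
  cat(sprintf("<clm_vocab> %d tokens: %s ...\n", length(x$tokens),
              paste(utils::head(x$tokens, 12), collapse = " ")))
  invisible(x)
}

#' Encode / decode SMILES against a vocabulary
#'
#' `encode_smiles` maps a SMILES to token ids (without GO/EOS); unknown
#' tokens raise a vocabulary error naming the offending span.
#' `decode_ids` inverts it, dropping special tokens.
#'
#' @param vocab A `clm_vocab`.
#' @param smiles A single SMILES string.
#' @return Integer vector of token ids.
#' @export
encode_smiles <- function(vocab, smiles) {
  if (!nzchar(smiles)) return(integer(0))
  toks <- smiles_tokens(smiles)
  ids <- vocab$id[as.character(toks)]
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    stop(structure(class = c("vocabulary_error", "error", "condition"),
                   list(message = sprintf("token '%s' (position %d) of '%s' not in vocabulary",
                                          toks[bad], bad, smiles), call = NULL)))
  }
  unname(ids)
}

#' @rdname encode_smiles
#' @param ids Integer vector of token ids.
#' @export
decode_ids <- function(vocab, ids) {
  ids <- ids[ids > 3L]
  paste0(vocab$tokens[ids], collapse = "")
}

# pad a list of id vectors (already including GO/EOS as desired) to a matrix
pad_batch <- function(seqs, pad_id) {
  Tm <- max(vapply(seqs, length, integer(1)))
  X <- matrix(pad_id, length(seqs), Tm)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (length(s) > 0L) X[i, seq_along(s)] <- s
  }
  X
}

#' Fit a GRU chemical language model on a SMILES corpus
#'
#' Trains a decoder-only recurrent language model by teacher forcing with
#' Adam on GO-prefixed, EOS-terminated token sequences. The default profile
#' is deliberately small: it is sized for corpora of a few thousand drug-
#' like-ish molecules, which is enough to exercise prompting and RL.
#'
#' @param corpus Character vector of training SMILES (or a data.frame from
#'   [read_smi()]).
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param embedding,hidden,layers Architecture sizes.
#' @param max_len Maximum token length; longer corpus entries are dropped.
#' @param seed RNG seed controlling init and batch order (reproducible).
#' @param extra_tokens Tokens guaranteed present in the vocabulary besides
#'   those observed in the corpus.
#' @param verbose Print per-epoch loss.
#' @return An object of class `promptclm_model` with elements `params`,
#'   `vocab`, `arch`, `config`, `log` (epoch, mean token NLL in nats) and
#'   `corpus_hash`.
#' @seealso [clm_sample()], [clm_nll()], [clm_callbacks()]
#' @export
clm <- function(corpus, epochs = 5L, batch_size = 64L, lr = 3e-3,
                embedding = 64L, hidden = 128L, layers = 1L,
                max_len = 100L, seed = 1L, extra_tokens = character(0),
                verbose = FALSE) {
  if (is.data.frame(corpus)) corpus <- corpus$smiles
  stopifnot(length(corpus) > 0L)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  vocab <- clm_vocab(corpus, extra = extra_tokens)
  seqs <- lapply(corpus, function(s) c(vocab$go, encode_smiles(vocab, s), vocab$eos))
  keep <- vapply(seqs, length, integer(1)) <= max_len
  seqs <- seqs[keep]

  P <- nn_init(length(vocab$tokens), emb = embedding, hidden = hidden,
               layers = layers)
  st <- adam_init(P)
  log <- data.frame(epoch = integer(0), nll = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(length(seqs))
    tot <- 0; ntok <- 0
    for (b0 in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      X <- pad_batch(seqs[idx], vocab$pad)
      fw <- nn_forward(P, X, vocab$pad, want_cache = TRUE)
      ntk <- sum(X[, -1L, drop = FALSE] != vocab$pad)
      G <- nn_backward(P, fw, X, vocab$pad, seq_w = rep(1 / ntk, nrow(X)))
      u <- adam_update(P, G, st, lr = lr)
      P <- u$P; st <- u$state
      tot <- tot + sum(fw$nll); ntok <- ntok + ntk
    }
    log <- rbind(log, data.frame(epoch = ep, nll = tot / ntok))
    if (verbose) message(sprintf("epoch %d: mean token NLL %.4f", ep, tot / ntok))
  }
  structure(list(params = P, vocab = vocab,
                 arch = attr(P, "arch"),
                 config = list(epochs = epochs, batch_size = batch_size, lr = lr,
                               max_len = max_len, seed = seed),
                 log = log,
                 corpus_hash = corpus_hash(corpus),
                 n_corpus = length(seqs)),
            class = "promptclm_model")
}

corpus_hash <- function(corpus) {
  f <- tempfile()
  writeLines(corpus, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

#' @export
print.promptclm_model <- function(x, ...) {
  cat(sprintf("<promptclm_model> GRU LM: %d layer(s), hidden %d, embedding %d, vocab %d\n",
              x$arch$layers, x$arch$hidden, x$arch$emb, x$arch$vocab_size))
  cat(sprintf("  trained %d epochs on %d sequences; final mean token NLL %.4f nats\n",
              nrow(x$log), x$n_corpus, utils::tail(x$log$nll, 1)))
  invisible(x)
}

#' @export
summary.promptclm_model <- function(object, ...) {
  cat(sprintf("GRU chemical language model\n"))
  print(object)
  cat("training log:\n")
  print(object$log, row.names = FALSE)
  invisible(object$log)
}

#' @export
logLik.promptclm_model <- function(object, smiles, ...) {
  ll <- -clm_nll(object, smiles)
  structure(ll, class = "logLik", df = NA_integer_)
}

#' Sample SMILES from the model, optionally from prompts
#'
#' Autoregressive sampling. Each row of the batch is conditioned on its own
#' prompt: while prompt tokens remain at a timestep they are forced (the
#' model's own prediction is discarded), afterwards tokens are sampled from
#' the softmax until EOS or `max_len`. With empty prompts this is plain de
#' novo generation.
#'
#' @param model A `promptclm_model`.
#' @param n Number of samples (ignored when `prompts` longer than 1 is
#'   given; then one sample per prompt).
#' @param prompts Character vector of prompt SMILES ("" for none); recycled
#'   to `n` when of length 1.
#' @param max_len Maximum generated length (tokens, including prompt).
#' @param temperature Softmax temperature.
#' @param seed Optional seed (local to the call).
#' @return data.frame with columns `smiles` (prompt + completion),
#'   `completion` (generated part only), `terminated` (EOS reached), and
#'   `nll` (negative log likelihood of the full sequence as accumulated by
#'   the sampler, prompt tokens included).
#' @export
clm_sample <- function(model, n = 1L, prompts = "", max_len = 100L,
                       temperature = 1, seed = NULL) {
  if (length(prompts) == 1L) prompts <- rep(prompts, n)
  B <- length(prompts)
  vocab <- model$vocab
  P <- model$params
  if (!is.null(seed)) { old <- get_rng_state(); on.exit(restore_rng_state(old)); set.seed(seed) }

  penc <- lapply(prompts, function(s) if (nzchar(s)) encode_smiles(vocab, s) else integer(0))
  plen <- vapply(penc, length, integer(1))
  H <- model$arch$hidden
  hs <- rep(list(matrix(0, B, H)), model$arch$layers)
  cur <- rep(vocab$go, B)
  out <- matrix(vocab$pad, B, max_len)
  nll <- numeric(B)
  alive <- rep(TRUE, B)
  V <- model$arch$vocab_size
  Ltri <- upper.tri(matrix(0, V, V), diag = TRUE) * 1

  for (t in seq_len(max_len)) {
    stp <- nn_step(P, cur, hs)
    hs <- stp$hs
    forced <- t <= plen
    nxt <- integer(B)
    if (any(!forced & alive)) {
      probs <- exp(row_log_softmax(stp$logits / temperature))
      probs[, c(vocab$pad, vocab$go)] <- 0  # never draw specials (EOS stays)
      probs <- probs / rowSums(probs)
      cum <- probs %*% Ltri
      u <- stats::runif(B)
      samp <- 1L + rowSums(cum < u)
      samp[samp > V] <- V
      nxt[!forced] <- samp[!forced]
    }
    if (any(forced)) {
      nxt[forced] <- vapply(which(forced), function(i) penc[[i]][t], integer(1))
    }
    # likelihood accounting at temperature-1 scale for scorer consistency
    lp1 <- row_log_softmax(stp$logits)
    nll <- nll - ifelse(alive, lp1[cbind(seq_len(B), pmax(nxt, 1L))], 0)
    out[, t] <- ifelse(alive, nxt, vocab$pad)
    done <- nxt == vocab$eos
    alive <- alive & !done
    cur <- ifelse(alive, nxt, vocab$pad)
    if (!any(alive)) break
  }
  terminated <- apply(out, 1L, function(r) any(r == vocab$eos))
  full <- vapply(seq_len(B), function(i) decode_ids(vocab, out[i, ]), character(1))
  completion <- substring(full, nchar(prompts) + 1L)
  data.frame(smiles = full, completion = completion,
             terminated = terminated, nll = nll, stringsAsFactors = FALSE)
}

#' @export
simulate.promptclm_model <- function(object, nsim = 1, seed = NULL, ...) {
  clm_sample(object, n = nsim, seed = seed, ...)$smiles
}

#' Sequence negative log likelihood under the model
#'
#' Teacher-forced NLL (nats) of each SMILES: the sum over timesteps of
#' \eqn{-\log P(x_t | x_{<t})} starting after the GO token. With
#' `eos = TRUE` the terminal EOS probability is included (full-sequence
#' likelihood); with `eos = FALSE` the string is scored as an open prefix,
#' which is how candidate prompts are compared.
#'
#' @param model A `promptclm_model`.
#' @param smiles Character vector.
#' @param eos Include the EOS term.
#' @return Numeric vector of NLLs (nats).
#' @export
clm_nll <- function(model, smiles, eos = TRUE) {
  if (length(smiles) == 0L) return(numeric(0))
  vocab <- model$vocab
  seqs <- lapply(smiles, function(s) {
    c(vocab$go, encode_smiles(vocab, s), if (eos) vocab$eos)
  })
  X <- pad_batch(seqs, vocab$pad)
  nn_forward(model$params, X, vocab$pad)$nll
}

#' The two callbacks required by the prompting layer
#'
#' Packages a model as the minimal interface the prompting algorithms rely
#' on: a prompted sampler and a string likelihood. Any list with the same
#' two elements (e.g. a scripted mock model in tests) can be passed to the
#' prompting functions instead of a fitted model.
#'
#' @param model A `promptclm_model`.
#' @param max_len,temperature Sampling controls.
#' @return list with elements `sample_fn(prompts)` returning the
#'   data.frame of [clm_sample()], and `nll_fn(smiles, eos = TRUE)`
#'   returning numeric NLLs.
#' @export
clm_callbacks <- function(model, max_len = 100L, temperature = 1) {
  stopifnot(inherits(model, "promptclm_model"))
  list(
    sample_fn = function(prompts) {
      clm_sample(model, n = length(prompts), prompts = prompts,
                 max_len = max_len, temperature = temperature)
    },
    nll_fn = function(smiles, eos = TRUE) clm_nll(model, smiles, eos = eos),
    model = model
  )
}

as_callbacks <- function(x, ...) {
  if (inherits(x, "promptclm_model")) return(clm_callbacks(x, ...))
  stopifnot(is.list(x), is.function(x$sample_fn), is.function(x$nll_fn))
  x
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing RDS container holding parameters,
#' vocabulary, architecture and training metadata.
#'
#' @param model A `promptclm_model`.
#' @param path File path.
#' @export
save_clm <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_clm
#' @export
load_clm <- function(path) {
  structure(readRDS(path), class = "promptclm_model")
}
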