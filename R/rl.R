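# REINVENT-style reinforcement learning over the prompting layer.
#
# The agent is a trainable copy of the pre-trained prior. Each step has a
# collection phase (sampling molecules through the prompting layer, no
# gradient bookkeeping) and an update phase minimizing
#   L = mean_i [ (-prior_nll_i + sigma * reward_i) - (-agent_nll_i) ]^2,
# the squared gap between the agent log-likelihood and the reward-augmented
# prior log-likelihood. Rewards are always computed on the completed
# molecule; the sequences that receive the gradient depend on the task and
# on update_mode ("single": one designated sequence per molecule; "multi":
# every prompt-completion iteration record, each with the molecule's final
# reward).

#' REINVENT augmented-likelihood loss
#'
#' @param prior_nll,agent_nll Per-sequence negative log likelihoods (nats).
#' @param reward Per-sequence rewards in [0, 1].
#' @param sigma Reward scaling (default 120).
#' @return Scalar loss; zero iff the agent log-likelihood equals the
#'   augmented log-likelihood for every sequence.
#' @export
reinvent_loss <- function(prior_nll, agent_nll, reward, sigma = 120) {
  stopifnot(length(prior_nll) == length(agent_nll),
            length(reward) == length(prior_nll), sigma > 0)
  aug <- -prior_nll + sigma * reward
  mean((aug - (-agent_nll))^2)
}

#' RL configuration
#'
#' @param sigma Reward scaling in the augmented likelihood (default 120).
#' @param batch_size Molecules sampled per step.
#' @param steps Number of RL steps for [rl_optimize()].
#' @param update_mode `"single"` (one update sequence per molecule) or
#'   `"multi"` (one per prompt-completion iteration).
#' @param lr Adam learning rate for the agent.
#' @param seed Seed for the run.
#' @param mask_prompt Exclude prompt tokens from the likelihood terms in the
#'   loss (default FALSE: whole sequences are scored).
#' @param diversity_bucket When positive, a scaffold-memory diversity filter
#'   zeroes the reward of molecules whose generic framework has already
#'   been produced more than `diversity_bucket` times.
#' @return list of class `rl_config`.
#' @export
rl_config <- function(sigma = 120, batch_size = 32L, steps = 100L,
                      update_mode = c("single", "multi"), lr = 1e-4,
                      seed = 1L, mask_prompt = FALSE, diversity_bucket = 0L) {
  update_mode <- match.arg(update_mode)
  stopifnot(sigma > 0, batch_size >= 1L, steps >= 0L, lr > 0)
  structure(list(sigma = sigma, batch_size = batch_size, steps = steps,
                 update_mode = update_mode, lr = lr, seed = seed,
                 mask_prompt = mask_prompt, diversity_bucket = diversity_bucket),
            class = "rl_config")
}

#' RL task constructors
#'
#' A task bundles the generation mode the agent is trained on. `de_novo`
#' samples unprompted; the others run the corresponding prompting
#' algorithm. All carry the per-molecule designated update sequence: the
#' completed SMILES for decoration and de novo, and the initial fragment
#' plus de novo linker for fragment linking (concatenating the second
#' fragment would teach the model to generate the fragments themselves).
#'
#' @param scaffold,fragments Task inputs (marker SMILES).
#' @param strategy,optimise,k_variants,max_len,temperature Passed through to
#'   the prompting layer.
#' @return list of class `rl_task` with a `collect(model, n)` closure.
#' @export
rl_task_decorate <- function(scaffold, strategy = "canonical",
                             optimise = FALSE, k_variants = 10L,
                             max_len = 100L, temperature = 1) {
  structure(list(
    name = "decorate",
    collect = function(model, n) {
      gs <- decorate(model, scaffold, n = n, strategy = strategy,
                     optimise = optimise, k_variants = k_variants,
                     max_len = max_len, temperature = temperature)
      gs$results
    }), class = "rl_task")
}

#' @rdname rl_task_decorate
#' @export
rl_task_link <- function(fragments, strategy = "canonical", optimise = FALSE,
                         k_variants = 10L, max_len = 100L, temperature = 1) {
  structure(list(
    name = if (length(fragments) == 2L) "link_pair" else "link_multi",
    collect = function(model, n) {
      gs <- link_fragments(model, fragments, n = n, strategy = strategy,
                           optimise = optimise, k_variants = k_variants,
                           max_len = max_len, temperature = temperature)
      gs$results
    }), class = "rl_task")
}

#' @rdname rl_task_decorate
#' @export
rl_task_denovo <- function(max_len = 100L, temperature = 1) {
  structure(list(
    name = "de_novo",
    collect = function(model, n) {
      s <- clm_sample(model, n = n, max_len = max_len, temperature = temperature)
      lapply(seq_len(n), function(i) {
        list(smiles = s$smiles[i], valid = s$terminated[i] && smiles_valid(s$smiles[i]),
             records = data.frame(iteration = 1L, marker = NA_integer_, prompt = "",
                                  completion = s$smiles[i], full = s$smiles[i],
                                  nll = s$nll[i], terminated = s$terminated[i],
                                  stringsAsFactors = FALSE),
             mode = "de_novo", update_smiles = s$smiles[i])
      })
    }), class = "rl_task")
}

#' Diversity penalty from a scaffold-occurrence memory
#'
#' The memory counts occurrences of each molecule's generic framework
#' (ring systems and linkers after iteratively pruning terminal atoms;
#' acyclic molecules bucket by their own canonical SMILES). The multiplier
#' is 1 until a bucket exceeds `bucket` occurrences and 0 afterwards.
#'
#' @param memory Environment from [reward_memory()] (counts stored in
#'   `memory$counts`).
#' @param smiles Molecule SMILES.
#' @param bucket Occurrences tolerated before zeroing.
#' @return 0 or 1 multiplier (the memory is updated in place).
#' @export
diversity_penalty <- function(memory, smiles, bucket = 25L) {
  if (is.null(memory$counts)) memory$counts <- new.env(parent = emptyenv())
  key <- murcko_framework(smiles)
  if (is.na(key)) return(0)
  cnt <- (memory$counts[[key]] %||% 0L) + 1L
  memory$counts[[key]] <- cnt
  if (cnt > bucket) 0 else 1
}

# generic framework: prune degree-1 atoms iteratively; canonical SMILES of
# the remainder (whole molecule when acyclic)
murcko_framework <- function(smiles) {
  mol <- tryCatch(parse_smiles_graph(smiles), error = function(e) NULL)
  if (is.null(mol)) return(NA_character_)
  keep <- seq_len(mol$n)
  repeat {
    deg <- table(factor(c(mol$bonds$a1[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep],
                          mol$bonds$a2[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep]),
                        levels = keep))
    leaves <- keep[deg <= 1L]
    if (length(leaves) == 0L || length(keep) <= 2L) break
    keep <- setdiff(keep, leaves)
  }
  if (length(keep) < 3L) return(canonicalize_smiles(smiles))
  sub <- subset_graph(mol, keep)
  s <- tryCatch(write_smiles_graph(sub, root = 1L), error = function(e) NA_character_)
  if (is.na(s)) return(canonicalize_smiles(smiles))
  cs <- canonicalize_smiles(as.character(s))
  if (is.na(cs)) canonicalize_smiles(smiles) else cs
}

# encode update strings; returns NULL rows that fail tokenization
encode_update <- function(vocab, smiles, prompt = NULL) {
  ids <- tryCatch(c(vocab$go, encode_smiles(vocab, smiles), vocab$eos),
                  error = function(e) NULL)
  if (is.null(ids)) return(NULL)
  plen <- 0L
  if (!is.null(prompt) && nzchar(prompt)) {
    plen <- tryCatch(length(encode_smiles(vocab, prompt)), error = function(e) 0L)
  }
  list(ids = ids, prompt_len = plen)
}

#' One reinforcement-learning step
#'
#' Collection phase: sample `config$batch_size` molecules through the
#' task's generation mode with the current agent (no gradients). Rewards
#' are computed on the completed SMILES (0 for invalid results), optionally
#' passed through the diversity filter. Update phase: one Adam step on the
#' REINVENT loss over the update sequences implied by `config$update_mode`.
#'
#' @param agent A `promptclm_model` (returned updated).
#' @param prior The frozen pre-trained model (same vocabulary).
#' @param task An `rl_task`.
#' @param reward_fn `function(smiles) -> [0,1]` scores on completed SMILES.
#' @param config An [rl_config()].
#' @param opt_state Adam state (created when NULL).
#' @param memory Optional [reward_memory()] shared across steps.
#' @return list(`agent`, `opt_state`, `metrics` (one-row data.frame),
#'   `batch` (collection details incl. prior/agent NLLs of the update
#'   sequences and the sampler-reported NLLs for consistency checks)).
#' @export
rl_step <- function(agent, prior, task, reward_fn, config, opt_state = NULL,
                    memory = NULL) {
  stopifnot(inherits(agent, "promptclm_model"), inherits(prior, "promptclm_model"),
            inherits(task, "rl_task"), inherits(config, "rl_config"))
  if (!identical(agent$vocab$tokens, prior$vocab$tokens)) {
    stop("agent and prior must share a vocabulary")
  }
  res <- task$collect(agent, config$batch_size)
  completed <- vapply(res, function(r) r$smiles %||% NA_character_, character(1))
  valid <- vapply(res, `[[`, logical(1), "valid")

  reward <- numeric(length(res))
  scorable <- which(valid & !is.na(completed))
  if (length(scorable) > 0L) {
    r <- reward_fn(completed[scorable])
    if (any(r < -1e-9 | r > 1 + 1e-9 | is.na(r))) {
      stop(structure(class = c("reward_contract_error", "error", "condition"),
                     list(message = "reward_fn returned values outside [0, 1]",
                          call = NULL)))
    }
    reward[scorable] <- pmin(pmax(r, 0), 1)
  }
  if (config$diversity_bucket > 0L && !is.null(memory)) {
    for (i in scorable) {
      reward[i] <- reward[i] * diversity_penalty(memory, completed[i],
                                                 config$diversity_bucket)
    }
  }

  # assemble update sequences
  upd <- list()
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (config$update_mode == "single") {
      s <- r$update_smiles
      if (is.null(s) || is.na(s) || !nzchar(s)) next
      pr <- if (nrow(r$records) > 0L) r$records$prompt[1] else ""
      e <- encode_update(agent$vocab, s, prompt = pr)
      if (!is.null(e)) upd[[length(upd) + 1L]] <-
          c(e, list(reward = reward[i], mol = i, sampled_nll = NA_real_))
    } else {
      if (nrow(r$records) == 0L) next
      for (k in seq_len(nrow(r$records))) {
        if (!isTRUE(r$records$terminated[k])) next
        e <- encode_update(agent$vocab, r$records$full[k],
                           prompt = r$records$prompt[k])
        if (!is.null(e)) upd[[length(upd) + 1L]] <-
            c(e, list(reward = reward[i], mol = i,
                      sampled_nll = r$records$nll[k]))
      }
    }
  }

  metrics <- data.frame(
    mean_reward = mean(reward), valid_frac = mean(valid),
    unique_frac = {
      cc <- canonicalize_smiles(completed[valid & !is.na(completed)])
      if (length(cc) == 0L) 0 else length(unique(cc)) / length(res)
    },
    loss = NA_real_, n_update = length(upd))
  if (length(upd) == 0L) {
    return(list(agent = agent, opt_state = opt_state, metrics = metrics,
                batch = list(reward = reward, completed = completed)))
  }

  seqs <- lapply(upd, `[[`, "ids")
  X <- pad_batch(seqs, agent$vocab$pad)
  rw <- vapply(upd, `[[`, numeric(1), "reward")
  prior_nll <- nn_forward(prior$params, X, prior$vocab$pad)$nll
  fw <- nn_forward(agent$params, X, agent$vocab$pad, want_cache = TRUE)
  agent_nll <- fw$nll

  tok_w <- NULL
  if (config$mask_prompt) {
    Tm <- ncol(X)
    tok_w <- matrix(1, nrow(X), Tm - 1L)
    for (i in seq_along(upd)) {
      pl <- upd[[i]]$prompt_len
      if (pl > 0L) tok_w[i, seq_len(min(pl, Tm - 1L))] <- 0
    }
  }
  aug <- -prior_nll + config$sigma * rw
  delta <- (-agent_nll) - aug
  loss <- mean(delta^2)
  B <- length(upd)
  seq_w <- -2 * delta / B  # dLoss/dNLL_i = 2*delta*d(-NLL)/dNLL / B
  G <- nn_backward(agent$params, fw, X, agent$vocab$pad, seq_w = seq_w,
                   tok_w = tok_w)
  if (is.null(opt_state)) opt_state <- adam_init(agent$params)
  u <- adam_update(agent$params, G, opt_state, lr = config$lr)
  agent$params <- u$P
  opt_state <- u$state
  metrics$loss <- loss

  list(agent = agent, opt_state = opt_state, metrics = metrics,
       batch = list(reward = reward, completed = completed, valid = valid,
                    update_reward = rw, prior_nll = prior_nll,
                    agent_nll = agent_nll,
                    sampled_nll = vapply(upd, `[[`, numeric(1), "sampled_nll"),
                    mol = vapply(upd, `[[`, numeric(1), "mol"),
                    update_smiles = vapply(upd, function(u)
                      decode_ids(agent$vocab, u$ids), character(1))))
}

#' Run a reinforcement-learning optimization
#'
#' Repeats [rl_step()] for `config$steps` steps with a frozen prior (a copy
#' of the starting agent unless given explicitly), collecting a per-step
#' metrics log.
#'
#' @inheritParams rl_step
#' @param log_every Keep every step's metrics (1) or a stride.
#' @param log_file Optional CSV path to stream the metrics log to.
#' @return list(`agent` trained model, `log` data.frame of per-step
#'   metrics, `prior`, `memory`).
#' @export
rl_optimize <- function(agent, task, reward_fn, config, prior = NULL,
                        memory = NULL, log_every = 1L, log_file = NULL) {
  if (is.null(prior)) prior <- agent
  if (is.null(memory)) memory <- reward_memory()
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  opt_state <- NULL
  log <- NULL
  for (step in seq_len(config$steps)) {
    st <- rl_step(agent, prior, task, reward_fn, config, opt_state, memory)
    agent <- st$agent; opt_state <- st$opt_state
    row <- cbind(step = step, st$metrics)
    if (step %% log_every == 0L || step == config$steps) log <- rbind(log, row)
    if (!is.null(log_file)) {
      utils::write.table(row, log_file, sep = ",", col.names = step == 1L,
                         row.names = FALSE, append = step > 1L)
    }
  }
  list(agent = agent, log = log, prior = prior, memory = memory)
}
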