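# The prompting algorithms: iterative scaffold decoration, two-fragment
# linking, and multi-fragment linking by likelihood-scored insertion.
#
# All three operate on the two CLM callbacks (a prompted sampler and a
# string likelihood) and are agnostic of the model behind them; a fitted
# promptclm_model is wrapped automatically, and any list carrying
# `sample_fn`/`nll_fn` (e.g. a scripted mock in tests) works identically.

as_attachment_spec <- function(x) {
  if (inherits(x, "attachment_spec")) x else parse_attachment_points(x)
}

# graph containment on the written structure (aromaticity as written),
# robust to toolkit aromaticity re-perception of exotic rings
contains_core <- function(full, core) {
  tryCatch(length(match_substructure(full, core)) > 0L, error = function(e) FALSE)
}

#' Select the next attachment marker
#'
#' `canonical` picks the first marker in order of appearance in the current
#' string; `shuffle` picks uniformly at random so that a batch mixes
#' selected attachment points.
#'
#' @param n_remaining Number of markers still present.
#' @param strategy `"canonical"` or `"shuffle"`.
#' @return The 1-based index (in appearance order) of the chosen marker.
#' @export
select_attachment <- function(n_remaining, strategy = c("canonical", "shuffle")) {
  strategy <- match.arg(strategy)
  if (n_remaining < 1L) {
    stop(structure(class = c("sites_exhausted_error", "error", "condition"),
                   list(message = "no attachment points remain", call = NULL)))
  }
  if (strategy == "canonical") 1L else sample.int(n_remaining, 1L)
}

# Remove the chosen marker, root+reverse the molecule at its attachment
# atom, strip the remaining markers, and (optionally) pick the CLM-likeliest
# variant. Returns list(prompt, ledger, candidates, cand_nll).
build_prompt_for <- function(working, marker_index, optimise = FALSE,
                             k_variants = 10L, nll_fn = NULL) {
  mol <- parse_smiles_graph(working, check_valence = FALSE)
  mk <- locate_markers(working, mol)
  mk <- mk[order(mk$span_start), , drop = FALSE]
  stopifnot(marker_index >= 1L, marker_index <= nrow(mk))
  row <- mk[marker_index, ]
  # delete the active marker span from the string
  w2 <- paste0(substr(working, 1L, row$span_start - 1L),
               substr(working, row$span_end + 1L, nchar(working)))
  # attachment atom ordinal in w2: its ordinal in `working` minus the dummy
  # (and any atoms inside the removed span, which holds only the dummy)
  dummy_atoms <- which(mol$atoms$dummy)
  active_dummy <- dummy_atoms[order(mol$atoms$start[dummy_atoms])][marker_index]
  a <- row$attach_atom
  a2 <- if (active_dummy < a) a - 1L else a

  cands <- if (optimise) {
    reversed_variants(w2, a2 - 1L, k = k_variants)
  } else {
    rooted_reversed(w2, a2 - 1L)
  }
  stripped <- lapply(cands, strip_markers)
  prompts <- vapply(stripped, `[[`, character(1), "core")
  pick <- 1L
  cand_nll <- rep(NA_real_, length(prompts))
  if (optimise && length(prompts) > 1L) {
    stopifnot(is.function(nll_fn))
    cand_nll <- nll_fn(prompts, eos = FALSE)
    pick <- which.min(cand_nll)  # ties: first occurrence
  }
  list(prompt = prompts[pick], ledger = stripped[[pick]]$ledger,
       candidates = prompts, cand_nll = cand_nll)
}

#' Build the prompt for one attachment point of a working molecule
#'
#' Public wrapper over the per-iteration prompt construction used by
#' [decorate()]: the chosen marker is removed, the molecule rooted at its
#' attachment atom and reversed so that atom comes last, remaining markers
#' stripped (ledger recorded), and — with `optimise` — the variant with the
#' lowest model NLL among `k_variants` enumerated rooted randomized forms
#' is returned.
#'
#' @param working Marker SMILES of the current molecule.
#' @param marker_index 1-based marker index (appearance order).
#' @param model A `promptclm_model` or callback list (needed for `optimise`).
#' @param optimise Pick the most likely variant instead of the canonical one.
#' @param k_variants Number of variants enumerated under `optimise`.
#' @return list with `prompt` (SMILES ending at the attachment atom, all
#'   markers removed), `ledger`, `candidates`, `cand_nll`.
#' @export
build_prompt <- function(working, marker_index = 1L, model = NULL,
                         optimise = FALSE, k_variants = 10L) {
  nll_fn <- if (!is.null(model)) as_callbacks(model)$nll_fn
  build_prompt_for(working, marker_index, optimise, k_variants, nll_fn)
}

new_generation_result <- function(final, valid, records, mode, extra = list()) {
  c(list(smiles = final, valid = valid, records = records, mode = mode), extra)
}

results_frame <- function(results) {
  data.frame(
    smiles = vapply(results, `[[`, character(1), "smiles"),
    valid = vapply(results, `[[`, logical(1), "valid"),
    iterations = vapply(results, function(r) nrow(r$records), integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Scaffold decoration by iterative prompting
#'
#' For each attempt: select an attachment point, rewrite the molecule so
#' that atom is last (other markers stripped, ledger kept), let the CLM
#' extend the string until EOS, reinsert the remaining markers, and repeat
#' until no markers remain. An immediate EOS leaves the site hydrogen-
#' capped, which is legal; unterminated (max-length) completions and
#' unparsable intermediates mark the attempt invalid.
#'
#' @param model A `promptclm_model` or callback list.
#' @param scaffold Marker SMILES or `attachment_spec` with >= 1 site.
#' @param n Number of decorated molecules to attempt.
#' @param strategy Attachment selection: `"canonical"` or `"shuffle"`.
#' @param optimise Use likelihood-optimised prompt variants.
#' @param k_variants Variants per optimisation.
#' @param max_len,temperature Sampling controls (used when `model` is a
#'   fitted model).
#' @param seed Optional seed local to the call.
#' @return An object of class `generation_set`: a data.frame-like summary
#'   (`$summary`) plus per-attempt records (`$results`), each holding the
#'   per-iteration prompt, completion and sampler NLL.
#' @export
decorate <- function(model, scaffold, n = 1L,
                     strategy = c("canonical", "shuffle"),
                     optimise = FALSE, k_variants = 10L,
                     max_len = 100L, temperature = 1, seed = NULL) {
  strategy <- match.arg(strategy)
  spec <- as_attachment_spec(scaffold)
  if (spec$n_sites == 0L) {
    stop(structure(class = c("no_attachment_points_error", "error", "condition"),
                   list(message = paste("scaffold has no attachment points;",
                                        "use plain de novo sampling (clm_sample)"),
                        call = NULL)))
  }
  cb <- as_callbacks(model, max_len = max_len, temperature = temperature)
  if (!is.null(seed)) { old <- get_rng_state(); on.exit(restore_rng_state(old)); set.seed(seed) }

  working <- rep(spec$source_smiles, n)
  remaining <- rep(spec$n_sites, n)
  failed <- rep(FALSE, n)
  recs <- rep(list(data.frame()), n)

  while (any(!failed & remaining > 0L)) {
    active <- which(!failed & remaining > 0L)
    prompts <- character(length(active))
    ledgers <- vector("list", length(active))
    sites <- integer(length(active))
    for (j in seq_along(active)) {
      i <- active[j]
      sites[j] <- select_attachment(remaining[i], strategy)
      bp <- tryCatch(
        build_prompt_for(working[i], sites[j], optimise, k_variants, cb$nll_fn),
        error = function(e) NULL)
      if (is.null(bp)) { failed[i] <- TRUE; prompts[j] <- NA_character_; next }
      prompts[j] <- bp$prompt
      ledgers[[j]] <- bp$ledger
    }
    ok <- !is.na(prompts)
    if (!any(ok)) break
    samp <- cb$sample_fn(prompts[ok])
    oki <- which(ok)
    for (jj in seq_along(oki)) {
      j <- oki[jj]; i <- active[j]
      full <- samp$smiles[jj]
      recs[[i]] <- rbind(recs[[i]], data.frame(
        iteration = nrow(recs[[i]]) + 1L, marker = sites[j],
        prompt = prompts[j], completion = samp$completion[jj],
        full = full, nll = samp$nll[jj],
        terminated = samp$terminated[jj], stringsAsFactors = FALSE))
      if (!samp$terminated[jj]) { failed[i] <- TRUE; next }
      wm <- tryCatch(reinsert_markers(full, ledgers[[j]]), error = function(e) NA)
      if (is.na(wm) ||
          inherits(tryCatch(parse_smiles_graph(wm, check_valence = TRUE),
                            error = identity), "error")) {
        failed[i] <- TRUE
        next
      }
      working[i] <- wm
      remaining[i] <- remaining[i] - 1L
    }
  }
  fin <- ifelse(failed, NA_character_, working)
  valid <- !failed & smiles_valid(ifelse(is.na(fin), "", fin)) &
    vapply(seq_len(n), function(i) failed[i] ||
             contains_core(fin[i], spec$core_smiles), logical(1))
  results <- lapply(seq_len(n), function(i) {
    new_generation_result(fin[i], valid[i], recs[[i]], "decorate",
                          list(update_smiles = fin[i], scaffold = spec$source_smiles))
  })
  structure(list(summary = results_frame(results), results = results,
                 task = "decorate", strategy = strategy, optimise = optimise),
            class = "generation_set")
}

#' @export
print.generation_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<generation_set> %s: %d attempts, %.1f%% valid\n",
              x$task, nrow(s), 100 * mean(s$valid)))
  print(utils::head(s, 10), row.names = FALSE)
  if (nrow(s) > 10) cat("...\n")
  invisible(x)
}

# root a 1-site fragment so its attachment atom is FIRST (not reversed);
# optionally enumerate randomized variants
fragment_head_first <- function(spec, k = 1L) {
  stopifnot(spec$n_sites == 1L)
  a0 <- spec$sites[1]
  base <- as.character(root_at_atom(spec$core_smiles, a0, randomize = FALSE))
  out <- base
  if (k > 1L) {
    mol <- parse_smiles_graph(spec$core_smiles, check_valence = FALSE)
    tries <- 0L
    while (length(out) < k && tries < 10L * k) {
      tries <- tries + 1L
      cand <- as.character(write_smiles_graph(mol, root = a0 + 1L, randomize = TRUE))
      if (!(cand %in% out)) out <- c(out, cand)
    }
  }
  out
}

renumber_ring_digits <- function(fragment, used_digits) {
  ftoks <- smiles_tokens(fragment)
  ftype <- attr(ftoks, "type")
  fdig <- digits_used(ftoks)
  if (length(fdig) == 0L) return(fragment)
  fresh <- next_free_digits(used_digits, length(fdig))
  map <- stats::setNames(fresh, as.character(fdig))
  for (i in which(ftype == "ring")) {
    d <- if (startsWith(ftoks[i], "%")) as.integer(substr(ftoks[i], 2L, 3L)) else as.integer(ftoks[i])
    ftoks[i] <- ring_digit_text(map[[as.character(d)]])
  }
  paste0(ftoks, collapse = "")
}

#' Link two fragments with a generated linker
#'
#' One fragment (chosen canonically or at random) is rooted at its
#' attachment atom and reversed into the prompt; the CLM generates a de
#' novo linker until EOS; the second fragment, rooted so its attachment
#' atom comes first (not reversed), is concatenated after renumbering its
#' ring digits. The recorded `update_smiles` is the initial fragment plus
#' de novo linker (without the second fragment), which is the sequence used
#' for single-mode RL updates.
#'
#' @inheritParams decorate
#' @param fragments Two marker SMILES (or `attachment_spec`s), one
#'   attachment point each.
#' @return A `generation_set`.
#' @export
link_pair <- function(model, fragments, n = 1L,
                      strategy = c("canonical", "shuffle"),
                      optimise = FALSE, k_variants = 10L,
                      max_len = 100L, temperature = 1, seed = NULL) {
  strategy <- match.arg(strategy)
  specs <- lapply(fragments, as_attachment_spec)
  if (length(specs) != 2L || any(vapply(specs, `[[`, integer(1), "n_sites") != 1L)) {
    stop(structure(class = c("fragment_spec_error", "error", "condition"),
                   list(message = "link_pair needs exactly 2 fragments with 1 attachment point each",
                        call = NULL)))
  }
  cb <- as_callbacks(model, max_len = max_len, temperature = temperature)
  if (!is.null(seed)) { old <- get_rng_state(); on.exit(restore_rng_state(old)); set.seed(seed) }

  ord <- lapply(seq_len(n), function(i) {
    if (strategy == "shuffle") sample(2L) else 1:2
  })
  prompts <- character(n)
  for (i in seq_len(n)) {
    s1 <- specs[[ord[[i]][1]]]
    cands <- enumerate_reversed_variants(s1, 1L, k = if (optimise) k_variants else 1L)
    pick <- 1L
    if (optimise && length(cands) > 1L) pick <- which.min(cb$nll_fn(cands, eos = FALSE))
    prompts[i] <- cands[pick]
  }
  samp <- cb$sample_fn(prompts)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    s2 <- specs[[ord[[i]][2]]]
    de_novo <- samp$smiles[i]  # prompt + linker, EOS removed by decoding
    rec <- data.frame(iteration = 1L, marker = ord[[i]][1], prompt = prompts[i],
                      completion = samp$completion[i], full = de_novo,
                      nll = samp$nll[i], terminated = samp$terminated[i],
                      stringsAsFactors = FALSE)
    if (!samp$terminated[i]) {
      results[[i]] <- new_generation_result(NA_character_, FALSE, rec, "link_pair",
                                            list(update_smiles = NA_character_))
      next
    }
    used <- tryCatch(digits_used(smiles_tokens(de_novo)), error = function(e) integer(0))
    f2cands <- fragment_head_first(s2, k = if (optimise) k_variants else 1L)
    fulls <- vapply(f2cands, function(fc)
      paste0(de_novo, renumber_ring_digits(fc, used)), character(1), USE.NAMES = FALSE)
    pick <- 1L
    if (optimise && length(fulls) > 1L) {
      nl <- tryCatch(cb$nll_fn(fulls, eos = TRUE), error = function(e) rep(Inf, length(fulls)))
      if (all(is.infinite(nl))) pick <- 1L else pick <- which.min(nl)
    }
    full <- fulls[pick]
    ok <- smiles_valid(full) &&
      contains_core(full, specs[[1]]$core_smiles) &&
      contains_core(full, specs[[2]]$core_smiles)
    results[[i]] <- new_generation_result(full, ok, rec, "link_pair",
                                          list(update_smiles = de_novo,
                                               order = ord[[i]]))
  }
  structure(list(summary = results_frame(results), results = results,
                 task = "link_pair", strategy = strategy, optimise = optimise),
            class = "generation_set")
}

#' Likelihood-scored insertion site selection
#'
#' Enumerates [insert_branch()] of the fragment at every candidate atom
#' (free valence, not forbidden), scores each full candidate string with
#' the model, and returns the highest-likelihood (minimum NLL) insertion;
#' ties break to the lowest atom index. Candidates whose strings the model
#' cannot tokenize score `Inf`.
#'
#' @param working Current molecule SMILES.
#' @param fragment A 1-site `attachment_spec` (or marker SMILES).
#' @param forbidden 0-based atom ordinals excluded from insertion.
#' @param model Model or callback list providing `nll_fn`.
#' @return list(`atom` 0-based index, `smiles` the chosen candidate,
#'   `nll`, `frag_atoms` 1-based ordinals of inserted atoms, plus all
#'   scored `candidates`).
#' @export
select_insertion_site <- function(working, fragment, forbidden = integer(0),
                                  model = NULL) {
  spec <- as_attachment_spec(fragment)
  stopifnot(spec$n_sites == 1L)
  cb <- if (!is.null(model)) as_callbacks(model)
  mol <- parse_smiles_graph(working)
  fv <- free_valence(mol)
  cand_atoms <- setdiff(which(fv >= 1) - 1L, forbidden)
  if (length(cand_atoms) == 0L) {
    stop(structure(class = c("no_insertion_site_error", "error", "condition"),
                   list(message = "no candidate insertion atoms (free valence, non-forbidden)",
                        call = NULL)))
  }
  fhead <- fragment_head_first(spec, k = 1L)
  cands <- lapply(cand_atoms, function(a0) {
    tryCatch(insert_branch(working, a0, fhead), error = function(e) NULL)
  })
  keep <- !vapply(cands, is.null, logical(1))
  cand_atoms <- cand_atoms[keep]; cands <- cands[keep]
  if (length(cands) == 0L) {
    stop(structure(class = c("no_insertion_site_error", "error", "condition"),
                   list(message = "every candidate insertion failed", call = NULL)))
  }
  strs <- vapply(cands, as.character, character(1))
  nll <- rep(Inf, length(strs))
  if (!is.null(cb)) {
    nll <- vapply(strs, function(s)
      tryCatch(cb$nll_fn(s, eos = TRUE), error = function(e) Inf), numeric(1),
      USE.NAMES = FALSE)
  }
  pick <- which.min(nll)  # ties: lowest atom index (candidates are ordered)
  list(atom = cand_atoms[pick], smiles = strs[pick], nll = nll[pick],
       frag_atoms = attr(cands[[pick]], "frag_atoms"),
       candidates = data.frame(atom = cand_atoms, smiles = strs, nll = nll,
                               stringsAsFactors = FALSE))
}

#' Link three or more fragments by likelihood-scored insertion
#'
#' The initial fragment (canonical or shuffled) is rooted, reversed and
#' completed into a full de novo molecule by the CLM. Each remaining
#' fragment is then inserted at the likelihood-optimal linker atom —
#' skipping fragments whose core the molecule already contains — with the
#' atoms of every placed fragment excluded from later insertions, which
#' permits non-linear (branched) linking topologies.
#'
#' @inheritParams decorate
#' @param fragments Three or more 1-site marker SMILES / `attachment_spec`s.
#' @return A `generation_set`; per-result `frag_atom_sets` records the
#'   0-based atom ordinals attributed to each fragment.
#' @export
link_multi <- function(model, fragments, n = 1L,
                       strategy = c("canonical", "shuffle"),
                       optimise = FALSE, k_variants = 10L,
                       max_len = 100L, temperature = 1, seed = NULL) {
  strategy <- match.arg(strategy)
  specs <- lapply(fragments, as_attachment_spec)
  if (length(specs) < 3L || any(vapply(specs, `[[`, integer(1), "n_sites") != 1L)) {
    stop(structure(class = c("fragment_spec_error", "error", "condition"),
                   list(message = "link_multi needs >= 3 fragments with 1 attachment point each",
                        call = NULL)))
  }
  cb <- as_callbacks(model, max_len = max_len, temperature = temperature)
  if (!is.null(seed)) { old <- get_rng_state(); on.exit(restore_rng_state(old)); set.seed(seed) }
  m <- length(specs)

  ords <- lapply(seq_len(n), function(i) if (strategy == "shuffle") sample(m) else seq_len(m))
  prompts <- character(n)
  for (i in seq_len(n)) {
    s1 <- specs[[ords[[i]][1]]]
    cands <- enumerate_reversed_variants(s1, 1L, k = if (optimise) k_variants else 1L)
    pick <- if (optimise && length(cands) > 1L) which.min(cb$nll_fn(cands, eos = FALSE)) else 1L
    prompts[i] <- cands[pick]
  }
  samp <- cb$sample_fn(prompts)
  results <- vector("list", n)
  for (i in seq_len(n)) {
    ordi <- ords[[i]]
    s1 <- specs[[ordi[1]]]
    rec <- data.frame(iteration = 1L, marker = ordi[1], prompt = prompts[i],
                      completion = samp$completion[i], full = samp$smiles[i],
                      nll = samp$nll[i], terminated = samp$terminated[i],
                      stringsAsFactors = FALSE)
    fail <- function(extra = list()) {
      results[[i]] <<- new_generation_result(NA_character_, FALSE, rec, "link_multi",
                                             c(list(update_smiles = samp$smiles[i]), extra))
    }
    if (!samp$terminated[i] || !smiles_valid(samp$smiles[i])) { fail(); next }
    working <- samp$smiles[i]
    n1 <- parse_smiles_graph(prompts[i], check_valence = FALSE)$n
    frag_sets <- list()
    frag_sets[[as.character(ordi[1])]] <- seq_len(n1) - 1L
    forbidden <- seq_len(n1) - 1L
    bad <- FALSE
    for (fi in ordi[-1]) {
      sp <- specs[[fi]]
      hits <- tryCatch(match_substructure(working, sp$core_smiles),
                       error = function(e) list())
      if (length(hits) > 0L) {
        # fragment already generated de novo: skip insertion, claim atoms
        atoms0 <- hits[[1]] - 1L
        frag_sets[[as.character(fi)]] <- atoms0
        forbidden <- union(forbidden, atoms0)
        next
      }
      ins <- tryCatch(select_insertion_site(working, sp, forbidden, model = cb),
                      error = function(e) NULL)
      if (is.null(ins) || is.infinite(ins$nll)) { bad <- TRUE; break }
      shift_at <- min(ins$frag_atoms) - 1L  # ordinals >= this shift up
      nshift <- length(ins$frag_atoms)
      frag_sets <- lapply(frag_sets, function(v) ifelse(v >= shift_at, v + nshift, v))
      forbidden <- unlist(frag_sets, use.names = FALSE)
      frag_sets[[as.character(fi)]] <- ins$frag_atoms - 1L
      forbidden <- union(forbidden, ins$frag_atoms - 1L)
      working <- ins$smiles
    }
    if (bad) { fail(list(frag_atom_sets = frag_sets)); next }
    ok <- smiles_valid(working) &&
      all(vapply(specs, function(sp) contains_core(working, sp$core_smiles), logical(1)))
    results[[i]] <- new_generation_result(
      working, ok, rec, "link_multi",
      list(update_smiles = samp$smiles[i], order = ordi, frag_atom_sets = frag_sets))
  }
  structure(list(summary = results_frame(results), results = results,
                 task = "link_multi", strategy = strategy, optimise = optimise),
            class = "generation_set")
}

#' Link fragments (dispatching on fragment count)
#'
#' Two fragments run the pair-linking algorithm; three or more run
#' insertion-based multi-fragment linking.
#'
#' @inheritParams link_multi
#' @export
link_fragments <- function(model, fragments, n = 1L, ...) {
  if (length(fragments) < 2L) {
    stop(structure(class = c("fragment_spec_error", "error", "condition"),
                   list(message = "need at least 2 fragments", call = NULL)))
  }
  if (length(fragments) == 2L) link_pair(model, fragments, n = n, ...)
  else link_multi(model, fragments, n = n, ...)
}
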