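# Seeded synthetic SMILES corpus generation and curated toy scaffolds /
# fragments. The generator grows random molecular graphs (acyclic growth
# plus ring templates) and writes them with the package's own writer, so
# every emitted string is valid by construction; validity is nevertheless
# re-checked before a molecule is accepted.

.RING_TEMPLATES <- list(
  benzene   = list(elem = c("c", "c", "c", "c", "c", "c"), arom = TRUE),
  benzene2  = list(elem = c("c", "c", "c", "c", "c", "c"), arom = TRUE),
  pyridine  = list(elem = c("n", "c", "c", "c", "c", "c"), arom = TRUE),
  cyclopentane = list(elem = c("C", "C", "C", "C", "C"), arom = FALSE),
  cyclohexane  = list(elem = c("C", "C", "C", "C", "C", "C"), arom = FALSE)
)

.MAX_VAL <- c(C = 4, N = 3, O = 2, F = 1, S = 2, c = 4, n = 3, o = 2, s = 2)

# one random molecule as a smiles_graph-compatible structure
grow_molecule <- function(size, ring_prob, branch_prob, hetero) {
  elem <- "C"; arom <- FALSE
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                      aromatic = logical(0), ring = logical(0))
  used <- 0  # valence used per atom
  add_atom <- function(e, a) { elem <<- c(elem, e); arom <<- c(arom, a); used <<- c(used, 0) }
  add_bond <- function(i, j, o = 1L, ar = FALSE) {
    bonds <<- rbind(bonds, data.frame(a1 = i, a2 = j, order = o,
                                      aromatic = ar, ring = FALSE))
    used[i] <<- used[i] + o; used[j] <<- used[j] + o
  }
  cap <- function(i) {
    v <- .MAX_VAL[[elem[i]]] - (if (arom[i]) 1 else 0)
    v - used[i]
  }
  while (length(elem) < size) {
    open <- which(vapply(seq_along(elem), cap, numeric(1)) >= 1)
    if (length(open) == 0L) break
    # chain-biased growth: usually extend the newest open atom, sometimes
    # branch from a random earlier one
    host <- if (stats::runif(1) < branch_prob) {
      open[sample.int(length(open), 1L)]
    } else {
      open[length(open)]
    }
    if (stats::runif(1) < ring_prob && length(elem) + 3L <= size + 2L) {
      tpl <- .RING_TEMPLATES[[sample.int(length(.RING_TEMPLATES), 1L)]]
      base <- length(elem)
      for (k in seq_along(tpl$elem)) add_atom(tpl$elem[k], tpl$arom)
      m <- length(tpl$elem)
      for (k in seq_len(m)) {
        add_bond(base + k, base + (k %% m) + 1L, 1L, tpl$arom)
      }
      # aromatic ring bonds consume 1 each; pi accounted by cap()
      # pick a template carbon with capacity as the attachment
      att <- base + which(tpl$elem %in% c("c", "C"))[1]
      add_bond(host, att, 1L, FALSE)
    } else {
      e <- if (stats::runif(1) < 0.22) hetero[sample.int(length(hetero), 1L)] else "C"
      add_atom(e, FALSE)
      j <- length(elem)
      o <- if (stats::runif(1) < 0.08 && cap(host) >= 2 && cap(j) >= 2 &&
               !elem[j] %in% c("F") && !arom[host]) 2L else 1L
      add_bond(host, j, o, FALSE)
    }
  }
  n <- length(elem)
  atoms <- data.frame(element = elem, aromatic = arom, charge = 0L,
                      hcount = 0L, isotope = 0L, bracket = FALSE,
                      dummy = FALSE, token = NA_integer_,
                      start = NA_integer_, end = NA_integer_,
                      implicit_h = 0L, stringsAsFactors = FALSE)
  structure(list(atoms = atoms, bonds = bonds, n = n, tokens = NULL,
                 smiles = NA_character_), class = "smiles_graph")
}

#' Generate a synthetic SMILES corpus
#'
#' Seed-deterministic random molecules with rings, branches and heteroatoms,
#' in a fixed small token vocabulary — a stand-in training corpus so that
#' pre-training, decoration, linking and RL can all be exercised without any
#' external dataset.
#'
#' @param n Number of unique molecules.
#' @param seed RNG seed (local to the call).
#' @param size_range Heavy atom count range.
#' @param ring_prob Probability that a growth step attaches a ring template.
#' @param branch_prob Growth-order randomization bias.
#' @param hetero Heteroatom palette for acyclic growth.
#' @return Character vector of `n` unique valid SMILES.
#' @export
generate_corpus <- function(n, seed = 1L, size_range = c(5L, 14L),
                            ring_prob = 0.15, branch_prob = 0.25,
                            hetero = c("N", "O", "F", "S")) {
  stopifnot(n >= 1L, length(size_range) == 2L, size_range[1] >= 3L)
  if (size_range[2] < size_range[1]) {
    stop(structure(class = c("corpus_spec_error", "error", "condition"),
                   list(message = "infeasible size range", call = NULL)))
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  out <- character(0)
  batch <- max(64L, ceiling(n / 4L))
  guard <- 0L
  while (length(out) < n && guard < 200L) {
    guard <- guard + 1L
    cand <- vapply(seq_len(batch), function(i) {
      size <- sample(size_range[1]:size_range[2], 1L)
      g <- grow_molecule(size, ring_prob, branch_prob, hetero)
      write_smiles_graph(g, root = chain_root(g), chain_order = TRUE)
    }, character(1))
    cand <- setdiff(unique(cand), out)
    if (length(cand) > 0L) {
      ok <- smiles_valid(cand)
      out <- c(out, cand[ok])
    }
  }
  if (length(out) < n) {
    stop(structure(class = c("corpus_spec_error", "error", "condition"),
                   list(message = sprintf("could only generate %d/%d unique molecules",
                                          length(out), n), call = NULL)))
  }
  out[seq_len(n)]
}

#' Curated toy scaffolds and fragments
#'
#' Small named marker-SMILES inputs used across examples and tests: a
#' two-site meta-substituted benzene scaffold, a one-site scaffold, a
#' cyclopropane/pyrazine two-fragment linking pair, and a four-fragment set
#' for multi-fragment linking.
#'
#' @return Named list: `meta_benzene`, `single_site`, `pair` (length 2, the
#'   cyclopropane/pyrazine pair), `four` (length 4, chemically clean
#'   fragments for insertion linking), and `four_target` (a hand-built
#'   molecule containing all four cores, used as a similarity reference).
#' @export
toy_cases <- function() {
  list(
    meta_benzene = "c1c(*)cc(*)cc1",
    single_site = "c1ccc(*)cc1",
    pair = c("C1C(*)C1", "n1(*)ccncc1"),
    four = c("C1C(*)C1", "c1ccc(*)cc1", "OC(*)", "NC(*)=O"),
    four_target = "NC(=O)CC(CO)Cc1ccc(C2CC2)cc1"
  )
}
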