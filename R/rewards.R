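# Reward functions for reinforcement learning: binary valid+unique,
# fingerprint Tanimoto similarity to a reference, linker property scores
# (length, linearity, flexibility), band rewards, and a weighted pipeline.
# All rewards map SMILES to [0, 1]; invalid molecules score 0.

#' A run-scoped memory for uniqueness accounting
#'
#' @return An environment holding the set of canonical SMILES seen so far.
#' @export
reward_memory <- function() {
  e <- new.env(parent = emptyenv())
  e$seen <- character(0)
  e
}

#' Binary valid-and-unique reward
#'
#' 1 when the molecule parses and its canonical SMILES has not been seen
#' before within the run memory; 0 when invalid or a repeat. The memory is
#' updated in place.
#'
#' @param batch Character vector of SMILES.
#' @param memory A [reward_memory()] (persist it across batches to score
#'   uniqueness over a whole run).
#' @return Numeric vector of 0/1 scores.
#' @export
valid_unique_reward <- function(batch, memory = reward_memory()) {
  can <- canonicalize_smiles(batch)
  out <- numeric(length(batch))
  for (i in seq_along(batch)) {
    if (is.na(can[i])) next
    if (can[i] %in% memory$seen) next
    memory$seen <- c(memory$seen, can[i])
    out[i] <- 1
  }
  out
}

#' Tanimoto similarity reward to a reference compound
#'
#' Circular (ECFP4) fingerprints via Open Babel; Tanimoto is the
#' intersection-over-union of the on-bit sets. Molecules that fail to parse
#' score 0.
#'
#' @param smiles Character vector of SMILES.
#' @param reference Reference SMILES.
#' @param type Open Babel fingerprint type (default `"ECFP4"`; `"FP2"` is a
#'   faster path-based alternative).
#' @return Numeric vector of similarities in [0, 1].
#' @export
tanimoto_reward <- function(smiles, reference, type = "ECFP4") {
  out <- numeric(length(smiles))
  ok <- which(smiles_valid(smiles))
  if (length(ok) == 0L) return(out)
  all <- c(reference, smiles[ok])
  sdf <- ChemmineR::smiles2sdf(stats::setNames(all, paste0("m", seq_along(all))))
  fps <- ChemmineR::fingerprintOB(sdf, type)
  sims <- ChemmineR::fpSim(fps[1], fps, method = "Tanimoto", sorted = FALSE,
                           addone = 0)  # plain |A∩B| / |A∪B|
  out[ok] <- as.numeric(sims[-1])
  out
}

#' Linker properties of a linked molecule
#'
#' Identifies the atoms of each fragment core by (induced) subgraph
#' matching, takes the remaining atoms as the linker, and reports: the
#' linker heavy-atom count; the shortest topological path between the two
#' junction atoms through the linker (counted in linker atoms); linearity =
#' path length / linker size (1 for an unbranched acyclic linker, by
#' convention 1 for an empty linker); and flexibility = the fraction of
#' linker-internal bonds that are rotatable (acyclic single bonds between
#' non-terminal heavy atoms; 0 when the linker has no internal bonds).
#' When several disjoint fragment placements exist the assignment
#' minimizing the linker size is used. The linearity measure is this
#' package's operational stand-in; there is no community-standard formula.
#'
#' @param full SMILES of the linked molecule.
#' @param fragments List of 1-site fragments (marker SMILES or
#'   `attachment_spec`).
#' @return list(`n_atoms`, `path_len`, `linearity`, `flexibility`,
#'   `linker_atoms` 0-based ordinals).
#' @export
linker_props <- function(full, fragments) {
  specs <- lapply(fragments, as_attachment_spec)
  mol <- parse_smiles_graph(full)
  hits <- lapply(specs, function(sp) match_substructure(mol, sp$core_smiles))
  if (any(vapply(hits, length, integer(1)) == 0L)) {
    stop(structure(class = c("containment_error", "error", "condition"),
                   list(message = "a fragment core is not contained in the molecule",
                        call = NULL)))
  }
  # choose a pairwise-disjoint assignment maximizing covered atoms
  best <- NULL
  pick <- function(i, chosen, covered) {
    if (i > length(hits)) {
      if (is.null(best) || length(covered) > length(attr(best, "covered"))) {
        b <- chosen; attr(b, "covered") <- covered; best <<- b
      }
      return(invisible())
    }
    for (h in hits[[i]]) {
      if (length(intersect(h, covered)) == 0L) pick(i + 1L, c(chosen, list(h)), c(covered, h))
    }
  }
  pick(1L, list(), integer(0))
  if (is.null(best)) {
    stop(structure(class = c("containment_error", "error", "condition"),
                   list(message = "fragment cores overlap in every placement", call = NULL)))
  }
  frag_atoms <- attr(best, "covered")
  linker <- setdiff(seq_len(mol$n), frag_atoms)
  nl <- length(linker)
  g <- igraph::make_graph(edges = as.vector(t(as.matrix(mol$bonds[, c("a1", "a2")]))),
                          n = mol$n, directed = FALSE)
  if (nl == 0L) {
    return(list(n_atoms = 0L, path_len = 0L, linearity = 1, flexibility = 0,
                linker_atoms = integer(0)))
  }
  # junction atoms: for each of the two fragments the atom bonded to the linker
  junctions <- vapply(best[1:2], function(h) {
    for (k in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[k, ]
      if (b$a1 %in% h && b$a2 %in% linker) return(b$a1)
      if (b$a2 %in% h && b$a1 %in% linker) return(b$a2)
    }
    NA_integer_
  }, integer(1))
  path_len <- nl
  if (!anyNA(junctions)) {
    keep <- sort(unique(c(linker, junctions)))  # induced_subgraph keeps sorted order
    sg <- igraph::induced_subgraph(g, keep)
    j1 <- match(junctions[1], keep); j2 <- match(junctions[2], keep)
    d <- tryCatch(igraph::distances(sg, v = j1, to = j2)[1, 1], error = function(e) Inf)
    if (is.finite(d)) path_len <- as.integer(d) - 1L  # atoms between junctions
    path_len <- max(path_len, 0L)
  }
  linearity <- if (nl == 0L) 1 else max(min(path_len / nl, 1), 0)
  # rotatable bonds among linker-internal bonds
  inner <- which(mol$bonds$a1 %in% linker & mol$bonds$a2 %in% linker)
  flex <- 0
  if (length(inner) > 0L) {
    bridges_e <- igraph::bridges(g)
    bridge_idx <- as.integer(bridges_e)
    degs <- igraph::degree(g)
    rot <- vapply(inner, function(k) {
      b <- mol$bonds[k, ]
      (k %in% bridge_idx) && b$order == 1L && !b$aromatic &&
        degs[b$a1] > 1L && degs[b$a2] > 1L
    }, logical(1))
    flex <- mean(rot)
  }
  list(n_atoms = nl, path_len = as.integer(path_len), linearity = linearity,
       flexibility = flex, linker_atoms = sort(linker) - 1L)
}

#' Band reward with linear margins
#'
#' 1 inside the closed interval `[low, high]`, decaying linearly to 0 over
#' `margin` outside it.
#'
#' @param value Numeric vector.
#' @param low,high Band edges (`low <= high`).
#' @param margin Width of the linear ramp outside the band.
#' @return Scores in [0, 1].
#' @export
range_reward <- function(value, low, high, margin = 0.2) {
  stopifnot(low <= high, margin > 0)
  below <- pmax(low - value, 0)
  above <- pmax(value - high, 0)
  pmax(1 - (below + above) / margin, 0)
}

#' Combine scorers into a weighted reward pipeline
#'
#' @param scorers List of `list(fn = function(smiles) ..., weight = w)`;
#'   each `fn` must return scores in [0, 1].
#' @return A reward function `function(smiles)` returning the weighted
#'   arithmetic mean of the component scores.
#' @export
reward_pipeline <- function(scorers) {
  w <- vapply(scorers, function(s) s$weight %||% 1, numeric(1))
  function(smiles) {
    sc <- vapply(scorers, function(s) s$fn(smiles), numeric(length(smiles)))
    if (is.null(dim(sc))) sc <- matrix(sc, nrow = length(smiles))
    as.numeric(sc %*% w / sum(w))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
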