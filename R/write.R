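# Molecular graph -> SMILES writer.
#
# Depth-first traversal from a chosen root atom. With randomize = FALSE the
# neighbour order is ascending atom id, giving a deterministic rooted form;
# with randomize = TRUE neighbour order is shuffled under the session RNG,
# enumerating alternative rooted representations of the same graph.

bond_symbol <- function(mol, k, explicit_single = FALSE) {
  b <- mol$bonds[k, ]
  both_arom <- mol$atoms$aromatic[b$a1] && mol$atoms$aromatic[b$a2]
  if (b$aromatic) return(if (both_arom) "" else ":")
  if (b$order == 2L) return("=")
  if (b$order == 3L) return("#")
  if (b$order == 1L && both_arom) return("-")  # explicit single between aromatics
  if (explicit_single) return("-")
  ""
}

atom_token_text <- function(mol, a) {
  at <- mol$atoms[a, ]
  if (at$dummy && !at$bracket) return("*")
  if (!at$bracket) return(at$element)
  paste0("[",
         if (at$isotope > 0L) at$isotope else "",
         at$element,
         if (at$hcount == 1L) "H" else if (at$hcount > 1L) paste0("H", at$hcount) else "",
         if (at$charge > 0L) paste0("+", if (at$charge > 1L) at$charge else "") else "",
         if (at$charge < 0L) paste0("-", if (at$charge < -1L) -at$charge else "") else "",
         "]")
}

ring_digit_text <- function(d) {
  if (d <= 9L) as.character(d) else sprintf("%%%02d", d)
}

# Write a SMILES for (a connected subset of) the graph.
# root: 1-based atom id; keep: optional atom id subset (must be connected and
# contain root). Returns the SMILES string with attribute "atom_order": the
# original atom ids in output appearance order.
write_smiles_graph <- function(mol, root = 1L, randomize = FALSE, keep = NULL,
                               chain_order = FALSE) {
  if (root < 1L || root > mol$n) {
    stop(structure(class = c("smiles_index_error", "error", "condition"),
                   list(message = sprintf("atom index %d out of range (0..%d)",
                                          root - 1L, mol$n - 1L), call = NULL)))
  }
  keepmask <- rep(TRUE, mol$n)
  if (!is.null(keep)) { keepmask[] <- FALSE; keepmask[keep] <- TRUE }
  if (!keepmask[root]) stop("root atom not in kept subset")
  adj <- adjacency(mol)

  # pass 1: DFS to fix child order, tree edges and ring-closure (back) edges
  visited <- rep(FALSE, mol$n)
  children <- vector("list", mol$n)    # list of c(child, bond) in visit order
  closures <- vector("list", mol$n)    # per atom: bond rows closing back
  emit_order <- integer(0)
  seen_bond <- rep(FALSE, nrow(mol$bonds) + 1L)

  stack <- list(root)
  visited[root] <- TRUE
  dfs <- function(a) {
    emit_order <<- c(emit_order, a)
    nb <- adj[[a]]
    if (is.null(nb)) return(invisible())
    idx <- seq_len(nrow(nb))
    if (randomize && length(idx) > 1L) {
      idx <- sample(idx)
    } else if (chain_order && length(idx) > 1L) {
      # visit small side-chains first so the longest path stays unbranched
      sz <- vapply(idx, function(j) reach_count(adj, nb[j, 1], a, keepmask), integer(1))
      idx <- idx[order(sz, nb[idx, 1])]
    } else {
      idx <- idx[order(nb[idx, 1])]
    }
    for (j in idx) {
      b <- nb[j, 1]; k <- nb[j, 2]
      if (!keepmask[b] || seen_bond[k]) next
      if (visited[b]) {
        seen_bond[k] <<- TRUE
        closures[[a]] <<- c(closures[[a]], k)
      } else {
        seen_bond[k] <<- TRUE
        visited[b] <<- TRUE
        children[[a]] <<- rbind(children[[a]], c(b, k))
        dfs(b)
      }
    }
  }
  dfs(root)

  # ring digit assignment in emit order
  digit_of_bond <- integer(nrow(mol$bonds))
  pool_used <- logical(0)
  open_count <- rep(0L, nrow(mol$bonds) + 1L)
  ring_tokens <- vector("list", mol$n)
  closure_bonds <- unlist(closures)
  if (length(closure_bonds) > 0L) {
    pos <- match(seq_len(mol$n), emit_order)
    free_digits <- rep(TRUE, 99L)
    events <- list()
    for (k in closure_bonds) {
      e <- c(mol$bonds$a1[k], mol$bonds$a2[k])
      first <- e[which.min(pos[e])]; second <- e[which.max(pos[e])]
      events[[length(events) + 1L]] <- list(k = k, first = first, second = second)
    }
    # assign digits greedily in emit order of first endpoints
    ord <- order(vapply(events, function(ev) pos[ev$first], numeric(1)))
    active <- list()  # digit -> closing position
    for (ev in events[ord]) {
      # release digits whose closure already passed
      for (d in names(active)) {
        if (active[[d]] < pos[ev$first]) { free_digits[as.integer(d)] <- TRUE; active[[d]] <- NULL }
      }
      d <- which(free_digits)[1]
      free_digits[d] <- FALSE
      active[[as.character(d)]] <- pos[ev$second]
      digit_of_bond[ev$k] <- d
      sym <- bond_symbol(mol, ev$k)
      ring_tokens[[ev$first]] <- c(ring_tokens[[ev$first]],
                                   paste0(sym, ring_digit_text(d)))
      ring_tokens[[ev$second]] <- c(ring_tokens[[ev$second]], ring_digit_text(d))
    }
  }

  # pass 2: emit
  out_atoms <- integer(0)
  emit <- function(a, inbond) {
    s <- paste0(inbond, atom_token_text(mol, a),
                paste0(ring_tokens[[a]], collapse = ""))
    out_atoms <<- c(out_atoms, a)
    ch <- children[[a]]
    if (!is.null(ch)) {
      nc <- nrow(ch)
      for (j in seq_len(nc)) {
        b <- ch[j, 1]; k <- ch[j, 2]
        sub <- emit(b, bond_symbol(mol, k))
        s <- paste0(s, if (j < nc) paste0("(", sub, ")") else sub)
      }
    }
    s
  }
  res <- emit(root, "")
  attr(res, "atom_order") <- out_atoms
  res
}

# atoms reachable from `from` without passing through `excl`
reach_count <- function(adj, from, excl, keepmask) {
  seen <- c(excl, from)
  queue <- from
  while (length(queue) > 0L) {
    a <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[a]]
    if (is.null(nb)) next
    for (j in seq_len(nrow(nb))) {
      b <- nb[j, 1]
      if (keepmask[b] && !(b %in% seen)) { seen <- c(seen, b); queue <- c(queue, b) }
    }
  }
  length(seen) - 2L
}

# endpoint of (an approximation of) the graph diameter: start of a long chain
chain_root <- function(mol) {
  adj <- adjacency(mol)
  bfs_far <- function(s) {
    dist <- rep(-1L, mol$n); dist[s] <- 0L; q <- s
    while (length(q) > 0L) {
      a <- q[1L]; q <- q[-1L]
      nb <- adj[[a]]
      if (is.null(nb)) next
      for (j in seq_len(nrow(nb))) {
        b <- nb[j, 1]
        if (dist[b] < 0L) { dist[b] <- dist[a] + 1L; q <- c(q, b) }
      }
    }
    which.max(dist)
  }
  bfs_far(bfs_far(1L))
}

# remap a graph to a subset of atoms (order preserved); bonds within subset
subset_graph <- function(mol, keep) {
  keep <- sort(unique(keep))
  newid <- integer(mol$n); newid[keep] <- seq_along(keep)
  b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
  b$a1 <- newid[b$a1]; b$a2 <- newid[b$a2]
  out <- list(atoms = mol$atoms[keep, , drop = FALSE], bonds = b,
              n = length(keep), tokens = NULL, smiles = NA_character_)
  rownames(out$atoms) <- NULL
  class(out) <- "smiles_graph"
  out
}
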