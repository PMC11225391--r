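# Token-level SMILES surgery: depth-0 "unit" structure, string reversal,
# attachment-marker strip/reinsert bookkeeping, and branch insertion.
#
# A depth-0 unit is one main-chain atom together with everything written
# against it: the bond symbol that precedes it, its ring-closure digits
# (with their optional bond prefixes), and its branch groups "(...)" kept
# verbatim. Reversing a SMILES is then a unit-order reversal: branches and
# ring digits travel with their atom, bonds stay between the same atom
# pairs, and branches of the (old) root are hoisted into leading
# dot-components re-attached through fresh ring-closure digits so that the
# old first atom becomes the last atom token of the string.

# parse token vector into depth-0 units; NULL if the string has a depth-0
# dot (multi-component) which unit reversal does not support
smiles_units <- function(toks) {
  type <- attr(toks, "type")
  units <- list()
  cur <- NULL
  pending_bond <- ""
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    ty <- type[i]
    if (ty == "dot") return(NULL)
    if (ty == "bond") {
      nxt <- if (i < n) type[i + 1L] else ""
      if (nxt == "ring") {
        cur$rings <- c(cur$rings, paste0(toks[i], toks[i + 1L]))
        i <- i + 2L
      } else {
        pending_bond <- toks[i]
        i <- i + 1L
      }
    } else if (ty == "atom") {
      if (!is.null(cur)) units[[length(units) + 1L]] <- cur
      cur <- list(prebond = pending_bond, atom = toks[i],
                  rings = character(0), branches = character(0))
      pending_bond <- ""
      i <- i + 1L
    } else if (ty == "ring") {
      if (is.null(cur)) return(NULL)
      cur$rings <- c(cur$rings, toks[i])
      i <- i + 1L
    } else if (ty == "open") {
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        if (type[j] == "open") depth <- depth + 1L
        if (type[j] == "close") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) return(NULL)
      cur$branches <- c(cur$branches, paste0(toks[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (ty == "close") {
      return(NULL)
    } else {
      i <- i + 1L
    }
  }
  if (!is.null(cur)) units[[length(units) + 1L]] <- cur
  units
}

render_unit <- function(u, with_prebond = TRUE) {
  paste0(if (with_prebond) u$prebond else "", u$atom,
         paste0(u$rings, collapse = ""), paste0(u$branches, collapse = ""))
}

# all ring digits (as integers) used anywhere in a token vector
digits_used <- function(toks) {
  type <- attr(toks, "type")
  r <- toks[type == "ring"]
  if (length(r) == 0L) return(integer(0))
  unique(vapply(r, function(x) {
    if (startsWith(x, "%")) as.integer(substr(x, 2L, nchar(x))) else as.integer(x)
  }, integer(1), USE.NAMES = FALSE))
}

next_free_digits <- function(used, k) {
  setdiff(seq_len(99L), used)[seq_len(k)]
}

# Ring-digit bookkeeping for reversal. SMILES pairs digits by sequential
# matching per digit value, so rearranging token order can silently re-pair
# reused digits. The robust scheme: (1) before rearranging, give every pair
# a unique digit (pairing then survives any reordering); (2) after the
# reversed string is assembled, relabel digits canonically — each pair gets
# the lowest digit free over its span, exactly like the writer — restoring
# natural digit usage.
unique_pair_digits <- function(toks) {
  type <- attr(toks, "type")
  ring_idx <- which(type == "ring")
  if (length(ring_idx) == 0L) return(toks)
  digit_of <- function(x) if (startsWith(x, "%")) as.integer(substr(x, 2L, 3L)) else as.integer(x)
  open <- list()
  pair_no <- 0L
  for (i in ring_idx) {
    d <- as.character(digit_of(toks[i]))
    if (is.null(open[[d]])) {
      open[[d]] <- i
    } else {
      pair_no <- pair_no + 1L
      toks[open[[d]]] <- ring_digit_text(pair_no)
      toks[i] <- ring_digit_text(pair_no)
      open[[d]] <- NULL
    }
  }
  attr(toks, "n_pairs") <- pair_no
  toks
}

# canonical relabeling of ring digits in a string whose digits are already
# pairwise unique: lowest free digit per pair, released at closure
relabel_ring_digits <- function(s) {
  toks <- smiles_tokens(s)
  type <- attr(toks, "type")
  ring_idx <- which(type == "ring")
  if (length(ring_idx) == 0L) return(s)
  digit_of <- function(x) if (startsWith(x, "%")) as.integer(substr(x, 2L, 3L)) else as.integer(x)
  free <- rep(TRUE, 99L)
  map <- list()
  for (i in ring_idx) {
    d <- as.character(digit_of(toks[i]))
    if (is.null(map[[d]])) {
      nd <- which(free)[1]
      free[nd] <- FALSE
      map[[d]] <- nd
      toks[i] <- ring_digit_text(nd)
    } else {
      toks[i] <- ring_digit_text(map[[d]])
      free[map[[d]]] <- TRUE
      map[[d]] <- NULL
    }
  }
  paste0(toks, collapse = "")
}

# token-level reversal: first atom of `smiles` becomes the last atom token.
# Returns the reversed string or NULL when the unit structure does not
# admit it (multi-component input).
reverse_smiles_tokens <- function(smiles) {
  toks <- smiles_tokens(smiles)
  toks2 <- unique_pair_digits(toks)
  n_pairs <- attr(toks2, "n_pairs") %||% 0L
  if (!identical(as.character(toks2), as.character(toks))) {
    toks <- smiles_tokens(paste0(toks2, collapse = ""))
  }
  units <- smiles_units(toks)
  if (is.null(units) || length(units) == 0L) return(NULL)
  root <- units[[1L]]

  components <- character(0)
  extra_root <- character(0)
  if (length(root$branches) > 0L) {
    used <- digits_used(toks)
    fresh <- next_free_digits(used, length(root$branches))
    for (bi in seq_along(root$branches)) {
      br <- root$branches[bi]
      inner <- substr(br, 2L, nchar(br) - 1L)
      itoks <- smiles_tokens(inner)
      itype <- attr(itoks, "type")
      lead_bond <- ""
      start <- 1L
      if (itype[1L] == "bond") { lead_bond <- itoks[1L]; start <- 2L }
      if (itype[start] != "atom") return(NULL)
      # insert fresh digit after the first atom token and its ring tokens
      j <- start + 1L
      while (j <= length(itoks) &&
             (itype[j] == "ring" ||
              (itype[j] == "bond" && j < length(itoks) && itype[j + 1L] == "ring"))) {
        j <- j + if (itype[j] == "bond") 2L else 1L
      }
      dg <- ring_digit_text(fresh[bi])
      comp <- paste0(paste0(itoks[start:(j - 1L)], collapse = ""), dg,
                     if (j <= length(itoks)) paste0(itoks[j:length(itoks)], collapse = "") else "")
      components <- c(components, comp)
      extra_root <- c(extra_root, paste0(lead_bond, dg))
    }
  }

  nmain <- length(units)
  parts <- character(0)
  if (nmain > 1L) {
    for (i in nmain:2L) {
      parts <- c(parts, render_unit(units[[i]], with_prebond = FALSE))
      parts <- c(parts, units[[i]]$prebond)
    }
  }
  root_txt <- paste0(root$atom, paste0(root$rings, collapse = ""),
                     paste0(extra_root, collapse = ""))
  body <- paste0(paste0(parts, collapse = ""), root_txt)
  if (length(components) > 0L) {
    body <- paste0(paste(components, collapse = "."), ".", body)
  }
  relabel_ring_digits(body)
}

# locate attachment markers; returns data.frame(site, span_start, span_end,
# text, attach_atom (1-based id in the marker graph)) ordered by appearance
locate_markers <- function(smiles, mol = NULL) {
  if (is.null(mol)) mol <- parse_smiles_graph(smiles, check_valence = FALSE)
  toks <- mol$tokens
  type <- attr(toks, "type")
  tstart <- attr(toks, "start")
  tend <- attr(toks, "end")
  adj <- adjacency(mol)
  dummies <- which(mol$atoms$dummy)
  if (length(dummies) == 0L) {
    return(data.frame(site = integer(0), span_start = integer(0),
                      span_end = integer(0), text = character(0),
                      attach_atom = integer(0), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_along(dummies), function(si) {
    a <- dummies[si]
    nb <- adj[[a]]
    if (is.null(nb) || nrow(nb) != 1L) {
      stop(structure(class = c("marker_topology_error", "error", "condition"),
                     list(message = sprintf(
                       "attachment marker %d has %d neighbours (need exactly 1)",
                       si, if (is.null(nb)) 0L else nrow(nb)), call = NULL)))
    }
    ti <- mol$atoms$token[a]
    s <- tstart[ti]; e <- tend[ti]
    # branch form: ( [bond] * )
    j <- ti - 1L
    if (j >= 1L && type[j] == "bond") j <- j - 1L
    if (j >= 1L && type[j] == "open" && ti + 1L <= length(toks) &&
        type[ti + 1L] == "close") {
      s <- tstart[j]; e <- tend[ti + 1L]
    } else if (ti > 1L && type[ti - 1L] == "bond") {
      s <- tstart[ti - 1L]
    }
    data.frame(site = si, span_start = s, span_end = e,
               text = substr(smiles, s, e),
               attach_atom = nb[1, 1], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
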