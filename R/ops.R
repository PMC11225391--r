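# Public SMILES string algebra: attachment-point parsing, marker ledger
# strip/reinsert, rooting, reversal, variant enumeration, branch insertion,
# canonicalization and substructure queries.
#
# Canonical SMILES (Open Babel, via ChemmineOB) is used throughout as the
# graph-isomorphism test; the rearrangement machinery itself is native.

#' Canonicalize SMILES
#'
#' Returns the Open Babel canonical SMILES of each input, `NA` for strings
#' that do not parse as valid molecules. Canonical equality is the package's
#' graph-isomorphism test.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES (`NA` where invalid).
#' @export
canonicalize_smiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  ok <- !is.na(smiles) & nzchar(smiles)
  # pre-filter with the native parser to avoid feeding obvious garbage to OB
  ok[ok] <- vapply(smiles[ok], function(s) {
    !inherits(tryCatch(parse_smiles_graph(s), error = identity), "error")
  }, logical(1), USE.NAMES = FALSE)
  idx <- which(ok)
  if (length(idx) > 0L) out[idx] <- ob_canonical_chunk(smiles[idx])
  out
}

# batch conversion with recursive bisection fallback: Open Babel truncates
# its batch output at the first invalid record
ob_canonical_chunk <- function(smis) {
  n <- length(smis)
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN",
                              paste0(paste(smis, collapse = "\n"), "\n")),
    error = function(e) "")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- sub("[\t ].*$", "", lines)
  lines <- lines[nzchar(lines) | seq_along(lines) <= n]
  if (length(lines) == n && all(nzchar(lines))) return(lines)
  if (n == 1L) return(NA_character_)
  h <- n %/% 2L
  c(ob_canonical_chunk(smis[seq_len(h)]), ob_canonical_chunk(smis[(h + 1L):n]))
}

#' Test SMILES validity
#'
#' A string is valid when it passes the native parser (syntax, ring-closure
#' completeness, valence model) and Open Babel canonicalization.
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector.
#' @export
smiles_valid <- function(smiles) {
  !is.na(canonicalize_smiles(smiles))
}

#' Parse attachment points from a marker SMILES
#'
#' Attachment points are dummy atoms `*`, written in branch form `(*)` or as
#' bare terminal `*` atoms; each must be bonded to exactly one real atom
#' with at least one unit of free valence.
#'
#' @param smiles A SMILES string containing zero or more `*` markers.
#' @return An object of class `attachment_spec` with fields `source_smiles`,
#'   `core_smiles` (markers removed), `sites` (0-based atom ordinals in the
#'   core, in order of marker appearance), `n_sites`, and the marker
#'   `ledger` (see [strip_markers()]).
#' @examples
#' spec <- parse_attachment_points("c1c(*)cc(*)cc1")
#' spec$sites
#' @export
parse_attachment_points <- function(smiles) {
  mol <- parse_smiles_graph(smiles)
  mk <- locate_markers(smiles, mol)
  sl <- strip_markers(smiles)
  dummies <- which(mol$atoms$dummy)
  # core ordinal of each attachment atom: full ordinal minus dummies before it
  sites <- vapply(mk$attach_atom, function(a) {
    a - sum(dummies < a) - 1L  # 0-based
  }, integer(1))
  core <- sl$core
  if (length(sites) > 0L) {
    cmol <- parse_smiles_graph(core)
    fv <- free_valence(cmol)
    bad <- which(fv[sites + 1L] < 1)
    if (length(bad) > 0L) {
      stop_valence(sprintf("attachment site %d (core atom %d) has no free valence",
                           bad[1], sites[bad[1]]))
    }
  }
  structure(list(source_smiles = smiles, core_smiles = core,
                 sites = as.integer(sites), n_sites = length(sites),
                 ledger = sl$ledger),
            class = "attachment_spec")
}

#' @export
print.attachment_spec <- function(x, ...) {
  cat(sprintf("<attachment_spec> %s  (core %s, %d site%s at core atom%s %s)\n",
              x$source_smiles, x$core_smiles, x$n_sites,
              if (x$n_sites == 1L) "" else "s",
              if (x$n_sites == 1L) "" else "s",
              paste(x$sites, collapse = ",")))
  invisible(x)
}

#' Strip attachment markers, recording a reinsertion ledger
#'
#' Removes every `*` marker from the string and records where each removed
#' span sat, so that [reinsert_markers()] is an exact string inverse as long
#' as the string is only modified after the recorded positions (which is the
#' case for prompt completion, where generated tokens are appended at the
#' end).
#'
#' @param smiles Marker SMILES.
#' @return `list(core, ledger)`; the ledger is a data.frame with columns
#'   `site`, `pos` (0-based character offset in `core` at which the marker
#'   text is reinserted) and `text` (the removed span, e.g. `"(*)"`).
#' @export
strip_markers <- function(smiles) {
  mol <- parse_smiles_graph(smiles, check_valence = FALSE)
  mk <- locate_markers(smiles, mol)
  if (nrow(mk) == 0L) {
    return(list(core = smiles,
                ledger = data.frame(site = integer(0), pos = integer(0),
                                    text = character(0), stringsAsFactors = FALSE)))
  }
  mk <- mk[order(mk$span_start), , drop = FALSE]
  removed_before <- cumsum(c(0L, (mk$span_end - mk$span_start + 1L)[-nrow(mk)]))
  pos <- mk$span_start - 1L - removed_before  # 0-based offset in core
  keep <- rep(TRUE, nchar(smiles))
  for (r in seq_len(nrow(mk))) keep[mk$span_start[r]:mk$span_end[r]] <- FALSE
  core <- paste(strsplit(smiles, "", fixed = TRUE)[[1]][keep], collapse = "")
  list(core = core,
       ledger = data.frame(site = mk$site, pos = as.integer(pos),
                           text = mk$text, stringsAsFactors = FALSE))
}

#' Reinsert attachment markers recorded by [strip_markers()]
#'
#' @param smiles A SMILES string whose prompt region (characters before the
#'   recorded positions) is unchanged since stripping.
#' @param ledger Ledger data.frame from [strip_markers()].
#' @return The marker SMILES.
#' @export
reinsert_markers <- function(smiles, ledger) {
  if (nrow(ledger) == 0L) return(smiles)
  if (any(ledger$pos > nchar(smiles))) {
    stop(structure(class = c("ledger_corruption_error", "error", "condition"),
                   list(message = "ledger position beyond string length", call = NULL)))
  }
  for (r in order(ledger$pos, decreasing = TRUE)) {
    p <- ledger$pos[r]
    smiles <- paste0(substr(smiles, 1L, p), ledger$text[r],
                     substr(smiles, p + 1L, nchar(smiles)))
  }
  smiles
}

#' Re-root a SMILES at a chosen atom
#'
#' Writes a SMILES for the same molecular graph whose first atom token is
#' the atom at `atom_index` (0-based, in order of atom appearance in the
#' input string). With `randomize = TRUE` the traversal beyond the root is
#' randomized under the session RNG.
#'
#' @param smiles Input SMILES.
#' @param atom_index 0-based atom ordinal.
#' @param randomize Randomize branching order of the traversal.
#' @return Rooted SMILES with attribute `atom_order` mapping output atom
#'   positions to input atom ordinals (1-based).
#' @export
root_at_atom <- function(smiles, atom_index, randomize = FALSE) {
  mol <- parse_smiles_graph(smiles, check_valence = FALSE)
  write_smiles_graph(mol, root = atom_index + 1L, randomize = randomize)
}

#' Reverse a SMILES so its first atom becomes the last atom token
#'
#' String growth in autoregressive generation happens at the end of the
#' string, so a prompt must end at the attachment atom. `reverse_smiles`
#' rewrites the input (typically already rooted at the attachment atom via
#' [root_at_atom()]) so that the first atom becomes the final atom token.
#' Branches hanging off the first atom are hoisted into leading
#' dot-components re-attached through ring-closure digits. If the token
#' construction fails self-verification, a rejection-sampling fallback over
#' randomized rooted forms is tried before signalling a reversal failure.
#'
#' @param smiles Input SMILES (single component).
#' @param verify Check canonical equality of output vs input (default TRUE).
#' @param max_tries Rejection-sampling budget for the fallback.
#' @return Reversed SMILES.
#' @export
reverse_smiles <- function(smiles, verify = TRUE, max_tries = 100L) {
  out <- tryCatch(reverse_smiles_tokens(smiles), error = function(e) NULL)
  if (!is.null(out)) {
    ok <- tryCatch({
      parse_smiles_graph(out)
      if (verify) {
        cc <- canonicalize_smiles(c(smiles, out))
        !is.na(cc[1]) && !is.na(cc[2]) && cc[1] == cc[2]
      } else TRUE
    }, error = function(e) FALSE)
    if (ok) return(out)
  }
  # fallback: rejection-sample randomized rooted forms ending at atom 1
  mol <- tryCatch(parse_smiles_graph(smiles, check_valence = FALSE),
                  error = function(e) NULL)
  if (!is.null(mol)) {
    for (i in seq_len(max_tries)) {
      r <- sample.int(mol$n, 1L)
      cand <- write_smiles_graph(mol, root = r, randomize = TRUE)
      ao <- attr(cand, "atom_order")
      if (ao[length(ao)] == 1L) {
        ok <- tryCatch({
          cc <- canonicalize_smiles(c(smiles, cand))
          !is.na(cc[2]) && identical(cc[1], cc[2])
        }, error = function(e) FALSE)
        if (ok) return(as.character(cand))
      }
    }
  }
  stop(structure(class = c("reversal_failure_error", "error", "condition"),
                 list(message = sprintf("cannot reverse '%s'", smiles), call = NULL)))
}

# fast rooted+reversed form: token construction with a parse check; falls
# back to the fully verified [reverse_smiles()] path when construction fails
rooted_reversed <- function(smiles, atom_index) {
  rooted <- root_at_atom(smiles, atom_index, randomize = FALSE)
  out <- tryCatch(reverse_smiles_tokens(rooted), error = function(e) NULL)
  if (!is.null(out) &&
      !inherits(tryCatch(parse_smiles_graph(out), error = identity), "error")) {
    return(out)
  }
  reverse_smiles(rooted)
}

# deterministic rooted+reversed form plus randomized variants, all ending at
# the given atom; exact-string deduplication (the CLM scores strings, not
# graphs)
reversed_variants <- function(smiles, atom_index, k = 10L, max_tries = NULL) {
  if (is.null(max_tries)) max_tries <- 10L * k
  first <- rooted_reversed(smiles, atom_index)
  vars <- first
  if (k > 1L) {
    mol <- parse_smiles_graph(smiles, check_valence = FALSE)
    tries <- 0L
    while (length(vars) < k && tries < max_tries) {
      tries <- tries + 1L
      rooted <- write_smiles_graph(mol, root = atom_index + 1L, randomize = TRUE)
      cand <- tryCatch(reverse_smiles_tokens(rooted), error = function(e) NULL)
      if (is.null(cand)) next
      ok <- !inherits(tryCatch(parse_smiles_graph(cand), error = identity), "error")
      if (ok && !(cand %in% vars)) vars <- c(vars, cand)
    }
  }
  vars
}

#' Enumerate reversed randomized variants ending at an attachment site
#'
#' @param spec An `attachment_spec` (or marker SMILES coerced with
#'   [parse_attachment_points()]).
#' @param site Which attachment site (1-based position in `spec$sites`).
#' @param k Maximum number of distinct variants.
#' @return Character vector of at most `k` distinct SMILES of the core, each
#'   ending at the site atom; the first is the deterministic rooted+reversed
#'   form.
#' @export
enumerate_reversed_variants <- function(spec, site = 1L, k = 10L) {
  if (is.character(spec)) spec <- parse_attachment_points(spec)
  stopifnot(inherits(spec, "attachment_spec"), site >= 1L, site <= spec$n_sites,
            k >= 1L)
  reversed_variants(spec$core_smiles, spec$sites[site], k = k)
}

#' Insert a fragment as a branch at an atom
#'
#' The fragment SMILES must be rooted at its attachment atom (first atom).
#' Its ring-closure digits are renumbered to digits unused anywhere in the
#' host string, and the branch is placed directly after the host atom's
#' ring-closure digits. When host and fragment attachment atoms are both
#' aromatic, an explicit single bond `-` is written to keep the new bond a
#' single bond.
#'
#' @param smiles Host SMILES.
#' @param atom_index 0-based host atom ordinal; must have free valence.
#' @param fragment Fragment SMILES rooted at its attachment atom.
#' @return The combined SMILES, with attributes `insert_pos` (0-based char
#'   offset of the inserted text), `insert_text`, and `frag_atoms` (1-based
#'   atom ordinals of the fragment atoms in the output string).
#' @export
insert_branch <- function(smiles, atom_index, fragment) {
  mol <- parse_smiles_graph(smiles)
  a <- atom_index + 1L
  if (a < 1L || a > mol$n) {
    stop(structure(class = c("smiles_index_error", "error", "condition"),
                   list(message = sprintf("atom index %d out of range", atom_index),
                        call = NULL)))
  }
  fv <- free_valence(mol)
  if (fv[a] < 1) {
    stop_valence(sprintf("atom %d has no free valence", atom_index))
  }
  fmol <- parse_smiles_graph(fragment)
  # renumber fragment ring digits to digits unused in the host
  ftoks <- smiles_tokens(fragment)
  ftype <- attr(ftoks, "type")
  used <- digits_used(mol$tokens)
  fdig <- digits_used(ftoks)
  if (length(fdig) > 0L) {
    fresh <- next_free_digits(union(used, integer(0)), length(fdig))
    map <- stats::setNames(fresh, as.character(fdig))
    ring_idx <- which(ftype == "ring")
    for (i in ring_idx) {
      d <- if (startsWith(ftoks[i], "%")) as.integer(substr(ftoks[i], 2L, 3L)) else as.integer(ftoks[i])
      ftoks[i] <- ring_digit_text(map[[as.character(d)]])
    }
  }
  frag2 <- paste0(ftoks, collapse = "")
  bond <- if (mol$atoms$aromatic[a] && fmol$atoms$aromatic[1]) "-" else ""
  ins_text <- paste0("(", bond, frag2, ")")

  # insertion point: after the host atom token and its ring-closure tokens
  toks <- mol$tokens
  type <- attr(toks, "type")
  tend <- attr(toks, "end")
  ti <- mol$atoms$token[a]
  j <- ti + 1L
  while (j <= length(toks) &&
         (type[j] == "ring" ||
          (type[j] == "bond" && j < length(toks) && type[j + 1L] == "ring"))) {
    j <- j + if (type[j] == "bond") 2L else 1L
  }
  ins_pos <- tend[if (j > ti + 1L) j - 1L else ti]  # insert after this char
  out <- paste0(substr(smiles, 1L, ins_pos), ins_text,
                substr(smiles, ins_pos + 1L, nchar(smiles)))
  res <- tryCatch(parse_smiles_graph(out), error = function(e) {
    stop(structure(class = c("insertion_error", "error", "condition"),
                   list(message = sprintf("insertion at atom %d produced unparsable '%s'",
                                          atom_index, out), call = NULL)))
  })
  n_before <- sum(mol$atoms$start <= ins_pos)
  attr(out, "insert_pos") <- ins_pos
  attr(out, "insert_text") <- ins_text
  attr(out, "frag_atoms") <- n_before + seq_len(fmol$n)
  out
}

#' Substructure test (SMARTS semantics, markers as wildcards)
#'
#' Uses Open Babel SMARTS matching; `*` atoms in the query match any atom.
#'
#' @param smiles Character vector of molecule SMILES.
#' @param query A SMILES/SMARTS substructure query (may carry `*` markers).
#' @return Logical vector; `FALSE` for invalid molecules.
#' @export
is_substructure <- function(smiles, query) {
  n <- length(smiles)
  out <- rep(FALSE, n)
  ok <- smiles_valid(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles[idx], paste0("m", idx)))
  cnt <- tryCatch(ChemmineR::smartsSearchOB(sdf, query, uniqueMatches = FALSE),
                  error = function(e) rep(0L, length(idx)))
  out[idx] <- cnt > 0
  out
}

# all VF2 matches of a query graph in a molecule graph (both smiles_graph or
# SMILES); element+aromatic vertex colours, order+aromatic edge colours.
# Returns a list of integer vectors: target atom ids for query atoms 1..k.
# Note: igraph VF2 finds *induced* matches; exact for fragment cores placed
# by this package (no cross-fragment ring formation).
match_substructure <- function(mol, query) {
  if (is.character(mol)) mol <- parse_smiles_graph(mol)
  if (is.character(query)) query <- parse_smiles_graph(query)
  vc <- function(m) {
    paste0(capitalize_element(m$atoms$element), ifelse(m$atoms$aromatic, "a", ""),
           ifelse(m$atoms$isotope > 0L, paste0("@", m$atoms$isotope), ""))
  }
  keys <- unique(c(vc(mol), vc(query)))
  col_t <- match(vc(mol), keys)
  col_p <- match(vc(query), keys)
  ec <- function(m) ifelse(m$bonds$aromatic, 4L, m$bonds$order)
  gt <- igraph::make_graph(edges = as.vector(t(as.matrix(mol$bonds[, c("a1", "a2")]))),
                           n = mol$n, directed = FALSE)
  gp <- igraph::make_graph(edges = as.vector(t(as.matrix(query$bonds[, c("a1", "a2")]))),
                           n = query$n, directed = FALSE)
  maps <- igraph::subgraph_isomorphisms(pattern = gp, target = gt, method = "vf2",
                                        vertex.color1 = col_t, vertex.color2 = col_p,
                                        edge.color1 = ec(mol), edge.color2 = ec(query))
  lapply(maps, as.integer)
}

#' Read / write `.smi` files
#'
#' One record per line: a SMILES, optionally followed by a tab and an
#' identifier. Lines starting with `#` and blank lines are ignored.
#'
#' @param path File path.
#' @return `read_smi` returns a data.frame with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(smiles = vapply(parts, `[`, character(1), 1L),
             id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                         character(1)),
             stringsAsFactors = FALSE)
}

#' @rdname read_smi
#' @param smiles Character vector of SMILES to write.
#' @param id Optional identifiers (recycled if length 1).
#' @export
write_smi <- function(smiles, path, id = NULL) {
  lines <- if (is.null(id)) smiles else paste(smiles, rep_len(id, length(smiles)), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
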