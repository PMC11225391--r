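# SMILES -> molecular graph parser.
#
# The parser keeps the atom order exactly as atoms appear in the string
# (0-based ordinals in the public API are over this appearance order), records
# the token index and character span of every atom, and computes implicit
# hydrogen counts from a standard valence model. Stereochemistry annotations
# (/, \, @) are accepted and dropped; the package operates on constitution
# only. Aromaticity is taken as written (lowercase atoms / ':' bonds), not
# re-perceived.

# allowed valence sets of the organic subset (implicit-H rule: smallest
# allowed valence >= current bond order sum)
.VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, H = 1
)

# parse one bracket-atom token like [13C@H2+] into its fields (stereo dropped)
parse_bracket_atom <- function(tok) {
  inner <- substr(tok, 2L, nchar(tok) - 1L)
  re <- "^([0-9]+)?([A-Za-z][a-z]?|\\*)(@{1,2})?(H[0-9]*)?(\\+{1,2}|-{1,2}|\\+[0-9]+|-[0-9]+)?(:[0-9]+)?$"
  m <- regmatches(inner, regexec(re, inner))[[1]]
  if (length(m) == 0L) {
    stop_smiles_parse(tok, sprintf("cannot parse bracket atom '%s'", tok))
  }
  iso <- if (nzchar(m[2])) as.integer(m[2]) else 0L
  elem <- m[3]
  hstr <- m[5]
  hcount <- if (!nzchar(hstr)) 0L else if (hstr == "H") 1L else as.integer(substr(hstr, 2L, nchar(hstr)))
  cstr <- m[6]
  charge <- if (!nzchar(cstr)) 0L else if (cstr %in% c("+", "++")) nchar(cstr) else
    if (cstr %in% c("-", "--")) -nchar(cstr) else as.integer(cstr)
  list(element = elem, isotope = iso, hcount = hcount, charge = charge,
       aromatic = elem == tolower(elem) && elem != "*")
}

# Parse a SMILES string into a graph.
#
# Returns a list with components:
#   atoms: data.frame(element, aromatic, charge, hcount (explicit, bracket
#          only), isotope, bracket, dummy, token (token index), start, end)
#   bonds: data.frame(a1, a2, order, aromatic, ring (closed via ring digit))
#   n: atom count; tokens: the token vector (with span/type attributes)
# Atom ids are 1-based in appearance order.
parse_smiles_graph <- function(smiles, check_valence = TRUE) {
  toks <- smiles_tokens(smiles)
  type <- attr(toks, "type")
  tstart <- attr(toks, "start")
  tend <- attr(toks, "end")

  n <- sum(type == "atom")
  atoms <- data.frame(
    element = character(n), aromatic = logical(n), charge = integer(n),
    hcount = integer(n), isotope = integer(n), bracket = logical(n),
    dummy = logical(n), token = integer(n), start = integer(n),
    end = integer(n), stringsAsFactors = FALSE
  )
  b_a1 <- integer(0); b_a2 <- integer(0); b_sym <- character(0)

  prev <- NA_integer_
  pending <- ""
  stack <- integer(0)
  ring_open <- list()  # digit -> list(atom, bond)
  ai <- 0L

  for (i in seq_along(toks)) {
    tk <- toks[i]
    ty <- type[i]
    if (ty == "atom") {
      ai <- ai + 1L
      if (startsWith(tk, "[")) {
        p <- parse_bracket_atom(tk)
        atoms$element[ai] <- p$element
        atoms$aromatic[ai] <- p$aromatic
        atoms$charge[ai] <- p$charge
        atoms$hcount[ai] <- p$hcount
        atoms$isotope[ai] <- p$isotope
        atoms$bracket[ai] <- TRUE
        atoms$dummy[ai] <- p$element == "*"
      } else {
        atoms$element[ai] <- tk
        atoms$aromatic[ai] <- tk %in% .AROMATIC_SUBSET
        atoms$bracket[ai] <- FALSE
        atoms$dummy[ai] <- tk == "*"
      }
      atoms$token[ai] <- i
      atoms$start[ai] <- tstart[i]
      atoms$end[ai] <- tend[i]
      if (!is.na(prev)) {
        b_a1 <- c(b_a1, prev); b_a2 <- c(b_a2, ai); b_sym <- c(b_sym, pending)
      } else if (nzchar(pending)) {
        stop_smiles_parse(smiles, "bond symbol with no preceding atom")
      }
      prev <- ai
      pending <- ""
    } else if (ty == "bond") {
      if (nzchar(pending)) stop_smiles_parse(smiles, "two consecutive bond symbols")
      pending <- tk
    } else if (ty == "open") {
      if (is.na(prev)) stop_smiles_parse(smiles, "branch with no preceding atom")
      if (nzchar(pending)) stop_smiles_parse(smiles, "bond symbol before '('")
      stack <- c(stack, prev)
    } else if (ty == "close") {
      if (length(stack) == 0L) stop_smiles_parse(smiles, "unmatched ')'")
      if (nzchar(pending)) stop_smiles_parse(smiles, "dangling bond before ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (ty == "ring") {
      if (is.na(prev)) stop_smiles_parse(smiles, "ring closure with no preceding atom")
      key <- tk
      if (!is.null(ring_open[[key]])) {
        op <- ring_open[[key]]
        if (op$atom == prev) stop_smiles_parse(smiles, "ring bond to self")
        sym <- if (nzchar(pending)) pending else op$bond
        if (nzchar(pending) && nzchar(op$bond) && pending != op$bond) {
          stop_smiles_parse(smiles, sprintf("conflicting ring bond symbols for '%s'", key))
        }
        b_a1 <- c(b_a1, op$atom); b_a2 <- c(b_a2, prev)
        b_sym <- c(b_sym, paste0("RING", sym))
        ring_open[[key]] <- NULL
      } else {
        ring_open[[key]] <- list(atom = prev, bond = pending)
      }
      pending <- ""
    } else if (ty == "dot") {
      if (nzchar(pending)) stop_smiles_parse(smiles, "bond symbol before '.'")
      prev <- NA_integer_
    }
  }
  if (length(stack) > 0L) stop_smiles_parse(smiles, "unmatched '('")
  if (length(ring_open) > 0L) {
    stop_smiles_parse(smiles, sprintf("%d unmatched ring bond(s)", length(ring_open)))
  }
  if (nzchar(pending)) stop_smiles_parse(smiles, "dangling bond symbol at end")
  if (n == 0L) stop_smiles_parse(smiles, "no atoms")

  ring <- startsWith(b_sym, "RING")
  sym <- sub("^RING", "", b_sym)
  nb <- length(b_a1)
  order <- integer(nb); arom <- logical(nb)
  for (k in seq_len(nb)) {
    s <- sym[k]
    both_arom <- atoms$aromatic[b_a1[k]] && atoms$aromatic[b_a2[k]]
    if (s == "" ) { order[k] <- 1L; arom[k] <- both_arom }
    else if (s == "-") { order[k] <- 1L; arom[k] <- FALSE }
    else if (s == "=") { order[k] <- 2L; arom[k] <- FALSE }
    else if (s == "#") { order[k] <- 3L; arom[k] <- FALSE }
    else if (s == ":") { order[k] <- 1L; arom[k] <- TRUE }
    else if (s %in% c("/", "\\", "~")) { order[k] <- 1L; arom[k] <- both_arom }
    else stop_smiles_parse(smiles, sprintf("unsupported bond symbol '%s'", s))
  }
  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = order,
                      aromatic = arom, ring = ring)
  mol <- list(atoms = atoms, bonds = bonds, n = n, tokens = toks,
              smiles = smiles)
  mol$atoms$implicit_h <- implicit_hydrogens(mol, check_valence = check_valence)
  class(mol) <- "smiles_graph"
  mol
}

# sum of bond orders at each atom (aromatic bonds count 1)
degree_order <- function(mol) {
  deg <- numeric(mol$n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      deg[mol$bonds$a1[k]] <- deg[mol$bonds$a1[k]] + o
      deg[mol$bonds$a2[k]] <- deg[mol$bonds$a2[k]] + o
    }
  }
  deg
}

# effective allowed valences given formal charge (simplified model:
# N/P/O/S gain with positive charge, C/B lose with any charge)
allowed_valences <- function(element, charge) {
  base <- .VALENCES[[element]]
  if (is.null(base)) return(NULL)
  if (charge == 0L) return(base)
  if (element %in% c("N", "P", "O", "S")) pmax(base + charge, 0) else
    pmax(base - abs(charge), 0)
}

# implicit hydrogen counts; signals smiles_valence_error when the written
# bond order sum exceeds every allowed valence
implicit_hydrogens <- function(mol, check_valence = TRUE) {
  deg <- degree_order(mol)
  ih <- integer(mol$n)
  for (a in seq_len(mol$n)) {
    at <- mol$atoms[a, ]
    if (at$dummy) { ih[a] <- 0L; next }
    if (at$bracket) {
      ih[a] <- 0L  # bracket atoms carry explicit hydrogens only
      if (check_valence) {
        val <- allowed_valences(capitalize_element(at$element), at$charge)
        if (!is.null(val) && deg[a] + at$hcount > max(val)) {
          stop_valence(sprintf(
            "atom %d (%s) exceeds valence: %g bonds + %d H > %g",
            a - 1L, at$element, deg[a], at$hcount, max(val)))
        }
      }
      next
    }
    val <- allowed_valences(capitalize_element(at$element), at$charge)
    if (is.null(val)) { ih[a] <- 0L; next }
    if (at$aromatic) val <- val[1]  # no hypervalent aromatic atoms
    d <- deg[a] + if (at$aromatic) 1L else 0L
    fit <- val[val >= d]
    if (length(fit) == 0L) {
      # pyrrole-type aromatic atom: the +1 pi increment does not apply
      if (at$aromatic && any(val >= deg[a])) {
        ih[a] <- 0L
        next
      }
      if (check_valence) {
        stop_valence(sprintf("atom %d (%s) exceeds valence: bond order sum %g > %g",
                             a - 1L, at$element, deg[a], max(val)))
      }
      ih[a] <- 0L
    } else {
      ih[a] <- as.integer(min(fit) - d)
    }
  }
  ih
}

capitalize_element <- function(e) {
  paste0(toupper(substr(e, 1L, 1L)), substr(e, 2L, nchar(e)))
}

# remaining bonding capacity of each atom; implicit hydrogens can be
# displaced by new bonds, explicit (bracket) hydrogens cannot. Aromatic
# N/P may trade the pi electron for a lone pair when gaining a substituent
# (pyridine-type -> pyrrole-type nitrogen), so their pi increment is not
# charged against free valence.
free_valence <- function(mol) {
  deg <- degree_order(mol)
  out <- numeric(mol$n)
  for (a in seq_len(mol$n)) {
    at <- mol$atoms[a, ]
    if (at$dummy) { out[a] <- Inf; next }
    val <- allowed_valences(capitalize_element(at$element), at$charge)
    if (is.null(val)) { out[a] <- if (at$bracket) 0 else Inf; next }
    if (at$aromatic) val <- val[1]
    pi_inc <- if (at$aromatic && !capitalize_element(at$element) %in% c("N", "P")) 1 else 0
    used <- deg[a] + pi_inc + (if (at$bracket) at$hcount else 0)
    out[a] <- max(max(val) - used, 0)
  }
  out
}

# adjacency list (atom id -> neighbour atom ids with bond row index)
adjacency <- function(mol) {
  adj <- vector("list", mol$n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    adj[[a]] <- rbind(adj[[a]], c(b, k))
    adj[[b]] <- rbind(adj[[b]], c(a, k))
  }
  adj
}

#' @export
print.smiles_graph <- function(x, ...) {
  cat(sprintf("<smiles_graph> %s: %d atoms, %d bonds\n",
              x$smiles, x$n, nrow(x$bonds)))
  invisible(x)
}
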