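# Shared fixtures: scripted mock CLMs, cached models, and an isotope-label
# oracle for positional (first/last atom) contracts. All models are trained
# in-session; nothing is loaded from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# the standard 5,000-molecule synthetic corpus and the model trained on it
fixture_corpus <- function() cached("corpus", generate_corpus(5000, seed = 7))

fixture_model <- function() cached("model", {
  clm(fixture_corpus(), epochs = 5, batch_size = 64, lr = 3e-3,
      embedding = 64, hidden = 160, layers = 1, seed = 3)
})

# a very small model for mechanics-level tests (seconds to train)
tiny_model <- function() cached("tiny", {
  clm(generate_corpus(300, seed = 5), epochs = 2, batch_size = 64,
      lr = 3e-3, embedding = 24, hidden = 48, seed = 2)
})

# scripted mock CLM: returns the given completions in order (cycled);
# deterministic string-keyed NLL so that argmin selections are predictable
make_mock_clm <- function(completions, nll_fn = NULL) {
  i <- 0
  if (is.null(nll_fn)) {
    nll_fn <- function(smiles, eos = TRUE) {
      vapply(smiles, function(s)
        nchar(s) + sum(utf8ToInt(s)) %% 7, numeric(1), USE.NAMES = FALSE)
    }
  }
  list(
    sample_fn = function(prompts) {
      out <- vapply(prompts, function(p) {
        i <<- i + 1
        completions[[(i - 1) %% length(completions) + 1]]
      }, character(1), USE.NAMES = FALSE)
      data.frame(smiles = paste0(prompts, out), completion = out,
                 terminated = TRUE, nll = nchar(prompts) + nchar(out),
                 stringsAsFactors = FALSE)
    },
    nll_fn = nll_fn
  )
}

# rewrite atom `ordinal0` (0-based appearance order) of a SMILES as a
# 13C-style isotope-labelled bracket atom with its implicit hydrogens made
# explicit; canonical equality of two labelings then certifies that the two
# positions are the same graph atom
label_atom <- function(smiles, ordinal0) {
  pe <- asNamespace("promptclm")
  mol <- pe$parse_smiles_graph(smiles)
  a <- ordinal0 + 1L
  at <- mol$atoms[a, ]
  if (at$bracket || at$dummy) return(NA_character_)
  h <- mol$atoms$implicit_h[a]
  # keep aromatic lowercase element inside the bracket
  lab <- paste0("[13", at$element,
                if (h == 1) "H" else if (h > 1) paste0("H", h) else "", "]")
  paste0(substr(smiles, 1, at$start - 1L), lab,
         substr(smiles, at$end + 1L, nchar(smiles)))
}

# convenience: 0-based ordinal of the last atom token of a SMILES
last_atom_ordinal <- function(smiles) {
  pe <- asNamespace("promptclm")
  pe$parse_smiles_graph(smiles, check_valence = FALSE)$n - 1L
}

# do two labelled SMILES denote the same labelled molecule? Canonical-string
# equality first; Open Babel's canonical form is not always stable across
# automorphic isotope placements, so fall back to an isotope-aware VF2
# isomorphism check (equal atom/bond counts + subgraph match).
same_labeled_molecule <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA)
  ca <- canonicalize_smiles(a); cb <- canonicalize_smiles(b)
  if (!is.na(ca) && !is.na(cb) && ca == cb) return(TRUE)
  pe <- asNamespace("promptclm")
  ga <- tryCatch(pe$parse_smiles_graph(a), error = function(e) NULL)
  gb <- tryCatch(pe$parse_smiles_graph(b), error = function(e) NULL)
  if (is.null(ga) || is.null(gb)) return(FALSE)
  ga$n == gb$n && nrow(ga$bonds) == nrow(gb$bonds) &&
    length(pe$match_substructure(ga, gb)) > 0L
}
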