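# SMILES tokenization shared by the string-algebra layer and the language model.

# master token regex: bracket atoms, two-letter halogens, %nn ring closures,
# organic-subset atoms, digits, bonds, branch/dot punctuation, dummy atoms
.SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]*\\]|Br|Cl|%[0-9]{2}|",
  "[BCNOPSFI]|[bcnops]|[0-9]|",
  "[-=#:/\\\\().*~]"
)

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")
.BOND_TOKENS <- c("-", "=", "#", ":", "/", "\\", "~")

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into grammar tokens: bracket atoms (`[nH]`, `[N+]`)
#' as single tokens, two-letter halogens (`Cl`, `Br`) as single tokens,
#' `%nn` ring closures as single tokens, and all remaining atoms, digits,
#' bond symbols and punctuation as one-character tokens.
#'
#' @param smiles A single SMILES string.
#' @return A character vector of tokens with attributes `start` and `end`
#'   giving the 1-based inclusive character span of each token, and `type`
#'   classifying each token as one of `"atom"`, `"bond"`, `"ring"`,
#'   `"open"`, `"close"`, `"dot"`.
#' @examples
#' smiles_tokens("c1c(Cl)cc[nH]c1=O")
#' @export
smiles_tokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(smiles)) {
    out <- character(0)
    attr(out, "start") <- integer(0)
    attr(out, "end") <- integer(0)
    attr(out, "type") <- character(0)
    return(out)
  }
  m <- gregexpr(.SMILES_TOKEN_RE, smiles, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    stop_smiles_parse(smiles, sprintf("no recognizable tokens in '%s'", smiles))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  ends <- starts + lens - 1L
  # every character must be consumed by some token
  covered <- unlist(mapply(seq.int, starts, ends, SIMPLIFY = FALSE))
  if (length(covered) != nchar(smiles)) {
    bad <- setdiff(seq_len(nchar(smiles)), covered)[1]
    stop_smiles_parse(smiles, sprintf(
      "unrecognized character '%s' at position %d in '%s'",
      substr(smiles, bad, bad), bad, smiles))
  }
  toks <- substring(smiles, starts, ends)
  type <- vapply(toks, token_type, character(1), USE.NAMES = FALSE)
  attr(toks, "start") <- starts
  attr(toks, "end") <- ends
  attr(toks, "type") <- type
  toks
}

token_type <- function(tok) {
  if (tok %in% .BOND_TOKENS) return("bond")
  if (tok == "(") return("open")
  if (tok == ")") return("close")
  if (tok == ".") return("dot")
  if (grepl("^[0-9]$|^%[0-9]{2}$", tok)) return("ring")
  "atom"
}

stop_smiles_parse <- function(smiles, msg) {
  stop(structure(class = c("smiles_parse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), smiles = smiles)))
}

stop_valence <- function(msg) {
  stop(structure(class = c("smiles_valence_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
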