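# SMILES tokenization for the sequence generator.

# token regex, longest-match first: bracket atoms, two-character elements,
# two-digit ring closures, then single-character symbols
.smiles_token_re <- paste0(
  "(\\[[^\\]]+\\]",                       # bracket atom
  "|Cl|Br",                               # two-letter organic-subset atoms
  "|%[0-9]{2}",                           # extended ring closure
  "|[BCNOPSFIbcnops]",                    # organic subset single letters
  "|[0-9]",                               # ring closures
  "|[-=#$:/\\\\().+*])"                   # bonds, branches, stereo
)

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into chemically meaningful tokens: bracket atoms
#' stay intact, two-character elements (Cl, Br) are single tokens, ring
#' closures and bond/branch symbols are one token each.
#'
#' @param smiles A single SMILES string.
#' @return Character vector of tokens; `detokenize(tokenize(s))` is the
#'   identity.
#' @export
#' @examples
#' tokenize("CC(=O)Nc1ccc(O)cc1")
tokenize <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  out <- character(0)
  rest <- smiles
  while (nchar(rest) > 0) {
    m <- regmatches(rest, regexpr(.smiles_token_re, rest, perl = TRUE))
    if (length(m) == 0 || !startsWith(rest, m)) {
      stop("Cannot tokenize SMILES at symbol '", substr(rest, 1, 1),
           "' in: ", smiles, call. = FALSE)
    }
    out <- c(out, m)
    rest <- substr(rest, nchar(m) + 1, nchar(rest))
  }
  out
}

#' @rdname tokenize
#' @param tokens Character vector of tokens.
#' @export
detokenize <- function(tokens) paste0(tokens, collapse = "")

# special tokens: padding/start/end
.tok_specials <- c("<pad>", "<bos>", "<eos>")

# build a vocabulary from a corpus; returns list(tokens, index env)
build_vocab <- function(smiles) {
  toks <- sort(unique(unlist(lapply(smiles, tokenize))))
  tokens <- c(.tok_specials, toks)
  list(tokens = tokens, size = length(tokens))
}

# encode tokens to integer ids (1-based into vocab$tokens); errors on OOV
encode_tokens <- function(tokens, vocab) {
  id <- match(tokens, vocab$tokens)
  if (anyNA(id)) {
    stop("Out-of-vocabulary token(s): ",
         paste(unique(tokens[is.na(id)]), collapse = " "), call. = FALSE)
  }
  id
}
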