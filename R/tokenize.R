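# Tokenization of structure strings and the token vocabulary.
#
# SMILES / DeepSMILES are split by longest-match rules: bracket atoms [...]
# are one token, two-letter elements (Cl, Br) are one token, %nn ring
# closures are one token, every other character is its own token. SELFIES
# are split at bracket boundaries. Sentinels <start>/<end> frame every
# sequence; <pad> carries index 0 so padding is zero in index space.

.OCSR_PAD <- "<pad>"
.OCSR_START <- "<start>"
.OCSR_END <- "<end>"
.OCSR_UNK <- "<unk>"
.ocsr_reserved <- c(.OCSR_PAD, .OCSR_START, .OCSR_END, .OCSR_UNK)

# Longest-match lexer for SMILES-like strings (no sentinels).
.lex_smiles <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop(ocsr_condition("ocsr_tokenize_error",
        paste0("unclosed bracket in: ", text)))
      toks <- c(toks, substr(text, i, j))
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop(ocsr_condition("ocsr_tokenize_error",
        paste0("truncated %nn ring closure in: ", text)))
      toks <- c(toks, substr(text, i, i + 2L))
      i <- i + 3L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      toks <- c(toks, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

.lex_selfies <- function(text) {
  toks <- regmatches(text, gregexpr("\\[[^][]*\\]", text))[[1]]
  if (paste(toks, collapse = "") != text) {
    stop(ocsr_condition("ocsr_tokenize_error",
      paste0("not a concatenation of bracketed symbols: ", text)))
  }
  toks
}

#' Tokenize a structure string
#'
#' @param text the string
#' @param representation one of "smiles", "deepsmiles", "selfies"
#' @return character vector of tokens framed by `<start>` and `<end>`
#' @examples
#' tokenize("CCl")  # <start> C Cl <end>
#' @export
tokenize <- function(text, representation = c("smiles", "deepsmiles", "selfies")) {
  representation <- match.arg(representation)
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  body <- if (representation == "selfies") .lex_selfies(text) else .lex_smiles(text)
  c(.OCSR_START, body, .OCSR_END)
}

#' Reassemble a token sequence into its source string
#'
#' Inverse of [tokenize()]: sentinels and padding are dropped, remaining
#' tokens concatenated.
#'
#' @param tokens character vector of tokens
#' @return the source string
#' @export
detokenize <- function(tokens) {
  paste(tokens[!(tokens %in% .ocsr_reserved)], collapse = "")
}

#' Build a token vocabulary from a corpus of token sequences
#'
#' Indices are 0-based so that `<pad>` = 0 and padded positions are zero in
#' index space. Reserved tokens come first, then the distinct corpus tokens
#' in lexicographic order; the assignment is deterministic and invariant to
#' corpus order.
#'
#' @param corpus list of token vectors (as produced by [tokenize()])
#' @return object of class `ocsr_vocab`: list with `token_to_index` (named
#'   0-based integer vector), `index_to_token`, `max_length` (longest corpus
#'   sequence, sentinels included), `size`
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(length(corpus) > 0L)
  toks <- sort(unique(unlist(corpus)))
  toks <- setdiff(toks, .ocsr_reserved)
  all_toks <- c(.ocsr_reserved, toks)
  t2i <- stats::setNames(seq_along(all_toks) - 1L, all_toks)
  structure(list(
    token_to_index = t2i,
    index_to_token = all_toks,
    max_length = max(lengths(corpus)),
    size = length(all_toks)
  ), class = "ocsr_vocab")
}

#' @export
print.ocsr_vocab <- function(x, ...) {
  cat(sprintf("<ocsr_vocab> %d tokens, max_length %d\n", x$size, x$max_length))
  invisible(x)
}

#' Encode a token sequence as a padded 0-based index vector
#'
#' @param tokens character vector of tokens (sentinels included)
#' @param vocab an `ocsr_vocab`
#' @param max_length pad/validate to this length (default: `vocab$max_length`)
#' @return integer vector of length `max_length`; unknown tokens map to
#'   `<unk>`, the tail is `<pad>` (= 0)
#' @export
encode_indices <- function(tokens, vocab, max_length = vocab$max_length) {
  if (length(tokens) > max_length) {
    stop(ocsr_condition("ocsr_length_overflow",
      sprintf("sequence length %d exceeds max_length %d",
              length(tokens), max_length)))
  }
  idx <- unname(vocab$token_to_index[tokens])
  idx[is.na(idx)] <- vocab$token_to_index[[.OCSR_UNK]]
  c(idx, rep(0L, max_length - length(idx)))
}

#' Decode a padded index vector back to tokens
#' @param indices 0-based integer vector
#' @param vocab an `ocsr_vocab`
#' @param strip_pad drop trailing `<pad>` entries (default TRUE)
#' @return character vector of tokens
#' @export
decode_indices <- function(indices, vocab, strip_pad = TRUE) {
  if (strip_pad) indices <- indices[indices != 0L]
  if (any(indices < 0L | indices >= vocab$size)) {
    stop(ocsr_condition("ocsr_contract_violation", "token index out of range"))
  }
  vocab$index_to_token[indices + 1L]
}

#' Serialize / load a vocabulary as JSON
#' @param vocab an `ocsr_vocab`
#' @param path file path
#' @return `write_vocabulary`: invisibly `vocab`; `read_vocabulary`: the vocabulary
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(list(
    tokens = vocab$index_to_token,
    max_length = vocab$max_length
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(vocab)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  toks <- as.character(obj$tokens)
  structure(list(
    token_to_index = stats::setNames(seq_along(toks) - 1L, toks),
    index_to_token = toks,
    max_length = as.integer(obj$max_length),
    size = length(toks)
  ), class = "ocsr_vocab")
}

# Stable polynomial hash of the vocabulary, used to guard checkpoints
# against decoding with a mismatched token set.
.vocab_hash <- function(vocab) {
  bytes <- utf8ToInt(paste(vocab$index_to_token, collapse = "\x01"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
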