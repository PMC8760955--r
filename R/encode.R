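#' One-hot encoding of numbered sequences
#'
#' Classifier features are a fixed-length one-hot encoding over an ordered
#' IMGT position universe: each universe position contributes a block of 21
#' indicators (20 amino acids plus an explicit gap state for positions absent
#' from the sequence). Exactly one indicator per block is 1.
#'
#' @name encoding
NULL

BLOCK <- 21L  # 20 amino acids + gap

#' Default classifier position universe
#'
#' All integer IMGT positions 1--128 in order, with no insertion codes:
#' insertion positions are rare in repertoires and excluded from classifier
#' features by default (they would triple the feature count for negligible
#' signal); pass an explicit universe to include them.
#'
#' @return character vector of 128 position codes.
#' @export
default_universe <- function() as.character(1:128)

#' Encode a sequence over a position universe
#'
#' @param seq a [numbered_sequence()].
#' @param universe ordered character vector of position codes.
#' @param strict if `TRUE`, sequence positions absent from the universe raise
#'   an error naming the offending codes; if `FALSE` (default) they are
#'   silently ignored, so the insertion-free default universe can encode
#'   sequences that carry insertions.
#' @return integer 0/1 vector of length `length(universe) * 21`.
#' @examples
#' s <- numbered_sequence("x", "heavy", "1", "M")
#' v <- encode_sequence(s, universe = c("1", "2"))
#' sum(v)  # one hot slot per universe position
#' @export
encode_sequence <- function(seq, universe = default_universe(),
                            strict = FALSE) {
  universe <- as.character(universe)
  imgt_parse(universe)  # validate codes
  idx <- match(seq$positions, universe)
  if (strict && anyNA(idx)) {
    stop("position(s) outside encoding universe: ",
         paste(seq$positions[is.na(idx)], collapse = ", "))
  }
  slot <- rep.int(BLOCK, length(universe))  # default: gap state
  hit <- !is.na(idx)
  slot[idx[hit]] <- match(seq$residues[hit], AA_ALPHABET)
  v <- integer(length(universe) * BLOCK)
  v[(seq_along(universe) - 1L) * BLOCK + slot] <- 1L
  v
}

#' Decode a one-hot vector back to a residue map
#'
#' Inverse of [encode_sequence()] on the universe: returns the position ->
#' residue map of all non-gap blocks.
#'
#' @param vector integer 0/1 vector from [encode_sequence()].
#' @param universe the universe used to encode.
#' @return named character vector (names = position codes).
#' @export
decode_sequence <- function(vector, universe = default_universe()) {
  universe <- as.character(universe)
  if (length(vector) != length(universe) * BLOCK) {
    stop("vector length ", length(vector), " does not match universe (",
         length(universe) * BLOCK, " expected)")
  }
  m <- matrix(vector, nrow = BLOCK)
  slot <- apply(m, 2L, which.max)
  keep <- slot <= length(AA_ALPHABET) & colSums(m) == 1L
  stats::setNames(AA_ALPHABET[slot[keep]], universe[keep])
}

#' Encode a list of sequences into a feature matrix
#'
#' @param seqs list of [numbered_sequence()] objects.
#' @inheritParams encode_sequence
#' @return integer matrix, one row per sequence.
#' @export
encode_matrix <- function(seqs, universe = default_universe(),
                          strict = FALSE) {
  universe <- as.character(universe)
  n <- length(seqs)
  out <- matrix(0L, nrow = n, ncol = length(universe) * BLOCK)
  for (i in seq_len(n)) {
    out[i, ] <- encode_sequence(seqs[[i]], universe, strict = strict)
  }
  rownames(out) <- vapply(seqs, function(s) s$id, "")
  out
}

# Map a feature column index back to (position, residue-or-gap).
feature_identity <- function(j, universe) {
  pos_i <- (j - 1L) %/% BLOCK + 1L
  slot <- (j - 1L) %% BLOCK + 1L
  data.frame(position = universe[pos_i],
             residue = c(AA_ALPHABET, GAP_SYMBOL)[slot],
             stringsAsFactors = FALSE)
}
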