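#' IMGT-numbered antibody variable-domain sequences
#'
#' A `numbered_sequence` is an ordered map from IMGT position codes to amino
#' acids, with chain-type and optional species / V-gene metadata. It is the
#' common currency of the package: the simulator emits them, the classifiers
#' encode them, and the humanizer mutates them.
#'
#' @param id single character identifier.
#' @param chain one of `"heavy"`, `"kappa"`, `"lambda"`.
#' @param positions character vector of IMGT position codes.
#' @param residues character vector of single-letter amino acids, parallel to
#'   `positions`.
#' @param species optional character scalar (e.g. `"human"`, `"mouse"`).
#' @param v_gene optional character scalar (e.g. `"V1"`).
#' @param source optional provenance string.
#' @return an object of class `numbered_sequence`.
#' @examples
#' s <- numbered_sequence("demo", "heavy",
#'                        positions = c("1", "2", "23"),
#'                        residues = c("E", "V", "C"))
#' s
#' @export
numbered_sequence <- function(id, chain, positions, residues,
                              species = NA_character_, v_gene = NA_character_,
                              source = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L)
  chain <- match.arg(chain, c("heavy", "kappa", "lambda"))
  positions <- as.character(positions)
  residues <- toupper(as.character(residues))
  if (length(positions) == 0L) stop("sequence '", id, "' is empty")
  if (length(positions) != length(residues)) {
    stop("positions and residues differ in length for '", id, "'")
  }
  bad <- !(residues %in% AA_ALPHABET)
  if (any(bad)) {
    stop("non-standard amino acid(s) in '", id, "': ",
         paste(unique(residues[bad]), collapse = ", "))
  }
  key <- imgt_key(positions)  # validates codes
  if (anyDuplicated(positions)) {
    stop("duplicate position(s) in '", id, "': ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "))
  }
  ord <- order(key)
  structure(
    list(id = id, chain = chain, positions = positions[ord],
         residues = residues[ord], species = species, v_gene = v_gene,
         source = source),
    class = "numbered_sequence")
}

#' @export
print.numbered_sequence <- function(x, ...) {
  cat(sprintf("<numbered_sequence> %s  chain=%s  %d positions", x$id, x$chain,
              length(x$positions)))
  if (!is.na(x$species)) cat("  species=", x$species, sep = "")
  if (!is.na(x$v_gene)) cat("  v_gene=", x$v_gene, sep = "")
  cat("\n ", paste0(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' Residue at a position
#'
#' @param seq a [numbered_sequence()].
#' @param code IMGT position code.
#' @return single residue, or `NA` when the position is absent.
#' @export
residue_at <- function(seq, code) {
  i <- match(as.character(code), seq$positions)
  if (is.na(i)) NA_character_ else seq$residues[i]
}

#' Replace a residue (pure substitution)
#'
#' The position must already exist; substitutions never create or delete
#' positions.
#'
#' @inheritParams residue_at
#' @param to replacement amino acid.
#' @return a new [numbered_sequence()].
#' @export
substitute_residue <- function(seq, code, to) {
  i <- match(as.character(code), seq$positions)
  if (is.na(i)) stop("position ", code, " absent from '", seq$id, "'")
  to <- toupper(to)
  if (!to %in% AA_ALPHABET) stop("invalid residue: ", to)
  seq$residues[i] <- to
  seq
}

residue_map_string <- function(seq) {
  paste(seq$positions, seq$residues, sep = ":", collapse = ",")
}

#' Quality-filter a set of numbered sequences
#'
#' Applies, in order, the three repertoire QC rules: exact-duplicate removal
#' (first occurrence kept; duplicates are identical position-residue maps),
#' removal of sequences without cysteine at IMGT 23 and 104, and removal of
#' sequences missing any conventionally occupied framework-1 position
#' (positions 1--26 occupied in every built-in germline template of the
#' chain, unless `fr1_required` overrides the set).
#'
#' @param seqs list of [numbered_sequence()] objects sharing one chain type.
#' @param fr1_required character vector of FR1 position codes that must be
#'   present; default derives from the built-in germline templates.
#' @return list with `kept` (sequences) and `removed`
#'   (data.frame `id`, `reason`).
#' @examples
#' g <- make_default_germlines()
#' s <- germline_as_sequence(g[[1]])
#' quality_filter(list(s, s))$removed
#' @export
quality_filter <- function(seqs, fr1_required = NULL) {
  stopifnot(is.list(seqs))
  if (length(seqs) == 0L) {
    return(list(kept = list(),
                removed = data.frame(id = character(), reason = character(),
                                     stringsAsFactors = FALSE)))
  }
  chains <- vapply(seqs, function(s) s$chain, "")
  if (length(unique(chains)) != 1L) {
    stop("quality_filter requires a single chain type; got: ",
         paste(unique(chains), collapse = ", "))
  }
  if (is.null(fr1_required)) {
    fr1_required <- default_fr1_positions(chains[[1]])
  }
  fr1_required <- as.character(fr1_required)

  kept <- list()
  removed_id <- character()
  removed_reason <- character()
  seen <- character()
  for (s in seqs) {
    key <- residue_map_string(s)
    if (key %in% seen) {
      removed_id <- c(removed_id, s$id)
      removed_reason <- c(removed_reason, "duplicate")
      next
    }
    if (!identical(residue_at(s, "23"), "C") ||
        !identical(residue_at(s, "104"), "C")) {
      removed_id <- c(removed_id, s$id)
      removed_reason <- c(removed_reason, "cysteine_error")
      next
    }
    if (!all(fr1_required %in% s$positions)) {
      removed_id <- c(removed_id, s$id)
      removed_reason <- c(removed_reason, "missing_fr1")
      next
    }
    seen <- c(seen, key)
    kept <- c(kept, list(s))
  }
  list(kept = kept,
       removed = data.frame(id = removed_id, reason = removed_reason,
                            stringsAsFactors = FALSE))
}

# FR1 positions occupied in every built-in germline template of a chain.
default_fr1_positions <- function(chain) {
  templates <- Filter(function(g) g$chain == chain, make_default_germlines())
  if (length(templates) == 0L) stop("no germline templates for chain ", chain)
  fr1 <- lapply(templates, function(g) {
    pos <- names(g$residues)
    pos[assign_region(pos) == "FR1"]
  })
  Reduce(intersect, fr1)
}
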