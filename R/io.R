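#' Reading and writing numbered sequences
#'
#' Two interchange formats are supported: a numbered-sequence CSV (one row per
#' residue, columns `id, chain, imgt_position, residue` and optionally
#' `species, v_gene`) and standard FASTA. FASTA carries no numbering, so
#' reading it requires a pluggable numbering callable (an ANARCI-style
#' backend); none is bundled.
#'
#' @name sequence_io
NULL

#' Write numbered sequences to CSV
#'
#' @param seqs list of [numbered_sequence()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_numbered_csv <- function(seqs, path) {
  rows <- lapply(seqs, function(s) {
    data.frame(id = s$id, chain = s$chain, imgt_position = s$positions,
               residue = s$residues, species = s$species, v_gene = s$v_gene,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read numbered sequences from CSV
#'
#' @param path CSV file with columns `id, chain, imgt_position, residue` and
#'   optional `species, v_gene`. CRLF line endings are tolerated.
#' @return list of [numbered_sequence()] objects in file order.
#' @export
read_numbered_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("id", "chain", "imgt_position", "residue")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !(toupper(df$residue) %in% AA_ALPHABET)
  if (any(bad)) {
    stop("non-amino-acid residue(s) at row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "), " of ", path,
         ": ", paste(unique(df$residue[bad]), collapse = ", "))
  }
  dup <- duplicated(df[, c("id", "imgt_position")])
  if (any(dup)) {
    stop("duplicate (id, position) row(s) in ", path, ": ",
         paste(utils::head(paste(df$id[dup], df$imgt_position[dup]), 5L),
               collapse = "; "))
  }
  has_species <- "species" %in% names(df)
  has_vgene <- "v_gene" %in% names(df)
  ids <- unique(df$id)
  lapply(ids, function(i) {
    d <- df[df$id == i, , drop = FALSE]
    sp <- if (has_species && nzchar(d$species[1])) d$species[1] else NA_character_
    vg <- if (has_vgene && nzchar(d$v_gene[1])) d$v_gene[1] else NA_character_
    numbered_sequence(i, d$chain[1], d$imgt_position, d$residue,
                      species = sp, v_gene = vg, source = path)
  })
}

#' Write sequences as FASTA
#'
#' Residues are concatenated in IMGT order; numbering is not representable in
#' FASTA and is dropped.
#'
#' @inheritParams write_numbered_csv
#' @export
write_fasta <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) {
    c(paste0(">", s$id), paste0(s$residues, collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read FASTA and number it with a pluggable backend
#'
#' @param path FASTA file.
#' @param numberer a callable `function(sequence_string, id)` returning a
#'   [numbered_sequence()]; an ANARCI-style aligner would be wrapped here.
#'   Reading FASTA without one is an error, since this package does not
#'   implement antibody numbering.
#' @return list of [numbered_sequence()] objects.
#' @export
read_fasta <- function(path, numberer = NULL) {
  if (is.null(numberer)) {
    stop("no numberer configured: FASTA input requires a numbering callable ",
         "(ANARCI-style); supply `numberer = function(seq, id) ...` or use ",
         "the numbered CSV format")
  }
  if (!is.function(numberer)) stop("`numberer` must be a function")
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no FASTA records in ", path)
  bounds <- c(headers, length(lines) + 1L)
  out <- vector("list", length(headers))
  for (k in seq_along(headers)) {
    id <- sub("^>\\s*", "", lines[headers[k]])
    id <- sub("\\s.*$", "", id)
    first <- headers[k] + 1L
    last <- bounds[k + 1L] - 1L
    body <- if (first > last) character() else lines[first:last]
    out[[k]] <- numberer(paste0(body, collapse = ""), id)
  }
  out
}
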