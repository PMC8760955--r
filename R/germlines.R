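#' Built-in synthetic germline templates
#'
#' A small fixture set of full-length variable-domain templates standing in
#' for species germline repertoires: three human heavy V genes (V1/V3/V4),
#' one human kappa, one human lambda, and mouse + rat counterparts of each
#' chain. The residues are *synthetic*: generated from a deterministic
#' per-chain pattern with the conserved cysteines at IMGT 23 and 104 and
#' tryptophans at 41 and 118, not copied from germline databases. Human and
#' non-human templates of a chain differ at exactly `signature_positions`
#' framework sites (species-distinct consensus residues) and share their CDR
#' residues, which is the separability the classifiers learn.
#'
#' @name germlines
NULL

# occupied integer positions per chain (synthetic occupancy with conventional
# FR1/CDR gaps, e.g. position 10 absent from heavy FR1)
chain_occupancy <- function(chain) {
  switch(chain,
    heavy = c(1:9, 11:26,            # FR1 (10 unoccupied)
              27:32, 37:38,          # CDR1
              39:55,                 # FR2
              56:62, 65,             # CDR2
              66:80, 83:104,         # FR3 (81-82 unoccupied)
              105:109, 112:117,      # CDR3
              118:128),              # FR4
    kappa = c(1:9, 11:26, 27:31, 38, 39:55, 56:57, 65, 66:80, 83:104,
              105:109, 114:117, 118:128),
    lambda = c(1:9, 11:26, 27:32, 37:38, 39:55, 56:58, 65, 66:80, 83:104,
               105:109, 113:117, 118:128),
    stop("unknown chain: ", chain))
}

# framework positions given species-distinct consensus residues, in the order
# they are consumed when `signature_positions` < length; all outside {23,104}
signature_candidates <- function(chain) {
  base <- c(1, 5, 11, 19, 24, 40, 43, 67, 72, 78, 85, 94,
            3, 14, 21, 46, 50, 69, 76, 88, 99, 120, 123, 126)
  occ <- chain_occupancy(chain)
  as.character(base[base %in% occ])
}

# chain-specific deterministic base residue per position; kappa and lambda use
# different phases so the light-chain type classifier has signal everywhere
base_residue <- function(positions, chain) {
  offset <- switch(chain, heavy = 0L, kappa = 7L, lambda = 13L)
  n <- as.integer(positions)
  AA_ALPHABET[((n * 3L + offset) %% 20L) + 1L]
}

make_template <- function(species, chain, v_gene, signature_positions,
                          n_signature) {
  occ <- as.character(chain_occupancy(chain))
  res <- stats::setNames(base_residue(occ, chain), occ)
  res["23"] <- "C"
  res["104"] <- "C"
  res["41"] <- "W"
  res["118"] <- "W"

  # V-gene identity: a few framework positions distinguishing human V genes
  vg_sites <- list(
    V1 = character(), V3 = c("16", "18", "45", "70", "84"),
    V4 = c("13", "20", "48", "68", "91"), V7 = c("8", "17", "53", "74", "96"),
    KV1 = character(), LV1 = character())
  shift <- function(aa, k) AA_ALPHABET[((match(aa, AA_ALPHABET) - 1L + k) %% 20L) + 1L]
  for (p in vg_sites[[v_gene]]) {
    if (p %in% occ) res[p] <- shift(res[p], 5L)
  }

  # species signature: mouse/rat consensus differ from human (and from each
  # other) at the signature framework positions
  k <- switch(species, human = 0L, mouse = 7L, rat = 11L)
  if (k > 0L) {
    for (p in signature_positions) res[p] <- shift(res[p], k)
  }
  # keep the conserved cysteines/tryptophans even if arithmetic landed there
  res["23"] <- "C"; res["104"] <- "C"

  structure(list(species = species, chain = chain, v_gene = v_gene,
                 residues = res, n_signature = n_signature),
            class = "germline_template")
}

#' Default germline template set
#'
#' @param signature_positions number of framework positions carrying
#'   species-distinct consensus residues (default 12).
#' @return named list of `germline_template` objects: human heavy V1/V3/V4,
#'   human kappa KV1, human lambda LV1, and mouse/rat counterparts of every
#'   human template.
#' @examples
#' names(make_default_germlines())
#' @export
make_default_germlines <- function(signature_positions = 12L) {
  spec <- list(
    c("heavy", "V1"), c("heavy", "V3"), c("heavy", "V4"),
    c("kappa", "KV1"), c("lambda", "LV1"))
  out <- list()
  for (sc in spec) {
    chain <- sc[1]; vg <- sc[2]
    sig <- utils::head(signature_candidates(chain), signature_positions)
    if (length(sig) < signature_positions) {
      stop("signature_positions exceeds available framework candidates for ",
           chain)
    }
    for (sp in c("human", "mouse", "rat")) {
      out[[paste(sp, chain, vg, sep = "_")]] <-
        make_template(sp, chain, vg, sig, length(sig))
    }
  }
  out
}

#' @export
print.germline_template <- function(x, ...) {
  cat(sprintf("<germline_template> %s %s %s  %d positions\n", x$species,
              x$chain, x$v_gene, length(x$residues)))
  invisible(x)
}

#' Germline template as a numbered sequence
#'
#' @param template a `germline_template`.
#' @param id identifier for the resulting sequence (default derived from the
#'   template metadata).
#' @return a [numbered_sequence()].
#' @export
germline_as_sequence <- function(template, id = NULL) {
  if (is.null(id)) {
    id <- paste(template$species, template$chain, template$v_gene, sep = "_")
  }
  numbered_sequence(id, template$chain, names(template$residues),
                    unname(template$residues), species = template$species,
                    v_gene = template$v_gene, source = "germline")
}

#' Signature framework positions of the default templates
#'
#' @param chain chain type.
#' @param signature_positions how many (default 12).
#' @return character vector of IMGT codes.
#' @export
signature_positions_for <- function(chain, signature_positions = 12L) {
  utils::head(signature_candidates(chain), signature_positions)
}
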