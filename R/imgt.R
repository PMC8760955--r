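#' IMGT position codes, ordering and region assignment
#'
#' Variable-domain positions follow the IMGT unique numbering: integer
#' positions 1--128 with optional single-letter insertion codes (e.g. "111A").
#' Insertion codes sort after their integer position in ascending letter order,
#' except on the inward-counting side of the CDR3 loop (position 112), where
#' they sort *before* the integer position in descending letter order, so that
#' 111 < 111A < 111B < ... < 112B < 112A < 112.
#'
#' @name imgt
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
GAP_SYMBOL <- "-"

# region boundaries (IMGT convention), inclusive integer ranges
IMGT_REGIONS <- data.frame(
  region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
  from = c(1, 27, 39, 56, 66, 105, 118),
  to = c(26, 38, 55, 65, 104, 117, 128),
  stringsAsFactors = FALSE
)

#' Parse IMGT position codes
#'
#' @param codes character vector of position codes such as `"23"` or `"111A"`.
#' @return data.frame with columns `code`, `number` (integer) and `insertion`
#'   (`""` when absent).
#' @examples
#' imgt_parse(c("1", "111A", "128"))
#' @export
imgt_parse <- function(codes) {
  codes <- as.character(codes)
  m <- regmatches(codes, regexec("^([0-9]+)([A-Z]?)$", codes))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("invalid IMGT position code(s): ",
         paste(unique(codes[bad]), collapse = ", "))
  }
  number <- as.integer(vapply(m, `[`, "", 2L))
  insertion <- vapply(m, `[`, "", 3L)
  if (any(number < 1L | number > 128L)) {
    stop("IMGT position number out of range 1-128: ",
         paste(unique(codes[number < 1L | number > 128L]), collapse = ", "))
  }
  data.frame(code = codes, number = number, insertion = insertion,
             stringsAsFactors = FALSE)
}

#' Sort key for IMGT position codes
#'
#' Returns a numeric key whose ordering is the IMGT total order, including the
#' inward-counting CDR3 insertion convention at position 112.
#'
#' @param codes character vector of position codes.
#' @return numeric vector of the same length.
#' @export
imgt_key <- function(codes) {
  p <- imgt_parse(codes)
  rank <- ifelse(p$insertion == "", 0L, match(p$insertion, LETTERS))
  key <- p$number * 100
  # ascending insertions after the integer position, except 112: descending
  # insertions before it (the inward-counting side of the CDR3 loop)
  ifelse(p$insertion == "", key,
         ifelse(p$number == 112L, key - rank, key + rank))
}

#' Order position codes in IMGT order
#'
#' @param codes character vector of position codes.
#' @return integer permutation (as from [order()]).
#' @export
imgt_order <- function(codes) order(imgt_key(codes))

#' Assign IMGT positions to regions
#'
#' Framework/CDR boundaries are fixed by the IMGT convention: FR1 1--26,
#' CDR1 27--38, FR2 39--55, CDR2 56--65, FR3 66--104, CDR3 105--117,
#' FR4 118--128. Insertion codes inherit the region of their integer position.
#'
#' @param codes character vector of position codes.
#' @return character vector of region labels
#'   (`"FR1"`, `"CDR1"`, ..., `"FR4"`).
#' @examples
#' assign_region(c("23", "105", "118"))
#' @export
assign_region <- function(codes) {
  p <- imgt_parse(codes)
  idx <- findInterval(p$number, IMGT_REGIONS$from)
  IMGT_REGIONS$region[idx]
}

#' Is a position in the framework?
#'
#' @param codes character vector of position codes.
#' @return logical vector; `TRUE` for FR1--FR4, `FALSE` for CDR1--CDR3.
#' @export
is_framework <- function(codes) {
  grepl("^FR", assign_region(codes))
}
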