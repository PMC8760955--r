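#' Comparing suggested and experimental humanizing mutations
#'
#' Humanization proposals are compared to experimental humanization as sets
#' of framework substitutions (final-state diffs: one entry per position).
#' The overlap ratio (OR) is the percentage of tool-suggested mutations also
#' made experimentally — matching requires the same position *and* the same
#' substituted residue. The adjusted overlap ratio (AOR) also counts a match
#' when the substituted residues fall in the same amino-acid similarity
#' group. The mutation ratio is the number of tool mutations relative to the
#' experimental count. All three round half-up to integer percent.
#'
#' @name evaluation
NULL

round_half_up <- function(x) floor(x + 0.5)

#' Construct a mutation set
#'
#' @param position character vector of IMGT framework position codes.
#' @param from,to parallel residue vectors (`from != to`).
#' @param chain optional chain label.
#' @param id optional sequence identifier.
#' @return data.frame of class `mutation_set` (one row per position).
#' @export
mutation_set <- function(position, from, to, chain = NA_character_,
                         id = NA_character_) {
  position <- as.character(position)
  from <- toupper(from); to <- toupper(to)
  if (length(position) > 0L) {
    if (!all(is_framework(position))) {
      stop("mutation sets are framework-only; offending position(s): ",
           paste(position[!is_framework(position)], collapse = ", "))
    }
    if (any(from == to)) stop("from == to at position(s): ",
                              paste(position[from == to], collapse = ", "))
    if (anyDuplicated(position)) {
      stop("one entry per position (final-state semantics); duplicated: ",
           paste(unique(position[duplicated(position)]), collapse = ", "))
    }
  }
  structure(data.frame(position = position, from = from, to = to,
                       stringsAsFactors = FALSE),
            chain = chain, id = id, class = c("mutation_set", "data.frame"))
}

#' Framework diff between precursor and final sequence
#'
#' @param precursor,final [numbered_sequence()] objects of the same chain
#'   over identical position sets.
#' @return a [mutation_set()]: one entry per framework position whose
#'   residue differs (CDR differences are ignored by definition).
#' @export
diff_sequences <- function(precursor, final) {
  if (!identical(precursor$chain, final$chain)) {
    stop("chain mismatch: ", precursor$chain, " vs ", final$chain)
  }
  if (!identical(precursor$positions, final$positions)) {
    stop("position sets differ between '", precursor$id, "' and '",
         final$id, "'")
  }
  fr <- is_framework(precursor$positions)
  diff <- fr & precursor$residues != final$residues
  mutation_set(precursor$positions[diff], precursor$residues[diff],
               final$residues[diff], chain = precursor$chain,
               id = precursor$id)
}

#' Default amino-acid similarity groups
#'
#' Hydrophobic (A V L I M), aromatic (F W Y), positive (K R H), negative
#' (D E), polar (S T N Q C), special (G P). A stand-in partition; pass a
#' custom named list to the adjusted overlap ratio to use another grouping.
#'
#' @return named list of character vectors partitioning the 20 amino acids.
#' @export
default_similarity_groups <- function() {
  list(hydrophobic = c("A", "V", "L", "I", "M"),
       aromatic = c("F", "W", "Y"),
       positive = c("K", "R", "H"),
       negative = c("D", "E"),
       polar = c("S", "T", "N", "Q", "C"),
       special = c("G", "P"))
}

group_of <- function(residues, groups) {
  all_aa <- unlist(groups, use.names = FALSE)
  if (length(all_aa) != 20L || anyDuplicated(all_aa) ||
      !setequal(all_aa, AA_ALPHABET)) {
    stop("similarity groups must partition the 20 amino acids")
  }
  lab <- rep(names(groups), lengths(groups))
  lab[match(residues, all_aa)]
}

match_count <- function(tool, exp, groups = NULL) {
  if (nrow(exp) == 0L) return(0L)
  i <- match(tool$position, exp$position)
  hit <- !is.na(i)
  if (is.null(groups)) {
    sum(hit & tool$to == exp$to[i])
  } else {
    g_tool <- group_of(tool$to, groups)
    g_exp <- group_of(exp$to, groups)
    sum(hit & (tool$to == exp$to[i] | g_tool == g_exp[i]))
  }
}

#' Overlap ratio (unadjusted)
#'
#' @param tool tool-suggested [mutation_set()] (must be non-empty).
#' @param exp experimental [mutation_set()].
#' @return integer percent (half-up): share of tool mutations matched by an
#'   experimental mutation at the same position with the same target residue.
#' @examples
#' t <- mutation_set(c("5", "11"), c("A", "G"), c("S", "T"))
#' overlap_ratio(t, t)
#' @export
overlap_ratio <- function(tool, exp) {
  if (nrow(tool) == 0L) stop("overlap ratio undefined for an empty tool set")
  round_half_up(100 * match_count(tool, exp) / nrow(tool))
}

#' Overlap ratio adjusted for similar residue types
#'
#' @inheritParams overlap_ratio
#' @param groups similarity partition (default
#'   [default_similarity_groups()]).
#' @return integer percent (half-up).
#' @export
adjusted_overlap_ratio <- function(tool, exp,
                                   groups = default_similarity_groups()) {
  if (nrow(tool) == 0L) stop("overlap ratio undefined for an empty tool set")
  round_half_up(100 * match_count(tool, exp, groups) / nrow(tool))
}

#' Mutation ratio
#'
#' @inheritParams overlap_ratio
#' @return integer percent (half-up): `100 * n_tool / n_exp`.
#' @export
mutation_ratio <- function(tool, exp) {
  if (nrow(exp) == 0L) stop("mutation ratio undefined for an empty ",
                            "experimental set")
  round_half_up(100 * nrow(tool) / nrow(exp))
}

#' Full overlap report for one chain
#'
#' @inheritParams adjusted_overlap_ratio
#' @return list: `n_tool`, `n_exp`, `or`, `aor`, `mutation_ratio`.
#' @export
overlap_report <- function(tool, exp, groups = default_similarity_groups()) {
  list(n_tool = nrow(tool), n_exp = nrow(exp),
       or = overlap_ratio(tool, exp),
       aor = adjusted_overlap_ratio(tool, exp, groups),
       mutation_ratio = mutation_ratio(tool, exp))
}

#' Aggregate overlap metrics over a panel
#'
#' @param reports data.frame with numeric metric columns (e.g. `or`, `aor`,
#'   `mutation_ratio`), one row per chain, or a list of [overlap_report()]
#'   results.
#' @return data.frame with rows `mean` and `median`, each column rounded
#'   half-up to integer percent.
#' @export
aggregate_reports <- function(reports) {
  if (!is.data.frame(reports)) {
    reports <- do.call(rbind, lapply(reports, function(r) {
      data.frame(or = r$or, aor = r$aor, mutation_ratio = r$mutation_ratio)
    }))
  }
  if (nrow(reports) == 0L) stop("no reports to aggregate")
  num <- vapply(reports, is.numeric, TRUE)
  out <- rbind(mean = vapply(reports[num], mean, 0),
               median = vapply(reports[num], stats::median, 0))
  as.data.frame(round_half_up(out))
}

#' Random-humanization baseline
#'
#' Monte-Carlo expectation of OR and AOR for a "humanizer" that picks
#' `n_tool` framework substitutions uniformly at random: positions drawn
#' without replacement from the mutable set, target residue uniform over the
#' 19 alternatives to the precursor residue.
#'
#' @param exp experimental [mutation_set()].
#' @param mutable named character vector mapping mutable framework position
#'   codes to the precursor residue at that position, or a
#'   [numbered_sequence()] (mutable = framework minus `immutable`).
#' @param n_tool number of random substitutions per replicate.
#' @param groups similarity partition for the AOR.
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @param immutable positions excluded when `mutable` is a sequence.
#' @return list: `or`, `aor` (mean percents, unrounded), `se_or`, `se_aor`
#'   (Monte-Carlo standard errors), `reps`.
#' @export
random_baseline <- function(exp, mutable, n_tool,
                            groups = default_similarity_groups(),
                            reps = 1000L, seed = 1L,
                            immutable = c("23", "104")) {
  if (reps < 1L) stop("reps must be >= 1")
  if (inherits(mutable, "numbered_sequence")) {
    keep <- is_framework(mutable$positions) &
      !(mutable$positions %in% immutable)
    mutable <- stats::setNames(mutable$residues[keep],
                               mutable$positions[keep])
  }
  positions <- names(mutable)
  if (n_tool > length(positions)) {
    stop("n_tool exceeds the number of mutable positions")
  }
  set.seed(seed)
  or <- aor <- numeric(reps)
  for (r in seq_len(reps)) {
    pos <- sample(positions, n_tool)
    to <- vapply(pos, function(p) sample(setdiff(AA_ALPHABET, mutable[[p]]),
                                         1L), "")
    tool <- mutation_set(pos, unname(mutable[pos]), to)
    or[r] <- 100 * match_count(tool, exp) / n_tool
    aor[r] <- 100 * match_count(tool, exp, groups) / n_tool
  }
  list(or = mean(or), aor = mean(aor),
       se_or = stats::sd(or) / sqrt(reps),
       se_aor = stats::sd(aor) / sqrt(reps), reps = reps)
}

#' Immunogenicity (ADA) correlation
#'
#' Coefficient of determination of the ordinary-least-squares regression of
#' the percentage of patients developing anti-drug antibodies on the
#' minimum-chain humanness score.
#'
#' @param records data.frame with columns `score` (min-chain humanness, in
#'   \[0, 1\]) and `ada_percent` (in \[0, 100\]); at least 3 rows.
#' @return R-squared in \[0, 1\].
#' @export
ada_correlation <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("score", "ada_percent") %in% names(records)))
  if (nrow(records) < 3L) stop("at least 3 records required")
  if (stats::var(records$score) == 0 || stats::var(records$ada_percent) == 0) {
    stop("degenerate variance: scores or ADA levels are constant")
  }
  fit <- stats::lm(ada_percent ~ score, data = records)
  y <- records$ada_percent
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Positional-category accounting
#'
#' Counts, per mutation set, the mutations falling in a position category
#' (e.g. VH-VL interface or Vernier-zone residues), and — when experimental
#' sets are supplied — the overlap ratio restricted to that category, pooled
#' over the panel.
#'
#' @param tool_sets list of tool [mutation_set()] objects.
#' @param category character vector of framework position codes (non-empty).
#' @param exp_sets optional list of experimental sets, parallel to
#'   `tool_sets`.
#' @return list: `counts` (per-set category mutation counts), `mean_count`,
#'   and `category_or` (pooled percent, `NA` when no tool mutation falls in
#'   the category or `exp_sets` is absent).
#' @export
positional_category_stats <- function(tool_sets, category,
                                      exp_sets = NULL) {
  category <- as.character(category)
  if (length(category) == 0L) stop("empty category")
  if (!all(is_framework(category))) {
    stop("category positions must lie in the framework")
  }
  counts <- vapply(tool_sets, function(s) sum(s$position %in% category), 0L)
  category_or <- NA_real_
  if (!is.null(exp_sets)) {
    stopifnot(length(exp_sets) == length(tool_sets))
    matched <- 0L
    total <- 0L
    for (i in seq_along(tool_sets)) {
      tool_cat <- tool_sets[[i]][tool_sets[[i]]$position %in% category, ,
                                 drop = FALSE]
      total <- total + nrow(tool_cat)
      matched <- matched + match_count(tool_cat, exp_sets[[i]])
    }
    if (total > 0L) category_or <- 100 * matched / total
  }
  list(counts = counts, mean_count = mean(counts), category_or = category_or)
}

#' Benchmark panel of experimentally humanized therapeutics
#'
#' The bundled 25-therapeutic panel of per-chain overlap metrics (unadjusted
#' and adjusted overlap ratio, tool and experimental framework mutation
#' counts, mutation ratio, for VH and VL), used by the aggregate checks.
#'
#' @return data.frame with one row per therapeutic.
#' @export
therapeutic_overlap_panel <- function() {
  path <- system.file("extdata", "therapeutic_overlap_panel.csv",
                      package = "abhumanize", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default VH-VL interface and Vernier-zone position lists
#'
#' Editable stand-in IMGT position sets for positional-category accounting;
#' not authoritative structural definitions.
#'
#' @param category `"interface"` or `"vernier"`.
#' @param chain `"heavy"` or `"light"`.
#' @return character vector of IMGT position codes.
#' @export
default_category_positions <- function(category = c("interface", "vernier"),
                                       chain = c("heavy", "light")) {
  category <- match.arg(category)
  chain <- match.arg(chain)
  sets <- list(
    interface = list(heavy = c("39", "45", "50", "91", "99"),
                     light = c("40", "44", "49", "87", "100")),
    vernier = list(heavy = c("2", "52", "53", "76", "78", "80"),
                   light = c("4", "41", "52", "53", "84", "94")))
  sets[[category]][[chain]]
}
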