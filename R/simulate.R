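#' Synthetic repertoire simulation
#'
#' Emulates germline-derived repertoires: each record is a germline template
#' of its class with region-dependent somatic hypermutation (SHM) applied —
#' a low per-position substitution rate in the framework and a higher rate in
#' the CDRs. Human records are the positive class (split by V gene); mouse
#' and rat records pool into the negative class. Optionally a fraction of
#' records is corrupted with the QC artifacts the quality filter removes
#' (duplicates, cysteine errors, truncated FR1).
#'
#' @name repertoire_sim
NULL

#' Simulation configuration
#'
#' Defaults state the benchmark world of the package: `framework_rate` 0.02
#' and `cdr_rate` 0.08 substitutions per occupied position, 12 signature
#' framework positions, negatives split evenly between mouse and rat.
#'
#' @param n_per_class records per class (human, and non-human pooled).
#' @param chain chain type to simulate.
#' @param framework_rate per-position substitution probability in FR1--FR4.
#' @param cdr_rate per-position substitution probability in CDR1--CDR3.
#' @param species_mix named numeric vector of negative-class species weights.
#' @param signature_positions count of species-distinct framework positions.
#' @param seed master seed; per-record streams are derived from it so any
#'   subset of records is reproducible.
#' @param inject_qc_artifacts corrupt a fraction of records with QC defects.
#' @param qc_fraction fraction corrupted when `inject_qc_artifacts` is TRUE.
#' @param substitution_weights optional 20x20 row-stochastic matrix (rows and
#'   columns in alphabet order, zero diagonal); default uniform over the 19
#'   alternatives.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_class = 1000L, chain = "heavy",
                       framework_rate = 0.02, cdr_rate = 0.08,
                       species_mix = c(mouse = 0.5, rat = 0.5),
                       signature_positions = 12L, seed = 1L,
                       inject_qc_artifacts = FALSE, qc_fraction = 0.05,
                       substitution_weights = NULL) {
  chain <- match.arg(chain, c("heavy", "kappa", "lambda"))
  stopifnot(n_per_class >= 1L,
            framework_rate >= 0, framework_rate <= 1,
            cdr_rate >= 0, cdr_rate <= 1,
            all(species_mix >= 0), sum(species_mix) > 0,
            signature_positions >= 1L,
            qc_fraction >= 0, qc_fraction <= 1)
  if (!is.null(substitution_weights)) {
    stopifnot(is.matrix(substitution_weights),
              all(dim(substitution_weights) == c(20L, 20L)),
              all(abs(rowSums(substitution_weights) - 1) < 1e-8),
              all(diag(substitution_weights) == 0))
  }
  structure(list(n_per_class = as.integer(n_per_class), chain = chain,
                 framework_rate = framework_rate, cdr_rate = cdr_rate,
                 species_mix = species_mix / sum(species_mix),
                 signature_positions = as.integer(signature_positions),
                 seed = as.integer(seed),
                 inject_qc_artifacts = isTRUE(inject_qc_artifacts),
                 qc_fraction = qc_fraction,
                 substitution_weights = substitution_weights),
            class = "sim_config")
}

# deterministic per-record seed below 2^31
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 1009) %% 2147483629)
}

apply_shm <- function(template, config) {
  pos <- names(template$residues)
  res <- unname(template$residues)
  rate <- ifelse(is_framework(pos), config$framework_rate, config$cdr_rate)
  hit <- stats::runif(length(pos)) < rate
  if (any(hit)) {
    w <- config$substitution_weights
    for (i in which(hit)) {
      from <- match(res[i], AA_ALPHABET)
      if (is.null(w)) {
        res[i] <- sample(AA_ALPHABET[-from], 1L)
      } else {
        res[i] <- sample(AA_ALPHABET, 1L, prob = w[from, ])
      }
    }
  }
  list(positions = pos, residues = res)
}

#' Simulate a labeled repertoire
#'
#' Draws `n_per_class` human records (template sampled uniformly over the
#' chain's human V genes) and `n_per_class` non-human records (species by
#' `species_mix`), applies SHM per region, removes exact duplicates, and
#' optionally injects QC artifacts. Identical seeds give identical output.
#'
#' @param config a [sim_config()].
#' @return list of [numbered_sequence()] objects with `species` and `v_gene`
#'   set; attribute `removed_duplicates` reports dedup losses.
#' @examples
#' reps <- simulate_repertoire(sim_config(n_per_class = 5, seed = 42))
#' length(reps)
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  templates <- make_default_germlines(config$signature_positions)
  templates <- Filter(function(g) g$chain == config$chain, templates)
  human <- Filter(function(g) g$species == "human", templates)
  if (length(human) == 0L) stop("no human templates for chain ", config$chain)

  draw_record <- function(i, class) {
    set.seed(derive_seed(config$seed, i))
    if (class == "human") {
      tpl <- human[[sample.int(length(human), 1L)]]
    } else {
      sp <- sample(names(config$species_mix), 1L, prob = config$species_mix)
      pool <- Filter(function(g) g$species == sp, templates)
      if (length(pool) == 0L) stop("no templates for species ", sp)
      tpl <- pool[[sample.int(length(pool), 1L)]]
    }
    mut <- apply_shm(tpl, config)
    numbered_sequence(sprintf("%s_%06d", substr(class, 1, 3), i),
                      config$chain, mut$positions, mut$residues,
                      species = tpl$species, v_gene = tpl$v_gene,
                      source = "simulated")
  }

  n <- config$n_per_class
  seqs <- c(lapply(seq_len(n), draw_record, class = "human"),
            lapply(n + seq_len(n), draw_record, class = "nonhuman"))

  # dedup sampling collisions first; injected artifacts (below) survive so the
  # downstream quality filter has duplicates to catch
  keys <- vapply(seqs, residue_map_string, "")
  dup <- duplicated(keys)
  n_dup <- sum(dup)
  seqs <- seqs[!dup]

  if (config$inject_qc_artifacts) {
    set.seed(derive_seed(config$seed, 0L))
    n_bad <- round(config$qc_fraction * length(seqs))
    victims <- sample.int(length(seqs), n_bad)
    kinds <- sample(c("cysteine", "fr1", "duplicate"), n_bad, replace = TRUE)
    for (k in seq_along(victims)) {
      i <- victims[k]
      s <- seqs[[i]]
      if (kinds[k] == "cysteine") {
        s <- substitute_residue(s, "23", "A")
      } else if (kinds[k] == "fr1") {
        keep <- imgt_key(s$positions) > imgt_key("5")
        s <- numbered_sequence(s$id, s$chain, s$positions[keep],
                               s$residues[keep], species = s$species,
                               v_gene = s$v_gene, source = s$source)
      } else {
        donor <- seqs[[if (i > 1L) i - 1L else length(seqs)]]
        s <- numbered_sequence(s$id, donor$chain, donor$positions,
                               donor$residues, species = donor$species,
                               v_gene = donor$v_gene, source = donor$source)
      }
      seqs[[i]] <- s
    }
  }

  attr(seqs, "removed_duplicates") <- n_dup
  seqs
}
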