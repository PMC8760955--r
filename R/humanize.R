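#' Greedy framework humanization
#'
#' The humanizer makes every possible single-site substitution in the
#' framework region of the input (CDRs and an immutable mask — by default the
#' conserved cysteines 23 and 104 — are never touched), scores all mutants,
#' and accepts the best strictly improving one; this repeats from the new
#' sequence until the target humanness score is reached, no mutant improves
#' the score (plateau), or the iteration cap is hit. Minimizing the number of
#' accepted mutations limits the risk to binding affinity.
#'
#' @name humanizer
NULL

#' Humanization configuration
#'
#' @param target target humanness score in (0, 1\]; `NULL` defers to the
#'   model's calibrated threshold tau at run time (the classification
#'   boundary — the natural default when no experimentally humanized
#'   reference score exists).
#' @param max_iterations iteration cap (default 60).
#' @param immutable IMGT position codes never mutated; default the conserved
#'   cysteines `c("23", "104")`. Must be framework positions.
#' @param allow_revisit whether a position may be mutated more than once
#'   across iterations (default TRUE; the greedy objective is free to refine
#'   earlier choices).
#' @return a `humanization_config` list.
#' @export
humanization_config <- function(target = NULL, max_iterations = 60L,
                                immutable = c("23", "104"),
                                allow_revisit = TRUE) {
  if (!is.null(target)) {
    stopifnot(is.numeric(target), length(target) == 1L, target > 0,
              target <= 1)
  }
  stopifnot(max_iterations >= 1L)
  immutable <- as.character(immutable)
  if (length(immutable) > 0L && !all(is_framework(immutable))) {
    stop("immutable positions must lie in the framework")
  }
  structure(list(target = target, max_iterations = as.integer(max_iterations),
                 immutable = immutable,
                 allow_revisit = isTRUE(allow_revisit)),
            class = "humanization_config")
}

#' Enumerate all single-site framework mutants
#'
#' @param seq a [numbered_sequence()].
#' @param config a [humanization_config()].
#' @return data.frame `position`, `from`, `to` — one row per candidate
#'   substitution (19 per mutable framework position), ordered by IMGT
#'   position then residue (the humanizer's tie-break order).
#' @export
enumerate_mutants <- function(seq, config = humanization_config()) {
  mutable <- seq$positions[is_framework(seq$positions) &
                           !(seq$positions %in% config$immutable)]
  if (length(mutable) == 0L) stop("no mutable framework positions in '",
                                  seq$id, "'")
  mutable <- mutable[imgt_order(mutable)]
  from <- unname(vapply(mutable, function(p) residue_at(seq, p), ""))
  n_alt <- length(AA_ALPHABET) - 1L
  to <- unlist(lapply(from, function(f) setdiff(AA_ALPHABET, f)),
               use.names = FALSE)
  data.frame(position = rep(mutable, each = n_alt),
             from = rep(from, each = n_alt), to = to,
             stringsAsFactors = FALSE)
}

# score every candidate mutant; model path uses one-hot row edits so each
# iteration is a single forest prediction over the candidate matrix
score_mutants <- function(seq, candidates, model) {
  if (is.function(model)) {
    vapply(seq_len(nrow(candidates)), function(i) {
      model(substitute_residue(seq, candidates$position[i],
                               candidates$to[i]))
    }, 0)
  } else {
    universe <- model$universe
    base <- encode_sequence(seq, universe)
    x <- matrix(rep(base, each = nrow(candidates)), nrow = nrow(candidates))
    pos_i <- match(candidates$position, universe)
    if (anyNA(pos_i)) {
      # positions outside the model universe cannot influence the score; give
      # them the base score so they are never selected as improvements
      known <- !is.na(pos_i)
      s <- rep(NA_real_, nrow(candidates))
      if (any(known)) {
        s[known] <- score_mutants(seq, candidates[known, , drop = FALSE],
                                  model)
      }
      s[!known] <- .rf_predict(model$forest, matrix(base, nrow = 1))
      return(s)
    }
    off <- (pos_i - 1L) * BLOCK
    idx <- cbind(seq_len(nrow(candidates)),
                 off + match(candidates$from, AA_ALPHABET))
    x[idx] <- 0L
    idx[, 2] <- off + match(candidates$to, AA_ALPHABET)
    x[idx] <- 1L
    .rf_predict(model$forest, x)
  }
}

score_one <- function(seq, model) {
  if (is.function(model)) model(seq) else score_sequences(model, seq)
}

#' Humanize a sequence by greedy framework substitution
#'
#' @param seq a [numbered_sequence()] precursor.
#' @param model a calibrated `humanness_model` matching the chain, or a plain
#'   scoring `function(seq) -> numeric` (useful for analysis with toy
#'   objectives).
#' @param config a [humanization_config()]. When `config$target` is `NULL`
#'   the model's calibrated tau is used.
#' @return object of class `humanization_trajectory`: the input and final
#'   sequences, an ordered data.frame of accepted steps (`step`, `position`,
#'   `from`, `to`, `score_before`, `score_after`), `reached_target`, and
#'   `stop_reason` in `{"target_reached", "plateau", "max_iterations"}`.
#' @examples
#' \donttest{
#' reps <- simulate_repertoire(sim_config(n_per_class = 150, seed = 3))
#' is_h <- vapply(reps, function(s) s$species == "human", TRUE)
#' pos <- Filter(function(s) identical(s$v_gene, "V1"), reps[is_h])
#' m <- train_model(pos, reps[!is_h], n_estimators = 50, seed = 1)
#' m <- calibrate_threshold(m, reps, as.integer(is_h))
#' mouse <- germline_as_sequence(make_default_germlines()$mouse_heavy_V1)
#' humanize(mouse, m, humanization_config(target = 0.9))
#' }
#' @export
humanize <- function(seq, model, config = humanization_config()) {
  is_model <- !is.function(model)
  if (is_model && !identical(model$chain, seq$chain)) {
    stop("chain mismatch: model is for ", model$chain, ", sequence is ",
         seq$chain)
  }
  target <- config$target
  if (is.null(target)) {
    if (!is_model || is.na(model$threshold)) {
      stop("config$target is NULL and the model has no calibrated threshold")
    }
    target <- model$threshold
  }

  current <- seq
  score <- score_one(current, model)
  steps <- data.frame(step = integer(), position = character(),
                      from = character(), to = character(),
                      score_before = numeric(), score_after = numeric(),
                      stringsAsFactors = FALSE)
  stop_reason <- NA_character_
  mutated <- character()

  for (iter in seq_len(config$max_iterations)) {
    if (score >= target) {
      stop_reason <- "target_reached"
      break
    }
    cand <- enumerate_mutants(current, config)
    if (!config$allow_revisit && length(mutated) > 0L) {
      cand <- cand[!(cand$position %in% mutated), , drop = FALSE]
      if (nrow(cand) == 0L) {
        stop_reason <- "plateau"
        break
      }
    }
    s <- score_mutants(current, cand, model)
    best <- max(s)
    if (best <= score) {
      stop_reason <- "plateau"
      break
    }
    pick <- which(s == best)[1L]  # cand is already in tie-break order
    current <- substitute_residue(current, cand$position[pick],
                                  cand$to[pick])
    steps <- rbind(steps, data.frame(
      step = nrow(steps) + 1L, position = cand$position[pick],
      from = cand$from[pick], to = cand$to[pick], score_before = score,
      score_after = best, stringsAsFactors = FALSE))
    mutated <- c(mutated, cand$position[pick])
    score <- best
  }
  if (is.na(stop_reason)) {
    stop_reason <- if (score >= target) "target_reached" else "max_iterations"
  }

  structure(list(input = seq, final = current, steps = steps,
                 target = target, final_score = score,
                 reached_target = score >= target, stop_reason = stop_reason),
            class = "humanization_trajectory")
}

#' @export
print.humanization_trajectory <- function(x, ...) {
  cat(sprintf(
    "<humanization_trajectory> %s: %d step(s), score %.3f -> %.3f, %s\n",
    x$input$id, nrow(x$steps),
    if (nrow(x$steps) > 0) x$steps$score_before[1] else x$final_score,
    x$final_score, x$stop_reason))
  invisible(x)
}

#' Wrong-V-gene negative-control humanization
#'
#' Scores the input under every supplied model, picks the *lowest*-scoring
#' one (uniformly at random among exact ties, seeded) and humanizes against
#' it — the control showing that V-gene-matched models humanize more
#' efficiently.
#'
#' @param seq a [numbered_sequence()].
#' @param models list of calibrated `humanness_model` objects of the
#'   matching chain (at least 2).
#' @param config a [humanization_config()].
#' @param seed integer seed for tie-breaking.
#' @return a `humanization_trajectory` with an extra `chosen_model` element
#'   (the selected model's V-gene label).
#' @export
negative_control_humanize <- function(seq, models,
                                      config = humanization_config(),
                                      seed = 1L) {
  models <- Filter(function(m) identical(m$chain, seq$chain), models)
  if (length(models) < 2L) {
    stop("need at least two models matching chain ", seq$chain)
  }
  scores <- vapply(models, function(m) score_sequences(m, seq), 0)
  lowest <- which(scores <= min(scores) + 1e-12)
  set.seed(seed)
  pick <- if (length(lowest) > 1L) sample(lowest, 1L) else lowest
  traj <- humanize(seq, models[[pick]], config)
  traj$chosen_model <- models[[pick]]$v_gene
  traj
}
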