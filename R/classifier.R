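#' Per-V-gene humanness classifiers
#'
#' One binary random-forest classifier per human V gene: positives are human
#' sequences of that V gene, negatives the whole non-human pool of the chain.
#' Scores are the mean per-tree positive-class probability, in \[0, 1\]. The
#' classification threshold tau is calibrated on a validation split as the
#' cutpoint maximizing Youden's J statistic (sensitivity + specificity - 1);
#' a sequence is called human when its score strictly exceeds tau for any
#' V-gene model of the chain.
#'
#' @name humanness_classifier
NULL

#' Stratified train/validation/test split
#'
#' Splits labeled records into disjoint partitions, stratified by label with
#' largest-remainder allocation, so class proportions in every partition are
#' within one record of the global proportions.
#'
#' @param labels vector of class labels (one per record).
#' @param fractions numeric length-3 vector summing to 1
#'   (default `c(0.8, 0.1, 0.1)`).
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `validation`, `test`.
#' @examples
#' split_dataset(rep(c("a", "b"), each = 5), seed = 1)
#' @export
split_dataset <- function(labels, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three numbers summing to 1")
  }
  n <- length(labels)
  if (n < 1L) stop("no records to split")
  lr_round <- function(total, frac) {
    base <- floor(total * frac)
    rem <- total - sum(base)
    if (rem > 0) {
      extra <- order(total * frac - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    base
  }
  global <- lr_round(n, fractions)
  allocated <- c(0L, 0L, 0L)
  out <- list(train = integer(), validation = integer(), test = integer())
  set.seed(seed)
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    base <- floor(length(idx) * fractions)
    leftover <- length(idx) - sum(base)
    take <- base
    if (leftover > 0L) {
      # route leftovers to partitions with the largest fractional remainder,
      # breaking ties toward the partition furthest below its global quota
      frac <- length(idx) * fractions - base
      deficit <- global - (allocated + base)
      recipients <- order(-frac, -deficit)[seq_len(leftover)]
      take[recipients] <- take[recipients] + 1L
    }
    cuts <- cumsum(c(0L, take))
    for (j in 1:3) {
      out[[j]] <- c(out[[j]], idx[seq_len(take[j]) + cuts[j]])
    }
    allocated <- allocated + take
  }
  out
}

#' Train a humanness model
#'
#' @param positives list of [numbered_sequence()] objects (human, one V gene).
#' @param negatives list of [numbered_sequence()] objects (non-human pool).
#' @param n_estimators number of trees (default 200).
#' @param seed integer seed for bootstrap/feature sampling.
#' @param universe encoding position universe (default [default_universe()]).
#' @param v_gene optional label; default taken from the positives.
#' @return object of class `humanness_model` with an uncalibrated threshold
#'   (`NA` until [calibrate_threshold()] is applied).
#' @export
train_model <- function(positives, negatives, n_estimators = 200L, seed = 1L,
                        universe = default_universe(), v_gene = NULL) {
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both classes must be non-empty")
  }
  chains <- unique(vapply(c(positives, negatives), function(s) s$chain, ""))
  if (length(chains) != 1L) {
    stop("all training sequences must share a chain; got: ",
         paste(chains, collapse = ", "))
  }
  if (is.null(v_gene)) {
    vg <- unique(stats::na.omit(vapply(positives, function(s) s$v_gene, "")))
    v_gene <- if (length(vg) == 1L) vg else NA_character_
  }
  x <- rbind(encode_matrix(positives, universe),
             encode_matrix(negatives, universe))
  y <- c(rep(1L, length(positives)), rep(0L, length(negatives)))
  mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  forest <- .rf_fit(x, y, as.integer(n_estimators), mtry, 2L)
  structure(
    list(chain = chains, v_gene = v_gene, forest = forest,
         n_estimators = as.integer(n_estimators), universe = universe,
         threshold = NA_real_, metrics = NULL,
         feature_freq_pos = colMeans(x[y == 1L, , drop = FALSE]),
         feature_freq_neg = colMeans(x[y == 0L, , drop = FALSE]),
         meta = list(n_positives = length(positives),
                     n_negatives = length(negatives), seed = as.integer(seed),
                     trained = format(Sys.time(), "%Y-%m-%d"))),
    class = "humanness_model")
}

#' @export
print.humanness_model <- function(x, ...) {
  cat(sprintf(
    "<humanness_model> chain=%s v_gene=%s trees=%d tau=%s (n+ %d, n- %d)\n",
    x$chain, x$v_gene, x$n_estimators,
    ifelse(is.na(x$threshold), "uncalibrated", format(x$threshold)),
    x$meta$n_positives, x$meta$n_negatives))
  invisible(x)
}

#' Score sequences with a humanness model
#'
#' @param model a `humanness_model` (or `chain_type_model`).
#' @param seqs a single [numbered_sequence()] or a list of them.
#' @return numeric vector of scores in \[0, 1\].
#' @export
score_sequences <- function(model, seqs) {
  if (inherits(seqs, "numbered_sequence")) seqs <- list(seqs)
  chains <- vapply(seqs, function(s) s$chain, "")
  ok <- if (identical(model$chain, "light")) {
    chains %in% c("kappa", "lambda")
  } else {
    chains == model$chain
  }
  if (!all(ok)) {
    stop("chain mismatch: model is for ", model$chain, ", input has ",
         paste(unique(chains[!ok]), collapse = ", "))
  }
  .rf_predict(model$forest, encode_matrix(seqs, model$universe))
}

# -- threshold calibration ---------------------------------------------------

# candidate cutpoints: midpoints between adjacent distinct scores, plus 0 & 1
threshold_candidates <- function(scores) {
  s <- sort(unique(scores))
  mids <- if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2 else numeric()
  sort(unique(c(0, mids, 1)))
}

threshold_stats <- function(tau, scores, labels) {
  pos <- labels == 1L
  tp <- sum(scores[pos] > tau)
  fn <- sum(pos) - tp
  tn <- sum(scores[!pos] <= tau)
  fp <- sum(!pos) - tn
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(sensitivity = sens, specificity = spec, yjs = sens + spec - 1,
       mcc = mcc)
}

#' Youden's-J-optimal threshold
#'
#' Searches candidate cutpoints (midpoints of adjacent distinct scores plus
#' the sentinels 0 and 1) for the one maximizing J = sensitivity +
#' specificity - 1 under the strict decision rule `score > tau`. Ties are
#' broken toward the smallest tau (maximizing sensitivity).
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels 0/1 labels (1 = positive class).
#' @return list with `threshold`, `yjs`, `sensitivity`, `specificity`,
#'   `mcc_threshold` (the MCC-maximizing cutpoint) and `mcc`.
#' @export
yjs_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2L) {
    stop("both classes required to calibrate a threshold")
  }
  cands <- threshold_candidates(scores)
  yjs <- mcc <- numeric(length(cands))
  for (i in seq_along(cands)) {
    st <- threshold_stats(cands[i], scores, labels)
    yjs[i] <- st$yjs
    mcc[i] <- st$mcc
  }
  best <- which(yjs >= max(yjs) - 1e-12)[1L]  # smallest tau among ties
  best_mcc <- which(mcc >= max(mcc) - 1e-12)[1L]
  st <- threshold_stats(cands[best], scores, labels)
  list(threshold = cands[best], yjs = st$yjs,
       sensitivity = st$sensitivity, specificity = st$specificity,
       mcc_threshold = cands[best_mcc], mcc = mcc[best_mcc])
}

#' Calibrate a model's threshold on a validation set
#'
#' @param model a `humanness_model`.
#' @param seqs validation sequences.
#' @param labels 0/1 labels for `seqs`.
#' @return the model with `threshold` set and `metrics` holding the
#'   validation statistics (including the MCC-optimal threshold for
#'   comparison).
#' @export
calibrate_threshold <- function(model, seqs, labels) {
  scores <- score_sequences(model, seqs)
  res <- yjs_threshold(scores, labels)
  model$threshold <- res$threshold
  model$metrics <- res
  model
}

#' ROC AUC by the rank statistic
#'
#' AUC as the probability a random positive outscores a random negative,
#' ties counting one half (the Mann-Whitney identity).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a calibrated model on a test set
#'
#' @inheritParams calibrate_threshold
#' @return list with `auc` and the threshold statistics at the model's tau.
#' @export
evaluate_model <- function(model, seqs, labels) {
  if (is.na(model$threshold)) stop("model is uncalibrated")
  scores <- score_sequences(model, seqs)
  st <- threshold_stats(model$threshold, scores, as.integer(labels))
  c(list(auc = roc_auc(scores, labels)), st)
}

# -- classification ----------------------------------------------------------

#' Classify one sequence against all V-gene models of its chain
#'
#' @param models list of calibrated `humanness_model` objects, same chain.
#' @param seq a [numbered_sequence()].
#' @return list (class `score_report`): `scores` (named by V gene),
#'   `thresholds`, `best_v_gene`, `best_score`, `is_human` (TRUE iff at least
#'   one score strictly exceeds its model's tau).
#' @export
classify_sequence <- function(models, seq) {
  if (length(models) == 0L) stop("at least one model required")
  chains <- unique(vapply(models, function(m) m$chain, ""))
  if (length(chains) != 1L) stop("models span multiple chains")
  if (!identical(chains, seq$chain)) {
    stop("chain mismatch: models are for ", chains, ", sequence is ",
         seq$chain)
  }
  vg <- vapply(models, function(m) m$v_gene, "")
  scores <- vapply(models, function(m) score_sequences(m, seq), 0)
  taus <- vapply(models, function(m) m$threshold, 0)
  if (anyNA(taus)) stop("all models must be calibrated")
  names(scores) <- names(taus) <- vg
  best <- which.max(scores)
  structure(list(id = seq$id, chain = seq$chain, scores = scores,
                 thresholds = taus, best_v_gene = unname(vg[best]),
                 best_score = unname(scores[best]),
                 is_human = any(scores > taus)),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> %s (%s): best %s = %.3f, human = %s\n", x$id,
              x$chain, x$best_v_gene, x$best_score, x$is_human))
  invisible(x)
}

#' Combined VH + VL classification
#'
#' A paired antibody is human only when both chains are individually human.
#'
#' @param vh_report a `score_report` for a heavy chain.
#' @param vl_report a `score_report` for a kappa or lambda chain.
#' @return logical scalar.
#' @export
classify_pair <- function(vh_report, vl_report) {
  stopifnot(inherits(vh_report, "score_report"),
            inherits(vl_report, "score_report"))
  heavy <- c(vh_report$chain, vl_report$chain) == "heavy"
  if (sum(heavy) != 1L) {
    stop("classify_pair needs one heavy and one light report; got ",
         vh_report$chain, " + ", vl_report$chain)
  }
  vh_report$is_human && vl_report$is_human
}

# -- kappa / lambda chain-type model -----------------------------------------

#' Train the light-chain type classifier
#'
#' A forest discriminating kappa from lambda light chains, applied before
#' light-chain humanness scoring to route a sequence to the right model set.
#'
#' @param kappa_seqs list of kappa [numbered_sequence()] objects.
#' @param lambda_seqs list of lambda [numbered_sequence()] objects.
#' @param n_estimators number of trees.
#' @param seed integer seed.
#' @return object of class `chain_type_model`.
#' @export
train_chain_type_model <- function(kappa_seqs, lambda_seqs,
                                   n_estimators = 200L, seed = 1L) {
  ok <- function(ss, ch) all(vapply(ss, function(s) s$chain, "") == ch)
  if (!ok(kappa_seqs, "kappa") || !ok(lambda_seqs, "lambda")) {
    stop("inputs must be kappa sequences and lambda sequences respectively")
  }
  universe <- default_universe()
  x <- rbind(encode_matrix(kappa_seqs, universe),
             encode_matrix(lambda_seqs, universe))
  y <- c(rep(1L, length(kappa_seqs)), rep(0L, length(lambda_seqs)))
  set.seed(seed)
  forest <- .rf_fit(x, y, as.integer(n_estimators),
                    max(1L, floor(sqrt(ncol(x)))), 2L)
  structure(list(chain = "light", forest = forest, universe = universe,
                 n_estimators = as.integer(n_estimators)),
            class = c("chain_type_model", "humanness_model"))
}

#' Classify a light chain as kappa or lambda
#'
#' @param model a `chain_type_model`.
#' @param seq a light-chain [numbered_sequence()] (heavy chains are
#'   rejected).
#' @return `"kappa"` or `"lambda"`.
#' @export
classify_chain_type <- function(model, seq) {
  stopifnot(inherits(model, "chain_type_model"))
  if (seq$chain == "heavy") {
    stop("chain-type classification applies to light chains only")
  }
  score <- .rf_predict(model$forest,
                       encode_matrix(list(seq), model$universe))
  if (score > 0.5) "kappa" else "lambda"
}

# -- feature importance ------------------------------------------------------

#' Ranked feature importances of a humanness model
#'
#' Impurity-decrease importances of the forest, mapped back through the
#' one-hot encoding to (IMGT position, residue) pairs, with the frequency of
#' that residue at that position in the positive and negative training sets.
#'
#' @param model a trained `humanness_model`.
#' @param top_k how many features to return (default 10).
#' @return data.frame `position`, `residue` (`"-"` for the gap state),
#'   `region`, `importance`, `freq_positives`, `freq_negatives`, ordered by
#'   decreasing importance.
#' @export
feature_importance <- function(model, top_k = 10L) {
  if (top_k < 1L) stop("top_k must be >= 1")
  imp <- model$forest$importance
  ord <- utils::head(order(imp, decreasing = TRUE), top_k)
  out <- feature_identity(ord, model$universe)
  out$region <- assign_region(out$position)
  out$importance <- imp[ord]
  out$freq_positives <- unname(model$feature_freq_pos[ord])
  out$freq_negatives <- unname(model$feature_freq_neg[ord])
  out
}
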