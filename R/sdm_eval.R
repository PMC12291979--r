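#' Area under the ROC curve (rank formulation)
#'
#' The probability that a randomly chosen presence outranks a randomly
#' chosen absence, with ties counted one half: computed from midranks, so
#' it equals the exhaustive mean over all presence-absence pairs.
#'
#' @param scores numeric prediction scores.
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
computeAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' True Skill Statistic of a binary prediction
#'
#' Sensitivity (fraction of presences predicted present) plus specificity
#' (fraction of absences predicted absent) minus one.
#'
#' @param predLabels predicted logical or 0/1 vector.
#' @param trueLabels true logical or 0/1 vector; both classes required.
#' @return TSS in `[-1, 1]`.
#' @export
computeTSS <- function(predLabels, trueLabels) {
  p <- as.logical(predLabels); y <- as.logical(trueLabels)
  if (length(p) != length(y)) stop("length mismatch")
  if (!any(y) || all(y))
    stop("both classes must be present in the truth to compute TSS")
  sens <- sum(p & y) / sum(y)
  spec <- sum(!p & !y) / sum(!y)
  sens + spec - 1
}

#' TSS-maximizing score threshold
#'
#' Exhaustive scan over all distinct score values as candidate cutoffs
#' (prediction rule `score >= cutoff`), returning the cutoff with maximal
#' TSS; ties resolve to the smallest such cutoff (deterministic).
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 vector; both classes required.
#' @return list with `threshold` and the achieved `tss`.
#' @export
tssThreshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present to choose a threshold")
  cand <- sort(unique(scores))
  if (length(cand) < 2)
    stop("degenerate scores: all values identical, no threshold exists")
  tss <- vapply(cand, function(t) computeTSS(scores >= t, labels),
                numeric(1))
  best <- which.max(tss)  # which.max returns the first (smallest) maximizer
  list(threshold = cand[best], tss = tss[best])
}

# Stratified fold assignment: each class is split into k near-equal folds
# at random. Returns an integer fold id per observation.
stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    i <- which(labels == cls)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of a learner
#'
#' For each of `repeats` repetitions the presence/background data are split
#' into `k` stratified folds (so each fold trains on (k-1)/k of the data,
#' 80% under the default k = 5). Held-out AUC is computed per fold, and
#' held-out TSS at the TSS-maximizing threshold of the fold's own test
#' scores; both are averaged over all `k * repeats` evaluations.
#'
#' @param learner a learner object (see [makeLogisticLearner()]).
#' @param X numeric predictor matrix (presences stacked over absences).
#' @param y logical/0-1 response (TRUE = presence); at least `k` of each
#'   class required.
#' @param k folds (default 5).
#' @param repeats repetitions (default 10).
#' @param seed integer seed.
#' @return an [EvaluationRecord-class]; the per-fold AUC/TSS values are
#'   attached as attribute `foldValues`.
#' @export
crossValidate <- function(learner, X, y, k = 5, repeats = 10, seed) {
  y <- as.logical(y)
  if (sum(y) < k || sum(!y) < k)
    stop(sprintf("need at least %d presences and %d absences for %d folds",
                 k, k, k))
  withSeed(seed, {
    aucs <- numeric(0); tsss <- numeric(0)
    for (r in seq_len(repeats)) {
      fold <- stratifiedFolds(y, k)
      for (f in seq_len(k)) {
        tr <- fold != f
        model <- learner$fit(X[tr, , drop = FALSE], y[tr])
        sc <- learner$predict(model, X[!tr, , drop = FALSE])
        aucs <- c(aucs, computeAUC(sc, y[!tr]))
        th <- tryCatch(tssThreshold(sc, y[!tr]),
                       error = function(e) list(tss = NA_real_))
        tsss <- c(tsss, th$tss)
      }
    }
    rec <- new("EvaluationRecord", learnerId = learner$id,
               auc = mean(aucs), tss = mean(tsss, na.rm = TRUE),
               folds = as.integer(k), repeats = as.integer(repeats))
    attr(rec, "foldValues") <- data.frame(auc = aucs, tss = tsss)
    rec
  })
}
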