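# Two-stage sampling-based classification with decision-fusion accounting.
#
# Stage 1: logistic regression on the original imbalanced training set;
# with a majority of non-binding (class 0) rows it maximizes detection of
# true negatives. Stage 2: Gaussian NB or KNN on the class-inverted
# (minority-biased) training set built by undersampling + SMOTE; it
# maximizes detection of true positives. The fusion ledger reconciles both
# stages on the same fixed test set and credits a sample as handled
# correctly when EITHER stage classifies it correctly.

stage_result <- function(stage, labels, scores, y_true) {
  structure(
    list(stage = stage, labels = as.integer(labels), scores = scores,
         counts = confusion(y_true, labels)),
    class = "stage_result"
  )
}

#' @export
print.stage_result <- function(x, ...) {
  m <- class_metrics(x$counts)
  cat(sprintf("<stage_result> stage %s: Acc=%.1f%% Se=%.3f Sp=%.3f\n",
              x$stage, m$accuracy, m$sensitivity, m$specificity))
  invisible(x)
}

#' Run stage 1: logistic regression on the original training set
#'
#' @param train,test [labeled_dataset()] objects from one shared split.
#' @param C,max_iter,tol,threshold,standardize Passed to [fit_logistic()].
#' @return A `stage_result` (stage `"1"`) holding test-set predictions,
#'   probability scores, and confusion counts.
#' @export
run_stage1 <- function(train, test, C = 5, max_iter = 500L, tol = 1e-8,
                       threshold = 0.5, standardize = TRUE) {
  model <- fit_logistic(train, C = C, max_iter = max_iter, tol = tol,
                        threshold = threshold, standardize = standardize)
  pred <- predict_logistic(model, test)
  out <- stage_result("1", pred$labels, pred$probabilities, test$labels)
  out$model <- model
  out
}

#' Run stage 2: SMOTE-rebalanced learner on the inverted training set
#'
#' Applies [invert_class_balance()] to the training set (undersample class 0
#' to the original class-1 count; SMOTE class 1 up to the original class-0
#' count), then fits the chosen learner and predicts the SAME fixed test set
#' used by stage 1. The swapped class counts of the inverted set are
#' asserted inside the run.
#'
#' @param train,test [labeled_dataset()] objects from one shared split.
#' @param learner `"gaussian_nb"` (aliases `"gnb"`, `"gb"`) or `"knn"`.
#' @param smote A [smote_config()].
#' @param seed Integer seed for the undersampling draw.
#' @param knn A [knn_config()] (used when `learner = "knn"`).
#' @param var_floor Passed to [fit_gaussian_nb()].
#' @return A `stage_result` (stage `"2"`) with scores = GNB class-1
#'   posterior or KNN vote fraction.
#' @export
run_stage2 <- function(train, test, learner = c("gaussian_nb", "gnb", "gb", "knn"),
                       smote = smote_config(), seed = 0L,
                       knn = knn_config(), var_floor = NULL) {
  learner <- match.arg(learner)
  n0 <- sum(train$labels == 0L)
  n1 <- sum(train$labels == 1L)
  inverted <- invert_class_balance(train, config = smote, seed = seed)
  stopifnot(sum(inverted$labels == 0L) == min(n0, n1),
            nrow(inverted$features) == nrow(train$features))
  if (learner == "knn") {
    pred <- predict_knn(inverted, test, config = knn)
    out <- stage_result("2", pred$labels, pred$scores, test$labels)
    out$learner <- "smote_knn"
  } else {
    model <- fit_gaussian_nb(inverted, var_floor = var_floor)
    pred <- predict_gaussian_nb(model, test)
    out <- stage_result("2", pred$labels, pred$posteriors[, 2L], test$labels)
    out$learner <- "smote_gnb"
    out$model <- model
  }
  out
}

#' Construct a fusion ledger from its cells
#'
#' Direct constructor for re-deriving fused metrics from counts printed in
#' published tables; [fuse()] builds the same object from per-sample
#' predictions. Only the invariants linking supplied cells are checked;
#' cells not needed for a given metric may be left `NA`.
#'
#' @param TP1,TN1,FN1,FP1 Stage-1 confusion cells.
#' @param TP2,TN2 Stage-2 confusion cells.
#' @param reconfirmed_TP2 Samples with true class 1 predicted 1 by both stages.
#' @param new_TP2 True-1 samples missed by stage 1 but caught by stage 2.
#' @param new_TN2 True-0 samples missed by stage 1 but caught by stage 2.
#' @param Ntest1,Ntest0 Class sizes of the fixed test set.
#' @return Object of class `fusion_ledger`.
#' @export
fusion_ledger <- function(TP1 = NA, TN1 = NA, FN1 = NA, FP1 = NA,
                          TP2 = NA, TN2 = NA, reconfirmed_TP2 = NA,
                          new_TP2 = NA, new_TN2 = NA,
                          Ntest1 = NA, Ntest0 = NA) {
  x <- list(TP1 = TP1, TN1 = TN1, FN1 = FN1, FP1 = FP1, TP2 = TP2, TN2 = TN2,
            reconfirmed_TP2 = reconfirmed_TP2, new_TP2 = new_TP2,
            new_TN2 = new_TN2, Ntest1 = Ntest1, Ntest0 = Ntest0)
  x <- lapply(x, function(v) if (is.na(v)) NA_integer_ else as.integer(v))
  ok <- function(...) all(!is.na(unlist(list(...))))
  if (ok(x$TP2, x$reconfirmed_TP2, x$new_TP2) &&
      x$new_TP2 != x$TP2 - x$reconfirmed_TP2) {
    stop("ledger violation: new_TP2 != TP2 - reconfirmed_TP2", call. = FALSE)
  }
  if (ok(x$new_TP2, x$FN1) && x$new_TP2 > x$FN1) {
    stop("ledger violation: new_TP2 > FN1", call. = FALSE)
  }
  if (ok(x$new_TN2, x$FP1) && x$new_TN2 > x$FP1) {
    stop("ledger violation: new_TN2 > FP1", call. = FALSE)
  }
  x$Ntest <- if (ok(x$Ntest1, x$Ntest0)) x$Ntest1 + x$Ntest0 else NA_integer_
  structure(x, class = "fusion_ledger")
}

#' @export
print.fusion_ledger <- function(x, ...) {
  cat(sprintf(paste0(
    "<fusion_ledger> TP1=%s TN1=%s | new TP2=%s new TN2=%s ",
    "reconfirmed TP2=%s | Ntest1=%s Ntest0=%s\n"),
    x$TP1, x$TN1, x$new_TP2, x$new_TN2, x$reconfirmed_TP2,
    x$Ntest1, x$Ntest0))
  invisible(x)
}

#' Reconcile two stage results into a fusion ledger
#'
#' Per-sample accounting over the shared test set:
#' `reconfirmed_TP2` = true-1 samples predicted 1 by both stages;
#' `new_TP2` = true-1 samples missed by stage 1 and caught by stage 2;
#' `new_TN2` = true-0 samples missed by stage 1 and caught by stage 2.
#' This accounting uses the true labels to resolve stage disagreements, so
#' the fused metrics are an optimistic audit/triage bound, not the output
#' of a deployable label-free classifier (see [fuse_predictions()] for a
#' label-free rule).
#'
#' @param stage1,stage2 `stage_result` objects evaluated on the identical
#'   test set.
#' @param y_true The test labels.
#' @return A `fusion_ledger`.
#' @export
fuse <- function(stage1, stage2, y_true) {
  stopifnot(inherits(stage1, "stage_result"), inherits(stage2, "stage_result"))
  y_true <- check_labels01(y_true, "y_true")
  s1 <- stage1$labels
  s2 <- stage2$labels
  if (length(s1) != length(y_true) || length(s2) != length(y_true)) {
    stop("misaligned test sets: prediction lengths differ from y_true",
         call. = FALSE)
  }
  fusion_ledger(
    TP1 = sum(y_true == 1L & s1 == 1L),
    TN1 = sum(y_true == 0L & s1 == 0L),
    FN1 = sum(y_true == 1L & s1 == 0L),
    FP1 = sum(y_true == 0L & s1 == 1L),
    TP2 = sum(y_true == 1L & s2 == 1L),
    TN2 = sum(y_true == 0L & s2 == 0L),
    reconfirmed_TP2 = sum(y_true == 1L & s1 == 1L & s2 == 1L),
    new_TP2 = sum(y_true == 1L & s1 == 0L & s2 == 1L),
    new_TN2 = sum(y_true == 0L & s1 == 1L & s2 == 0L),
    Ntest1 = sum(y_true == 1L),
    Ntest0 = sum(y_true == 0L)
  )
}

#' Label-free fused predictions
#'
#' The deployable union rule: predict class 1 when either stage predicts 1.
#' This is NOT the accounting behind the fused accuracy metrics; it is
#' provided for honest prospective use where true labels are unknown.
#'
#' @param stage1,stage2 `stage_result` objects on the same test set.
#' @return Integer 0/1 vector.
#' @export
fuse_predictions <- function(stage1, stage2) {
  stopifnot(inherits(stage1, "stage_result"), inherits(stage2, "stage_result"))
  as.integer(stage1$labels == 1L | stage2$labels == 1L)
}

#' Fused accuracy metrics from a fusion ledger
#'
#' `total_accuracy = 100 (TP1 + TN1 + new_TN2 + new_TP2) / Ntest`,
#' `TPacc = 100 (TP1 + new_TP2) / Ntest1`,
#' `TNacc = 100 (TN1 + new_TN2) / Ntest0`.
#' Any metric whose required cells are missing, or whose denominator is
#' zero, is returned as `NA_real_` (undefined marker).
#'
#' @param ledger A `fusion_ledger`.
#' @return List with `total_accuracy`, `TPacc`, `TNacc` (percent).
#' @export
fused_metrics <- function(ledger) {
  stopifnot(inherits(ledger, "fusion_ledger"))
  tot <- with(ledger, {
    if (anyNA(c(TP1, TN1, new_TP2, new_TN2, Ntest)) || Ntest == 0L) NA_real_
    else 100 * (TP1 + TN1 + new_TN2 + new_TP2) / Ntest
  })
  tpacc <- with(ledger, {
    if (anyNA(c(TP1, new_TP2, Ntest1)) || Ntest1 == 0L) NA_real_
    else 100 * (TP1 + new_TP2) / Ntest1
  })
  tnacc <- with(ledger, {
    if (anyNA(c(TN1, new_TN2, Ntest0)) || Ntest0 == 0L) NA_real_
    else 100 * (TN1 + new_TN2) / Ntest0
  })
  list(total_accuracy = tot, TPacc = tpacc, TNacc = tnacc)
}

stage_report <- function(sr) {
  m <- class_metrics(sr$counts)
  roc <- roc_auc(attr(sr, "y_true"), sr$scores)
  list(counts = unclass(sr$counts)[c("TP", "TN", "FN", "FP")],
       accuracy = m$accuracy, sensitivity = m$sensitivity,
       specificity = m$specificity, auc = roc$auc,
       f1 = if (sr$counts$TP + sr$counts$FP + sr$counts$FN > 0)
         f1_score(sr$counts$TP, sr$counts$FP, sr$counts$FN) else NA_real_)
}

#' Run the full two-stage system on one dataset
#'
#' Splits the data, runs stage 1 (logistic regression) and one stage 2 per
#' requested learner on the shared split, fuses each pair, and assembles a
#' structured report. Fully reproducible from (`config`, `seed`): the split,
#' the undersampling draw, and SMOTE each consume a seed derived from the
#' root `seed`.
#'
#' Fused ROC/AUC uses the average of the stage-1 and stage-2 scores — one
#' of several possible constructions for a system whose fusion rule is not
#' score-based; it is labeled as such in the report. Fused F1 is computed
#' from the fused cells (`TP = TP1 + new_TP2` etc.).
#'
#' @param data A [labeled_dataset()].
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer root seed.
#' @param learners Character vector of stage-2 learners
#'   (`"gaussian_nb"`, `"knn"`).
#' @param C,threshold Stage-1 logistic regression settings.
#' @param smote_K SMOTE neighbor count.
#' @param knn_K KNN neighbor count.
#' @return Object of class `two_stage_report`: config echo, split counts,
#'   `stage1`, per-learner `stage2`, and per-learner `fusion` sections.
#' @export
run_two_stage <- function(data, fraction = 0.3, seed = 1L,
                          learners = c("gaussian_nb", "knn"),
                          C = 5, threshold = 0.5, smote_K = 5L, knn_K = 5L) {
  stopifnot(inherits(data, "labeled_dataset"))
  learners <- match.arg(learners, several.ok = TRUE)
  sp <- random_split(data, fraction, derive_seed(seed, "split"))
  y_test <- sp$test$labels

  s1 <- run_stage1(sp$train, sp$test, C = C, threshold = threshold)
  attr(s1, "y_true") <- y_test

  report <- list(
    config = list(fraction = fraction, seed = as.integer(seed),
                  learners = learners, C = C, threshold = threshold,
                  smote_K = as.integer(smote_K), knn_K = as.integer(knn_K)),
    split = list(
      n_train = nrow(sp$train$features), n_test = nrow(sp$test$features),
      train_class0 = sum(sp$train$labels == 0L),
      train_class1 = sum(sp$train$labels == 1L),
      test_class0 = sum(y_test == 0L), test_class1 = sum(y_test == 1L)),
    stage1 = stage_report(s1),
    stage2 = list(), fusion = list()
  )

  for (lrn in learners) {
    tag <- if (lrn == "knn") "smote_knn" else "smote_gnb"
    s2 <- run_stage2(sp$train, sp$test, learner = lrn,
                     smote = smote_config(K = smote_K,
                                          seed = derive_seed(seed, paste0("smote_", tag))),
                     seed = derive_seed(seed, paste0("under_", tag)),
                     knn = knn_config(K = knn_K))
    attr(s2, "y_true") <- y_test
    ledger <- fuse(s1, s2, y_test)
    fm <- fused_metrics(ledger)
    fused_scores <- (s1$scores + s2$scores) / 2
    fused_tp <- ledger$TP1 + ledger$new_TP2
    fused_tn <- ledger$TN1 + ledger$new_TN2
    report$stage2[[tag]] <- stage_report(s2)
    report$fusion[[tag]] <- list(
      ledger = unclass(ledger),
      metrics = fm,
      auc_score_average = roc_auc(y_test, fused_scores)$auc,
      f1_fused_cells = f1_score(fused_tp,
                                ledger$Ntest0 - fused_tn,
                                ledger$Ntest1 - fused_tp))
  }
  structure(report, class = "two_stage_report")
}

#' @export
print.two_stage_report <- function(x, ...) {
  cat(sprintf("Two-stage run: fraction %.2f, seed %d\n",
              x$config$fraction, x$config$seed))
  cat(sprintf("  split: %d train (%d/%d), %d test (%d/%d)  [class0/class1]\n",
              x$split$n_train, x$split$train_class0, x$split$train_class1,
              x$split$n_test, x$split$test_class0, x$split$test_class1))
  cat(sprintf("  stage 1 (LR):       Acc=%5.1f%%  Se=%.3f  Sp=%.3f  AUC=%.3f\n",
              x$stage1$accuracy, x$stage1$sensitivity, x$stage1$specificity,
              x$stage1$auc))
  for (tag in names(x$stage2)) {
    s <- x$stage2[[tag]]
    cat(sprintf("  stage 2 (%-9s): Acc=%5.1f%%  Se=%.3f  Sp=%.3f  AUC=%.3f\n",
                tag, s$accuracy, s$sensitivity, s$specificity, s$auc))
  }
  for (tag in names(x$fusion)) {
    f <- x$fusion[[tag]]$metrics
    cat(sprintf("  fused  (LR+%-9s): Total=%5.1f%%  TPacc=%5.1f%%  TNacc=%5.1f%%\n",
                tag, f$total_accuracy, f$TPacc, f$TNacc))
  }
  invisible(x)
}

#' Write a two-stage report to JSON
#'
#' @param report A `two_stage_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "two_stage_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
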