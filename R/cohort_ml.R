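# Serum-cohort stage: balanced-split sex classification with a random
# forest, optional leak-free BMI correction by residualization, and the
# per-variable fold-change / p-value table (fold change relative to males).

#' Construct a cohort table
#'
#' @param subjects A data.frame with columns \code{id}, \code{sex} (two
#'   labels), \code{age}, \code{bmi} (> 0), plus one numeric column per
#'   lipid feature.
#' @return A \code{cohort_table} (validated data.frame).
#' @export
cohort_table <- function(subjects) {
  need <- c("id", "sex", "bmi")
  miss <- setdiff(need, names(subjects))
  if (length(miss) > 0L) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$id)) stop("duplicated subject ids")
  if (length(unique(subjects$sex)) != 2L) stop("cohort needs exactly two sex labels")
  if (any(subjects$bmi <= 0, na.rm = TRUE)) stop("BMI must be > 0")
  class(subjects) <- c("cohort_table", "data.frame")
  subjects
}

#' Lipid feature columns of a cohort
#' @param cohort A \code{cohort_table}.
#' @return Character vector of feature column names (everything numeric
#'   except id, sex, age, bmi).
#' @export
cohort_features <- function(cohort) {
  setdiff(names(cohort), c("id", "sex", "age", "bmi"))
}

#' Balanced train/test split
#'
#' Draws \code{n_per_class} subjects per sex uniformly without replacement
#' for training (so the model is not biased by class imbalance); every
#' remaining subject is a test subject.
#'
#' @param cohort A \code{cohort_table}.
#' @param n_per_class Training subjects per sex.
#' @param seed Integer RNG seed; the same seed yields the same partition.
#' @return List with \code{train_ids} and \code{test_ids} (disjoint,
#'   exhaustive) and \code{seed}.
#' @export
balanced_split <- function(cohort, n_per_class, seed) {
  sizes <- table(cohort$sex)
  if (n_per_class > min(sizes))
    stop("n_per_class (", n_per_class, ") exceeds smallest class (",
         min(sizes), ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  train <- unlist(lapply(sort(unique(cohort$sex)), function(s) {
    ids <- cohort$id[cohort$sex == s]
    sample(ids, n_per_class)
  }), use.names = FALSE)
  list(train_ids = train,
       test_ids = setdiff(cohort$id, train),
       seed = as.integer(seed))
}

#' Residualize lipid features on BMI
#'
#' Replaces each lipid feature by its residual from a univariate linear
#' regression on BMI. Coefficients are estimated on the training subjects
#' only and applied to everyone (leak-free), and BMI is removed from the
#' feature set, so a subsequent classifier cannot use BMI directly or
#' through its imprint on the lipids.
#'
#' By default the regression acts on log-transformed abundances: lipid
#' signals are right-skewed and covariate effects on them are close to
#' multiplicative, so a linear fit on the raw scale would leave a
#' BMI-correlated remnant. Set \code{log = FALSE} for features already on
#' an additive scale (the residuals are then raw-scale).
#'
#' @param cohort A \code{cohort_table}.
#' @param train_ids Ids used to fit the per-feature regressions.
#' @param log Residualize \code{log(feature)} rather than the raw value
#'   (default TRUE; requires strictly positive features).
#' @return A \code{cohort_table} with residualized features and no
#'   \code{bmi} column (BMI kept as attribute \code{"bmi"} for audit).
#' @export
bmi_correct <- function(cohort, train_ids, log = TRUE) {
  if (any(is.na(cohort$bmi))) stop("BMI missing for some subjects")
  tr <- cohort$id %in% train_ids
  if (stats::sd(cohort$bmi[tr]) == 0) stop("zero-variance BMI in training set")
  out <- cohort
  for (f in cohort_features(cohort)) {
    v <- cohort[[f]]
    if (log) {
      if (any(v <= 0, na.rm = TRUE))
        stop("log-scale correction needs strictly positive '", f,
             "'; use log = FALSE")
      v <- base::log(v)
    }
    fit <- stats::lm(y ~ bmi, data = data.frame(y = v[tr],
                                                bmi = cohort$bmi[tr]))
    out[[f]] <- v - stats::predict(
      fit, newdata = data.frame(bmi = cohort$bmi))
  }
  attr(out, "bmi") <- cohort$bmi
  out$bmi <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Fit and evaluate the sex classifier
#'
#' Trains a random forest (500 trees, sqrt-features at each split, seeded)
#' on the training partition and evaluates on the held-out test set:
#' accuracy at a 0.5 score threshold, balanced accuracy, AUC of the
#' continuous class score, the confusion matrix, and the permutation-based
#' importance ranking.
#'
#' Terminal nodes are kept moderately large (default 5\% of the training
#' set, at least 10): class-probability estimates from fully grown trees
#' collapse toward 0/1 and lose ranking resolution, while
#' probability-machine-style node sizes keep the score honest for AUC.
#'
#' @param cohort A \code{cohort_table} (possibly [bmi_correct()]-ed).
#' @param split A [balanced_split()] partition.
#' @param include_bmi Use BMI as a feature when present. Default TRUE
#'   (mirrors an uncorrected model in which BMI can rank among the drivers).
#' @param ntree Number of trees (default 500).
#' @param nodesize Minimum terminal-node size; default
#'   \code{max(10, ceiling(0.05 * n_train))}.
#' @param seed Integer seed for the forest.
#' @return A \code{cohort_model_report}: list with \code{train_n},
#'   \code{test_n} (named per sex), \code{accuracy_pct},
#'   \code{balanced_accuracy_pct}, \code{auc_pct}, \code{confusion}
#'   (2x2 matrix, rows = truth), \code{importance} (data.frame, ranked),
#'   \code{roc} (data.frame of ROC points), \code{positive_class},
#'   \code{ntree}, \code{seed}.
#' @export
fit_and_evaluate <- function(cohort, split, include_bmi = TRUE,
                             ntree = 500L, nodesize = NULL, seed = 1L) {
  feats <- cohort_features(cohort)
  if (include_bmi && "bmi" %in% names(cohort)) feats <- c(feats, "bmi")
  if (length(feats) == 0L) stop("no features to train on")
  tr <- cohort$id %in% split$train_ids
  te <- cohort$id %in% split$test_ids
  y <- factor(cohort$sex)
  if (length(unique(y[tr])) < 2L) stop("single-class training set")
  pos <- levels(y)[2L]  # score = P(second level)

  x <- as.matrix(cohort[, feats, drop = FALSE])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (is.null(nodesize)) nodesize <- max(10L, ceiling(0.05 * sum(tr)))
  set.seed(seed)
  rf <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                   ntree = ntree, nodesize = nodesize,
                                   importance = TRUE)
  score <- stats::predict(rf, x[te, , drop = FALSE], type = "prob")[, pos]
  pred <- factor(ifelse(score >= 0.5, pos, levels(y)[1L]), levels = levels(y))
  truth <- y[te]

  confusion <- table(truth = truth, predicted = pred)
  acc <- 100 * sum(diag(confusion)) / sum(confusion)
  recalls <- diag(confusion) / rowSums(confusion)
  roc_obj <- pROC::roc(response = truth, predictor = score,
                       levels = levels(y), direction = "<", quiet = TRUE)
  imp <- randomForest::importance(rf, type = 1L)  # permutation importance
  imp_df <- data.frame(variable = rownames(imp),
                       importance = imp[, 1L], stringsAsFactors = FALSE,
                       row.names = NULL)
  imp_df <- imp_df[order(-imp_df$importance), ]
  rownames(imp_df) <- NULL

  structure(list(
    train_n = table(y[tr]), test_n = table(truth),
    accuracy_pct = acc,
    balanced_accuracy_pct = 100 * mean(recalls),
    auc_pct = 100 * as.numeric(pROC::auc(roc_obj)),
    confusion = confusion,
    importance = imp_df,
    roc = data.frame(fpr = 1 - roc_obj$specificities,
                     tpr = roc_obj$sensitivities),
    positive_class = pos, ntree = as.integer(ntree),
    seed = as.integer(seed)),
    class = "cohort_model_report")
}

#' @export
print.cohort_model_report <- function(x, ...) {
  cat("<cohort_model_report>\n",
      "  accuracy ", sprintf("%.1f%%", x$accuracy_pct),
      " (balanced ", sprintf("%.1f%%", x$balanced_accuracy_pct), ")",
      ", AUC ", sprintf("%.1f%%", x$auc_pct), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Per-variable fold changes relative to a reference sex
#'
#' For every lipid feature: fold change = mean(other) / mean(reference)
#' (reference defaults to the male group, so values below 1 mean lower
#' abundance in females) and the nonparametric two-group p-value, floored
#' for display at 2.2e-16, with a Benjamini-Hochberg adjusted column.
#'
#' @param cohort A \code{cohort_table}.
#' @param reference Reference sex label (default "male").
#' @return A data.frame: variable, fold_change, p_value, p_adj, tier,
#'   calculable, ordered by p then variable.
#' @export
variable_fold_changes <- function(cohort, reference = "male") {
  sexes <- unique(cohort$sex)
  if (!reference %in% sexes) stop("reference sex '", reference, "' not in cohort")
  other <- setdiff(sexes, reference)
  rows <- lapply(cohort_features(cohort), function(f) {
    a <- cohort[[f]][cohort$sex == other]   # numerator group
    b <- cohort[[f]][cohort$sex == reference]
    mb <- mean(b, na.rm = TRUE)
    calc <- is.finite(mb) && mb != 0
    fc <- if (calc) mean(a, na.rm = TRUE) / mb else NA_real_
    p <- group_test(a, b)$p_value
    data.frame(variable = f, fold_change = fc, p_value = p_floor(p),
               calculable = calc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$tier <- p_tier(out$p_value)
  out <- out[order(out$p_value, out$variable), ]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  out
}
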