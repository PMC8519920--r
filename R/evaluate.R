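#' Binarise yields into Low/High labels
#'
#' Yields below the threshold are Low, otherwise High: the boundary value
#' itself maps to High.
#'
#' @param yields numeric vector in `[0, 1]`.
#' @param threshold classification cut-off (default 0.2).
#' @return character vector of `"Low"`/`"High"`.
#' @export
#' @examples
#' binarise(c(0.19, 0.2, 1.0))
binarise <- function(yields, threshold = 0.2) {
  ifelse(yields < threshold, "Low", "High")
}

# rank-based AUROC (mid-rank tie handling, equivalent to the trapezoidal
# ROC area); positive class scores should be higher
auroc_score <- function(truth_pos, scores) {
  n_pos <- sum(truth_pos); n_neg <- sum(!truth_pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification report after yield binarisation
#'
#' Scores predicted yields against true labels: per-class precision, recall
#' and F1, Matthews correlation coefficient, AUROC (from the continuous
#' scores, mid-rank tie handling), mean squared error against true yields
#' when supplied, and the confusion counts. High is the positive class.
#'
#' @param truth true labels (`"Low"`/`"High"`), or true yields (numeric, in
#'   which case they are binarised at `threshold`).
#' @param predicted_yields predicted continuous scores in `[0, 1]`.
#' @param threshold binarisation threshold (default 0.2).
#' @param true_yields optional numeric true yields for the MSE.
#' @return an `evaluation_report` list.
#' @export
classification_report <- function(truth, predicted_yields, threshold = 0.2,
                                  true_yields = NULL) {
  if (is.numeric(truth)) {
    true_yields <- true_yields %||% truth
    truth <- binarise(truth, threshold)
  }
  truth <- as.character(truth)
  if (!all(truth %in% c("Low", "High"))) stop("labels must be Low/High")
  if (length(truth) != length(predicted_yields))
    stop("truth and predictions differ in length")
  pred <- binarise(predicted_yields, threshold)
  pos <- truth == "High"; ppos <- pred == "High"
  tp <- sum(pos & ppos); fp <- sum(!pos & ppos)
  fn <- sum(pos & !ppos); tn <- sum(!pos & !ppos)
  prf <- function(tp, fp, fn) {
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
          else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  }
  high <- prf(tp, fp, fn)
  low <- prf(tn, fn, fp) # Low as positive: TP=tn, FP=fn, FN=fp
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  structure(list(
    threshold = threshold,
    per_class = rbind(Low = low, High = high),
    mcc = mcc,
    auroc = auroc_score(pos, predicted_yields),
    mse = if (is.null(true_yields)) NA_real_
          else mean((true_yields - predicted_yields)^2),
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> threshold %.2f\n", x$threshold))
  print(round(x$per_class, 4))
  cat(sprintf("  MCC %.4f  AUROC %s  MSE %s\n", x$mcc,
              ifelse(is.na(x$auroc), "NA", sprintf("%.4f", x$auroc)),
              ifelse(is.na(x$mse), "NA", sprintf("%.5f", x$mse))))
  cat("  confusion:", paste(names(x$confusion), x$confusion, collapse = "  "),
      "\n")
  invisible(x)
}

# misclassified ids by error type, High being the positive class
error_ids <- function(truth, predicted_yields, ids, threshold = 0.2) {
  pred <- binarise(predicted_yields, threshold)
  truth <- as.character(truth)
  list(fp = ids[truth == "Low" & pred == "High"],
       fn = ids[truth == "High" & pred == "Low"])
}

#' Shared and unique misclassifications of two predictors
#'
#' Compares two predictors' false positives and false negatives over the
#' same evaluation set, reporting shared and per-model-unique id sets.
#'
#' @param truth true labels (or true yields).
#' @param pred_a,pred_b the two predictors' continuous predictions.
#' @param ids record identifiers, common to both predictors.
#' @param threshold binarisation threshold.
#' @return nested list: for `fp` and `fn`, the `shared`, `only_a` and
#'   `only_b` id vectors.
#' @export
error_overlap <- function(truth, pred_a, pred_b, ids, threshold = 0.2) {
  if (length(pred_a) != length(ids) || length(pred_b) != length(ids))
    stop("predictions and ids must cover the same records")
  if (is.numeric(truth)) truth <- binarise(truth, threshold)
  ea <- error_ids(truth, pred_a, ids, threshold)
  eb <- error_ids(truth, pred_b, ids, threshold)
  ov <- function(xa, xb) list(shared = intersect(xa, xb),
                              only_a = setdiff(xa, xb),
                              only_b = setdiff(xb, xa))
  list(fp = ov(ea$fp, eb$fp), fn = ov(ea$fn, eb$fn))
}

#' Evaluate a frozen model across temperatures
#'
#' Scores the same model's predictions against each temperature's ground
#' truth, with labels re-derived per temperature: the cross-temperature
#' generalisation protocol.
#'
#' @param model a trained predictor (see [train_model()]).
#' @param ds a `hyb_dataset` carrying yields at all requested temperatures.
#' @param temps temperatures to evaluate.
#' @param split which split to evaluate on.
#' @param threshold binarisation threshold.
#' @return named list of [classification_report()]s, one per temperature.
#' @export
cross_temperature_eval <- function(model, ds, temps = DEFAULT_TEMPERATURES,
                                   split = "test", threshold = 0.2) {
  rec <- dataset_split(ds, split)
  for (tt in temps) {
    if (!paste0("yield_", tt) %in% names(rec))
      stop("dataset lacks yields at ", tt, " C")
  }
  preds <- predict_yield(model, rec$seq_a, rec$seq_b)
  out <- lapply(temps, function(tt) {
    y <- rec[[paste0("yield_", tt)]]
    classification_report(binarise(y, threshold), preds,
                          threshold = threshold, true_yields = y)
  })
  names(out) <- paste0("T", temps)
  out
}
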