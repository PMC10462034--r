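#' Evaluate read calls against ground truth
#'
#' Computes accuracy, a confusion matrix, and (when a positive class is
#' named) precision, recall and F1, each both unweighted and read-length
#' weighted. In signal space there is no basecalled length, so the
#' post-compression query symbol count (`n_symbols`) serves as the length
#' proxy for weighting; reads the classifier abstained on
#' (`"unclassified"`) count as errors and appear in the confusion matrix.
#'
#' @param calls call data.frame (from [classifyReads()] etc.).
#' @param truth truth data.frame with `read_id` and `class`.
#' @param positiveClass optional class label treated as positive for
#'   precision/recall/F1.
#' @param weights optional per-read weights (default `n_symbols`, falling
#'   back to 1).
#' @return list: `accuracy`, `weighted_accuracy`, `confusion`,
#'   `n_unclassified`, and with a positive class also `precision`,
#'   `recall`, `f1`, `precision_weighted`, `recall_weighted`,
#'   `f1_weighted`.
#' @export
evaluateCalls <- function(calls, truth, positiveClass = NULL,
                          weights = NULL) {
  m <- merge(calls, truth[, c("read_id", "class")], by = "read_id")
  if (nrow(m) != nrow(calls))
    warning("some calls had no matching truth record")
  if (is.null(weights)) {
    weights <- if (!is.null(m$n_symbols) && !anyNA(m$n_symbols))
      as.numeric(m$n_symbols) else rep(1, nrow(m))
  }
  hit <- m$predicted_class == m$class
  out <- list(
    accuracy = mean(hit),
    weighted_accuracy = sum(weights * hit) / sum(weights),
    confusion = table(truth = m$class, predicted = m$predicted_class),
    n_unclassified = sum(m$predicted_class == "unclassified"))
  if (!is.null(positiveClass)) {
    prf <- function(w) {
      tp <- sum(w * (m$predicted_class == positiveClass &
                       m$class == positiveClass))
      fp <- sum(w * (m$predicted_class == positiveClass &
                       m$class != positiveClass))
      fn <- sum(w * (m$predicted_class != positiveClass &
                       m$class == positiveClass))
      p <- if (tp + fp > 0) tp / (tp + fp) else 0
      r <- if (tp + fn > 0) tp / (tp + fn) else 0
      f <- if (p + r > 0) 2 * p * r / (p + r) else 0
      c(p, r, f)
    }
    u <- prf(rep(1, nrow(m)))
    w <- prf(weights)
    out$precision <- u[1L]; out$recall <- u[2L]; out$f1 <- u[3L]
    out$precision_weighted <- w[1L]; out$recall_weighted <- w[2L]
    out$f1_weighted <- w[3L]
  }
  out
}
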