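#' Confusion matrix of a score set
#'
#' Disease is the positive class: TP = disease subjects classified as
#' disease, TN = healthy classified healthy, FP = healthy classified
#' disease, FN = disease classified healthy.
#'
#' @param scores A [decision_scores()] tibble (or any data frame with
#'   `predicted` and `true` columns holding `"disease"`/`"healthy"`).
#' @return A list of class `confusion_matrix` with integer fields `TP`,
#'   `FN`, `FP`, `TN`.
#' @export
confusion <- function(scores) {
  stopifnot(is.data.frame(scores),
            all(c("predicted", "true") %in% names(scores)))
  if (nrow(scores) == 0L) stop("empty score set")
  if (anyNA(scores$true)) stop("true labels missing: cannot build a confusion matrix")
  cm <- confusion_counts(scores$true, scores$predicted)
  structure(cm, class = "confusion_matrix")
}

#' @rdname confusion
#' @param TP,FN,FP,TN Non-negative integer counts, for building a confusion
#'   matrix directly from published numbers.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  counts <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(lapply(counts, as.integer), class = "confusion_matrix")
}

confusion_counts <- function(true, predicted) {
  list(TP = sum(true == "disease" & predicted == "disease"),
       FN = sum(true == "disease" & predicted == "healthy"),
       FP = sum(true == "healthy" & predicted == "disease"),
       TN = sum(true == "healthy" & predicted == "healthy"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$TP + x$FN,
                x$FP, x$TN, x$FP + x$TN,
                x$TP + x$FP, x$FN + x$TN, x$TP + x$FN + x$FP + x$TN),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("Disease subjects", "Healthy subjects", "Total"),
                              c("Classified disease", "Classified healthy", "Total")))
  print(m)
  invisible(x)
}

#' Diagnostic-test metrics from a confusion matrix
#'
#' The five standard ratios with disease as the positive class:
#' \describe{
#'   \item{Se}{TP / (TP + FN), sensitivity}
#'   \item{Sp}{TN / (TN + FP), specificity}
#'   \item{PPV}{TP / (TP + FP), positive predictive value}
#'   \item{NPV}{TN / (TN + FN), negative predictive value}
#'   \item{Acc}{(TP + TN) / (TP + FP + TN + FN), accuracy}
#' }
#' A zero denominator yields `NA` for that metric with a warning — never a
#' silent zero.
#'
#' @param cm A `confusion_matrix`.
#' @return Tibble with columns `metric` (Se, Sp, PPV, NPV, Acc) and
#'   `value` (proportions in `[0, 1]`).
#' @examples
#' classification_metrics(confusion_matrix(TP = 17, FN = 2, FP = 3, TN = 17))
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", what))
      return(NA_real_)
    }
    num / den
  }
  tibble::tibble(
    metric = c("Se", "Sp", "PPV", "NPV", "Acc"),
    value = c(
      ratio(cm$TP, cm$TP + cm$FN, "sensitivity"),
      ratio(cm$TN, cm$TN + cm$FP, "specificity"),
      ratio(cm$TP, cm$TP + cm$FP, "PPV"),
      ratio(cm$TN, cm$TN + cm$FN, "NPV"),
      ratio(cm$TP + cm$TN, cm$TP + cm$FN + cm$FP + cm$TN, "accuracy")
    )
  )
}

#' Printed-style percentage rounding
#'
#' Formats metric proportions the two ways clinical reports print them:
#' nearest-integer percent and one-decimal percent.
#'
#' @param metrics Output of [classification_metrics()].
#' @return The tibble with added columns `pct_integer` and `pct_1dp`.
#' @export
format_metrics_percent <- function(metrics) {
  dplyr::mutate(metrics,
                pct_integer = round(.data$value * 100),
                pct_1dp = round(.data$value * 100, 1))
}

#' Mann-Whitney U comparison of two score samples
#'
#' Computes `U` for the first sample (number of pairs `(x, y)` with
#' `x > y`, ties counting 1/2) and a two-sided p-value: by exhaustive
#' enumeration of all rank assignments when the combined sample size is at
#' most `exact_max_n` (default 12), otherwise by the normal approximation
#' with tie and continuity corrections. The method used is recorded in the result.
#'
#' @param x,y Numeric score vectors (each nonempty).
#' @param exact_max_n Largest combined n for the exact enumeration path.
#' @return List with `U`, `p`, `method` (`"exact"` or `"normal"`), `n1`,
#'   `n2`. If every value is tied across both samples, `p = 1` with a
#'   warning.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact_max_n = 12) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x)
  n2 <- length(y)
  if (all(c(x, y) == c(x, y)[1])) {
    warning("all values tied across both samples; p = 1")
    return(list(U = n1 * n2 / 2, p = 1, method = "degenerate",
                n1 = n1, n2 = n2))
  }
  U <- mw_u(x, y)
  if (n1 + n2 <= exact_max_n) {
    # enumerate every assignment of the pooled values to sample 1
    pooled <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(idx) mw_u(pooled[idx], pooled[-idx]))
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nties <- table(c(x, y))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
    # continuity-corrected two-sided normal approximation
    z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = min(p, 1), method = method, n1 = n1, n2 = n2)
}

# U statistic for sample x vs y (pairs with x > y; ties count 1/2)
mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Full evaluation report for a score set
#'
#' Bundles the confusion matrix, the five diagnostic metrics and the
#' Mann-Whitney comparison of disease vs healthy decision scores.
#'
#' @param scores A [decision_scores()] tibble with true labels.
#' @return List of class `eval_report` with `counts`, `metrics`,
#'   `mann_whitney`.
#' @export
evaluate_scores <- function(scores) {
  cm <- confusion(scores)
  mt <- classification_metrics(cm)
  mw <- mann_whitney(scores$score[scores$true == "disease"],
                     scores$score[scores$true == "healthy"])
  structure(list(counts = cm, metrics = mt, mann_whitney = mw),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$counts)
  cat("\n")
  print(format_metrics_percent(x$metrics))
  cat(sprintf("\nMann-Whitney U = %.1f, two-sided p = %.4g (%s)\n",
              x$mann_whitney$U, x$mann_whitney$p, x$mann_whitney$method))
  invisible(x)
}
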