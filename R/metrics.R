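# Diagnostic agreement statistics: 2x2 confusion tables, validity metrics,
# Cohen's kappa with Landis-Koch interpretation, and the large-sample kappa
# z-test.

#' Build a 2x2 confusion table for one diagnostic category
#'
#' Tabulates algorithm calls against gold-standard labels by the usual
#' convention (positive = category present): `tp` both positive, `fp`
#' prediction-only, `fn` gold-only, `tn` both negative.
#'
#' @param pred,gold logical (or 0/1) vectors, optionally named by worker id.
#'   If both are named, they are aligned by name and the id sets must match.
#' @return an object of class `"confusion_table"` with integer fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, gold) {
  if (!is.null(names(pred)) && !is.null(names(gold))) {
    extra <- setdiff(names(pred), names(gold))
    miss <- setdiff(names(gold), names(pred))
    if (length(extra) || length(miss)) {
      stop("worker id sets differ; only in pred: [",
           paste(extra, collapse = ", "), "], only in gold: [",
           paste(miss, collapse = ", "), "]", call. = FALSE)
    }
    gold <- gold[names(pred)]
  } else if (length(pred) != length(gold)) {
    stop("pred and gold have different lengths", call. = FALSE)
  }
  p <- as.logical(pred)
  g <- as.logical(gold)
  if (anyNA(p) || anyNA(g)) stop("labels must be binary with no missing values",
                                 call. = FALSE)
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 fn = sum(!p & g), tn = sum(!p & !g)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(pred = c("pos", "neg"), gold = c("pos", "neg")))
  print(m)
  invisible(x)
}

.ct_n <- function(c) c$tp + c$fp + c$fn + c$tn

#' Validity metrics from a confusion table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each as a
#' proportion in \[0, 1\]. A metric whose denominator is zero is undefined
#' and returned as `NA` — never coerced to 0 or 1.
#'
#' @param c a [confusion()] table with at least one observation.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
metric_set <- function(c) {
  if (.ct_n(c) == 0L) stop("empty confusion table", call. = FALSE)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  list(sensitivity = ratio(c$tp, c$tp + c$fn),
       specificity = ratio(c$tn, c$tn + c$fp),
       ppv = ratio(c$tp, c$tp + c$fp),
       npv = ratio(c$tn, c$tn + c$fn))
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement between the algorithm and the gold standard:
#' with observed agreement `po = (tp+tn)/n` and chance agreement
#' `pe = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / n^2`,
#' `kappa = (po - pe) / (1 - pe)`.
#'
#' When `pe == 1` (both raters constant, e.g. an all-negative fold of a rare
#' category) the formula is 0/0; kappa is then defined as 1 if agreement is
#' perfect and 0 otherwise, with a warning.
#'
#' @param c a [confusion()] table with at least one observation.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(c) {
  n <- .ct_n(c)
  if (n == 0L) stop("empty confusion table", call. = FALSE)
  po <- (c$tp + c$tn) / n
  pe <- ((c$tp + c$fp) * (c$tp + c$fn) + (c$fn + c$tn) * (c$fp + c$tn)) / n^2
  if (pe == 1) {
    warning("both raters constant (pe = 1); kappa set by convention",
            call. = FALSE)
    return(if (po == 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Large-sample z-test of kappa against zero
#'
#' Tests H0: kappa = 0 using the standard error of kappa under the null,
#' `se0 = sqrt(pe + pe^2 - sum_i p_i. p_.i (p_i. + p_.i)) / ((1 - pe) sqrt(n))`,
#' the classic large-sample result for agreement tables. Returns the z
#' statistic and two-sided p-value.
#'
#' @param c a [confusion()] table.
#' @return list with `kappa`, `z`, `p_value` (`NA` when degenerate).
#' @export
kappa_ztest <- function(c) {
  n <- .ct_n(c)
  if (n == 0L) stop("empty confusion table", call. = FALSE)
  k <- suppressWarnings(cohens_kappa(c))
  p_r <- c(c$tp + c$fp, c$fn + c$tn) / n  # prediction margins (pos, neg)
  p_c <- c(c$tp + c$fn, c$fp + c$tn) / n  # gold margins
  pe <- sum(p_r * p_c)
  if (pe >= 1) return(list(kappa = k, z = NA_real_, p_value = NA_real_))
  se0 <- sqrt(pe + pe^2 - sum(p_r * p_c * (p_r + p_c))) / ((1 - pe) * sqrt(n))
  z <- k / se0
  list(kappa = k, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Interpret a kappa value on the Landis-Koch scale
#'
#' Maps kappa to the conventional agreement bands: `<= 0` no agreement,
#' `(0, 0.20]` slight, `(0.20, 0.40]` fair, `(0.40, 0.60]` moderate,
#' `(0.60, 0.80]` substantial, `(0.80, 1.00]` almost perfect.
#'
#' @param kappa a value in \[-1, 1\].
#' @return character band label.
#' @export
interpret_kappa <- function(kappa) {
  if (!is.finite(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  if (kappa <= 0) "no agreement"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Round half away from zero
#'
#' Report-time rounding used for the summary tables (base R's `round()`
#' rounds half to even). Internal computations are never rounded.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
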