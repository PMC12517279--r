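# k-fold cross-validation harness: fold planning, per-fold agreement
# metrics, and the fold-mean +/- SD report.

#' Plan a k-fold partition of workers
#'
#' Seeded uniform shuffle of the worker ids followed by a contiguous split
#' into `k` folds whose sizes differ by at most one (320 workers with
#' `k = 5` gives five folds of 64). Reproducible: the same ids and seed
#' always yield the same assignment, and the caller's RNG state is left
#' untouched.
#'
#' @param worker_ids character vector of unique ids.
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return an object of class `"fold_plan"`: `k`, `seed`, and `assignment`
#'   (named integer vector, id -> fold in `1..k`).
#' @export
kfold_plan <- function(worker_ids, k = 5, seed = 1) {
  worker_ids <- as.character(worker_ids)
  n <- length(worker_ids)
  if (anyDuplicated(worker_ids)) stop("worker ids must be unique",
                                      call. = FALSE)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the number of workers (", n, ")",
                  call. = FALSE)
  shuffled <- withr::with_seed(seed, sample(worker_ids))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  assignment <- rep.int(seq_len(k), sizes)
  names(assignment) <- shuffled
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignment = assignment), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d, seed = %d, fold sizes: %s\n", x$k, x$seed,
              paste(tabulate(x$assignment, x$k), collapse = ", ")))
  invisible(x)
}

.gold_matrix <- function(gold, categories = .CATEGORIES) {
  stopifnot(is.data.frame(gold), "worker_id" %in% names(gold))
  missing_cols <- setdiff(categories, names(gold))
  if (length(missing_cols)) {
    stop("gold table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(gold[categories]) > 0
  rownames(m) <- as.character(gold$worker_id)
  m
}

#' Cross-validate the rule engine against gold-standard labels
#'
#' Partitions the workers into `k` folds, audits the rules on each training
#' split (the engine has no fitted parameters, so training is a documented
#' no-op that records the training-fold category prevalences), classifies
#' each held-out test fold, and reports per-category sensitivity,
#' specificity, PPV, NPV and Cohen's kappa as fold-wise mean and SD, plus
#' pooled metrics over the concatenated test folds. Because the engine is
#' deterministic and untrained, the pooled metrics equal the whole-dataset
#' metrics for any fold seed.
#'
#' Evaluation is worker-level one-vs-rest per category. A fold metric whose
#' denominator is zero (e.g. no gold positives of a rare category in that
#' fold) is undefined and excluded from the mean/SD, with the exclusion
#' counted in the summary.
#'
#' @param records list of `worker_record`s.
#' @param gold data.frame in the gold dialect: `worker_id` plus 0/1 columns
#'   `normal`, `hearing_loss`, `hearing_impairment`, `psts`, `tsts`, `nihl`.
#' @param cfg a [rule_config()].
#' @param k folds (default 5).
#' @param seed fold-partition seed.
#' @param sd_type `"sample"` (divide by k-1; default) or `"population"`
#'   (divide by k) for the SD across fold values.
#' @return an object of class `"cv_report"`; see Details. Fields:
#'   `fold_metrics` (long data.frame: fold x category x metric value),
#'   `summary` (per category x metric: mean, sd, folds used/excluded),
#'   `pooled` (whole-dataset metrics, kappa z-test p-value and Landis-Koch
#'   band), `train_prevalence`, `plan`, `sd_type`.
#' @export
cross_validate <- function(records, gold, cfg = rule_config(), k = 5,
                           seed = 1, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  ids <- vapply(records, `[[`, "", "worker_id")
  gm <- .gold_matrix(gold)
  missing_gold <- setdiff(ids, rownames(gm))
  if (length(missing_gold)) {
    stop("missing gold label for worker(s): ",
         paste(utils::head(missing_gold, 5), collapse = ", "), call. = FALSE)
  }
  gm <- gm[ids, , drop = FALSE]

  # deterministic engine: classify once, evaluate per fold
  res <- classify_cohort(records, cfg)
  wres <- res[res$ear == "worker", ]
  pm <- as.matrix(wres[.CATEGORIES]) > 0
  rownames(pm) <- wres$worker_id
  pm <- pm[ids, , drop = FALSE]

  plan <- kfold_plan(ids, k = k, seed = seed)
  fold_of <- plan$assignment[ids]

  metrics <- c("sensitivity", "specificity", "ppv", "npv", "kappa")
  fold_rows <- list()
  train_prev <- matrix(NA_real_, nrow = k, ncol = length(.CATEGORIES),
                       dimnames = list(NULL, .CATEGORIES))
  for (f in seq_len(k)) {
    test <- fold_of == f
    # "training" audit: prevalence of each category in the training folds
    train_prev[f, ] <- colMeans(gm[!test, , drop = FALSE])
    for (cat in .CATEGORIES) {
      ct <- confusion(pm[test, cat], gm[test, cat])
      ms <- metric_set(ct)
      kap <- suppressWarnings(cohens_kappa(ct))
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        fold = f, category = cat, n = sum(test),
        sensitivity = ms$sensitivity, specificity = ms$specificity,
        ppv = ms$ppv, npv = ms$npv, kappa = kap,
        stringsAsFactors = FALSE)
    }
  }
  fold_metrics <- do.call(rbind, fold_rows)

  agg <- function(v) {
    used <- v[!is.na(v)]
    s <- if (length(used) < 2L) {
      if (length(used) == 1L) NA_real_ else NA_real_
    } else if (sd_type == "sample") {
      stats::sd(used)
    } else {
      sqrt(mean((used - mean(used))^2))
    }
    if (length(used) >= 2L && sd_type == "population") {
      s <- sqrt(sum((used - mean(used))^2) / length(used))
    }
    c(mean = if (length(used)) mean(used) else NA_real_, sd = s,
      n_used = length(used), n_excluded = length(v) - length(used))
  }
  summ <- do.call(rbind, lapply(.CATEGORIES, function(cat) {
    sub <- fold_metrics[fold_metrics$category == cat, ]
    do.call(rbind, lapply(metrics, function(m) {
      a <- agg(sub[[m]])
      data.frame(category = cat, metric = m, mean = a[["mean"]],
                 sd = a[["sd"]], n_folds_used = as.integer(a[["n_used"]]),
                 n_folds_excluded = as.integer(a[["n_excluded"]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL

  pooled <- do.call(rbind, lapply(.CATEGORIES, function(cat) {
    ct <- confusion(pm[, cat], gm[, cat])
    ms <- metric_set(ct)
    zt <- kappa_ztest(ct)
    data.frame(category = cat, sensitivity = ms$sensitivity,
               specificity = ms$specificity, ppv = ms$ppv, npv = ms$npv,
               kappa = zt$kappa, kappa_p = zt$p_value,
               agreement = interpret_kappa(min(max(zt$kappa, -1), 1)),
               stringsAsFactors = FALSE)
  }))

  structure(list(k = as.integer(k), seed = as.integer(seed),
                 sd_type = sd_type, categories = .CATEGORIES,
                 plan = plan, fold_metrics = fold_metrics, summary = summ,
                 pooled = pooled, train_prevalence = train_prev,
                 n_workers = length(ids)),
            class = "cv_report")
}

#' Format a cross-validation report as a summary table
#'
#' One row per diagnostic category with `mean +/- SD` columns: percentages
#' to one decimal, kappa to three decimals, both rounded half away from
#' zero. This is the report-time rounding; stored fold values keep full
#' precision.
#'
#' @param report a `cv_report`.
#' @return data.frame of formatted strings.
#' @export
format_cv_report <- function(report) {
  fmt <- function(cat, metric, pct, digits) {
    row <- report$summary[report$summary$category == cat &
                            report$summary$metric == metric, ]
    scale <- if (pct) 100 else 1
    m <- round_half_up(row$mean * scale, digits)
    s <- if (is.na(row$sd)) NA_real_ else round_half_up(row$sd * scale, digits)
    val <- if (is.na(row$mean)) "undefined"
      else sprintf(paste0("%.", digits, "f ± %.", digits, "f"), m,
                   if (is.na(s)) 0 else s)
    if (row$n_folds_excluded > 0) {
      val <- paste0(val, sprintf(" [%d fold(s) undefined]",
                                 row$n_folds_excluded))
    }
    val
  }
  labels <- c(normal = "Normal hearing", hearing_loss = "Hearing loss",
              hearing_impairment = "Hearing impairment", psts = "PSTS",
              tsts = "TSTS", nihl = "NIHL")
  out <- data.frame(
    category = unname(labels[report$categories]),
    sensitivity = vapply(report$categories, fmt, "", "sensitivity", TRUE, 1),
    specificity = vapply(report$categories, fmt, "", "specificity", TRUE, 1),
    ppv = vapply(report$categories, fmt, "", "ppv", TRUE, 1),
    npv = vapply(report$categories, fmt, "", "npv", TRUE, 1),
    kappa = vapply(report$categories, fmt, "", "kappa", FALSE, 3),
    stringsAsFactors = FALSE)
  names(out) <- c("Category", "Sensitivity ± SD (%)",
                  "Specificity ± SD (%)", "PPV ± SD (%)",
                  "NPV ± SD (%)", "Cohen's Kappa ± SD")
  rownames(out) <- NULL
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation, %d workers, seed %d (%s SD)\n",
              x$k, x$n_workers, x$seed, x$sd_type))
  print(format_cv_report(x), right = FALSE)
  invisible(x)
}

#' Write a cross-validation report to disk
#'
#' Emits the formatted summary as CSV and, optionally, the full fold-level
#' detail (fold metrics, pooled metrics, fold plan) as JSON.
#'
#' @param report a `cv_report`.
#' @param csv_path path for the summary CSV (or `NULL` to skip).
#' @param json_path path for the JSON detail (or `NULL` to skip).
#' @return invisibly, the formatted summary.
#' @export
write_cv_report <- function(report, csv_path = NULL, json_path = NULL) {
  fmt <- format_cv_report(report)
  if (!is.null(csv_path)) {
    utils::write.csv(fmt, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    detail <- list(
      k = report$k, seed = report$seed, sd_type = report$sd_type,
      n_workers = report$n_workers,
      fold_sizes = tabulate(report$plan$assignment, report$k),
      fold_metrics = report$fold_metrics,
      summary = report$summary,
      pooled = report$pooled,
      train_prevalence = as.data.frame(report$train_prevalence))
    jsonlite::write_json(detail, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(fmt)
}
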