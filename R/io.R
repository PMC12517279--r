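# CSV readers and writers for the audiogram, gold-label and results
# dialects, with column-mapping support for foreign layouts.

.AUD_COLUMNS <- c("worker_id", "ear", "occasion", "test_date",
                  paste0("hz", AUD_FREQUENCIES))

#' Read audiograms from CSV into worker records
#'
#' Expects the audiogram dialect: header
#' `worker_id,ear,occasion,test_date,hz500,hz1000,hz2000,hz3000,hz4000,hz6000,hz8000`,
#' one row per ear and test occasion, `ear` in `{L, R}`, `occasion` in
#' `{baseline, annual, retest}`, dates ISO-8601, thresholds numeric dB HL.
#' Foreign layouts are adapted with `mapping`, a named character vector from
#' dialect names to the file's column names.
#'
#' Hard errors (missing column, unparseable value, duplicate
#' worker/ear/occasion key) abort with row context; off-grid thresholds and
#' single-ear records surface later through [validate_record()].
#'
#' @param path CSV file path.
#' @param mapping optional named character vector, e.g.
#'   `c(worker_id = "id", hz500 = "thr_500")`.
#' @return named list of `worker_record`s, ordered by first appearance.
#' @export
read_audiograms <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!is.null(mapping)) {
    for (std in names(mapping)) {
      if (!mapping[[std]] %in% names(df)) {
        stop("mapped column not in file: ", mapping[[std]], call. = FALSE)
      }
      names(df)[names(df) == mapping[[std]]] <- std
    }
  }
  missing_cols <- setdiff(.AUD_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("no audiogram rows in ", path, call. = FALSE)
  key <- paste(df$worker_id, df$ear, df$occasion, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    stop("duplicate (worker, ear, occasion) row(s): ",
         paste(unique(dup), collapse = "; "), call. = FALSE)
  }
  auds <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    thr <- suppressWarnings(as.numeric(row[paste0("hz", AUD_FREQUENCIES)]))
    if (anyNA(thr)) {
      stop("row ", i, " (worker ", row$worker_id,
           "): unparseable threshold value", call. = FALSE)
    }
    names(thr) <- as.character(AUD_FREQUENCIES)
    tryCatch(
      audiogram(row$worker_id, row$ear, row$occasion, row$test_date,
                thresholds(thr, warn_off_grid = FALSE)),
      error = function(e) stop("row ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  })
  ids <- unique(df$worker_id)
  recs <- lapply(ids, function(id) {
    worker_record(auds[df$worker_id == id])
  })
  stats::setNames(recs, ids)
}

#' Read a gold-standard label table from CSV
#'
#' Expects `worker_id` plus 0/1 columns for the six diagnostic categories
#' (`normal,hearing_loss,hearing_impairment,psts,tsts,nihl`).
#'
#' @param path CSV file path.
#' @return data.frame in the gold dialect.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .gold_matrix(df)  # validates columns and binary values
  if (anyDuplicated(df$worker_id)) {
    stop("duplicate worker_id in gold table", call. = FALSE)
  }
  df
}

#' Write a classification results table to CSV
#'
#' @param results data.frame from [classify_cohort()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to the audiogram and gold CSV dialects
#'
#' @param cohort a list from [generate_cohort()].
#' @param audiogram_path,gold_path output paths (either may be `NULL` to
#'   skip).
#' @return invisibly, the audiogram data.frame.
#' @export
write_cohort <- function(cohort, audiogram_path = NULL, gold_path = NULL) {
  rows <- list()
  for (r in cohort$records) {
    for (ear in names(r$ears)) {
      for (occ in intersect(c("baseline", "annual", "retest"),
                            names(r$ears[[ear]]))) {
        a <- r$ears[[ear]][[occ]]
        t <- unclass(a$thresholds)
        rows[[length(rows) + 1L]] <- data.frame(
          worker_id = a$worker_id, ear = a$ear, occasion = a$occasion,
          test_date = format(a$test_date),
          hz500 = t[["500"]], hz1000 = t[["1000"]], hz2000 = t[["2000"]],
          hz3000 = t[["3000"]], hz4000 = t[["4000"]], hz6000 = t[["6000"]],
          hz8000 = t[["8000"]], stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(audiogram_path)) {
    utils::write.csv(df, audiogram_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(gold_path)) {
    utils::write.csv(cohort$gold, gold_path, row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}
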