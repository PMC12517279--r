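# The six diagnostic rules, per-ear and per-worker classification, and the
# action flags used in occupational hearing surveillance.

.CATEGORIES <- c("normal", "hearing_loss", "hearing_impairment",
                 "psts", "tsts", "nihl")

#' Diagnostic rule configuration
#'
#' Numeric cutoffs and behavioural switches for the six rules. Defaults are
#' the published criteria:
#' * `loss_cutoff_db = 20` — hearing loss if any threshold is strictly
#'   greater than 20 dB HL at any tested frequency (WHO-style binary call);
#' * `impairment_cutoff_db = 25` — hearing impairment if the speech-frequency
#'   PTA is 25 dB HL or more (inclusive), relative to the 0-dB reference;
#' * `sts_shift_db = 10` — a standard threshold shift is a worsening of
#'   10 dB or more (inclusive) in the 2/3/4 kHz PTA versus baseline;
#' * `nihl_notch_db = 15`, `nihl_recovery_db = 10` — the V-shaped 3--6 kHz
#'   notch terms and the 8 kHz recovery terms of the NIHL rule;
#' * `retest_window_days = 92` — a follow-up audiogram counts towards
#'   permanent/temporary STS resolution only within about 3 months of the
#'   annual test;
#' * `recovery_sign` — `"corrected"` (default) requires the 8 kHz threshold
#'   to be *better* (lower) than the notch frequencies by the recovery
#'   margin, matching the clinical meaning of recovery; `"literal"` keeps
#'   the opposite sign as sometimes typeset, retained for auditability.
#'
#' @param loss_cutoff_db,impairment_cutoff_db,sts_shift_db,nihl_notch_db,nihl_recovery_db
#'   cutoffs in dB (all positive).
#' @param retest_window_days retest window in calendar days (>= 1).
#' @param recovery_sign `"corrected"` or `"literal"`.
#' @return an object of class `"rule_config"`.
#' @export
rule_config <- function(loss_cutoff_db = 20,
                        impairment_cutoff_db = 25,
                        sts_shift_db = 10,
                        nihl_notch_db = 15,
                        nihl_recovery_db = 10,
                        retest_window_days = 92,
                        recovery_sign = c("corrected", "literal")) {
  recovery_sign <- match.arg(recovery_sign)
  cut <- c(loss_cutoff_db, impairment_cutoff_db, sts_shift_db,
           nihl_notch_db, nihl_recovery_db)
  if (any(!is.finite(cut)) || any(cut <= 0)) {
    stop("all dB cutoffs must be positive", call. = FALSE)
  }
  if (retest_window_days < 1) stop("retest_window_days must be >= 1",
                                   call. = FALSE)
  structure(list(loss_cutoff_db = loss_cutoff_db,
                 impairment_cutoff_db = impairment_cutoff_db,
                 sts_shift_db = sts_shift_db,
                 nihl_notch_db = nihl_notch_db,
                 nihl_recovery_db = nihl_recovery_db,
                 retest_window_days = retest_window_days,
                 recovery_sign = recovery_sign),
            class = "rule_config")
}

.thr <- function(a) {
  if (inherits(a, "audiogram")) unclass(a$thresholds) else unclass(a)
}

#' Hearing-loss rule
#'
#' TRUE iff any of the seven thresholds is strictly greater than the cutoff
#' (default 20 dB HL).
#'
#' @param a an `audiogram` or `freq_thresholds`.
#' @param cfg a [rule_config()].
#' @export
detect_hearing_loss <- function(a, cfg = rule_config()) {
  any(.thr(a) > cfg$loss_cutoff_db)
}

#' Hearing-impairment rule
#'
#' TRUE iff the speech-frequency pure-tone average (500/1000/2000/3000 Hz)
#' is greater than or equal to the cutoff (default 25 dB HL) — a permanent
#' shift of 25 dB or more relative to the 0-dB reference.
#'
#' @inheritParams detect_hearing_loss
#' @export
detect_hearing_impairment <- function(a, cfg = rule_config()) {
  pta_speech(if (inherits(a, "audiogram")) a$thresholds else a) >=
    cfg$impairment_cutoff_db
}

#' Standard threshold shift in dB
#'
#' Signed change in the 2/3/4 kHz pure-tone average between two audiograms
#' of the same ear: `pta_sts(later) - pta_sts(baseline)`. Positive values
#' mean worsening; negative values mean improvement.
#'
#' @param baseline,later `audiogram`s for the same worker and ear.
#' @return shift in dB (plain numeric).
#' @export
sts_shift <- function(baseline, later) {
  if (inherits(baseline, "audiogram") && inherits(later, "audiogram")) {
    if (baseline$ear != later$ear) {
      stop("ear mismatch: ", baseline$ear, " vs ", later$ear, call. = FALSE)
    }
    if (baseline$worker_id != later$worker_id) {
      stop("worker mismatch: ", baseline$worker_id, " vs ", later$worker_id,
           call. = FALSE)
    }
  }
  pta_sts(later) - pta_sts(baseline)
}

#' Resolve a standard threshold shift as permanent, temporary or pending
#'
#' If the annual audiogram shows a shift of at least `sts_shift_db` versus
#' baseline, the shift must be confirmed by a retest within the retest
#' window (about 3 months): a persisting shift is permanent (`"PSTS"`), a
#' resolved one temporary (`"TSTS"`). Without an in-window retest the shift
#' is `"PENDING"` and the record is flagged for repeat testing downstream.
#'
#' @param baseline,annual,retest `audiogram`s (retest may be `NULL`).
#' @param cfg a [rule_config()].
#' @return one of `"NONE"`, `"PSTS"`, `"TSTS"`, `"PENDING"`.
#' @export
resolve_sts <- function(baseline, annual, retest = NULL,
                        cfg = rule_config()) {
  if (sts_shift(baseline, annual) < cfg$sts_shift_db) return("NONE")
  if (!is.null(retest)) {
    if (retest$test_date < annual$test_date) {
      stop("retest dated before annual audiogram", call. = FALSE)
    }
    days <- as.numeric(retest$test_date - annual$test_date)
    if (days <= cfg$retest_window_days) {
      return(if (sts_shift(baseline, retest) >= cfg$sts_shift_db) "PSTS"
             else "TSTS")
    }
  }
  "PENDING"
}

#' Noise-induced hearing loss (audiometric notch) rule
#'
#' Evaluates the conjunction of five notch terms and three recovery terms on
#' one audiogram. With `T(f)` the threshold at `f` Hz, all of the following
#' must hold (defaults 15 dB notch, 10 dB recovery):
#'
#' notch: `T(3000)-T(1000) >= 15`; `T(4000)-T(500) >= 15`;
#' `T(4000)-T(1000) >= 15`; `T(6000)-T(500) >= 15`; `T(6000)-T(1000) >= 15`.
#'
#' recovery (`recovery_sign = "corrected"`): `T(3000)-T(8000) >= 10`;
#' `T(4000)-T(8000) >= 10`; `T(6000)-T(8000) >= 10` — the 8 kHz threshold
#' recovers (is lower) after the notch. With `"literal"` the differences are
#' taken the other way around (`T(8000)-T(3000) >= 10`, ...).
#'
#' @inheritParams detect_hearing_loss
#' @export
detect_nihl <- function(a, cfg = rule_config()) {
  t <- .thr(a)
  n <- cfg$nihl_notch_db
  r <- cfg$nihl_recovery_db
  notch <- t[["3000"]] - t[["1000"]] >= n &&
    t[["4000"]] - t[["500"]] >= n &&
    t[["4000"]] - t[["1000"]] >= n &&
    t[["6000"]] - t[["500"]] >= n &&
    t[["6000"]] - t[["1000"]] >= n
  if (!notch) return(FALSE)
  if (cfg$recovery_sign == "corrected") {
    t[["3000"]] - t[["8000"]] >= r &&
      t[["4000"]] - t[["8000"]] >= r &&
      t[["6000"]] - t[["8000"]] >= r
  } else {
    t[["8000"]] - t[["3000"]] >= r &&
      t[["8000"]] - t[["4000"]] >= r &&
      t[["8000"]] - t[["6000"]] >= r
  }
}

.diagnosis_set <- function(hearing_loss, hearing_impairment, psts, tsts,
                           nihl, sts_pending) {
  structure(list(
    normal = !(hearing_loss || hearing_impairment || psts || tsts || nihl),
    hearing_loss = hearing_loss,
    hearing_impairment = hearing_impairment,
    psts = psts, tsts = tsts, nihl = nihl,
    sts_pending = sts_pending), class = "diagnosis_set")
}

#' Classify one ear
#'
#' Applies all six rules to one ear's serial audiograms. Hearing loss,
#' hearing impairment and NIHL are evaluated on the annual (surveillance)
#' audiogram; the retest serves only to resolve a standard threshold shift.
#' Normal hearing is the negation of the five positive categories; an
#' unconfirmed (pending) shift is not itself a diagnosis and does not negate
#' normal — it is carried in `sts_pending` and surfaced via the repeat flag.
#'
#' @param ear_record a list with elements `baseline`, `annual` and optional
#'   `retest` (as stored per ear in a `worker_record`).
#' @param cfg a [rule_config()].
#' @return an object of class `"diagnosis_set"`: logicals `normal`,
#'   `hearing_loss`, `hearing_impairment`, `psts`, `tsts`, `nihl`,
#'   `sts_pending`.
#' @export
classify_ear <- function(ear_record, cfg = rule_config()) {
  if (is.null(ear_record$baseline) || is.null(ear_record$annual)) {
    stop("baseline and annual audiograms are required for classification",
         call. = FALSE)
  }
  annual <- ear_record$annual
  sts <- resolve_sts(ear_record$baseline, annual, ear_record$retest, cfg)
  .diagnosis_set(
    hearing_loss = detect_hearing_loss(annual, cfg),
    hearing_impairment = detect_hearing_impairment(annual, cfg),
    psts = sts == "PSTS",
    tsts = sts == "TSTS",
    nihl = detect_nihl(annual, cfg),
    sts_pending = sts == "PENDING")
}

#' Classify a worker
#'
#' Classifies each available ear and aggregates to the worker level: each
#' positive category is true if true in at least one ear, and the worker is
#' normal only when both classified ears are normal. Action flags follow
#' from the aggregated result (see [action_flags()]).
#'
#' @param r a `worker_record`.
#' @param cfg a [rule_config()].
#' @return an object of class `"worker_diagnosis"`: `worker_id`, per-ear
#'   diagnosis sets in `ears`, the worker-level set in `overall`, and
#'   `flags`.
#' @export
classify_worker <- function(r, cfg = rule_config()) {
  stopifnot(inherits(r, "worker_record"))
  ears <- lapply(r$ears, function(e) {
    tryCatch(classify_ear(e, cfg), error = function(err) {
      stop("worker ", r$worker_id, ": ", conditionMessage(err),
           call. = FALSE)
    })
  })
  pos <- function(field) any(vapply(ears, `[[`, NA, field))
  overall <- .diagnosis_set(
    hearing_loss = pos("hearing_loss"),
    hearing_impairment = pos("hearing_impairment"),
    psts = pos("psts"), tsts = pos("tsts"), nihl = pos("nihl"),
    sts_pending = pos("sts_pending"))
  wd <- structure(list(worker_id = r$worker_id, ears = ears,
                       overall = overall, flags = NULL),
                  class = "worker_diagnosis")
  wd$flags <- action_flags(wd, cfg)
  wd
}

#' Action flags for occupational-health follow-up
#'
#' Surveillance alerts derived from a worker's diagnosis: `repeat_required`
#' when any ear carries an unconfirmed (pending) standard threshold shift,
#' and `report_required` when any ear has a confirmed permanent shift, NIHL
#' or hearing impairment — the findings notifiable to the occupational
#' health authority. `reasons` lists one code per trigger, e.g. `"PSTS_L"`
#' or `"STS_PENDING_R"`.
#'
#' @param d a `worker_diagnosis`.
#' @param cfg a [rule_config()] (reserved for configurable triggers).
#' @return list with `repeat_required`, `report_required`, `reasons`.
#' @export
action_flags <- function(d, cfg = rule_config()) {
  reasons <- character()
  for (ear in names(d$ears)) {
    s <- d$ears[[ear]]
    if (s$sts_pending) reasons <- c(reasons, paste0("STS_PENDING_", ear))
    if (s$psts) reasons <- c(reasons, paste0("PSTS_", ear))
    if (s$nihl) reasons <- c(reasons, paste0("NIHL_", ear))
    if (s$hearing_impairment) reasons <- c(reasons, paste0("IMPAIRMENT_", ear))
  }
  list(repeat_required = any(grepl("^STS_PENDING_", reasons)),
       report_required = any(grepl("^(PSTS|NIHL|IMPAIRMENT)_", reasons)),
       reasons = reasons)
}

#' Classify a whole cohort into a results table
#'
#' @param records list of `worker_record`s.
#' @param cfg a [rule_config()].
#' @return a data.frame in the results dialect: one row per classified ear
#'   plus one `ear = "worker"` summary row per worker, with 0/1 columns for
#'   the six categories, `sts_pending`, and the two action flags.
#' @export
classify_cohort <- function(records, cfg = rule_config()) {
  rows <- lapply(records, function(r) {
    wd <- classify_worker(r, cfg)
    ear_rows <- lapply(names(wd$ears), function(e)
      .diag_row(wd$worker_id, e, wd$ears[[e]], wd$flags))
    do.call(rbind, c(ear_rows,
                     list(.diag_row(wd$worker_id, "worker", wd$overall,
                                    wd$flags))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.diag_row <- function(worker_id, ear, s, flags) {
  data.frame(worker_id = worker_id, ear = ear,
             normal = as.integer(s$normal),
             hearing_loss = as.integer(s$hearing_loss),
             hearing_impairment = as.integer(s$hearing_impairment),
             psts = as.integer(s$psts), tsts = as.integer(s$tsts),
             nihl = as.integer(s$nihl),
             sts_pending = as.integer(s$sts_pending),
             repeat_required = as.integer(flags$repeat_required),
             report_required = as.integer(flags$report_required),
             stringsAsFactors = FALSE)
}

#' @export
print.diagnosis_set <- function(x, ...) {
  on <- names(x)[vapply(x, isTRUE, NA)]
  cat("<diagnosis_set>", if (length(on)) paste(on, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
print.worker_diagnosis <- function(x, ...) {
  cat("<worker_diagnosis>", x$worker_id, "\n")
  for (e in names(x$ears)) {
    on <- names(x$ears[[e]])[vapply(x$ears[[e]], isTRUE, NA)]
    cat(" ", e, ":", if (length(on)) paste(on, collapse = ", ") else "normal",
        "\n")
  }
  on <- names(x$overall)[vapply(x$overall, isTRUE, NA)]
  cat("  worker:", paste(on, collapse = ", "), "\n")
  if (length(x$flags$reasons)) {
    cat("  flags:", paste(x$flags$reasons, collapse = ", "), "\n")
  }
  invisible(x)
}
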