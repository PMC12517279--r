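# Brute-force reference classifier: a deliberately naive, literal
# transcription of the six diagnostic inequalities, sharing no helpers with
# the rule engine. Used as the independent oracle in property tests and to
# produce gold labels for the synthetic cohort.

#' Classify a worker with the brute-force reference implementation
#'
#' Same contract as [classify_worker()], but every pure-tone average,
#' inequality and date comparison is written out longhand, without calling
#' any of the engine's helpers. The engine and this oracle must agree on
#' every input; any disagreement is a bug in one of them.
#'
#' @param r a `worker_record`.
#' @param cfg a [rule_config()].
#' @return an object of class `"worker_diagnosis"`.
#' @export
oracle_classify <- function(r, cfg = rule_config()) {
  ear_sets <- list()
  for (ear in names(r$ears)) {
    b <- r$ears[[ear]]$baseline
    a <- r$ears[[ear]]$annual
    rt <- r$ears[[ear]]$retest
    if (is.null(b) || is.null(a)) {
      stop("worker ", r$worker_id, ": baseline and annual audiograms are ",
           "required for classification", call. = FALSE)
    }
    t <- unclass(a$thresholds)

    # hearing loss: any threshold strictly above the cutoff
    loss <- FALSE
    for (f in c("500", "1000", "2000", "3000", "4000", "6000", "8000")) {
      if (t[[f]] > cfg$loss_cutoff_db) loss <- TRUE
    }

    # hearing impairment: speech PTA at or above the cutoff
    speech_pta <- (t[["500"]] + t[["1000"]] + t[["2000"]] + t[["3000"]]) / 4
    impairment <- speech_pta >= cfg$impairment_cutoff_db

    # standard threshold shift on the 2/3/4 kHz PTA
    tb <- unclass(b$thresholds)
    pta_b <- (tb[["2000"]] + tb[["3000"]] + tb[["4000"]]) / 3
    pta_a <- (t[["2000"]] + t[["3000"]] + t[["4000"]]) / 3
    psts <- FALSE; tsts <- FALSE; pending <- FALSE
    if (pta_a - pta_b >= cfg$sts_shift_db) {
      if (!is.null(rt) &&
          as.numeric(rt$test_date - a$test_date) <= cfg$retest_window_days) {
        tr <- unclass(rt$thresholds)
        pta_r <- (tr[["2000"]] + tr[["3000"]] + tr[["4000"]]) / 3
        if (pta_r - pta_b >= cfg$sts_shift_db) psts <- TRUE else tsts <- TRUE
      } else {
        pending <- TRUE
      }
    }

    # NIHL: five notch terms AND three recovery terms
    nn <- cfg$nihl_notch_db
    rr <- cfg$nihl_recovery_db
    notch <- (t[["3000"]] - t[["1000"]] >= nn) &&
      (t[["4000"]] - t[["500"]] >= nn) &&
      (t[["4000"]] - t[["1000"]] >= nn) &&
      (t[["6000"]] - t[["500"]] >= nn) &&
      (t[["6000"]] - t[["1000"]] >= nn)
    recovery <- if (cfg$recovery_sign == "corrected") {
      (t[["3000"]] - t[["8000"]] >= rr) &&
        (t[["4000"]] - t[["8000"]] >= rr) &&
        (t[["6000"]] - t[["8000"]] >= rr)
    } else {
      (t[["8000"]] - t[["3000"]] >= rr) &&
        (t[["8000"]] - t[["4000"]] >= rr) &&
        (t[["8000"]] - t[["6000"]] >= rr)
    }
    nihl <- notch && recovery

    normal <- !loss && !impairment && !psts && !tsts && !nihl
    ear_sets[[ear]] <- structure(
      list(normal = normal, hearing_loss = loss,
           hearing_impairment = impairment, psts = psts, tsts = tsts,
           nihl = nihl, sts_pending = pending),
      class = "diagnosis_set")
  }

  any_of <- function(field) {
    out <- FALSE
    for (s in ear_sets) if (isTRUE(s[[field]])) out <- TRUE
    out
  }
  overall <- structure(
    list(normal = !(any_of("hearing_loss") || any_of("hearing_impairment") ||
                      any_of("psts") || any_of("tsts") || any_of("nihl")),
         hearing_loss = any_of("hearing_loss"),
         hearing_impairment = any_of("hearing_impairment"),
         psts = any_of("psts"), tsts = any_of("tsts"),
         nihl = any_of("nihl"), sts_pending = any_of("sts_pending")),
    class = "diagnosis_set")

  reasons <- character()
  for (ear in names(ear_sets)) {
    s <- ear_sets[[ear]]
    if (isTRUE(s$sts_pending)) reasons <- c(reasons, paste0("STS_PENDING_", ear))
    if (isTRUE(s$psts)) reasons <- c(reasons, paste0("PSTS_", ear))
    if (isTRUE(s$nihl)) reasons <- c(reasons, paste0("NIHL_", ear))
    if (isTRUE(s$hearing_impairment)) {
      reasons <- c(reasons, paste0("IMPAIRMENT_", ear))
    }
  }
  flags <- list(
    repeat_required = any(substr(reasons, 1, 11) == "STS_PENDING"),
    report_required = any(substr(reasons, 1, 4) %in%
                            c("PSTS", "NIHL", "IMPA")),
    reasons = reasons)

  structure(list(worker_id = r$worker_id, ears = ear_sets,
                 overall = overall, flags = flags),
            class = "worker_diagnosis")
}
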