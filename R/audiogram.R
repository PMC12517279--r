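# Audiogram data model, validation, and the two pure-tone averages every
# diagnostic rule consumes.

#' Standard audiometric test frequencies
#'
#' The seven frequencies (Hz) at which hearing threshold levels are recorded
#' in occupational pure-tone audiometry, and the two named subsets over which
#' pure-tone averages are taken: the speech frequencies (500--3000 Hz, used
#' for the hearing-impairment rule) and the 2--4 kHz set used for standard
#' threshold shift (STS) monitoring.
#'
#' @format `AUD_FREQUENCIES` is an integer vector of length 7;
#'   `SPEECH_FREQUENCIES` and `STS_FREQUENCIES` are its subsets.
#' @export
AUD_FREQUENCIES <- c(500L, 1000L, 2000L, 3000L, 4000L, 6000L, 8000L)

#' @rdname AUD_FREQUENCIES
#' @export
SPEECH_FREQUENCIES <- c(500L, 1000L, 2000L, 3000L)

#' @rdname AUD_FREQUENCIES
#' @export
STS_FREQUENCIES <- c(2000L, 3000L, 4000L)

# dB HL range a clinical audiometer can output
.THRESHOLD_RANGE <- c(-10, 120)

.EARS <- c("L", "R")
.OCCASIONS <- c("baseline", "annual", "retest")

#' Construct one ear's set of hearing thresholds
#'
#' @param ... threshold levels in dB HL, either as a single named numeric
#'   vector/list or as individual named arguments; names are the test
#'   frequencies in Hz (`"500"`, `"1000"`, ..., `"8000"`). All seven standard
#'   frequencies must be present.
#' @param warn_off_grid warn when a threshold is not a multiple of 5 dB
#'   (clinical audiometers step in 5-dB increments).
#'
#' @return a named numeric vector of class `"freq_thresholds"`, ordered by
#'   frequency.
#' @examples
#' thresholds(`500` = 10, `1000` = 10, `2000` = 15, `3000` = 40,
#'            `4000` = 45, `6000` = 40, `8000` = 25)
#' @export
thresholds <- function(..., warn_off_grid = TRUE) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.numeric(args[[1L]]) || is.list(args[[1L]]))) {
    args <- as.list(args[[1L]])
  }
  vals <- vapply(args, function(x) as.numeric(x)[1L], numeric(1))
  nm <- names(vals)
  missing <- setdiff(as.character(AUD_FREQUENCIES), nm)
  if (length(missing)) {
    stop("missing threshold for frequency ", paste(missing, collapse = ", "),
         " Hz", call. = FALSE)
  }
  vals <- vals[as.character(AUD_FREQUENCIES)]
  if (anyNA(vals)) {
    stop("non-numeric or missing threshold at ",
         paste(names(vals)[is.na(vals)], collapse = ", "), " Hz",
         call. = FALSE)
  }
  bad <- vals < .THRESHOLD_RANGE[1] | vals > .THRESHOLD_RANGE[2]
  if (any(bad)) {
    stop("threshold out of range [-10, 120] dB HL at ",
         paste(names(vals)[bad], collapse = ", "), " Hz", call. = FALSE)
  }
  off <- vals %% 5 != 0
  if (warn_off_grid && any(off)) {
    warning("threshold not on the 5-dB grid at ",
            paste(names(vals)[off], collapse = ", "), " Hz", call. = FALSE)
  }
  structure(vals, class = "freq_thresholds")
}

#' Construct a single audiogram (one ear, one test occasion)
#'
#' @param worker_id opaque worker identifier.
#' @param ear `"L"` or `"R"`.
#' @param occasion `"baseline"`, `"annual"` or `"retest"`.
#' @param test_date test date, `Date` or ISO-8601 string (`YYYY-MM-DD`).
#' @param t thresholds: a `freq_thresholds` object or anything accepted by
#'   [thresholds()].
#' @param warn_off_grid passed to [thresholds()].
#'
#' @return an object of class `"audiogram"`.
#' @export
audiogram <- function(worker_id, ear, occasion, test_date, t,
                      warn_off_grid = TRUE) {
  ear <- match.arg(as.character(ear), .EARS)
  occasion <- match.arg(as.character(occasion), .OCCASIONS)
  if (!inherits(t, "freq_thresholds")) {
    t <- thresholds(t, warn_off_grid = warn_off_grid)
  }
  d <- tryCatch(as.Date(test_date), error = function(e) NA)
  if (is.na(d)) stop("unparseable test_date: ", test_date, call. = FALSE)
  structure(
    list(worker_id = as.character(worker_id), ear = ear,
         occasion = occasion, test_date = d, thresholds = t),
    class = "audiogram")
}

#' Assemble a worker's per-ear serial audiograms
#'
#' A record holds, for each ear, the mandatory baseline and annual audiograms
#' and an optional retest (follow-up) audiogram used to resolve a standard
#' threshold shift as permanent or temporary.
#'
#' @param ... `audiogram` objects for one worker (any order); occasion and
#'   ear are taken from each audiogram.
#'
#' @return an object of class `"worker_record"` with elements `worker_id`
#'   and `ears` (a list with `L` and/or `R`, each a list
#'   `baseline`/`annual`/`retest`).
#' @export
worker_record <- function(...) {
  auds <- list(...)
  if (length(auds) == 1L && !inherits(auds[[1L]], "audiogram")) {
    auds <- auds[[1L]]
  }
  stopifnot(length(auds) >= 1L)
  ids <- unique(vapply(auds, `[[`, "", "worker_id"))
  if (length(ids) != 1L) {
    stop("audiograms belong to different workers: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  ears <- list()
  for (a in auds) {
    if (!inherits(a, "audiogram")) stop("not an audiogram", call. = FALSE)
    if (!is.null(ears[[a$ear]][[a$occasion]])) {
      stop("duplicate audiogram for worker ", ids, ", ear ", a$ear,
           ", occasion ", a$occasion, call. = FALSE)
    }
    ears[[a$ear]][[a$occasion]] <- a
  }
  structure(list(worker_id = ids, ears = ears), class = "worker_record")
}

#' Speech-frequency pure-tone average
#'
#' Arithmetic mean of the hearing thresholds at 500, 1000, 2000 and 3000 Hz,
#' the quantity the hearing-impairment rule compares to its 25 dB HL cutoff.
#' Kept at full precision; rounding happens only at report time.
#'
#' @param t a `freq_thresholds` object (or an `audiogram`).
#' @return the mean in dB HL (plain numeric).
#' @examples
#' pta_speech(thresholds(`500` = 20, `1000` = 20, `2000` = 20, `3000` = 40,
#'                       `4000` = 0, `6000` = 0, `8000` = 0))  # 25
#' @export
pta_speech <- function(t) .pta(t, SPEECH_FREQUENCIES)

#' STS-monitoring pure-tone average
#'
#' Arithmetic mean of the hearing thresholds at 2000, 3000 and 4000 Hz, the
#' quantity whose change from baseline defines a standard threshold shift.
#'
#' @inheritParams pta_speech
#' @return the mean in dB HL.
#' @export
pta_sts <- function(t) .pta(t, STS_FREQUENCIES)

.pta <- function(t, freqs) {
  if (inherits(t, "audiogram")) t <- t$thresholds
  if (!inherits(t, "freq_thresholds")) t <- thresholds(t, warn_off_grid = FALSE)
  mean(unclass(t)[as.character(freqs)])
}

.finding <- function(severity, code, message) {
  list(severity = severity, code = code, message = message)
}

#' Validate a worker record
#'
#' Checks a record against the input contract and returns a list of findings
#' rather than throwing: each finding has a `severity` (`"error"` or
#' `"warning"`), a machine-readable `code` and a human-readable `message`.
#' A conformant two-ear record yields an empty list. The check is pure:
#' it never modifies the record and repeated calls return identical results.
#'
#' Codes: `missing_occasion`, `out_of_range`, `off_grid` (threshold not on
#' the 5-dB audiometer grid), `date_order` (baseline after annual, or retest
#' before annual), `single_ear`.
#'
#' @param r a `worker_record`.
#' @return list of findings (possibly empty).
#' @export
validate_record <- function(r) {
  stopifnot(inherits(r, "worker_record"))
  findings <- list()
  add <- function(f) findings[[length(findings) + 1L]] <<- f
  if (length(r$ears) < 2L) {
    add(.finding("warning", "single_ear",
                 sprintf("worker %s: only ear %s present", r$worker_id,
                         names(r$ears))))
  }
  for (ear in names(r$ears)) {
    e <- r$ears[[ear]]
    for (occ in c("baseline", "annual")) {
      if (is.null(e[[occ]])) {
        add(.finding("error", "missing_occasion",
                     sprintf("worker %s ear %s: missing %s audiogram",
                             r$worker_id, ear, occ)))
      }
    }
    for (occ in intersect(names(e), .OCCASIONS)) {
      v <- unclass(e[[occ]]$thresholds)
      bad <- v < .THRESHOLD_RANGE[1] | v > .THRESHOLD_RANGE[2]
      if (any(bad)) {
        add(.finding("error", "out_of_range",
                     sprintf("worker %s ear %s %s: threshold out of range at %s Hz",
                             r$worker_id, ear, occ,
                             paste(names(v)[bad], collapse = ", "))))
      }
      off <- !bad & v %% 5 != 0
      if (any(off)) {
        add(.finding("warning", "off_grid",
                     sprintf("worker %s ear %s %s: threshold off 5-dB grid at %s Hz",
                             r$worker_id, ear, occ,
                             paste(names(v)[off], collapse = ", "))))
      }
    }
    if (!is.null(e$baseline) && !is.null(e$annual) &&
        e$baseline$test_date > e$annual$test_date) {
      add(.finding("error", "date_order",
                   sprintf("worker %s ear %s: baseline dated after annual",
                           r$worker_id, ear)))
    }
    if (!is.null(e$annual) && !is.null(e$retest) &&
        e$retest$test_date < e$annual$test_date) {
      add(.finding("error", "date_order",
                   sprintf("worker %s ear %s: retest dated before annual",
                           r$worker_id, ear)))
    }
  }
  findings
}

#' @export
print.audiogram <- function(x, ...) {
  cat(sprintf("<audiogram> worker %s, ear %s, %s, %s\n", x$worker_id, x$ear,
              x$occasion, format(x$test_date)))
  print(unclass(x$thresholds))
  invisible(x)
}

#' @export
print.worker_record <- function(x, ...) {
  occ <- vapply(names(x$ears), function(e)
    paste(intersect(.OCCASIONS, names(x$ears[[e]])), collapse = "+"), "")
  cat(sprintf("<worker_record> %s: %s\n", x$worker_id,
              paste(sprintf("%s[%s]", names(x$ears), occ), collapse = " ")))
  invisible(x)
}
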