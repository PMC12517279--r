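# Builders for audiograms and worker records used across the suite.

FREQ_NAMES <- as.character(AUD_FREQUENCIES)

thr <- function(...) {
  # thr(500 = 10, ...) or thr(flat = 10) or thr(c(...))
  args <- list(...)
  if (length(args) == 1L && identical(names(args), "flat")) {
    v <- stats::setNames(rep(args$flat, 7), FREQ_NAMES)
  } else if (length(args) == 1L && is.null(names(args))) {
    v <- stats::setNames(as.numeric(args[[1L]]), FREQ_NAMES)
  } else {
    v <- stats::setNames(rep(0, 7), FREQ_NAMES)
    v[names(args)] <- unlist(args)
  }
  thresholds(v, warn_off_grid = FALSE)
}

aud <- function(t, id = "W1", ear = "L", occ = "annual",
                date = "2025-01-10") {
  audiogram(id, ear, occ, date, t)
}

# a two-ear record from per-ear threshold sets; dates fixed and ordered
make_record <- function(baseline_t, annual_t = baseline_t, retest_t = NULL,
                        id = "W1", retest_gap = 30,
                        mirror = TRUE) {
  mk <- function(ear) {
    a <- list(aud(baseline_t, id, ear, "baseline", "2024-01-10"),
              aud(annual_t, id, ear, "annual", "2025-01-10"))
    if (!is.null(retest_t)) {
      a <- c(a, list(aud(retest_t, id, ear, "retest",
                         as.Date("2025-01-10") + retest_gap)))
    }
    a
  }
  worker_record(c(mk("L"), if (mirror) mk("R")))
}

# uniform draw from the 5-dB audiometer grid in [-10, 120]
rand_thr <- function() {
  thresholds(stats::setNames(sample(seq(-10, 120, by = 5), 7, replace = TRUE),
                             FREQ_NAMES), warn_off_grid = FALSE)
}

# random serial record: retest present half the time, sometimes outside the
# 92-day resolution window
rand_record <- function(id = "W1") {
  has_retest <- stats::runif(1) < 0.5
  gap <- sample(1:150, 1)
  make_record(rand_thr(), rand_thr(),
              retest_t = if (has_retest) rand_thr(),
              id = id, retest_gap = gap)
}

diag_equal <- function(a, b) {
  fields <- c("normal", "hearing_loss", "hearing_impairment", "psts",
              "tsts", "nihl", "sts_pending")
  all(vapply(fields, function(f) identical(a[[f]], b[[f]]), NA))
}

worker_diag_equal <- function(a, b) {
  ok <- diag_equal(a$overall, b$overall) &&
    setequal(names(a$ears), names(b$ears)) &&
    identical(sort(a$flags$reasons), sort(b$flags$reasons)) &&
    identical(a$flags$repeat_required, b$flags$repeat_required) &&
    identical(a$flags$report_required, b$flags$report_required)
  for (e in names(a$ears)) ok <- ok && diag_equal(a$ears[[e]], b$ears[[e]])
  ok
}
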