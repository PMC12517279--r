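# The NIHL worked example: clear 3-6 kHz notch with 8 kHz recovery.
NOTCH <- list(`500` = 10, `1000` = 10, `2000` = 20, `3000` = 40,
              `4000` = 45, `6000` = 40, `8000` = 25)

test_that("hearing loss requires a threshold strictly above the cutoff", {
  cfg <- rule_config()
  expect_false(detect_hearing_loss(thr(flat = 20), cfg))  # boundary: strict
  expect_false(detect_hearing_loss(thr(flat = 0), cfg))
  expect_true(detect_hearing_loss(thr(`500` = 10, `1000` = 10, `2000` = 10,
                                      `3000` = 10, `4000` = 10, `6000` = 25,
                                      `8000` = 10), cfg))
  # grid boundary sweep: 15 / 20 / 25 at a single frequency
  for (v in c(15, 20, 25)) {
    t <- thr(flat = 10); t[["6000"]] <- v
    expect_identical(detect_hearing_loss(t, cfg), v > 20)
  }
})

test_that("hearing impairment is an inclusive speech-PTA cutoff", {
  cfg <- rule_config()
  expect_true(detect_hearing_impairment(thr(flat = 25), cfg))   # inclusive
  expect_true(detect_hearing_impairment(
    thr(`500` = 20, `1000` = 20, `2000` = 20, `3000` = 40), cfg))  # PTA 25
  expect_false(detect_hearing_impairment(
    thr(`500` = 20, `1000` = 20, `2000` = 20, `3000` = 35), cfg))  # 23.75
  for (v in c(20, 25, 30)) {
    expect_identical(detect_hearing_impairment(thr(flat = v), cfg), v >= 25)
  }
})

test_that("sts_shift is the signed 2/3/4 kHz PTA difference", {
  b <- aud(thr(`2000` = 10, `3000` = 10, `4000` = 10), occ = "baseline",
           date = "2024-01-10")
  a <- aud(thr(`2000` = 20, `3000` = 20, `4000` = 20))
  expect_equal(sts_shift(b, a), 10)
  expect_equal(sts_shift(b, b), 0)
  b30 <- aud(thr(flat = 30), occ = "baseline", date = "2024-01-10")
  a25 <- aud(thr(flat = 25))
  expect_equal(sts_shift(b30, a25), -5)
  expect_error(sts_shift(b, aud(thr(flat = 20), ear = "R")), "ear mismatch")
})

test_that("resolve_sts distinguishes permanent, temporary and pending", {
  cfg <- rule_config()
  b <- aud(thr(flat = 10), occ = "baseline", date = "2024-01-10")
  ann <- function(v) aud(thr(flat = v), date = "2025-01-10")
  ret <- function(v, gap) aud(thr(flat = v), occ = "retest",
                              date = as.Date("2025-01-10") + gap)
  # shift +15, retest shift +12ish persists at day 30 -> permanent
  expect_identical(resolve_sts(b, ann(25), ret(22.5, 30), cfg), "PSTS")
  # shift +10, retest back near baseline -> temporary
  expect_identical(resolve_sts(b, ann(20), ret(12.5, 30), cfg), "TSTS")
  # shift below cutoff -> none; no retest -> pending
  expect_identical(resolve_sts(b, ann(15), NULL, cfg), "NONE")
  expect_identical(resolve_sts(b, ann(20), NULL, cfg), "PENDING")
  # the 92-day window is inclusive; a later retest cannot resolve the shift
  expect_identical(resolve_sts(b, ann(25), ret(25, 92), cfg), "PSTS")
  expect_identical(resolve_sts(b, ann(25), ret(25, 93), cfg), "PENDING")
  # shift boundary sweep at 5 / 10 / 15 dB
  for (v in c(5, 10, 15)) {
    got <- resolve_sts(b, ann(10 + v), NULL, cfg)
    expect_identical(got, if (v >= 10) "PENDING" else "NONE")
  }
  expect_error(resolve_sts(b, ann(25), ret(25, -5), cfg), "retest dated")
})

test_that("NIHL rule is the printed conjunction of notch and recovery
           terms", {
  cfg <- rule_config()
  expect_true(detect_nihl(thr(NOTCH), cfg))
  expect_false(detect_nihl(thr(flat = 10), cfg))
  # literal recovery sign: 8 kHz must be worse than the notch, which this
  # audiogram is not
  expect_false(detect_nihl(thr(NOTCH), rule_config(recovery_sign = "literal")))
  # and an upward-sloping audiogram satisfies literal but not corrected
  up <- thr(`500` = 10, `1000` = 10, `2000` = 20, `3000` = 30, `4000` = 30,
            `6000` = 30, `8000` = 45)
  expect_true(detect_nihl(up, rule_config(recovery_sign = "literal")))
  expect_false(detect_nihl(up, cfg))

  # boundary sweep on the notch depth (all five terms move together):
  # exactly 15 dB passes (inclusive), 10 dB fails, 20 dB passes
  for (d in c(10, 15, 20)) {
    t <- thr(`500` = 10, `1000` = 10, `2000` = 10, `3000` = 10 + d,
             `4000` = 10 + d, `6000` = 10 + d, `8000` = 10 + d - 10)
    expect_identical(detect_nihl(t, cfg), d >= 15)
  }
  # boundary sweep on recovery with a deep notch: 5 dB fails, 10 passes
  for (r in c(5, 10, 15)) {
    t <- thr(`500` = 10, `1000` = 10, `2000` = 10, `3000` = 40,
             `4000` = 40, `6000` = 40, `8000` = 40 - r)
    expect_identical(detect_nihl(t, cfg), r >= 10)
  }
})

test_that("classify_ear composes the six rules on the annual audiogram", {
  cfg <- rule_config()
  # flat 10 dB, no shift -> normal only
  d <- classify_ear(list(baseline = aud(thr(flat = 10), occ = "baseline",
                                        date = "2024-01-10"),
                         annual = aud(thr(flat = 10))), cfg)
  expect_true(d$normal)
  expect_false(any(d$hearing_loss, d$hearing_impairment, d$psts, d$tsts,
                   d$nihl, d$sts_pending))

  # the notch example with identical baseline: NIHL plus hearing loss
  d2 <- classify_ear(list(baseline = aud(thr(NOTCH), occ = "baseline",
                                         date = "2024-01-10"),
                          annual = aud(thr(NOTCH))), cfg)
  expect_true(d2$nihl)
  expect_true(d2$hearing_loss)
  expect_false(d2$normal)
  expect_false(d2$hearing_impairment)  # speech PTA 20 < 25

  # flat 15 dB annual with a resolved +10 shift: temporary STS only
  d3 <- classify_ear(list(
    baseline = aud(thr(flat = 5), occ = "baseline", date = "2024-01-10"),
    annual = aud(thr(flat = 15)),
    retest = aud(thr(flat = 5), occ = "retest", date = "2025-02-10")), cfg)
  expect_true(d3$tsts)
  expect_false(d3$psts)
  expect_false(d3$normal)

  # a pending (unconfirmed) shift does not negate normal on its own
  d4 <- classify_ear(list(
    baseline = aud(thr(flat = 5), occ = "baseline", date = "2024-01-10"),
    annual = aud(thr(flat = 15))), cfg)
  expect_true(d4$sts_pending)
  expect_true(d4$normal)

  expect_error(classify_ear(list(annual = aud(thr(flat = 10))), cfg),
               "baseline")
})

test_that("classify_worker takes the ear-wise union and sets flags", {
  cfg <- rule_config()
  # both ears normal -> worker normal, no flags
  wd <- classify_worker(make_record(thr(flat = 10)), cfg)
  expect_true(wd$overall$normal)
  expect_false(wd$flags$repeat_required)
  expect_false(wd$flags$report_required)
  expect_identical(wd$flags$reasons, character())

  # left-ear NIHL only -> worker nihl = TRUE, normal = FALSE
  rec <- worker_record(
    aud(thr(NOTCH), ear = "L", occ = "baseline", date = "2024-01-10"),
    aud(thr(NOTCH), ear = "L", date = "2025-01-10"),
    aud(thr(flat = 10), ear = "R", occ = "baseline", date = "2024-01-10"),
    aud(thr(flat = 10), ear = "R", date = "2025-01-10"))
  wd2 <- classify_worker(rec, cfg)
  expect_true(wd2$overall$nihl)
  expect_false(wd2$overall$normal)
  expect_true(wd2$ears$L$nihl)
  expect_false(wd2$ears$R$nihl)
  expect_true(wd2$flags$report_required)
  expect_true("NIHL_L" %in% wd2$flags$reasons)

  # right-ear pending shift -> repeat required
  rec3 <- worker_record(
    aud(thr(flat = 5), ear = "L", occ = "baseline", date = "2024-01-10"),
    aud(thr(flat = 5), ear = "L", date = "2025-01-10"),
    aud(thr(flat = 5), ear = "R", occ = "baseline", date = "2024-01-10"),
    aud(thr(flat = 15), ear = "R", date = "2025-01-10"))
  wd3 <- classify_worker(rec3, cfg)
  expect_true(wd3$flags$repeat_required)
  expect_identical(wd3$flags$reasons, "STS_PENDING_R")

  # permanent shift -> reportable with ear-coded reason
  rec4 <- worker_record(
    aud(thr(flat = 5), ear = "L", occ = "baseline", date = "2024-01-10"),
    aud(thr(flat = 15), ear = "L", date = "2025-01-10"),
    aud(thr(flat = 15), ear = "L", occ = "retest", date = "2025-02-01"),
    aud(thr(flat = 5), ear = "R", occ = "baseline", date = "2024-01-10"),
    aud(thr(flat = 5), ear = "R", date = "2025-01-10"))
  wd4 <- classify_worker(rec4, cfg)
  expect_true(wd4$flags$report_required)
  expect_true("PSTS_L" %in% wd4$flags$reasons)
})

test_that("classification is deterministic and mutually exclusive", {
  set.seed(7)
  cfg <- rule_config()
  for (i in 1:300) {
    r <- rand_record()
    a <- classify_worker(r, cfg)
    b <- classify_worker(r, cfg)
    expect_true(worker_diag_equal(a, b))
    for (s in c(a$ears, list(a$overall))) {
      positives <- s$hearing_loss || s$hearing_impairment || s$psts ||
        s$tsts || s$nihl
      expect_identical(s$normal, !positives)     # exclusion by construction
      expect_false(s$psts && s$tsts)             # mutual exclusion
      if (s$sts_pending) expect_false(s$psts || s$tsts)
    }
  }
})

test_that("raising one threshold never clears hearing loss, nor a speech
           frequency hearing impairment", {
  set.seed(11)
  cfg <- rule_config()
  for (i in 1:200) {
    t <- unclass(rand_thr())
    f <- sample(FREQ_NAMES, 1)
    t2 <- t
    t2[[f]] <- min(t2[[f]] + sample(c(5, 20, 50), 1), 120)
    before <- detect_hearing_loss(thr(t), cfg)
    after <- detect_hearing_loss(thr(t2), cfg)
    expect_false(before && !after)
    if (f %in% as.character(SPEECH_FREQUENCIES)) {
      expect_false(detect_hearing_impairment(thr(t), cfg) &&
                     !detect_hearing_impairment(thr(t2), cfg))
    }
  }
})

test_that("rule_config rejects nonsensical cutoffs", {
  expect_error(rule_config(loss_cutoff_db = -5), "positive")
  expect_error(rule_config(retest_window_days = 0), "retest_window_days")
  expect_error(rule_config(recovery_sign = "flipped"))
})
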