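# Seeded synthetic cohort generator: worker records built from audiometric
# scenario templates, with gold labels recomputed by the independent oracle
# so that labels stay consistent even when templates interact.

.SCENARIOS <- c("normal", "hearing_loss", "hearing_impairment",
                "psts", "tsts", "nihl")

#' Specification for a synthetic worker cohort
#'
#' Defaults describe an occupational cohort in which 51.4% of workers carry
#' at least one noise-related finding: 48.6% normal, and the remainder split
#' across isolated hearing loss, hearing loss with impairment, permanent and
#' temporary standard threshold shifts, and NIHL. Thresholds are drawn from
#' scenario templates with Gaussian test-retest noise (SD 2.5 dB, the order
#' of magnitude of audiometric test-retest variability), snapped to the
#' 5-dB audiometer grid and clamped so each scenario keeps its defining
#' audiometric signature.
#'
#' @param n_workers cohort size (>= 1).
#' @param seed integer RNG seed; identical spec -> identical cohort.
#' @param mixture named numeric vector of scenario probabilities over
#'   `r paste(.SCENARIOS, collapse = ", ")`; must sum to 1.
#' @param noise_sd threshold noise SD in dB, applied before grid snapping.
#' @param retest_prob probability that an STS worker's follow-up audiogram
#'   is available (absent follow-up leaves the shift pending).
#' @param bilateral_prob probability that an abnormal scenario affects both
#'   ears rather than one.
#' @param nihl_flip_prob expert-disagreement knob: probability of flipping a
#'   worker's gold NIHL label, emulating the criteria variability between
#'   clinicians that makes NIHL the least reproducible category.
#' @param cfg [rule_config()] used by the oracle to produce gold labels.
#' @return an object of class `"generator_spec"`.
#' @export
generator_spec <- function(n_workers = 320, seed = 1,
                           mixture = c(normal = 0.486,
                                       hearing_loss = 0.100,
                                       hearing_impairment = 0.130,
                                       psts = 0.090,
                                       tsts = 0.090,
                                       nihl = 0.104),
                           noise_sd = 2.5,
                           retest_prob = 1.0,
                           bilateral_prob = 0.3,
                           nihl_flip_prob = 0,
                           cfg = rule_config()) {
  if (n_workers < 1) stop("n_workers must be >= 1", call. = FALSE)
  if (!setequal(names(mixture), .SCENARIOS)) {
    stop("mixture must name exactly: ", paste(.SCENARIOS, collapse = ", "),
         call. = FALSE)
  }
  mixture <- mixture[.SCENARIOS]
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  probs <- c(retest_prob, bilateral_prob, nihl_flip_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  structure(list(n_workers = as.integer(n_workers), seed = as.integer(seed),
                 mixture = mixture, noise_sd = noise_sd,
                 retest_prob = retest_prob, bilateral_prob = bilateral_prob,
                 nihl_flip_prob = nihl_flip_prob, cfg = cfg),
            class = "generator_spec")
}

# scenario template: named thresholds plus per-frequency clamp bounds that
# preserve the scenario's audiometric signature under noise
.scenario_template <- function(scenario) {
  f <- as.character(AUD_FREQUENCIES)
  tmpl <- stats::setNames(rep(10, 7), f)
  lo <- tmpl - 5
  hi <- tmpl + 5
  fixed <- character()          # frequencies exempt from noise
  shift <- 0                    # dB added to the 2/3/4 kHz set on the annual
  switch(scenario,
    normal = NULL,
    hearing_loss = {            # one elevated high frequency, flat elsewhere
      tmpl["6000"] <- 30; lo["6000"] <- 25; hi["6000"] <- 35
    },
    hearing_impairment = {      # broadband elevation: impairment + loss
      tmpl[] <- 35; lo[] <- 30; hi[] <- 40
    },
    psts = ,
    tsts = {                    # low flat baseline; exact +15 dB STS overlay
      tmpl[] <- 5; lo[] <- 0; hi[] <- 10
      fixed <- as.character(STS_FREQUENCIES)
      shift <- 15
    },
    nihl = {                    # 3-6 kHz notch with 8 kHz recovery
      tmpl[c("500", "1000")] <- 10
      tmpl["2000"] <- 15; lo["2000"] <- 10; hi["2000"] <- 20
      tmpl["3000"] <- 45; lo["3000"] <- 40; hi["3000"] <- 45
      tmpl["4000"] <- 50; lo["4000"] <- 45; hi["4000"] <- 55
      tmpl["6000"] <- 45; lo["6000"] <- 40; hi["6000"] <- 50
      tmpl["8000"] <- 20; lo["8000"] <- 15; hi["8000"] <- 25
    },
    stop("unknown scenario: ", scenario, call. = FALSE))
  list(tmpl = tmpl, lo = pmax(lo, -10), hi = pmin(hi, 120),
       fixed = fixed, shift = shift)
}

.noisy_thresholds <- function(tm, noise_sd) {
  v <- tm$tmpl
  noisy <- setdiff(names(v), tm$fixed)
  v[noisy] <- v[noisy] + stats::rnorm(length(noisy), 0, noise_sd)
  v <- round(v / 5) * 5                       # snap to audiometer grid
  pmin(pmax(v, tm$lo), tm$hi)
}

#' Generate one synthetic worker with known ground truth
#'
#' Builds baseline/annual (and, for threshold-shift targets, retest)
#' audiograms from the scenario template for `target`, then labels the
#' record with the independent brute-force oracle. The target expresses
#' construction *intent*; the oracle's output is the truth, so gold labels
#' remain consistent even where templates interact (a NIHL notch, for
#' instance, always also constitutes hearing loss).
#'
#' Consumes the current RNG stream; seed outside (as [generate_cohort()]
#' does) for reproducibility.
#'
#' @param worker_id identifier for the generated worker.
#' @param target one of `"normal"`, `"hearing_loss"`, `"hearing_impairment"`,
#'   `"psts"`, `"tsts"`, `"nihl"`, or a character vector combining an STS
#'   target with `"nihl"` (e.g. `c("psts", "nihl")`). `"psts"` and `"tsts"`
#'   are mutually exclusive.
#' @param noise_sd,retest_prob,bilateral_prob see [generator_spec()].
#' @param cfg [rule_config()] for the oracle labelling.
#' @param start_date baseline test date.
#' @return list with `record` (a `worker_record`), `gold` (the oracle's
#'   worker-level `diagnosis_set`), `target`, and `affected_ears`.
#' @export
generate_case <- function(worker_id, target = "normal", noise_sd = 2.5,
                          retest_prob = 1.0, bilateral_prob = 0.3,
                          cfg = rule_config(),
                          start_date = as.Date("2024-01-15")) {
  target <- match.arg(target, c(.SCENARIOS, "psts+nihl", "tsts+nihl"),
                      several.ok = TRUE)
  if (length(target) > 1L) {
    if (all(c("psts", "tsts") %in% target)) {
      stop("inconsistent target: psts and tsts are mutually exclusive",
           call. = FALSE)
    }
    if (!all(target %in% c("psts", "tsts", "nihl")) || length(target) != 2L) {
      stop("unsupported target combination: ",
           paste(target, collapse = "+"), call. = FALSE)
    }
    target <- paste(sort(target, decreasing = TRUE), collapse = "+")
    target <- sub("tsts\\+nihl|nihl\\+tsts", "tsts+nihl", target)
  }
  sts_part <- if (grepl("psts", target)) "psts"
    else if (grepl("tsts", target)) "tsts" else NA
  base_scn <- if (grepl("\\+nihl$", target)) "nihl" else target

  affected <- if (identical(target, "normal")) character()
    else if (stats::runif(1) < bilateral_prob) c("L", "R")
    else sample(c("L", "R"), 1)

  annual_gap <- sample(350:380, 1)
  retest_gap <- sample(20:45, 1)
  has_retest <- !is.na(sts_part) && stats::runif(1) < retest_prob

  auds <- list()
  for (ear in c("L", "R")) {
    scn <- if (ear %in% affected) base_scn else "normal"
    tm <- .scenario_template(scn)
    with_sts <- ear %in% affected && !is.na(sts_part)
    if (with_sts && scn == "nihl") {
      tm$fixed <- as.character(STS_FREQUENCIES)
      tm$shift <- 15
    }
    sts_f <- as.character(STS_FREQUENCIES)

    baseline <- .noisy_thresholds(tm, noise_sd)
    annual <- .noisy_thresholds(tm, noise_sd)
    if (with_sts) annual[sts_f] <- tm$tmpl[sts_f] + tm$shift

    auds <- c(auds, list(
      audiogram(worker_id, ear, "baseline", start_date,
                thresholds(baseline, warn_off_grid = FALSE)),
      audiogram(worker_id, ear, "annual", start_date + annual_gap,
                thresholds(annual, warn_off_grid = FALSE))))

    if (with_sts && has_retest) {
      retest <- .noisy_thresholds(tm, noise_sd)
      retest[sts_f] <- if (sts_part == "psts") tm$tmpl[sts_f] + tm$shift
        else tm$tmpl[sts_f]
      auds <- c(auds, list(
        audiogram(worker_id, ear, "retest",
                  start_date + annual_gap + retest_gap,
                  thresholds(retest, warn_off_grid = FALSE))))
    }
  }
  record <- worker_record(auds)
  gold <- oracle_classify(record, cfg)$overall
  list(record = record, gold = gold, target = target,
       affected_ears = affected)
}

#' Generate a full synthetic cohort with gold-standard labels
#'
#' Draws each worker's scenario from the mixture, builds the records with
#' [generate_case()], and labels them with the oracle. The whole process
#' runs under the spec's seed: an identical spec yields an identical cohort
#' (byte-identical CSVs through [write_cohort()]).
#'
#' @param spec a [generator_spec()].
#' @return list with `records` (list of `worker_record`), `gold`
#'   (worker-level gold data.frame in the gold dialect), and `scenarios`
#'   (the drawn per-worker scenario names).
#' @export
generate_cohort <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(spec$seed, {
    scenarios <- sample(names(spec$mixture), spec$n_workers, replace = TRUE,
                        prob = spec$mixture)
    ids <- sprintf("W%04d", seq_len(spec$n_workers))
    cases <- lapply(seq_len(spec$n_workers), function(i) {
      generate_case(ids[i], scenarios[i], noise_sd = spec$noise_sd,
                    retest_prob = spec$retest_prob,
                    bilateral_prob = spec$bilateral_prob, cfg = spec$cfg)
    })
    gold <- do.call(rbind, lapply(cases, function(cs) {
      g <- cs$gold
      data.frame(worker_id = cs$record$worker_id,
                 normal = as.integer(g$normal),
                 hearing_loss = as.integer(g$hearing_loss),
                 hearing_impairment = as.integer(g$hearing_impairment),
                 psts = as.integer(g$psts), tsts = as.integer(g$tsts),
                 nihl = as.integer(g$nihl), stringsAsFactors = FALSE)
    }))
    if (spec$nihl_flip_prob > 0) {
      flip <- stats::runif(nrow(gold)) < spec$nihl_flip_prob
      gold$nihl[flip] <- 1L - gold$nihl[flip]
      # a flipped-on NIHL label also breaks "normal" for consistency
      gold$normal[flip & gold$nihl == 1L] <- 0L
    }
    list(records = lapply(cases, `[[`, "record"), gold = gold,
         scenarios = scenarios)
  })
}
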