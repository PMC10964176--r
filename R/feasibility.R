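#' Pre-specified feasibility and acceptability outcomes from a ledger
#'
#' Computes every funnel-derivable feasibility outcome from a
#' per-participant ledger: interest, enrolment, consent rate, retention,
#' support-call receipt, app download and continued app use. Each row
#' carries its raw numerator and denominator so every percentage is
#' re-derivable; percentages use round-half-up to integer percent, with a
#' 1-decimal variant alongside. A zero denominator yields an "undefined"
#' outcome (`NA` percentage), never 0.
#'
#' @param ledger Per-participant ledger tibble (see [generate_ledger()]).
#' @return Tibble: `outcome`, `numerator`, `denominator`, `percentage`
#'   (integer %, round-half-up), `percentage_1dp`, `undefined`.
#' @export
#' @examples
#' feasibility_report(pilot_ledger())
feasibility_report <- function(ledger) {
  cn <- ledger_counts(ledger)
  n_rand <- cn$n_randomised_intervention + cn$n_randomised_control
  rows <- list(
    c("interest", cn$n_willing, cn$n_sent_letter),
    c("enrolment", n_rand, cn$n_sent_pis),
    c("consent", cn$n_consented, cn$n_sent_pis),
    c("retention", cn$n_followup_any, n_rand),
    c("first_call_received", cn$n_first_call, cn$n_randomised_intervention),
    c("second_call_received", cn$n_second_call, cn$n_randomised_intervention),
    c("app_downloaded", cn$n_app_downloaded, cn$n_randomised_intervention),
    c("app_still_using", cn$n_app_still_using, cn$n_app_question_asked)
  )
  out <- tibble::tibble(
    outcome = vapply(rows, `[[`, "", 1),
    numerator = as.numeric(vapply(rows, `[[`, "", 2)),
    denominator = as.numeric(vapply(rows, `[[`, "", 3))
  )
  out$undefined <- out$denominator == 0
  pct <- 100 * out$numerator / out$denominator
  out$percentage <- ifelse(out$undefined, NA_real_, round_half_up(pct))
  out$percentage_1dp <- ifelse(out$undefined, NA_real_,
                               round_half_up(pct, 1))
  out[, c("outcome", "numerator", "denominator", "percentage",
          "percentage_1dp", "undefined")]
}

#' Aggregate site population counts for the recruitment-bias comparison
#'
#' @param total Total patients in the site population.
#' @param categories Named list of named integer vectors, one per
#'   characteristic (e.g. `sex`, `cancer_type`); each vector must sum to
#'   `total`.
#' @return An object of class `site_aggregate`.
#' @export
site_aggregate <- function(total, categories) {
  for (nm in names(categories)) {
    if (sum(categories[[nm]]) != total) {
      stop(sprintf("category '%s' sums to %d, not the stated total %d",
                   nm, sum(categories[[nm]]), total), call. = FALSE)
    }
  }
  structure(list(total = total, categories = categories),
            class = "site_aggregate")
}

#' Site-population preset for the reference pilot's recruiting hospital
#'
#' Aggregate counts for the 1072 patients diagnosed with breast, prostate
#' or colorectal cancer at the recruiting site, used to assess potential
#' recruitment bias.
#'
#' @return A [site_aggregate()].
#' @export
pilot_site_aggregate <- function() {
  site_aggregate(1072, list(
    sex = c(male = 435, female = 637),
    cancer_type = c(breast = 405, prostate = 71, colorectal = 596),
    ethnicity = c(white = 977, other = 95),
    imd_quintile = c(`1` = 271, `2` = 225, `3` = 203, `4` = 270, `5` = 103)
  ))
}

#' Compare recruited-sample composition with the site population
#'
#' Side-by-side n (%) per category for the recruited sample and the site
#' aggregate, for the characteristics present in both.
#'
#' @param sample_counts Named list of named integer vectors for the
#'   recruited sample, same shape as the `categories` of
#'   [site_aggregate()].
#' @param site A [site_aggregate()].
#' @return Tibble: `characteristic`, `category`, `sample_n`, `sample_pct`,
#'   `site_n`, `site_pct`, `pct_difference`.
#' @export
recruitment_bias <- function(sample_counts, site) {
  stopifnot(inherits(site, "site_aggregate"))
  shared <- intersect(names(sample_counts), names(site$categories))
  if (length(shared) == 0) {
    stop("no shared characteristics between sample and site", call. = FALSE)
  }
  rows <- lapply(shared, function(nm) {
    sc <- sample_counts[[nm]]
    st <- site$categories[[nm]]
    if (!setequal(names(sc), names(st))) {
      stop(sprintf("category definitions for '%s' do not match", nm),
           call. = FALSE)
    }
    st <- st[names(sc)]
    tibble::tibble(
      characteristic = nm,
      category = names(sc),
      sample_n = as.numeric(sc),
      sample_pct = round_half_up(100 * sc / sum(sc)),
      site_n = as.numeric(st),
      site_pct = round_half_up(100 * st / site$total)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$pct_difference <- out$sample_pct - out$site_pct
  out
}

#' Tabulate sample counts from a cohort table
#'
#' Helper building the `sample_counts` input of [recruitment_bias()]
#' from a cohort tibble.
#'
#' @param cohort Cohort tibble with the named columns.
#' @param vars Character vector of cohort columns to tabulate.
#' @return Named list of named count vectors.
#' @export
cohort_counts <- function(cohort, vars = c("sex", "cancer_type")) {
  out <- lapply(vars, function(v) {
    tb <- table(cohort[[v]])
    stats::setNames(as.integer(tb), names(tb))
  })
  stats::setNames(out, vars)
}

check_codings <- function(codings) {
  bct_cols <- grep("^bct_", names(codings), value = TRUE)
  if (length(bct_cols) != 25) {
    stop("codings must have exactly 25 bct_* indicator columns",
         call. = FALSE)
  }
  vals <- as.matrix(codings[, bct_cols])
  if (!all(vals %in% c(0, 1))) {
    stop("BCT indicators must be binary", call. = FALSE)
  }
  bct_cols
}

#' Fidelity of intervention-call delivery against the 25-item BCT checklist
#'
#' Each intervention call is coded against a checklist of 25 behaviour
#' change techniques; per-call fidelity is the percentage delivered, and
#' the headline figure is the mean over calls.
#'
#' @param codings Tibble with `call_id` and indicator columns
#'   `bct_01`..`bct_25` (0/1).
#' @return A list with `per_call` (tibble: `call_id`, `n_delivered`,
#'   `pct_delivered`) and `overall_mean_pct`.
#' @export
bct_fidelity <- function(codings) {
  if (nrow(codings) == 0) stop("need at least one coding", call. = FALSE)
  bct_cols <- check_codings(codings)
  per_call <- tibble::tibble(
    call_id = codings$call_id,
    n_delivered = rowSums(codings[, bct_cols]),
    pct_delivered = 100 * rowSums(codings[, bct_cols]) / 25
  )
  list(per_call = per_call,
       overall_mean_pct = mean(per_call$pct_delivered))
}

#' Double-coding agreement on the BCT checklist
#'
#' Per-transcript percent agreement between two coders over the 25
#' indicators. Transcripts whose discrepancy exceeds 20% (agreement
#' strictly below 80%) are flagged for consensus discussion; exactly 80%
#' is acceptable and not flagged.
#'
#' @param coder_a,coder_b Coding tibbles (same `call_id`s) as in
#'   [bct_fidelity()].
#' @return Tibble: `call_id`, `n_agree`, `pct_agreement`, `flagged`.
#' @export
double_code_agreement <- function(coder_a, coder_b) {
  cols <- check_codings(coder_a)
  check_codings(coder_b)
  if (!setequal(coder_a$call_id, coder_b$call_id)) {
    stop("both coders must cover the same calls", call. = FALSE)
  }
  coder_b <- coder_b[match(coder_a$call_id, coder_b$call_id), ]
  agree <- rowSums(coder_a[, cols] == coder_b[, cols])
  tibble::tibble(
    call_id = coder_a$call_id,
    n_agree = agree,
    pct_agreement = 100 * agree / 25,
    flagged = 100 * agree / 25 < 80
  )
}
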