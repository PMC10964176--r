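#' Specify aggregate counts for a participant-flow ledger
#'
#' A `ledger_spec` holds the aggregate counts of a two-arm pilot-trial
#' recruitment funnel (screening, invitation letter, willingness,
#' information sheet, consent, randomisation) together with follow-up and
#' app-engagement counts for the intervention arm. [generate_ledger()]
#' expands these aggregates into a per-participant ledger in which exactly
#' the specified number of participants carries each flag.
#'
#' @param n_screened Patients screened against medical records.
#' @param n_excluded_records Patients excluded at the records stage.
#' @param n_sent_letter Patients sent the invitation letter.
#' @param n_willing Patients willing to answer eligibility questions.
#' @param n_sent_pis Patients sent the participant information sheet.
#' @param n_consented Patients consenting to take part.
#' @param n_randomised_intervention,n_randomised_control Randomised per arm.
#' @param n_followup_any Randomised participants completing any follow-up
#'   assessment.
#' @param n_first_call,n_second_call Intervention participants receiving
#'   the first and second behavioural support call.
#' @param n_app_downloaded Intervention participants who downloaded the app.
#' @param n_app_question_asked Intervention participants asked the
#'   follow-up question about app use.
#' @param n_app_still_using Of those asked, participants still using the
#'   app at follow-up.
#' @param seed Integer seed controlling which individual participants
#'   carry each flag (aggregates are unaffected).
#' @return An object of class `ledger_spec`.
#' @seealso [generate_ledger()], [pilot_ledger()]
#' @export
ledger_spec <- function(n_screened = 0,
                        n_excluded_records = 0,
                        n_sent_letter = 0,
                        n_willing = 0,
                        n_sent_pis = 0,
                        n_consented = 0,
                        n_randomised_intervention = 0,
                        n_randomised_control = 0,
                        n_followup_any = 0,
                        n_first_call = 0,
                        n_second_call = 0,
                        n_app_downloaded = 0,
                        n_app_question_asked = 0,
                        n_app_still_using = 0,
                        seed = 1L) {
  spec <- list(
    n_screened = n_screened,
    n_excluded_records = n_excluded_records,
    n_sent_letter = n_sent_letter,
    n_willing = n_willing,
    n_sent_pis = n_sent_pis,
    n_consented = n_consented,
    n_randomised_intervention = n_randomised_intervention,
    n_randomised_control = n_randomised_control,
    n_followup_any = n_followup_any,
    n_first_call = n_first_call,
    n_second_call = n_second_call,
    n_app_downloaded = n_app_downloaded,
    n_app_question_asked = n_app_question_asked,
    n_app_still_using = n_app_still_using,
    seed = as.integer(seed)
  )
  class(spec) <- "ledger_spec"
  validate_ledger_spec(spec)
  spec
}

validate_ledger_spec <- function(spec) {
  counts <- unlist(spec[setdiff(names(spec), "seed")])
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("ledger_spec counts must be non-negative integers", call. = FALSE)
  }
  n_rand <- spec$n_randomised_intervention + spec$n_randomised_control
  chain <- list(
    c("n_excluded_records + n_sent_letter", spec$n_excluded_records + spec$n_sent_letter,
      "n_screened", spec$n_screened),
    c("n_willing", spec$n_willing, "n_sent_letter", spec$n_sent_letter),
    c("n_sent_pis", spec$n_sent_pis, "n_willing", spec$n_willing),
    c("n_consented", spec$n_consented, "n_sent_pis", spec$n_sent_pis),
    c("n_randomised (both arms)", n_rand, "n_consented", spec$n_consented),
    c("n_followup_any", spec$n_followup_any, "n_randomised", n_rand),
    c("n_first_call", spec$n_first_call,
      "n_randomised_intervention", spec$n_randomised_intervention),
    c("n_second_call", spec$n_second_call, "n_first_call", spec$n_first_call),
    c("n_app_downloaded", spec$n_app_downloaded,
      "n_randomised_intervention", spec$n_randomised_intervention),
    c("n_app_question_asked", spec$n_app_question_asked,
      "n_app_downloaded", spec$n_app_downloaded),
    c("n_app_still_using", spec$n_app_still_using,
      "n_app_question_asked", spec$n_app_question_asked)
  )
  for (ck in chain) {
    if (as.numeric(ck[2]) > as.numeric(ck[4])) {
      stop(sprintf("funnel not monotone: %s (%s) exceeds %s (%s)",
                   ck[1], ck[2], ck[3], ck[4]), call. = FALSE)
    }
  }
  invisible(spec)
}

#' Built-in preset encoding the reference pilot-trial participant flow
#'
#' Aggregate counts of the reference two-arm pilot RCT of an app-based
#' walking intervention in adults living with and beyond breast, prostate
#' or colorectal cancer: 1037 screened, 577 sent the invitation letter,
#' 369 willing to answer eligibility questions, 148 sent the information
#' sheet, 93 consented, 90 randomised (44 intervention, 46 control), 87
#' with any follow-up, 43/39 first/second support calls received, 42 app
#' downloads, 39 asked about continued app use and 33 still using it.
#'
#' @param seed Seed for the assignment of flags to individual rows.
#' @return A `ledger_spec`.
#' @export
pilot_ledger_spec <- function(seed = 1L) {
  ledger_spec(
    n_screened = 1037,
    n_excluded_records = 460,
    n_sent_letter = 577,
    n_willing = 369,
    n_sent_pis = 148,
    n_consented = 93,
    n_randomised_intervention = 44,
    n_randomised_control = 46,
    n_followup_any = 87,
    n_first_call = 43,
    n_second_call = 39,
    n_app_downloaded = 42,
    n_app_question_asked = 39,
    n_app_still_using = 33,
    seed = seed
  )
}

#' Generate a per-participant ledger from aggregate funnel counts
#'
#' Expands a [ledger_spec()] into one row per screened patient with
#' logical stage columns. Which individual rows carry each flag is decided
#' by seeded sampling nested down the funnel (a participant can only carry
#' a flag if they carry all upstream flags), so aggregates are exact and a
#' fixed seed gives identical output.
#'
#' @param spec A [ledger_spec()].
#' @return A tibble with one row per screened patient: `participant_id`,
#'   logical columns `sent_letter`, `willing`, `sent_pis`, `consented`,
#'   `randomised`, `followup_any`, `first_call`, `second_call`,
#'   `app_downloaded`, `app_question_asked`, `app_still_using`, and `arm`
#'   (`"intervention"`, `"control"` or `NA` if not randomised).
#' @export
#' @examples
#' ledger <- generate_ledger(pilot_ledger_spec())
#' sum(ledger$randomised)        # 90
#' table(ledger$arm)
generate_ledger <- function(spec) {
  stopifnot(inherits(spec, "ledger_spec"))
  validate_ledger_spec(spec)
  n <- spec$n_screened
  if (n == 0) {
    return(tibble::tibble(
      participant_id = character(),
      sent_letter = logical(), willing = logical(), sent_pis = logical(),
      consented = logical(), randomised = logical(),
      arm = character(),
      followup_any = logical(), first_call = logical(),
      second_call = logical(), app_downloaded = logical(),
      app_question_asked = logical(), app_still_using = logical()
    ))
  }
  with_seed(spec$seed, {
    pick <- function(from, k) sort(sample(from, k))
    ids <- seq_len(n)
    letter <- pick(ids, spec$n_sent_letter)
    willing <- pick(letter, spec$n_willing)
    pis <- pick(willing, spec$n_sent_pis)
    consented <- pick(pis, spec$n_consented)
    n_rand <- spec$n_randomised_intervention + spec$n_randomised_control
    randomised <- pick(consented, n_rand)
    arm_int <- pick(randomised, spec$n_randomised_intervention)
    followup <- pick(randomised, spec$n_followup_any)
    first_call <- pick(arm_int, spec$n_first_call)
    second_call <- pick(first_call, spec$n_second_call)
    app_dl <- pick(arm_int, spec$n_app_downloaded)
    app_q <- pick(app_dl, spec$n_app_question_asked)
    app_using <- pick(app_q, spec$n_app_still_using)

    arm <- rep(NA_character_, n)
    arm[randomised] <- "control"
    arm[arm_int] <- "intervention"
    flag <- function(which) ids %in% which
    tibble::tibble(
      participant_id = sprintf("P%04d", ids),
      sent_letter = flag(letter),
      willing = flag(willing),
      sent_pis = flag(pis),
      consented = flag(consented),
      randomised = flag(randomised),
      arm = arm,
      followup_any = flag(followup),
      first_call = flag(first_call),
      second_call = flag(second_call),
      app_downloaded = flag(app_dl),
      app_question_asked = flag(app_q),
      app_still_using = flag(app_using)
    )
  })
}

#' Per-participant ledger for the reference pilot trial
#'
#' Convenience wrapper: [generate_ledger()] applied to
#' [pilot_ledger_spec()].
#'
#' @inheritParams pilot_ledger_spec
#' @return A per-participant ledger tibble (see [generate_ledger()]).
#' @export
pilot_ledger <- function(seed = 1L) {
  generate_ledger(pilot_ledger_spec(seed = seed))
}

#' Aggregate a per-participant ledger back to funnel counts
#'
#' @param ledger A ledger tibble from [generate_ledger()].
#' @return A named list of counts matching the `ledger_spec` fields.
#' @export
ledger_counts <- function(ledger) {
  list(
    n_screened = nrow(ledger),
    n_sent_letter = sum(ledger$sent_letter),
    n_willing = sum(ledger$willing),
    n_sent_pis = sum(ledger$sent_pis),
    n_consented = sum(ledger$consented),
    n_randomised_intervention = sum(ledger$arm == "intervention", na.rm = TRUE),
    n_randomised_control = sum(ledger$arm == "control", na.rm = TRUE),
    n_followup_any = sum(ledger$followup_any),
    n_first_call = sum(ledger$first_call),
    n_second_call = sum(ledger$second_call),
    n_app_downloaded = sum(ledger$app_downloaded),
    n_app_question_asked = sum(ledger$app_question_asked),
    n_app_still_using = sum(ledger$app_still_using)
  )
}
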