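#' Published summary statistics of the STAR-MH validation study
#'
#' The raw item responses of the original STAR-MH validation cohort were never
#' deposited, but the study's printed summary tables are public. These
#' constructors return those printed numbers as plain data frames so that the
#' arithmetic built on them (participation rates, endorsement percentages,
#' likelihood ratios, Youden sums, cut-score selection) can be recomputed and
#' so that the cohort simulator can be anchored to the published geometry.
#'
#' `starmh_items()` lists the nine fielded items (two immediate screen-in
#' items and the 7-item scale; the original "trouble sleeping" item was
#' dropped for poor endorsement specificity before the Rasch analyses).
#'
#' @return A data frame; see the individual descriptions.
#' @name starmh_reference
NULL

#' @describeIn starmh_reference The nine fielded items with their role
#'   (`screen_in` or `scale`) and short labels used throughout the package.
#' @export
starmh_items <- function() {
  data.frame(
    item = c("item_1", "item_2", "restless", "interest", "crazy",
             "fearful", "trapped", "pain", "worthless"),
    role = c("screen_in", "screen_in", rep("scale", 7L)),
    text = c(
      "Ever seen a doctor / taken medicines for your 'nerves'?",
      "Often wished you were dead, or attempted suicide or self-harm?",
      "Have you felt very restless, like you can't keep still?",
      "Have you lost interest in things?",
      "Have you worried about going crazy or 'losing your mind'?",
      "Have you felt very fearful?",
      "Have you felt very trapped or caught?",
      "Have you had a lot of pain in your body?",
      "Have you felt very worthless?"),
    stringsAsFactors = FALSE
  )
}

#' @describeIn starmh_reference Recruitment and refusal counts per study site
#'   (community welfare centre and community health service).
#' @export
starmh_recruitment <- function() {
  data.frame(
    site = c("ASRC", "MHC"),
    recruited = c(87L, 105L),
    declined = c(85L, 10L),
    stringsAsFactors = FALSE
  )
}

#' @describeIn starmh_reference Headline sample accounting: persons screened,
#'   persons omitted for missing scale responses, persons analyzed, and
#'   interview-confirmed cases (MDD and/or PTSD) among those analyzed.
#' @export
starmh_sample_counts <- function() {
  data.frame(
    n_screened = 192L, n_missing_omitted = 7L,
    n_analyzed = 185L, n_cases = 61L
  )
}

#' @describeIn starmh_reference Published per-item yes/no response counts for
#'   the eight prospectively fielded scale items (percentages in the study are
#'   taken over the full analyzed N even where an item has missing cells).
#' @export
starmh_endorsement_counts <- function() {
  data.frame(
    item = c("restless", "interest", "crazy", "sleep",
             "fearful", "trapped", "pain", "worthless"),
    n_yes = c(55L, 55L, 48L, 62L, 62L, 59L, 61L, 54L),
    n_no = c(130L, 130L, 137L, 122L, 123L, 126L, 124L, 131L),
    stringsAsFactors = FALSE
  )
}

#' @describeIn starmh_reference Published Rasch item difficulties (logits,
#'   sum-zero convention) and standard errors for the final 7-item scale.
#'   These difficulties are the default truth of the cohort simulator.
#' @export
starmh_difficulties <- function() {
  data.frame(
    item = c("restless", "interest", "crazy", "fearful",
             "trapped", "pain", "worthless"),
    difficulty = c(0.06, 0.06, 0.40, -0.27, -0.13, -0.22, 0.11),
    se = c(0.20, 0.20, 0.21, 0.20, 0.20, 0.20, 0.20),
    stringsAsFactors = FALSE
  )
}

#' @describeIn starmh_reference Published sensitivity and specificity (percent)
#'   of the 7-item score at every cut-score 1-7; the inputs from which the
#'   likelihood-ratio and Youden columns of the published accuracy table are
#'   recomputed.
#' @export
starmh_published_cutoffs <- function() {
  data.frame(
    cutoff = 1:7,
    sn_pct = c(96.7, 93.4, 83.6, 73.8, 55.7, 32.8, 16.4),
    sp_pct = c(63.1, 74.6, 84.6, 91.5, 95.4, 98.5, 98.5)
  )
}
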