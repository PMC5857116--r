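#' Default covariate category frequencies
#'
#' Marginal frequencies of the dichotomized grouping covariates, anchored to
#' the validation cohort's demographic table (male 69.7%; age 18-33 at the
#' median split 53.5%; interpreter required 61.1%; welfare-centre site 45.3%;
#' Southern-Asian origin 53.0%; partnered 60.0%; irregular maritime arrival
#' 53.0%; post-migration detention 53.5%). Only marginal frequencies are
#' emulated, not the joint dependence structure.
#'
#' @return Named list mapping covariate name to `list(levels, prob)`.
#' @export
default_covariate_freqs <- function() {
  list(
    sex = list(levels = c("male", "female"), prob = c(0.697, 0.303)),
    age_group = list(levels = c("18-33", "34+"), prob = c(0.535, 0.465)),
    interpreter = list(levels = c("yes", "no"), prob = c(0.611, 0.389)),
    agency = list(levels = c("ASRC", "MHC"), prob = c(0.453, 0.547)),
    origin = list(levels = c("southern_asia", "other"), prob = c(0.530, 0.470)),
    marital = list(levels = c("partnered", "single"), prob = c(0.600, 0.400)),
    travel_mode = list(levels = c("irregular_maritime", "other"),
                       prob = c(0.530, 0.470)),
    detention = list(levels = c("yes", "no"), prob = c(0.535, 0.465))
  )
}

#' Simulation configuration
#'
#' Generative parameters for synthetic validation cohorts. The defaults are
#' the package's emulation of the validation study's geometry: 185 persons,
#' the published sum-zero item difficulties, 33% caseness prevalence, and a
#' two-component normal trait mixture (non-case mean -2.5, case mean +1.0,
#' SD 1.5) calibrated once so that per-item endorsement is about 31%, the
#' 7-item score discriminates caseness at AUC about 0.91, and the mean
#' inter-item correlation is about 0.46 (see `analysis/00_tune_generator.R`
#' for the grid). Screen-in response rates
#' (0.35 given case, 0.05 given non-case) are ansatz values: the study gives
#' no generative description of the screen-in items.
#'
#' @param n_persons cohort size.
#' @param difficulties named vector of scale-item difficulties (logits).
#' @param trait_mean_noncase,trait_mean_case,trait_sd trait mixture.
#' @param prevalence caseness prevalence in (0, 1).
#' @param screen_in_rates `c(case = , noncase = )` per screen-in item.
#' @param n_screen_in number of screen-in items.
#' @param dif_shift optional list of lists `list(item =, covariate =,
#'   level =, delta = )`: difficulty shift (logits, subtracted from the linear
#'   predictor) injected for persons in that covariate level.
#' @param missing_rate MCAR per-cell missingness in `[0, 1)`.
#' @param second_factor optional `list(items =, cor =)`: the named items load
#'   on a second trait correlated `cor` with the primary trait.
#' @param n_noise_items,noise_rate extra trait-independent Bernoulli items
#'   (used to exercise the item-selection cascade).
#' @param covariate_freqs see [default_covariate_freqs()].
#' @param seed optional integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 185L,
                       difficulties = NULL,
                       trait_mean_noncase = -2.5,
                       trait_mean_case = 1.0,
                       trait_sd = 1.5,
                       prevalence = 0.33,
                       screen_in_rates = c(case = 0.35, noncase = 0.05),
                       n_screen_in = 2L,
                       dif_shift = NULL,
                       missing_rate = 0,
                       second_factor = NULL,
                       n_noise_items = 0L,
                       noise_rate = 0.3,
                       covariate_freqs = default_covariate_freqs(),
                       seed = NULL) {
  if (is.null(difficulties)) {
    dd <- starmh_difficulties()
    difficulties <- setNames(dd$difficulty, dd$item)
  }
  problems <- character(0)
  if (n_persons < 1L) problems <- c(problems, "n_persons < 1")
  if (!(prevalence > 0 && prevalence < 1)) problems <- c(problems, "prevalence outside (0,1)")
  if (trait_sd <= 0) problems <- c(problems, "trait_sd <= 0")
  if (!(missing_rate >= 0 && missing_rate < 1)) problems <- c(problems, "missing_rate outside [0,1)")
  if (any(screen_in_rates < 0 | screen_in_rates > 1)) problems <- c(problems, "screen_in_rates outside [0,1]")
  if (noise_rate <= 0 || noise_rate >= 1) problems <- c(problems, "noise_rate outside (0,1)")
  if (!is.null(second_factor) &&
      (is.null(second_factor$items) || is.null(second_factor$cor) ||
         abs(second_factor$cor) > 1)) {
    problems <- c(problems, "second_factor needs $items and $cor in [-1,1]")
  }
  if (length(problems)) {
    stop("invalid simulation config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(list(n_persons = as.integer(n_persons), difficulties = difficulties,
                 trait_mean_noncase = trait_mean_noncase,
                 trait_mean_case = trait_mean_case, trait_sd = trait_sd,
                 prevalence = prevalence, screen_in_rates = screen_in_rates,
                 n_screen_in = as.integer(n_screen_in), dif_shift = dif_shift,
                 missing_rate = missing_rate, second_factor = second_factor,
                 n_noise_items = as.integer(n_noise_items),
                 noise_rate = noise_rate, covariate_freqs = covariate_freqs,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a validation cohort
#'
#' Caseness is Bernoulli(prevalence); the latent distress trait is normal with
#' a caseness-dependent mean; scale-item responses follow the dichotomous
#' Rasch model `P(X = 1) = plogis(theta - beta)` (with optional injected DIF
#' shifts and an optional correlated second factor for a designated item
#' subset); screen-in items are Bernoulli with caseness-dependent rates;
#' covariates are drawn from their marginal frequencies; MCAR missingness is
#' applied last. All latent quantities are returned in the truth record.
#'
#' @param config a [sim_config()].
#' @return List of class `starmh_sim`: `cohort` (a `starmh_cohort` whose
#'   response matrix holds screen-in, scale and any noise items) and `truth`
#'   (list with `theta`, `caseness`, `difficulties`, `config`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_persons
  beta <- config$difficulties
  m <- length(beta)
  caseness <- rbinom(n, 1L, config$prevalence)
  mu <- ifelse(caseness == 1L, config$trait_mean_case, config$trait_mean_noncase)
  z1 <- rnorm(n)
  theta <- mu + config$trait_sd * z1

  # covariates from marginal frequencies
  cov_df <- as.data.frame(lapply(config$covariate_freqs, function(cv) {
    sample(cv$levels, n, replace = TRUE, prob = cv$prob)
  }), stringsAsFactors = FALSE)

  # linear predictor theta - beta, with second factor and DIF shifts
  eta <- outer(theta, beta, "-")
  colnames(eta) <- names(beta)
  if (!is.null(config$second_factor)) {
    rho <- config$second_factor$cor
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    theta_b <- mu + config$trait_sd * z2
    sf_items <- intersect(config$second_factor$items, names(beta))
    eta[, sf_items] <- outer(theta_b, beta[sf_items], "-")
  }
  for (sh in config$dif_shift) {
    in_group <- cov_df[[sh$covariate]] == sh$level
    eta[in_group, sh$item] <- eta[in_group, sh$item] + sh$delta
  }
  scale_resp <- array(rbinom(n * m, 1L, plogis(eta)), dim(eta),
                      dimnames = list(NULL, names(beta)))

  si_rate <- ifelse(caseness == 1L, config$screen_in_rates[["case"]],
                    config$screen_in_rates[["noncase"]])
  screen_resp <- vapply(seq_len(config$n_screen_in),
                        function(j) rbinom(n, 1L, si_rate), integer(n))
  screen_resp <- array(screen_resp, c(n, config$n_screen_in),
                       dimnames = list(NULL, paste0("item_", seq_len(config$n_screen_in))))

  noise_resp <- NULL
  if (config$n_noise_items > 0L) {
    noise_resp <- array(rbinom(n * config$n_noise_items, 1L, config$noise_rate),
                        c(n, config$n_noise_items),
                        dimnames = list(NULL, paste0("noise_", seq_len(config$n_noise_items))))
  }
  resp <- cbind(screen_resp, scale_resp, noise_resp)
  rownames(resp) <- sprintf("p%03d", seq_len(n))
  if (config$missing_rate > 0) {
    drop <- array(runif(length(resp)) < config$missing_rate, dim(resp))
    resp[drop] <- NA_integer_
  }
  cohort <- new_cohort(resp, caseness, cov_df)
  structure(list(cohort = cohort,
                 truth = list(theta = setNames(theta, rownames(resp)),
                              caseness = setNames(caseness, rownames(resp)),
                              difficulties = beta, config = config)),
            class = "starmh_sim")
}
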