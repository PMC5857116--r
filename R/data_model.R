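#' @title Cohort container and validators
#' @description Internal constructors/validators for the binary response
#'   matrix and cohort objects that every analysis consumes.
#' @keywords internal
#' @name data_model_internal
NULL

MISSING_SPELLINGS <- c("", "na", "nan")

#' Coerce to a binary response matrix
#'
#' A binary response matrix is an integer matrix (persons in rows, items in
#' columns, dimnames set) whose cells are 0, 1 or `NA`. It is the substrate of
#' every analysis in the package.
#'
#' @param x matrix or data frame of 0/1/NA values.
#' @return An integer matrix with row and column names.
#' @export
as_response_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("`x` must be a matrix or data frame", call. = FALSE)
  storage.mode(x) <- "integer"
  bad <- !is.na(x) & !(x %in% c(0L, 1L))
  if (any(bad)) {
    stop(sprintf("response matrix has %d cells outside {0, 1, NA}", sum(bad)),
         call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("p", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("item_", seq_len(ncol(x)))
  x
}

#' Construct a cohort
#'
#' Bundles a binary response matrix with per-person caseness (reference
#' diagnosis of MDD and/or PTSD) and categorical grouping covariates.
#'
#' @param responses binary response matrix (see [as_response_matrix()]).
#' @param caseness integer/logical vector of 0/1 (NA allowed), one per person.
#' @param covariates data frame of per-person categorical covariates, or NULL.
#' @return An object of class `starmh_cohort`: a list with elements
#'   `responses`, `caseness`, `covariates`.
#' @export
new_cohort <- function(responses, caseness = NULL, covariates = NULL) {
  responses <- as_response_matrix(responses)
  n <- nrow(responses)
  if (!is.null(caseness)) {
    caseness <- as.integer(caseness)
    if (length(caseness) != n) stop("caseness length != number of persons", call. = FALSE)
    bad <- !is.na(caseness) & !(caseness %in% c(0L, 1L))
    if (any(bad)) stop("caseness must be 0/1/NA", call. = FALSE)
    names(caseness) <- rownames(responses)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != n) stop("covariates rows != number of persons", call. = FALSE)
    rownames(covariates) <- rownames(responses)
  }
  structure(list(responses = responses, caseness = caseness,
                 covariates = covariates),
            class = "starmh_cohort")
}

#' @export
print.starmh_cohort <- function(x, ...) {
  cat(sprintf("STAR-MH cohort: %d persons x %d items; %s caseness; %d covariates\n",
              nrow(x$responses), ncol(x$responses),
              if (is.null(x$caseness)) "no" else
                sprintf("%.1f%%", 100 * mean(x$caseness, na.rm = TRUE)),
              if (is.null(x$covariates)) 0L else ncol(x$covariates)))
  invisible(x)
}

#' Number of persons in a cohort
#' @param cohort a `starmh_cohort`.
#' @return Integer person count.
#' @export
n_persons <- function(cohort) nrow(cohort$responses)

# parse a character vector of cells into integer, mapping accepted missing
# spellings to NA and counting malformed entries
parse_cells <- function(x, allowed) {
  x_trim <- tolower(trimws(x))
  is_missing <- is.na(x) | x_trim %in% MISSING_SPELLINGS
  out <- suppressWarnings(as.integer(x_trim))
  malformed <- !is_missing & (is.na(out) | !(out %in% allowed))
  out[is_missing | malformed] <- NA_integer_
  list(values = out, n_malformed = sum(malformed))
}

#' Default column mapping for cohort CSV files
#'
#' @param items character vector of item column names.
#' @param person_id name of the person-identifier column.
#' @param mdd,ptsd names of the reference-diagnosis columns (0/1), or NULL.
#' @param covariates character vector of covariate column names (may be empty).
#' @return A list schema consumed by [load_cohort()].
#' @export
cohort_schema <- function(items,
                          person_id = "person_id",
                          mdd = "mini_mdd", ptsd = "mini_ptsd",
                          covariates = c("sex", "age_group", "interpreter",
                                         "agency", "origin", "marital",
                                         "travel_mode", "detention")) {
  list(person_id = person_id, items = items, mdd = mdd, ptsd = ptsd,
       covariates = covariates)
}

#' Read a wide cohort CSV
#'
#' Reads a one-row-per-person CSV with binary item columns, reference
#' diagnoses and grouping covariates. Accepted missing spellings are the empty
#' string, "NA" and "NaN" (case-insensitive); any other malformed cell becomes
#' missing and is counted in a single warning. Unmapped columns are ignored.
#'
#' @param path CSV path (UTF-8, header required).
#' @param schema column mapping from [cohort_schema()].
#' @return A `starmh_cohort`; the count of malformed cells is available as
#'   `attr(, "n_malformed")`.
#' @export
load_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
  mandatory <- c(schema$person_id, schema$items)
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- trimws(raw[[schema$person_id]])
  if (anyDuplicated(ids)) {
    stop("integrity error: duplicated person_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  n_malformed <- 0L
  resp <- matrix(NA_integer_, nrow(raw), length(schema$items),
                 dimnames = list(ids, schema$items))
  for (it in schema$items) {
    p <- parse_cells(raw[[it]], allowed = 0:1)
    resp[, it] <- p$values
    n_malformed <- n_malformed + p$n_malformed
  }
  caseness <- NULL
  diag_cols <- intersect(c(schema$mdd, schema$ptsd), names(raw))
  if (length(diag_cols)) {
    dx <- sapply(diag_cols, function(cn) {
      p <- parse_cells(raw[[cn]], allowed = 0:1)
      n_malformed <<- n_malformed + p$n_malformed
      p$values
    })
    dx <- matrix(dx, nrow = nrow(raw))
    # case if positive on any mapped diagnosis; NA only if all are NA
    caseness <- as.integer(apply(dx, 1L, function(r) {
      if (all(is.na(r))) NA_integer_ else as.integer(any(r == 1L, na.rm = TRUE))
    }))
  }
  cov_cols <- intersect(schema$covariates, names(raw))
  covariates <- if (length(cov_cols)) raw[cov_cols] else NULL
  if (n_malformed > 0L) {
    warning(sprintf("%d malformed cells set to missing", n_malformed),
            call. = FALSE)
  }
  out <- new_cohort(resp, caseness, covariates)
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Dichotomize Likert responses
#'
#' Maps 1-4 Likert responses to clinical-relevance indicators: values at or
#' above `threshold` become 1, values below become 0, missing stays missing.
#' The validation study used `threshold = 3` ("quite a bit" or "extremely").
#'
#' @param responses long data frame with columns `person_id`, `item_id`,
#'   `value` (integers 1-4 or NA), or a wide matrix of such values.
#' @param threshold integer cut in `{2, 3, 4}`.
#' @return A binary response matrix (persons x items).
#' @export
dichotomize_likert <- function(responses, threshold = 3L) {
  if (!threshold %in% 2:4) {
    stop("threshold must be 2, 3 or 4 (1 would map every observed value to 1)",
         call. = FALSE)
  }
  if (is.data.frame(responses) &&
      all(c("person_id", "item_id", "value") %in% names(responses))) {
    if (anyDuplicated(responses[c("person_id", "item_id")])) {
      stop("duplicate (person_id, item_id) pairs", call. = FALSE)
    }
    persons <- unique(as.character(responses$person_id))
    items <- unique(as.character(responses$item_id))
    wide <- matrix(NA_integer_, length(persons), length(items),
                   dimnames = list(persons, items))
    wide[cbind(as.character(responses$person_id),
               as.character(responses$item_id))] <-
      as.integer(responses$value)
  } else if (is.matrix(responses) || is.data.frame(responses)) {
    wide <- as.matrix(responses)
    storage.mode(wide) <- "integer"
  } else {
    stop("responses must be a long data frame or a wide matrix", call. = FALSE)
  }
  bad <- !is.na(wide) & !(wide %in% 1:4)
  if (any(bad)) {
    stop(sprintf("validation error: %d non-Likert values (must be 1-4 or missing)",
                 sum(bad)), call. = FALSE)
  }
  out <- ifelse(is.na(wide), NA_integer_, as.integer(wide >= threshold))
  dimnames(out) <- dimnames(wide)
  as_response_matrix(out)
}

#' Sample accounting record
#'
#' @param recruited,declined named per-site counts.
#' @param n_missing_omitted persons dropped for missing responses.
#' @return Object of class `starmh_accounting`.
#' @export
sample_accounting <- function(recruited, declined = integer(0),
                              n_missing_omitted = 0L) {
  recruited <- setNames(as.integer(recruited), names(recruited))
  declined <- setNames(as.integer(declined), names(declined))
  n_missing_omitted <- as.integer(n_missing_omitted)
  if (any(c(recruited, declined, n_missing_omitted) < 0L)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(list(recruited_per_site = recruited, declined_per_site = declined,
                 n_missing_omitted = n_missing_omitted,
                 n_analyzed = sum(recruited) - n_missing_omitted),
            class = "starmh_accounting")
}

#' Drop persons with incomplete responses on a set of items
#'
#' Removes every person with at least one missing cell among `item_subset`,
#' preserving the order of the remaining persons, and reports the accounting
#' (the validation study omitted 7 of 192 screened persons, 3.6%).
#'
#' @param cohort a `starmh_cohort`.
#' @param item_subset non-empty character vector of item columns to require.
#' @return List with elements `cohort` (filtered) and `accounting`
#'   (`starmh_accounting` with `omitted_pct`, 1 d.p.).
#' @export
drop_incomplete <- function(cohort, item_subset = colnames(cohort$responses)) {
  stopifnot(inherits(cohort, "starmh_cohort"))
  if (!length(item_subset)) stop("item_subset must be non-empty", call. = FALSE)
  item_subset <- match.arg(item_subset, colnames(cohort$responses),
                           several.ok = TRUE)
  keep <- rowSums(is.na(cohort$responses[, item_subset, drop = FALSE])) == 0L
  if (!any(keep)) {
    stop("degenerate input: no person has complete responses on the requested items",
         call. = FALSE)
  }
  n0 <- n_persons(cohort)
  filtered <- new_cohort(cohort$responses[keep, , drop = FALSE],
                         if (!is.null(cohort$caseness)) cohort$caseness[keep],
                         if (!is.null(cohort$covariates))
                           cohort$covariates[keep, , drop = FALSE])
  acc <- sample_accounting(recruited = c(total = n0),
                           n_missing_omitted = n0 - sum(keep))
  acc$omitted_pct <- round(100 * (n0 - sum(keep)) / n0, 1L)
  list(cohort = filtered, accounting = acc)
}

#' Per-item endorsement table
#'
#' Yes/no counts and the endorsement percentage per item. Following the
#' convention of the published response-frequency table, percentages are taken
#' over a single stated denominator even for items with missing cells.
#'
#' @param matrix binary response matrix.
#' @param denominator denominator for percentages; defaults to the person
#'   count. Must be at least the largest per-item observed total.
#' @return Data frame with `item`, `n_yes`, `n_no`, `pct_yes` (1 d.p.).
#' @export
endorsement_table <- function(matrix, denominator = nrow(matrix)) {
  matrix <- as_response_matrix(matrix)
  n_yes <- colSums(matrix == 1L, na.rm = TRUE)
  n_no <- colSums(matrix == 0L, na.rm = TRUE)
  if (denominator < max(n_yes + n_no)) {
    stop("denominator smaller than an observed per-item total", call. = FALSE)
  }
  data.frame(item = colnames(matrix), n_yes = as.integer(n_yes),
             n_no = as.integer(n_no),
             pct_yes = round(100 * n_yes / denominator, 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Participation rate from recruitment accounting
#'
#' @param accounting a `starmh_accounting` with per-site recruited and
#'   declined counts.
#' @return List with `rate_pct` (overall participation, percent, 1 d.p.) and
#'   `per_site_pct`.
#' @export
participation_summary <- function(accounting) {
  stopifnot(inherits(accounting, "starmh_accounting"))
  rec <- accounting$recruited_per_site
  dec <- accounting$declined_per_site
  if (length(dec) != length(rec)) {
    dec <- rep_len(if (length(dec)) dec else 0L, length(rec))
  }
  tot <- rec + dec
  if (sum(tot) == 0L) stop("degenerate input: nobody approached", call. = FALSE)
  per_site <- ifelse(tot > 0L, round(100 * rec / tot, 1L), NA_real_)
  names(per_site) <- names(rec)
  list(rate_pct = round(100 * sum(rec) / sum(tot), 1L),
       per_site_pct = per_site)
}
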