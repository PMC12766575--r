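#' Forced-choice T-maze indices
#'
#' Group-level choice indices for T-maze trials in which a cohort of flies
#' chooses between an odor arm (A) and a control arm (B), with
#' non-participating flies (DNP, those remaining in the elevator) counted
#' separately. Recorded deaths are subtracted before computing: from the
#' arm of death when `dead_arm` is given, otherwise from DNP (conservative —
#' it leaves the choice index unchanged).
#'
#' * Conditioned preference index: `CPI = (A - B) / (A + B)`; positive means
#'   odor preference.
#' * Participation index: `(A + B) / (A + B + DNP)`.
#'
#' @param n_a,n_b,n_dnp Fly counts in the odor arm, control arm and
#'   did-not-participate tube (>= 0; vectors recycled).
#' @param n_dead Deaths recorded for the trial, default 0.
#' @param dead_arm Where deaths occurred: `"A"`, `"B"`, `"DNP"`, or `NA`
#'   (unrecorded, subtracted from DNP).
#' @return `cpi()`: value in `[-1, 1]` (`NA` when no fly chose);
#'   `participation_index()`: value in `[0, 1]`.
#' @export
cpi <- function(n_a, n_b, n_dnp = 0, n_dead = 0, dead_arm = NA) {
  cc <- subtract_deaths(n_a, n_b, n_dnp, n_dead, dead_arm)
  tot <- cc$a + cc$b
  ifelse(tot > 0, (cc$a - cc$b) / tot, NA_real_)
}

#' @rdname cpi
#' @export
participation_index <- function(n_a, n_b, n_dnp, n_dead = 0, dead_arm = NA) {
  cc <- subtract_deaths(n_a, n_b, n_dnp, n_dead, dead_arm)
  tot <- cc$a + cc$b + cc$dnp
  if (any(tot <= 0)) stop("participation index undefined: no flies recovered")
  (cc$a + cc$b) / tot
}

subtract_deaths <- function(a, b, dnp, dead, arm) {
  if (any(c(a, b, dnp, dead) < 0)) stop("counts must be non-negative")
  if (any(dead > a + b + dnp)) stop("more deaths than flies")
  n <- max(length(a), length(b), length(dnp), length(dead))
  a <- rep_len(a, n); b <- rep_len(b, n)
  dnp <- rep_len(dnp, n); dead <- rep_len(dead, n)
  arm <- rep_len(if (length(arm)) arm else NA, n)
  arm[is.na(arm)] <- "DNP"
  a <- ifelse(arm == "A", a - dead, a)
  b <- ifelse(arm == "B", b - dead, b)
  dnp <- ifelse(arm == "DNP", dnp - dead, dnp)
  if (any(c(a, b, dnp) < 0)) stop("death subtraction drove a count negative")
  list(a = a, b = b, dnp = dnp)
}

#' Apply the participation exclusion rule to T-maze trials
#'
#' Trials in which half or fewer of the flies participated (participation
#' index <= 0.5) are excluded from analysis; the rest are kept. Both
#' partitions are returned, each annotated with `cpi`, `participation`, and
#' for exclusions a `reason`.
#'
#' @param trials Data frame with columns `n_A`, `n_B`, `n_DNP` and
#'   optionally `n_dead`, `dead_arm`, `trial_id`.
#' @return List with data frames `kept` and `excluded`.
#' @export
filter_trials <- function(trials) {
  stopifnot(all(c("n_A", "n_B", "n_DNP") %in% names(trials)))
  nd <- if ("n_dead" %in% names(trials)) trials$n_dead else 0
  da <- if ("dead_arm" %in% names(trials)) trials$dead_arm else NA
  trials$participation <- participation_index(trials$n_A, trials$n_B,
                                              trials$n_DNP, nd, da)
  trials$cpi <- cpi(trials$n_A, trials$n_B, trials$n_DNP, nd, da)
  drop <- trials$participation <= 0.5
  excluded <- trials[drop, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf("participation %.3f <= 0.5",
                               excluded$participation)
  list(kept = trials[!drop, , drop = FALSE], excluded = excluded)
}

#' Read a T-maze trial table
#'
#' CSV with columns `trial_id`, `n_A`, `n_B`, `n_DNP` and optionally
#' `n_dead`, `dead_arm`.
#'
#' @param path CSV path.
#' @return Data frame of trials.
#' @export
read_tmaze_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("n_A", "n_B", "n_DNP")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df
}
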