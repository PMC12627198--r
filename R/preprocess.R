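#' RT-outlier flagging
#'
#' Marks trials with RTs strictly below 300 ms or strictly above 10 s as
#' outlier trials; flagged trials are removed from all downstream
#' likelihoods.  Boundary values (exactly 0.3 s or 10 s) are kept.
#'
#' @param records Data frame with an `rt` column (seconds, positive).
#' @return `records` with `is_rt_outlier` (re)set.
#' @export
flag_outlier_trials <- function(records) {
  stopifnot(all(records$rt > 0))
  records$is_rt_outlier <- records$rt < 0.3 | records$rt > 10
  records
}

#' Apply the exclusion cascade
#'
#' Three criteria, applied per participant:
#' \itemize{
#'   \item two or more catch-trial errors: excluded from all analyses;
#'   \item 10\% or more RT-outlier trials: additionally excluded from the
#'     DDM analyses;
#'   \item 100 or more preference switches in total: additionally excluded
#'     from the DDM analyses.
#' }
#' "10\% or more" and "100 or more" are inclusive; the outlier percentage
#' is computed over all trials including catch trials (configurable via
#' `outlier_denominator`).
#'
#' @param behavior Cohort behaviour table (`participant`, `kind`, `choice`,
#'   `rt`, `n_switches` columns).
#' @param outlier_denominator `"all"` (default) or `"choice"`: which trials
#'   enter the denominator of the outlier percentage.
#' @return Data frame (one row per participant): `participant`,
#'   `n_catch_errors`, `pct_outlier_trials`, `n_switches_total`,
#'   `included_glmm`, `included_ddm`.
#' @export
apply_exclusions <- function(behavior,
                             outlier_denominator = c("all", "choice")) {
  outlier_denominator <- match.arg(outlier_denominator)
  behavior <- flag_outlier_trials(behavior)
  ids <- unique(behavior$participant)
  out <- lapply(ids, function(id) {
    b <- behavior[behavior$participant == id, , drop = FALSE]
    catch <- b[b$kind == "catch", , drop = FALSE]
    if (nrow(catch) == 0L)
      stop("participant ", id, " has no catch trials; the catch-error ",
           "criterion cannot be evaluated")
    n_catch_err <- sum(catch$choice == "variable")
    denom <- if (outlier_denominator == "all") b else
      b[b$kind != "catch", , drop = FALSE]
    pct_out <- mean(denom$is_rt_outlier)
    n_sw <- sum(b$n_switches)
    inc_glmm <- n_catch_err < 2L
    inc_ddm <- inc_glmm && pct_out < 0.10 && n_sw < 100L
    data.frame(participant = id, n_catch_errors = n_catch_err,
               pct_outlier_trials = pct_out, n_switches_total = n_sw,
               included_glmm = inc_glmm, included_ddm = inc_ddm)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Retain the trials that enter the DDM likelihood
#'
#' Drops catch trials and RT-outlier trials for participants eligible for
#' the DDM analyses.
#'
#' @inheritParams apply_exclusions
#' @param report Output of [apply_exclusions()]; recomputed if missing.
#' @return Filtered behaviour table.
#' @export
ddm_ready_trials <- function(behavior, report = NULL) {
  if (is.null(report)) report <- apply_exclusions(behavior)
  behavior <- flag_outlier_trials(behavior)
  keep_ids <- report$participant[report$included_ddm]
  behavior[behavior$participant %in% keep_ids &
             behavior$kind != "catch" & !behavior$is_rt_outlier, ,
           drop = FALSE]
}
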