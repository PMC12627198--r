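#' Task-design grids and session assembly
#'
#' The task crosses a variable option (amount in euros, with an exact or an
#' ambiguous delay / win probability) against a constant alternative of
#' EUR 5 now for sure.  Each domain contributes 98 unique choice trials:
#' 7 amounts x 9 exact attribute levels plus 7 amounts x 5 ambiguity levels.
#' Ambiguous delays are ranges centred on 100 days; ambiguous probabilities
#' are ranges centred on 50%.  A session holds both grids in 14 alternating
#' 15-trial blocks, each block carrying one catch trial whose variable
#' amount equals the constant EUR 5.
#'
#' @name task_design
NULL

.AMOUNTS <- c(8, 15, 22, 29, 36, 43, 50)
# Nine exact delays (days).  The published list prints eight values with a
# gap at 124; 124 restores the ladder symmetric around 100 days that mirrors
# the nine probability levels.
.DELAYS <- c(10, 26, 50, 76, 100, 124, 150, 174, 190)
.PROBS  <- c(0.05, 0.13, 0.25, 0.38, 0.50, 0.62, 0.75, 0.87, 0.95)
.AMB_DAYS <- c(0, 48, 100, 148, 200)    # range widths, midpoint always 100
.AMB_PROB <- c(0, 0.24, 0.50, 0.74, 1.00)

.trial_df <- function(domain, kind, amount, delay_days, prob_win,
                      amb_days, amb_prob) {
  data.frame(domain = domain, kind = kind, amount = amount,
             delay_days = delay_days, prob_win = prob_win,
             amb_days = amb_days, amb_prob = amb_prob,
             stringsAsFactors = FALSE)
}

#' Build the 98-trial intertemporal choice grid
#'
#' Cross product of the 7 reward amounts with the 9 exact delays, plus the
#' 7 amounts with the 5 time-ambiguity range widths (midpoint fixed at 100
#' days).  Deterministic amount-major order.
#'
#' @return A data frame of trials with columns `domain`, `kind`, `amount`,
#'   `delay_days`, `prob_win`, `amb_days`, `amb_prob`.
#' @export
#' @examples
#' nrow(build_intertemporal_grid())  # 98
build_intertemporal_grid <- function() {
  exact <- expand.grid(delay_days = .DELAYS, amount = .AMOUNTS)
  exact <- exact[order(exact$amount, exact$delay_days), ]
  amb <- expand.grid(amb_days = .AMB_DAYS, amount = .AMOUNTS)
  amb <- amb[order(amb$amount, amb$amb_days), ]
  rbind(
    .trial_df("delay", "exact", exact$amount, exact$delay_days,
              prob_win = 1, amb_days = 0, amb_prob = 0),
    .trial_df("delay", "ambiguous", amb$amount, delay_days = 100,
              prob_win = 1, amb_days = amb$amb_days, amb_prob = 0)
  )
}

#' Build the 98-trial risky choice grid
#'
#' 7 amounts x 9 exact win probabilities (63 exact trials) plus 7 amounts x
#' 5 probability-ambiguity range widths (35 ambiguous trials, midpoint fixed
#' at 50%).
#'
#' @return A data frame of trials (same schema as
#'   [build_intertemporal_grid()]).
#' @export
build_risky_grid <- function() {
  exact <- expand.grid(prob_win = .PROBS, amount = .AMOUNTS)
  exact <- exact[order(exact$amount, exact$prob_win), ]
  amb <- expand.grid(amb_prob = .AMB_PROB, amount = .AMOUNTS)
  amb <- amb[order(amb$amount, amb$amb_prob), ]
  rbind(
    .trial_df("probability", "exact", exact$amount, delay_days = 0,
              prob_win = exact$prob_win, amb_days = 0, amb_prob = 0),
    .trial_df("probability", "ambiguous", amb$amount, delay_days = 0,
              prob_win = 0.5, amb_days = 0, amb_prob = amb$amb_prob)
  )
}

.catch_trial <- function(domain) {
  # attention check: variable amount equals the constant EUR 5; mid-level
  # exact attribute so nothing but the amount distinguishes it
  if (domain == "delay") {
    .trial_df("delay", "catch", .CONST_AMOUNT, 100, 1, 0, 0)
  } else {
    .trial_df("probability", "catch", .CONST_AMOUNT, 0, 0.5, 0, 0)
  }
}

#' Assemble a full 210-trial session
#'
#' Shuffles each 98-trial grid into seven 14-trial blocks, inserts one catch
#' trial per block at a random position, and interleaves delay and
#' probability blocks (14 blocks of 15 trials).  Which domain opens the
#' session follows the parity of `seed`.  Fully reproducible given `seed`.
#'
#' @param seed Integer seed controlling trial order and catch positions.
#' @return A data frame of 210 trials with additional columns `block`
#'   (1..14) and `trial_index` (1..210).
#' @export
assemble_session <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  itc <- build_intertemporal_grid()
  rsk <- build_risky_grid()
  if (nrow(itc) != 98L || nrow(rsk) != 98L)
    stop("grid sizes inconsistent with the 14x15 block structure")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  itc <- itc[sample.int(nrow(itc)), ]
  rsk <- rsk[sample.int(nrow(rsk)), ]
  first <- if (as.integer(seed) %% 2L == 0L) "probability" else "delay"
  blocks <- vector("list", 14L)
  ii <- 0L; ri <- 0L
  for (b in seq_len(14L)) {
    dom <- if ((b %% 2L == 1L) == (first == "delay")) "delay" else "probability"
    if (dom == "delay") {
      blk <- itc[ii + seq_len(14L), ]; ii <- ii + 14L
    } else {
      blk <- rsk[ri + seq_len(14L), ]; ri <- ri + 14L
    }
    pos <- sample.int(15L, 1L)
    blk <- rbind(utils::head(blk, pos - 1L),
                 .catch_trial(dom),
                 utils::tail(blk, 15L - pos))
    blk$block <- b
    blocks[[b]] <- blk
  }
  out <- do.call(rbind, blocks)
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  out
}

# preserve the caller's RNG state around seeded internals
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
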