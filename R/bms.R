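#' Akaike-type model weights via softmax
#'
#' `w_m = exp(elpd_m - max(elpd)) / sum(exp(elpd - max(elpd)))`.
#' Shift-invariant; equal inputs give uniform weights.
#'
#' @param elpd Numeric vector of K >= 2 finite model scores (e.g.
#'   per-participant elpd-LOO values).
#' @return Vector of non-negative weights summing to 1.
#' @export
akaike_weights <- function(elpd) {
  if (length(elpd) < 2 || any(!is.finite(elpd)))
    stop("akaike_weights needs >= 2 finite scores")
  w <- exp(elpd - max(elpd))
  w / sum(w)
}

#' Pseudo-inclusion Bayes factor
#'
#' Posterior odds of a model family built from softmax model weights,
#' corrected for the prior family odds (uniform prior over models, so the
#' correction is the ratio of family sizes):
#' `PBF = (sum w_in / sum w_out) / (n_in / n_out)`.
#'
#' @param weights Model weights (from [akaike_weights()]); must sum to 1.
#' @param in_group Logical vector: which models carry the feature (e.g.
#'   ambiguity models, attribute-wise models).  Both groups must be
#'   non-empty.
#' @param cap Sentinel returned (with a flag) when the out-group mass is
#'   zero.
#' @return List: `pbf`, `log_pbf`, `capped`.
#' @export
pbf_inclusion <- function(weights, in_group, cap = 1e12) {
  stopifnot(length(weights) == length(in_group))
  if (!any(in_group) || all(in_group))
    stop("both model groups must be non-empty")
  w_in <- sum(weights[in_group]); w_out <- sum(weights[!in_group])
  prior_odds <- sum(in_group) / sum(!in_group)
  if (w_out <= 0) {
    return(list(pbf = cap, log_pbf = log(cap), capped = TRUE))
  }
  pbf <- (w_in / w_out) / prior_odds
  list(pbf = pbf, log_pbf = log(pbf), capped = FALSE)
}

#' Feature labels for a set of models
#'
#' @param model_ids Character vector of registry ids.
#' @param feature `"ambiguity"` or `"attribute_wise"`.
#' @return Logical vector: feature present.
#' @export
model_feature <- function(model_ids,
                          feature = c("ambiguity", "attribute_wise")) {
  feature <- match.arg(feature)
  vapply(model_ids, function(id) {
    m <- ddm_model(id)
    if (feature == "ambiguity") m$has_ambiguity else m$is_attribute_wise
  }, logical(1))
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across participants:
#' a Dirichlet posterior over population model frequencies is obtained by
#' variational Bayes from the per-participant model scores (log evidences;
#' here elpd-LOO values), the exceedance probability (EP) of each model is
#' estimated by Monte-Carlo sampling of that Dirichlet, the Bayes omnibus
#' risk (BOR) compares the random-effects model against the
#' equal-frequency null via their free energies, and the protected
#' exceedance probability is `PXP = (1 - BOR) * EP + BOR / K`.
#'
#' @param scores N x K matrix: per-participant (rows) log evidence per
#'   model (columns).  N >= 2.
#' @param n_samples Dirichlet Monte-Carlo sample size for the EP.
#' @param seed Seed for the EP sampling.
#' @param alpha0 Prior Dirichlet concentration (uniform by default).
#' @param max_iter,tol VB iteration controls.
#' @return Object of class `bms_result`: `alpha`, `expected_freq`, `ep`,
#'   `bor`, `pxp`, `F1`, `F0`.
#' @export
re_bms <- function(scores, n_samples = 1e5, seed = 1, alpha0 = NULL,
                   max_iter = 500, tol = 1e-8) {
  scores <- as.matrix(scores)
  N <- nrow(scores); K <- ncol(scores)
  if (N < 2) stop("random-effects BMS undefined for fewer than 2 subjects")
  if (is.null(alpha0)) alpha0 <- rep(1, K)
  alpha <- alpha0
  z <- matrix(1 / K, N, K)
  for (it in seq_len(max_iter)) {
    lg <- sweep(scores, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lg <- lg - apply(lg, 1, max)
    z_new <- exp(lg) / rowSums(exp(lg))
    alpha_new <- alpha0 + colSums(z_new)
    if (max(abs(alpha_new - alpha)) < tol) { z <- z_new; alpha <- alpha_new; break }
    z <- z_new; alpha <- alpha_new
  }
  r <- alpha / sum(alpha)
  # free energy of the RE model at the converged variational solution
  zl <- z * scores
  ent <- z * log(z); ent[z == 0] <- 0
  F1 <- sum(zl) - sum(ent) +
    lgamma(sum(alpha0)) - sum(lgamma(alpha0)) -
    lgamma(sum(alpha)) + sum(lgamma(alpha))
  # null model: frequencies fixed and equal
  F0 <- sum(apply(scores, 1, .logsumexp)) - N * log(K)
  bor <- 1 / (1 + exp(F1 - F0))
  # exceedance probabilities by Dirichlet Monte Carlo
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  g <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              n_samples, K)
  ep <- tabulate(max.col(g), K) / n_samples
  pxp <- (1 - bor) * ep + bor / K
  structure(list(alpha = alpha, expected_freq = r, ep = ep, bor = bor,
                 pxp = pxp, F1 = F1, F0 = F0,
                 model_names = colnames(scores)),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  df <- data.frame(model = x$model_names %||% seq_along(x$pxp),
                   expected_freq = round(x$expected_freq, 3),
                   ep = round(x$ep, 3), pxp = round(x$pxp, 3))
  print(df, row.names = FALSE)
  cat("BOR =", round(x$bor, 4), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Participant-level model comparison table
#'
#' Convenience wrapper: given a list of per-model `loo_result`s per
#' participant, assembles the N x K elpd matrix, per-participant Akaike
#' weights and pseudo-inclusion Bayes factors for a feature partition.
#'
#' @param elpd_matrix N x K matrix of per-participant elpd-LOO values with
#'   model ids as column names.
#' @param feature Feature partition for the PBF (see [model_feature()]).
#' @return List: `weights` (N x K), `pbf` (data frame: participant,
#'   pbf, log_pbf, capped), `in_group`.
#' @export
compare_models <- function(elpd_matrix,
                           feature = c("ambiguity", "attribute_wise")) {
  feature <- match.arg(feature)
  elpd_matrix <- as.matrix(elpd_matrix)
  in_group <- model_feature(colnames(elpd_matrix), feature)
  W <- t(apply(elpd_matrix, 1, akaike_weights))
  colnames(W) <- colnames(elpd_matrix)
  pbf <- do.call(rbind, lapply(seq_len(nrow(W)), function(i) {
    r <- pbf_inclusion(W[i, ], in_group)
    data.frame(participant = i, pbf = r$pbf, log_pbf = r$log_pbf,
               capped = r$capped)
  }))
  list(weights = W, pbf = pbf, in_group = in_group)
}
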