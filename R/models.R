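#' Drift-rate model registry
#'
#' Twelve intertemporal-choice and nine risky-choice drift-rate models.
#' Integrated-value models map trial attributes to a subjective value (SV)
#' for each option and set the drift to `eta * (SV_variable - SV_constant)`;
#' attribute-wise models set the drift to a weighted sum of attribute
#' differences (for those, `eta` is fixed to 1 since the weights absorb the
#' scale).  Ambiguity enters additively (`beta * Amb/2`), through perceived
#' time/probability (time-perception and Gilboa-Schmeidler models), or as a
#' separate attribute with weight `w_amb`.  The constant option is always
#' EUR 5 now for sure (V = 5, D = 0, P = 1).
#'
#' Each entry records the ordered parameter list, the sampling transform for
#' each parameter, whether the model contains an ambiguity term
#' (`has_ambiguity`), whether it is attribute-wise, the name of its
#' ambiguity parameter and the sign of `dv/dAmb` for a positive value of
#' that parameter (`amb_direction`; ambiguity aversion corresponds to
#' `amb_direction * parameter < 0`).
#'
#' @param model_id Character id, e.g. `"itc_aw_amb_rxd"` or `"risk_gs"`.
#' @return `ddm_model()` returns the registry entry (a list);
#'   `list_models()` a data frame summarising all entries.
#' @export
ddm_model <- function(model_id) {
  reg <- .model_registry()
  if (!model_id %in% names(reg))
    stop("unknown model_id: ", model_id,
         " (see list_models() for the registry)")
  reg[[model_id]]
}

#' @rdname ddm_model
#' @export
list_models <- function() {
  reg <- .model_registry()
  do.call(rbind, lapply(reg, function(m)
    data.frame(model_id = m$model_id, domain = m$domain,
               n_params = length(m$param_names),
               params = paste(m$param_names, collapse = ","),
               has_ambiguity = m$has_ambiguity,
               is_attribute_wise = m$is_attribute_wise,
               stringsAsFactors = FALSE)))
}

# transforms: sampling is done on an unconstrained scale theta with
# natural = scale * exp(theta) ("log"), plogis(theta) ("logit") or theta
# ("identity"); the scale constant centres theta = 0 on a typical value.
.par <- function(name, transform, scale = 1) {
  list(name = name, transform = transform, scale = scale)
}

.BASE_PARS <- list(.par("A", "log", 1), .par("t0", "log", 0.2),
                   .par("z", "logit"))

.model_entry <- function(model_id, domain, drift_pars, drift_fun,
                         has_ambiguity, is_attribute_wise,
                         amb_param = NA_character_, amb_direction = 0) {
  pars <- c(.BASE_PARS, drift_pars)
  list(model_id = model_id, domain = domain,
       param_names = vapply(pars, `[[`, "", "name"),
       param_meta = pars,
       drift_fun = drift_fun,
       has_ambiguity = has_ambiguity,
       is_attribute_wise = is_attribute_wise,
       amb_param = amb_param, amb_direction = amb_direction)
}

.p_eta  <- .par("eta", "log", 0.05)
.p_k    <- .par("k", "log", 0.01)
.p_s    <- .par("s", "log", 1)
.p_alpha<- .par("alpha", "log", 1)

.model_registry <- function() {
  if (!is.null(.registry_cache$reg)) return(.registry_cache$reg)
  V0 <- .CONST_AMOUNT; D0 <- .CONST_DELAY; P0 <- .CONST_PROB
  reg <- list()
  add <- function(e) reg[[e$model_id]] <<- e

  # ---- intertemporal: integrated-value (hyperbolic family) -------------
  # The published sooner-smaller term prints V_LL; with D_SS = 0 this makes
  # the drift non-positive for every trial, so the constant option's V_SS
  # is used unless strict_printed = TRUE reproduces the printed form.
  ss_amt <- function(V, strict) if (strict) V else V0

  add(.model_entry("itc_hyp", "delay", list(.p_eta, .p_k),
    function(p, tr, strict = FALSE) {
      p$eta * (tr$amount / (1 + p$k * tr$delay_days) -
               ss_amt(tr$amount, strict) / (1 + p$k * D0))
    }, FALSE, FALSE))

  add(.model_entry("itc_hyp_add", "delay",
    list(.p_eta, .p_k, .par("beta_itc", "identity")),
    function(p, tr, strict = FALSE) {
      p$eta * (tr$amount / (1 + p$k * tr$delay_days) -
               ss_amt(tr$amount, strict) / (1 + p$k * D0) -
               p$beta_itc * tr$amb_days / 2)
    }, TRUE, FALSE, "beta_itc", -1))

  add(.model_entry("itc_hyp_tp", "delay",
    list(.p_eta, .p_k, .par("beta_itc", "identity")),
    function(p, tr, strict = FALSE) {
      deff <- pmax(tr$delay_days - p$beta_itc * tr$amb_days, 0)  # full range
      p$eta * (tr$amount / (1 + p$k * deff) -
               ss_amt(tr$amount, strict) / (1 + p$k * D0))
    }, TRUE, FALSE, "beta_itc", +1))

  add(.model_entry("itc_ghyp", "delay", list(.p_eta, .p_k, .p_s),
    function(p, tr, strict = FALSE) {
      p$eta * (tr$amount / (1 + (p$k * tr$delay_days)^p$s) -
               ss_amt(tr$amount, strict) / (1 + (p$k * D0)^p$s))
    }, FALSE, FALSE))

  add(.model_entry("itc_ghyp_add", "delay",
    list(.p_eta, .p_k, .p_s, .par("beta_itc", "identity")),
    function(p, tr, strict = FALSE) {
      p$eta * (tr$amount / (1 + (p$k * tr$delay_days)^p$s) -
               ss_amt(tr$amount, strict) / (1 + (p$k * D0)^p$s) -
               p$beta_itc * tr$amb_days / 2)
    }, TRUE, FALSE, "beta_itc", -1))

  add(.model_entry("itc_ghyp_tp", "delay",
    list(.p_eta, .p_k, .p_s, .par("beta_itc", "identity")),
    function(p, tr, strict = FALSE) {
      base <- pmax(p$k * tr$delay_days - p$beta_itc * tr$amb_days / 2, 0)
      p$eta * (tr$amount / (1 + base^p$s) -
               ss_amt(tr$amount, strict) / (1 + (p$k * D0)^p$s))
    }, TRUE, FALSE, "beta_itc", +1))

  # ---- intertemporal: attribute-wise -----------------------------------
  dV <- function(tr) tr$amount - V0
  dD <- function(tr) tr$delay_days - D0

  add(.model_entry("itc_aw", "delay",
    list(.par("w_r", "identity"), .par("w_t", "identity")),
    function(p, tr, strict = FALSE) p$w_r * dV(tr) + p$w_t * dD(tr),
    FALSE, TRUE))

  add(.model_entry("itc_aw_rxd", "delay",
    list(.par("w_r", "identity"), .par("w_t", "identity"),
         .par("w_inter", "identity")),
    function(p, tr, strict = FALSE)
      p$w_r * dV(tr) + p$w_t * dD(tr) + p$w_inter * dV(tr) * dD(tr),
    FALSE, TRUE))

  add(.model_entry("itc_aw_amb", "delay",
    list(.par("w_r", "identity"), .par("w_t", "identity"),
         .par("w_amb", "identity")),
    function(p, tr, strict = FALSE)
      p$w_r * dV(tr) + p$w_t * dD(tr) + p$w_amb * tr$amb_days / 2,
    TRUE, TRUE, "w_amb", +1))

  add(.model_entry("itc_aw_amb_rxd", "delay",
    list(.par("w_r", "identity"), .par("w_t", "identity"),
         .par("w_inter", "identity"), .par("w_amb", "identity")),
    function(p, tr, strict = FALSE)
      p$w_r * dV(tr) + p$w_t * dD(tr) +
        p$w_inter * dV(tr) * dD(tr) + p$w_amb * tr$amb_days / 2,
    TRUE, TRUE, "w_amb", +1))

  # rows with a reward x ambiguity interaction carry the ambiguity main
  # effect on the FULL range width, as printed
  add(.model_entry("itc_aw_amb_rxa", "delay",
    list(.par("w_r", "identity"), .par("w_t", "identity"),
         .par("w_amb", "identity"), .par("w_inter_amb", "identity")),
    function(p, tr, strict = FALSE)
      p$w_r * dV(tr) + p$w_t * dD(tr) + p$w_amb * tr$amb_days +
        p$w_inter_amb * dV(tr) * tr$amb_days / 2,
    TRUE, TRUE, "w_amb", +1))

  add(.model_entry("itc_aw_full", "delay",
    list(.par("w_r", "identity"), .par("w_t", "identity"),
         .par("w_amb", "identity"), .par("w_inter", "identity"),
         .par("w_inter_amb", "identity")),
    function(p, tr, strict = FALSE)
      p$w_r * dV(tr) + p$w_t * dD(tr) + p$w_amb * tr$amb_days +
        p$w_inter * dV(tr) * dD(tr) +
        p$w_inter_amb * dV(tr) * tr$amb_days / 2,
    TRUE, TRUE, "w_amb", +1))

  # ---- risky: integrated-value -----------------------------------------
  add(.model_entry("risk_eu", "probability", list(.p_eta, .p_alpha),
    function(p, tr, strict = FALSE)
      p$eta * (tr$prob_win * tr$amount^p$alpha - P0 * V0^p$alpha),
    FALSE, FALSE))

  add(.model_entry("risk_gs", "probability",
    list(.p_eta, .p_alpha, .par("beta_risk", "identity")),
    function(p, tr, strict = FALSE)
      p$eta * ((tr$prob_win - p$beta_risk * tr$amb_prob / 2) *
                 tr$amount^p$alpha - P0 * V0^p$alpha),
    TRUE, FALSE, "beta_risk", -1))

  add(.model_entry("risk_eu_add", "probability",
    list(.p_eta, .p_alpha, .par("beta_risk", "identity")),
    function(p, tr, strict = FALSE)
      p$eta * (tr$prob_win * tr$amount^p$alpha - P0 * V0^p$alpha -
               p$beta_risk * tr$amb_prob / 2),
    TRUE, FALSE, "beta_risk", -1))

  # ---- risky: attribute-wise -------------------------------------------
  dP <- function(tr) tr$prob_win - P0

  add(.model_entry("risk_aw", "probability",
    list(.par("w_r", "identity"), .par("w_p", "identity")),
    function(p, tr, strict = FALSE) p$w_r * dV(tr) + p$w_p * dP(tr),
    FALSE, TRUE))

  add(.model_entry("risk_aw_rxp", "probability",
    list(.par("w_r", "identity"), .par("w_p", "identity"),
         .par("w_inter", "identity")),
    function(p, tr, strict = FALSE)
      p$w_r * dV(tr) + p$w_p * dP(tr) + p$w_inter * dV(tr) * dP(tr),
    FALSE, TRUE))

  add(.model_entry("risk_aw_amb", "probability",
    list(.par("w_r", "identity"), .par("w_p", "identity"),
         .par("w_amb", "identity")),
    function(p, tr, strict = FALSE)
      p$w_r * dV(tr) + p$w_p * dP(tr) + p$w_amb * tr$amb_prob / 2,
    TRUE, TRUE, "w_amb", +1))

  add(.model_entry("risk_aw_amb_rxp", "probability",
    list(.par("w_r", "identity"), .par("w_p", "identity"),
         .par("w_amb", "identity"), .par("w_inter", "identity")),
    function(p, tr, strict = FALSE)
      p$w_r * dV(tr) + p$w_p * dP(tr) + p$w_amb * tr$amb_prob +
        p$w_inter * dV(tr) * dP(tr),
    TRUE, TRUE, "w_amb", +1))

  add(.model_entry("risk_aw_amb_rxa", "probability",
    list(.par("w_r", "identity"), .par("w_p", "identity"),
         .par("w_amb", "identity"), .par("w_inter_amb", "identity")),
    function(p, tr, strict = FALSE)
      p$w_r * dV(tr) + p$w_p * dP(tr) + p$w_amb * tr$amb_prob +
        p$w_inter_amb * dV(tr) * tr$amb_prob / 2,
    TRUE, TRUE, "w_amb", +1))

  add(.model_entry("risk_aw_full", "probability",
    list(.par("w_r", "identity"), .par("w_p", "identity"),
         .par("w_amb", "identity"), .par("w_inter", "identity"),
         .par("w_inter_amb", "identity")),
    function(p, tr, strict = FALSE)
      p$w_r * dV(tr) + p$w_p * dP(tr) + p$w_amb * tr$amb_prob +
        p$w_inter * dV(tr) * dP(tr) +
        p$w_inter_amb * dV(tr) * tr$amb_prob / 2,
    TRUE, TRUE, "w_amb", +1))

  .registry_cache$reg <- reg
  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' Evaluate a model's drift rate on trials
#'
#' @param model A registry entry from [ddm_model()] or a model id.
#' @param params Named list/vector of natural-scale parameter values
#'   (the drift parameters; `A`, `t0`, `z` are ignored here).
#' @param trials Data frame of trials (schema of
#'   [build_intertemporal_grid()]).
#' @param strict_printed Reproduce the published sooner-smaller term
#'   (variable amount instead of the constant EUR 5) in the hyperbolic
#'   family.
#' @return Numeric vector of drift rates (evidence units per second).
#' @export
drift_rate <- function(model, params, trials, strict_printed = FALSE) {
  if (is.character(model)) model <- ddm_model(model)
  if (!all(trials$domain %in% model$domain))
    stop("trial domain does not match model domain (", model$domain, ")")
  p <- as.list(params)
  missing <- setdiff(setdiff(model$param_names, c("A", "t0", "z")), names(p))
  if (length(missing))
    stop("missing drift parameters: ", paste(missing, collapse = ", "))
  v <- model$drift_fun(p, trials, strict_printed)
  if (any(!is.finite(v))) stop("non-finite drift rate for in-range inputs")
  v
}
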