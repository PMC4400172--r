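#' Per-second design table for the turn-taking models
#'
#' One row per second that falls inside any speech turn (seconds with
#' no active turn are excluded).  The floor-holder of a second is
#' resolved by the last-starter rule ([floor_holder()]); moderator
#' seconds stay in the table, coded as "target not speaking".
#'
#' @param annotation A [debate_annotation()].
#' @param rates A [rate_series()] aligned to the same event, with a
#'   channel named after `target` and a `"total"` channel.
#' @param target Principal whose mention channel is the response of the
#'   speaker model (must be a speaker label and a channel label).
#' @return Data frame with columns `t_s`, `turn_id`,
#'   `speaker_is_target`, `speaking_time_s`, `is_interruption`,
#'   `count_target`, `count_total`.
#' @export
build_turn_design <- function(annotation, rates, target) {
  stopifnot(inherits(annotation, "debate_annotation"),
            inherits(rates, "rate_series"))
  if (!target %in% names(rates$channels))
    stop("no rate channel named '", target, "'")
  if (!target %in% annotation$speakers)
    stop("'", target, "' is not a declared speaker")
  if (!nrow(annotation$turns)) stop("annotation has no turns")
  t_s <- rates$t0_s + (seq_len(rates$n_bins) - 1L) * rates$bin_width_s
  fh <- floor_holder(annotation, t_s)
  keep <- !is.na(fh)
  fh <- fh[keep]
  t_s <- t_s[keep]
  data.frame(
    t_s = t_s,
    turn_id = fh,
    speaker_is_target = as.integer(annotation$turns$speaker[fh] == target),
    speaking_time_s = t_s - annotation$turns$start_s[fh],
    is_interruption = as.integer(annotation$turns$is_interruption[fh]),
    count_target = rates$channels[[target]][keep],
    count_total = rates$channels[["total"]][keep])
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant variable")
  (x - mean(x)) / s
}

fit_lmm <- function(formula, data, fallback_formula) {
  warn <- character()
  fit <- withCallingHandlers(
    suppressMessages(lmerTest::lmer(formula, data = data, REML = TRUE)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- !any(grepl("failed to converge", warn))
  fallback <- FALSE
  if (!converged || lme4::isSingular(fit, tol = 1e-4)) {
    warn2 <- character()
    fit2 <- withCallingHandlers(
      suppressMessages(lmerTest::lmer(fallback_formula, data = data,
                                      REML = TRUE)),
      warning = function(w) {
        warn2 <<- c(warn2, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    fit <- fit2
    converged <- !any(grepl("failed to converge", warn2))
    fallback <- TRUE
  }
  list(fit = fit, converged = converged, fallback = fallback,
       singular = lme4::isSingular(fit, tol = 1e-4))
}

new_entrain_lmm <- function(fitted, response, data) {
  fit <- fitted$fit
  sm <- stats::coef(summary(fit))
  r2 <- r2_mixed(fit)
  structure(list(
    coefficients = data.frame(term = rownames(sm),
                              beta = sm[, "Estimate"],
                              t_value = sm[, "t value"],
                              p_value = sm[, "Pr(>|t|)"],
                              row.names = NULL),
    r2_marginal = r2[["r2_marginal"]],
    r2_conditional = r2[["r2_conditional"]],
    converged = fitted$converged,
    fallback = fitted$fallback,
    singular = fitted$singular,
    n_obs = nrow(data),
    response = response,
    model = fit), class = "entrain_lmm")
}

#' Mixed-effects model of mention rate against speaker and speaking time
#'
#' Fits, by REML, the per-second standardized mention count of one
#' principal on fixed effects *speaker* (is the target holding the
#' floor), *speaking time* (seconds into the current turn,
#' standardized) and their interaction, with random intercepts and
#' uncorrelated random slopes for speaker and speaking time grouped by
#' turn.  Continuous variables are z-scored before fitting, so the
#' reported betas are standardized; p-values use the Satterthwaite
#' degrees-of-freedom approximation.
#'
#' If the full random structure fails to converge or is singular, the
#' model falls back to a random intercept only and the result is
#' flagged (`fallback = TRUE`).  A boundary (zero-variance) fit of the
#' fallback is reported with `singular = TRUE` rather than an error,
#' since it still yields valid fixed-effect estimates — the expected
#' outcome when there is genuinely no turn-to-turn heterogeneity.
#'
#' @param design Design table from [build_turn_design()].
#' @return An object of class `entrain_lmm` with elements
#'   `coefficients` (term, standardized beta, t, p), `r2_marginal`,
#'   `r2_conditional`, `converged`, `fallback`, `singular`, `n_obs`,
#'   and the underlying `lmerMod` in `$model`.
#' @export
fit_speaker_model <- function(design) {
  per_level <- tapply(design$turn_id, design$speaker_is_target,
                      function(x) length(unique(x)))
  if (length(per_level) < 2L || any(per_level < 2L))
    stop("need at least 2 turns at each speaker level")
  d <- data.frame(y = zscore(design$count_target),
                  speaker = design$speaker_is_target,
                  stime = zscore(design$speaking_time_s),
                  turn_id = factor(design$turn_id))
  fitted <- fit_lmm(y ~ speaker * stime + (1 + speaker + stime || turn_id),
                    d, y ~ speaker * stime + (1 | turn_id))
  new_entrain_lmm(fitted, "count_target (standardized)", d)
}

#' Mixed-effects model of overall rate against interruptions
#'
#' Same structure as [fit_speaker_model()] but with the standardized
#' *total* per-second count as response and fixed effects
#' *interruption* (is the floor-holding turn an interruption),
#' *speaking time* and their interaction; random intercept and
#' uncorrelated slopes by turn.
#'
#' @param design Design table from [build_turn_design()].
#' @return An `entrain_lmm`; see [fit_speaker_model()].
#' @export
fit_interruption_model <- function(design) {
  if (length(unique(design$is_interruption)) < 2L)
    stop("degenerate design: no variance in the interruption predictor")
  d <- data.frame(y = zscore(design$count_total),
                  interruption = design$is_interruption,
                  stime = zscore(design$speaking_time_s),
                  turn_id = factor(design$turn_id))
  fitted <- fit_lmm(
    y ~ interruption * stime + (1 + interruption + stime || turn_id),
    d, y ~ interruption * stime + (1 | turn_id))
  new_entrain_lmm(fitted, "count_total (standardized)", d)
}

#' Marginal and conditional R-squared of a linear mixed model
#'
#' Variance decomposition in the Nakagawa–Schielzeth sense: the
#' marginal R² is the variance of the fixed-effect predictor divided by
#' the total of fixed, random and residual variance; the conditional R²
#' adds the random-effect variance to the numerator.  Random-slope
#' variance contributions are averaged over the observed covariate
#' values (Johnson's extension), computed directly from the lme4
#' variance components.
#'
#' @param model A fitted `lmerMod`/`lmerModLmerTest`, or an
#'   `entrain_lmm`.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
r2_mixed <- function(model) {
  if (inherits(model, "entrain_lmm")) model <- model$model
  stopifnot(inherits(model, "lmerMod"))
  var_f <- stats::var(as.vector(
    lme4::getME(model, "X") %*% lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  mm <- lme4::getME(model, "mmList")
  if (length(vc) != length(mm))
    stop("random-effect terms and model matrices do not align")
  var_r <- 0
  for (i in seq_along(vc)) {
    Sig <- as.matrix(vc[[i]])
    Xi <- as.matrix(mm[[i]])
    # mean_i x_i' Sigma x_i = sum(Sigma * X'X / n)
    var_r <- var_r + sum(Sig * (crossprod(Xi) / nrow(Xi)))
  }
  if (var_r < 0) stop("negative random-effect variance estimate")
  var_e <- stats::sigma(model)^2
  tot <- var_f + var_r + var_e
  c(r2_marginal = var_f / tot, r2_conditional = (var_f + var_r) / tot)
}

#' @method print entrain_lmm
#' @export
print.entrain_lmm <- function(x, digits = 3, ...) {
  cat(sprintf("Linear mixed model of %s (n = %d)\n", x$response, x$n_obs))
  co <- x$coefficients
  co$beta <- round(co$beta, digits)
  co$t_value <- round(co$t_value, 2)
  co$p_value <- signif(co$p_value, 2)
  print(co, row.names = FALSE)
  cat(sprintf("R2 marginal = %.3f, conditional = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  if (x$fallback)
    cat("note: random slopes dropped (fallback to random intercept)\n")
  if (x$singular) cat("note: boundary (singular) variance estimate\n")
  if (!x$converged) cat("warning: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.entrain_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$term)
}

#' @method summary entrain_lmm
#' @export
summary.entrain_lmm <- function(object, ...) {
  print(object)
}

#' @export
residuals.entrain_lmm <- function(object, ...) {
  stats::residuals(object$model, ...)
}
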