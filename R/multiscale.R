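#' Assemble the combined multiscale design table
#'
#' One row per bin of the whole event, with predictor blocks for each
#' timescale:
#' \describe{
#'   \item{quadratic}{standardized centred time `t_lin` and its square
#'     `t_quad`;}
#'   \item{speaker_duration}{`speak_time` (seconds into the current
#'     turn while a principal holds the floor, 0 otherwise,
#'     standardized) and the indicator `cand_a` (first principal holds
#'     the floor);}
#'   \item{interruption}{indicator `interrupt` (the floor-holding turn
#'     is an interruption);}
#'   \item{salient}{`salient`, the summed fitted composite kernel value
#'     of the supplied salient-event fits at each bin (0 outside their
#'     windows, standardized); omitted when no fits are given, e.g. in
#'     transfer mode.}
#' }
#' Pairwise products among the primary covariates (`speak_time`,
#' `interrupt`, `t_lin`, and `salient` when present) are appended as
#' interaction columns; an interaction belongs to both parents'
#' blocks for the purposes of [unique_variance()].  The response is the
#' raw `"total"` per-bin count.
#'
#' @param annotation A [debate_annotation()].
#' @param rates A [rate_series()] with a `"total"` channel.
#' @param meme_fits Named list of [fit_meme()] results; each name must
#'   match a salient-event label of the annotation, whose onset places
#'   the kernel on the event's time base.  `NULL` for no salient block.
#' @param scale_from A design previously built by this function whose
#'   standardization statistics (means/SDs) should be reused, so that
#'   coefficients fitted on one event apply meaningfully to another.
#' @return A data frame of class `multiscale_design` with attributes
#'   `blocks` (block -> columns, interactions included) and
#'   `scale_stats`.
#' @export
build_multiscale_design <- function(annotation, rates, meme_fits = NULL,
                                    scale_from = NULL) {
  stopifnot(inherits(annotation, "debate_annotation"),
            inherits(rates, "rate_series"))
  if (!"total" %in% names(rates$channels))
    stop("rates must contain a 'total' channel")
  n <- rates$n_bins
  t_s <- rates$t0_s + (seq_len(n) - 1L) * rates$bin_width_s
  fh <- floor_holder(annotation, t_s)
  cands <- candidates(annotation)
  sp <- rep(NA_character_, n)
  sp[!is.na(fh)] <- annotation$turns$speaker[fh[!is.na(fh)]]
  cand_speaking <- !is.na(sp) & sp %in% cands

  raw <- list()
  tc <- t_s - mean(t_s)
  raw$t_lin <- tc
  raw$t_quad <- tc^2
  st <- numeric(n)
  st[cand_speaking] <- t_s[cand_speaking] -
    annotation$turns$start_s[fh[cand_speaking]]
  raw$speak_time <- st
  raw$cand_a <- as.numeric(cand_speaking & sp == cands[1L])
  int_now <- numeric(n)
  int_now[!is.na(fh)] <-
    as.numeric(annotation$turns$is_interruption[fh[!is.na(fh)]])
  raw$interrupt <- int_now

  has_salient <- !is.null(meme_fits) && length(meme_fits) > 0L
  if (has_salient) {
    if (is.null(names(meme_fits)) || any(!nzchar(names(meme_fits))))
      stop("meme_fits must be a named list (names = salient-event labels)")
    sal <- numeric(n)
    for (lab in names(meme_fits)) {
      i <- match(lab, annotation$salient_events$label)
      if (is.na(i))
        stop("no salient event labelled '", lab, "' in the annotation")
      onset <- annotation$salient_events$onset_s[i]
      fit <- meme_fits[[lab]]
      stopifnot(inherits(fit, "meme_fit"))
      dt <- t_s - onset
      on <- dt >= 0 & dt < fit$window_s
      sal[on] <- sal[on] + meme_composite(dt[on], fit$params)
    }
    raw$salient <- sal
  }

  continuous <- c("t_lin", "t_quad", "speak_time",
                  if (has_salient) "salient")
  stats_in <- if (!is.null(scale_from)) attr(scale_from, "scale_stats")
  scale_stats <- list()
  cols <- raw
  for (cn in continuous) {
    if (!is.null(stats_in) && cn %in% names(stats_in)) {
      st_ <- stats_in[[cn]]
    } else {
      s <- stats::sd(raw[[cn]])
      if (!is.finite(s) || s == 0)
        stop("cannot standardize constant column '", cn, "'")
      st_ <- c(center = mean(raw[[cn]]), scale = s)
    }
    cols[[cn]] <- (raw[[cn]] - st_[["center"]]) / st_[["scale"]]
    scale_stats[[cn]] <- st_
  }

  primaries <- c("speak_time", "interrupt", "t_lin",
                 if (has_salient) "salient")
  blocks <- list(quadratic = c("t_lin", "t_quad"),
                 speaker_duration = c("speak_time", "cand_a"),
                 interruption = "interrupt")
  if (has_salient) blocks$salient <- "salient"
  block_of <- function(col) names(blocks)[vapply(blocks, function(b)
    col %in% b, logical(1L))][1L]
  pairs <- utils::combn(primaries, 2L, simplify = FALSE)
  for (pr in pairs) {
    nm <- paste(pr[1L], pr[2L], sep = "_x_")
    cols[[nm]] <- cols[[pr[1L]]] * cols[[pr[2L]]]
    for (p in pr) {
      bl <- block_of(p)
      blocks[[bl]] <- c(blocks[[bl]], nm)
    }
  }

  out <- as.data.frame(cols)
  out$count_total <- as.numeric(rates$channels$total)
  structure(out, blocks = blocks, scale_stats = scale_stats,
            class = c("multiscale_design", "data.frame"))
}

ms_r2 <- function(design, cols) {
  y <- design$count_total
  X <- cbind(`(Intercept)` = 1, as.matrix(design[cols]))
  fit <- stats::lm.fit(X, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Fit the combined multiscale regression
#'
#' OLS of the total per-bin count on every predictor of a
#' [build_multiscale_design()].  Columns made redundant by degeneracy
#' (rank deficiency) are dropped by the pivoted fit and recorded in
#' `$dropped`.  The unique variance of every block (its semi-partial
#' R-squared, obtained by entering the block last) is computed
#' alongside.
#'
#' @param design A [build_multiscale_design()] table.
#' @return An object of class `multiscale_fit`: `r2`, `coefficients`
#'   (term, estimate, t, p), `unique_r2` (named, one entry per block),
#'   `blocks`, `dropped`, `schema`, `scale_stats`, `n_obs`, and the
#'   underlying `lm` in `$model`.
#' @export
fit_multiscale <- function(design) {
  stopifnot(inherits(design, "multiscale_design"))
  preds <- setdiff(names(design), "count_total")
  fit <- stats::lm(count_total ~ ., data = as.data.frame(design))
  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped) == length(preds))
    stop("design is rank-deficient beyond repair: no usable predictor")
  sm <- stats::coef(summary(fit))
  blocks <- attr(design, "blocks")
  u <- vapply(names(blocks), function(b) unique_variance(design, b),
              numeric(1L))
  structure(list(
    r2 = summary(fit)$r.squared,
    coefficients = data.frame(term = rownames(sm),
                              estimate = sm[, "Estimate"],
                              t_value = sm[, "t value"],
                              p_value = sm[, "Pr(>|t|)"],
                              row.names = NULL),
    unique_r2 = u,
    blocks = blocks,
    dropped = dropped,
    schema = preds,
    scale_stats = attr(design, "scale_stats"),
    n_obs = nrow(design),
    model = fit), class = "multiscale_fit")
}

#' Unique variance (semi-partial R-squared) of a predictor block
#'
#' The drop in R-squared when the block — its main columns and every
#' interaction involving them — is removed from the full model,
#' equivalently the gain from entering the block last.  Nonnegative up
#' to numerical tolerance by model nesting.
#'
#' @param design A [build_multiscale_design()] table.
#' @param block Block name (`"quadratic"`, `"speaker_duration"`,
#'   `"interruption"`, `"salient"`).
#' @return The R-squared difference.
#' @export
unique_variance <- function(design, block) {
  stopifnot(inherits(design, "multiscale_design"))
  blocks <- attr(design, "blocks")
  if (!block %in% names(blocks))
    stop("unknown block: ", block, " (have: ",
         paste(names(blocks), collapse = ", "), ")")
  preds <- setdiff(names(design), "count_total")
  ms_r2(design, preds) - ms_r2(design, setdiff(preds, blocks[[block]]))
}

#' @export
predict.multiscale_fit <- function(object, design, ...) {
  if (!setequal(setdiff(names(design), "count_total"), object$schema))
    stop("design schema does not match the fitted model")
  cf <- stats::coef(object$model)
  cf[is.na(cf)] <- 0
  X <- cbind(1, as.matrix(as.data.frame(design)[object$schema]))
  as.vector(X %*% cf[c("(Intercept)", object$schema)])
}

#' Cross-event transfer prediction
#'
#' Applies the coefficients fitted on a source event to the covariates
#' of a target event and correlates predicted with observed counts.
#' The target design must be built without a salient block (salient
#' events are identified post hoc and do not generalise to a new
#' event) and with the source's standardization statistics
#' (`scale_from` in [build_multiscale_design()]).
#'
#' @param source A [fit_multiscale()] result fitted without a salient
#'   block.
#' @param target_design A [build_multiscale_design()] for the target
#'   event, same schema as the source.
#' @return Pearson correlation between predicted and observed counts.
#' @export
transfer_predict <- function(source, target_design) {
  stopifnot(inherits(source, "multiscale_fit"),
            inherits(target_design, "multiscale_design"))
  if ("salient" %in% names(source$blocks))
    stop("transfer requires a source model fitted without a salient block")
  if ("salient" %in% names(attr(target_design, "blocks")))
    stop("target design must be built without a salient block")
  pred <- predict(source, target_design)
  stats::cor(pred, target_design$count_total)
}

#' @method print multiscale_fit
#' @export
print.multiscale_fit <- function(x, ...) {
  cat(sprintf("Multiscale regression of total rate (n = %d bins)\n",
              x$n_obs))
  cat(sprintf("  R2 = %.3f\n", x$r2))
  cat("  unique variance by block:\n")
  for (b in names(x$unique_r2))
    cat(sprintf("    %-18s %.4f\n", b, x$unique_r2[[b]]))
  if (length(x$dropped))
    cat("  dropped (rank-deficient):", paste(x$dropped, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.multiscale_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}
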