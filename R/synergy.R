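# Median-effect dose-response model and Chou-Talalay combination index.
#
# The median-effect model writes the fraction of cells affected at dose D as
#   fa / fu = (D / Dm)^m,   fu = 1 - fa,
# where Dm is the dose producing a 50% effect (the IC50 under this model)
# and m the sigmoidicity of the curve.  Linearizing,
#   log10(fa/fu) = m * log10(D) - m * log10(Dm),
# so (m, Dm) are recovered by ordinary least squares on the transformed
# points.  The combination index of a drug pair at an observed combined
# effect fa is
#   CI = d1 / Dx1(fa) + d2 / Dx2(fa),
# where Dx_i(fa) = Dm_i * (fa/(1-fa))^(1/m_i) is the dose of drug i alone
# producing that effect.  CI < 1 indicates synergy, CI = 1 additivity and
# CI > 1 antagonism.

#' Convert percent-live viability to fraction affected
#'
#' Maps a treated-well percentage of live cells, relative to the vehicle
#' control, onto the fraction-affected scale used by the median-effect
#' model: `fa = 1 - pct_live_treated / pct_live_vehicle`.  Values are
#' clipped to `[eps, 1 - eps]` because the log(fa/fu) transform is
#' undefined at the boundaries; apparent stimulation (treated > vehicle)
#' clips to `eps` with a warning.
#'
#' @param pct_live_treated Percentage of live cells in the treated well.
#' @param pct_live_vehicle Percentage of live cells in the vehicle control;
#'   must be positive.
#' @param eps Clipping margin keeping `fa` strictly inside (0, 1).
#' @return Fraction affected in `[eps, 1 - eps]`; vectorized over
#'   `pct_live_treated`.
#' @examples
#' viability_to_fa(40, 80)  # 0.5
#' @export
viability_to_fa <- function(pct_live_treated, pct_live_vehicle, eps = 1e-3) {
  check_scalar(pct_live_vehicle, "pct_live_vehicle", lo = 0, strict_lo = TRUE)
  check_scalar(eps, "eps", lo = 0, hi = 0.5, strict_lo = TRUE, strict_hi = TRUE)
  if (!is.numeric(pct_live_treated) || any(!is.finite(pct_live_treated))) {
    stop_config("'pct_live_treated' must be finite numeric")
  }
  fa <- 1 - pct_live_treated / pct_live_vehicle
  if (any(fa < eps)) {
    if (any(pct_live_treated > pct_live_vehicle)) {
      warning("treated viability exceeds vehicle; fa clipped to eps ",
              "(apparent stimulation)", call. = FALSE)
    }
    fa[fa < eps] <- eps
  }
  fa[fa > 1 - eps] <- 1 - eps
  fa
}

#' Fit the median-effect model to dose-response points
#'
#' Ordinary least squares of `y = log10(fa / (1 - fa))` on `x = log10(D)`.
#' The slope is `m` and the intercept `-m * log10(Dm)`, so
#' `Dm = 10^(-intercept / m)`.  The Pearson correlation `r` of the
#' linearized points is reported with every fit, as is conventional for
#' median-effect analyses.
#'
#' @param dose Numeric vector of doses (same units throughout, e.g. uM);
#'   all positive.
#' @param fa Fraction affected at each dose, strictly inside (0, 1).
#'   Replicates may be supplied as repeated doses.
#' @param drug_id Optional drug label carried into the result.
#' @return An object of class `median_effect_fit`: a list with `drug_id`,
#'   `m`, `Dm`, `r`, `n_points`, and `non_monotone` (TRUE when the fitted
#'   slope is not positive, flagging an unusable fit).
#' @seealso [dose_for_effect()], [combination_index()]
#' @examples
#' d <- c(0.25, 0.5, 1, 2, 4)
#' fa <- (d / 1)^2 / (1 + (d / 1)^2)  # true m = 2, Dm = 1
#' fit_median_effect(d, fa)
#' @export
fit_median_effect <- function(dose, fa, drug_id = NA_character_) {
  if (length(dose) != length(fa)) {
    stop_config("'dose' and 'fa' must have equal length")
  }
  keep <- is.finite(dose) & is.finite(fa) & dose > 0 & fa > 0 & fa < 1
  dose <- dose[keep]
  fa <- fa[keep]
  if (length(unique(dose)) < 2L) {
    stop_config("fit_median_effect needs >= 2 distinct doses with fa in (0,1)")
  }
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  fit <- stats::lm.fit(cbind(1, x), y)
  m <- unname(fit$coefficients[2L])
  b <- unname(fit$coefficients[1L])
  r <- if (stats::sd(y) == 0) 1 else unname(stats::cor(x, y))
  non_monotone <- !is.finite(m) || m <= 0
  if (non_monotone) {
    warning(sprintf("median-effect slope %.3g is not positive for '%s'; ",
                    m, drug_id),
            "fit flagged as non-monotone", call. = FALSE)
  }
  structure(
    list(drug_id = drug_id, m = m, Dm = 10^(-b / m), r = r,
         n_points = length(dose), non_monotone = non_monotone),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("Median-effect fit%s: m = %.4g, Dm = %.4g, r = %.4f (n = %d)%s\n",
              if (is.na(x$drug_id)) "" else paste0(" [", x$drug_id, "]"),
              x$m, x$Dm, x$r, x$n_points,
              if (isTRUE(x$non_monotone)) " [non-monotone]" else ""))
  invisible(x)
}

#' Dose of a single agent producing a given effect
#'
#' Inverts the median-effect model:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`.  `Dx(0.5) = Dm` by definition, and
#' `Dx` is strictly increasing in `fa` for `m > 0`.
#'
#' @param fit A [fit_median_effect()] result (or a list with `m` and `Dm`).
#' @param fa Fraction affected, strictly inside (0, 1); vectorized.
#' @return Dose(s) in the units of `Dm`.
#' @export
dose_for_effect <- function(fit, fa) {
  if (!is.numeric(fa) || any(!is.finite(fa)) || any(fa <= 0) || any(fa >= 1)) {
    stop_config("'fa' must lie strictly inside (0, 1)")
  }
  if (!is.finite(fit$m) || fit$m == 0) stop_config("fit has m == 0")
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Default combination-index classification bands
#'
#' The published convention labels CI in 0.3-0.85 synergism and 0.9-1.1
#' additive, with the coarse rule CI < 1 synergy / CI > 1 antagonism.  The
#' gaps between the printed bands are filled with "slight" labels; band
#' edges are inclusive on the synergism side and configurable.
#'
#' @return A data.frame with columns `upper` (inclusive upper CI edge) and
#'   `label`, partitioning (0, Inf).
#' @export
ci_bands <- function() {
  data.frame(
    upper = c(0.85, 0.9, 1.1, 1.2, Inf),
    label = c("synergism", "slight_synergism", "additive",
              "slight_antagonism", "antagonism"),
    stringsAsFactors = FALSE
  )
}

#' Classify a combination index into a synergy band
#'
#' @param ci Positive combination index (vectorized).
#' @param bands Band table as returned by [ci_bands()]: strictly increasing
#'   inclusive upper edges ending at `Inf`, one label each.
#' @return Character vector of band labels.
#' @examples
#' classify_ci(c(0.75, 1.0, 1.5))
#' @export
classify_ci <- function(ci, bands = ci_bands()) {
  if (!is.numeric(ci) || any(!is.finite(ci)) || any(ci <= 0)) {
    stop_config("'ci' must be positive and finite")
  }
  if (!is.data.frame(bands) || !all(c("upper", "label") %in% names(bands))) {
    stop_config("'bands' must be a data.frame with columns upper, label")
  }
  if (is.unsorted(bands$upper, strictly = TRUE) ||
      !is.infinite(bands$upper[nrow(bands)])) {
    stop_config("band upper edges must be strictly increasing and end at Inf")
  }
  idx <- findInterval(ci, bands$upper, left.open = TRUE) + 1L
  bands$label[idx]
}

#' Combination index of a drug pair at an observed effect
#'
#' Computes the Chou-Talalay combination index
#' `CI = dose_a / DxA(fa) + dose_b / DxB(fa)` at a single observed
#' combination point, in non-constant-ratio mode: each dose pair is
#' evaluated independently at its own observed fraction affected.
#'
#' @param fit_a,fit_b [fit_median_effect()] results for the two agents.
#' @param dose_a,dose_b Doses of the two agents at the combination point.
#' @param fa_observed Observed fraction affected of the combination,
#'   strictly inside (0, 1).
#' @param bands Classification bands, see [classify_ci()].
#' @return A one-row data.frame (class `ci_result`) with `dose_a`,
#'   `dose_b`, `fa_observed`, `dx_a`, `dx_b`, `ci` and `label`.
#' @examples
#' fa <- function(d, m, Dm) (d / Dm)^m / (1 + (d / Dm)^m)
#' fit1 <- fit_median_effect(c(0.5, 1, 2), fa(c(0.5, 1, 2), 1, 1))
#' fit2 <- fit_median_effect(c(0.5, 1, 2), fa(c(0.5, 1, 2), 1, 2))
#' combination_index(fit1, fit2, 0.5, 0.5, 0.5)  # CI = 0.75, synergism
#' @export
combination_index <- function(fit_a, fit_b, dose_a, dose_b, fa_observed,
                              bands = ci_bands()) {
  for (f in list(fit_a, fit_b)) {
    if (!is.finite(f$m) || f$m <= 0) {
      stop_config("degenerate median-effect fit (m <= 0) for drug '%s'",
                  f$drug_id)
    }
  }
  check_scalar(dose_a, "dose_a", lo = 0, strict_lo = TRUE)
  check_scalar(dose_b, "dose_b", lo = 0, strict_lo = TRUE)
  check_scalar(fa_observed, "fa_observed", lo = 0, hi = 1,
               strict_lo = TRUE, strict_hi = TRUE)
  dx_a <- dose_for_effect(fit_a, fa_observed)
  dx_b <- dose_for_effect(fit_b, fa_observed)
  ci <- dose_a / dx_a + dose_b / dx_b
  out <- data.frame(dose_a = dose_a, dose_b = dose_b,
                    fa_observed = fa_observed, dx_a = dx_a, dx_b = dx_b,
                    ci = ci, label = classify_ci(ci, bands),
                    stringsAsFactors = FALSE)
  class(out) <- c("ci_result", class(out))
  out
}

#' Score a combination viability table against single-agent fits
#'
#' Convenience wrapper applying [combination_index()] to every dose pair of
#' a combination table.  Fraction affected is computed per replicate with
#' [viability_to_fa()], the CI is computed on the replicate-mean fa, and
#' per-replicate CIs are summarised by their standard deviation for
#' dispersion.
#'
#' @param combo Data.frame with columns `dose_a_um`, `dose_b_um`,
#'   `replicate`, `pct_live`.
#' @param fit_a,fit_b Single-agent median-effect fits.
#' @param pct_live_vehicle Vehicle-control percent live (default 100,
#'   i.e. `pct_live` is already vehicle-normalized).
#' @param bands Classification bands.
#' @param eps Clipping margin passed to [viability_to_fa()].
#' @return Data.frame with one row per dose pair: the [combination_index()]
#'   columns plus `n_replicates` and `ci_sd` (NA with a single replicate).
#' @export
score_combinations <- function(combo, fit_a, fit_b, pct_live_vehicle = 100,
                               bands = ci_bands(), eps = 1e-3) {
  need <- c("dose_a_um", "dose_b_um", "replicate", "pct_live")
  miss <- setdiff(need, names(combo))
  if (length(miss)) {
    stop_config("combination table lacks column(s): %s",
                paste(miss, collapse = ", "))
  }
  key <- interaction(combo$dose_a_um, combo$dose_b_um, drop = TRUE)
  rows <- lapply(split(combo, key), function(d) {
    fa_rep <- viability_to_fa(d$pct_live, pct_live_vehicle, eps = eps)
    res <- combination_index(fit_a, fit_b, d$dose_a_um[1L], d$dose_b_um[1L],
                             mean(fa_rep), bands = bands)
    ci_rep <- vapply(fa_rep, function(f) {
      combination_index(fit_a, fit_b, d$dose_a_um[1L], d$dose_b_um[1L], f,
                        bands = bands)$ci
    }, numeric(1))
    res$n_replicates <- length(fa_rep)
    res$ci_sd <- if (length(ci_rep) > 1L) stats::sd(ci_rep) else NA_real_
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$dose_a, out$dose_b), , drop = FALSE]
}
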