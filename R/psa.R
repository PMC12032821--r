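## Probabilistic sensitivity analysis: parameter draws from beta (rates and
## proportions), gamma (costs) and triangular (risk ratios) distributions,
## paired across scenarios by common random numbers, summarized by mean and
## interquartile range.

#' Fit a beta distribution from a point estimate and interval
#'
#' Method of moments: the beta mean equals the point estimate and the
#' standard deviation is `(high - low) / 3.92`, reading the interval as an
#' approximate 95% range. A degenerate interval (or a boundary point
#' estimate) yields a point mass.
#'
#' @param point Point estimate in \[0, 1\].
#' @param low,high Interval bounds with `low <= point <= high`.
#' @return A list `list(dist = "beta", shape1 =, shape2 =)` or
#'   `list(dist = "point", value =)`.
#' @export
fit_beta_from_range <- function(point, low, high) {
  if (!(low <= point && point <= high)) {
    stop("requires low <= point <= high", call. = FALSE)
  }
  if (point <= 0 || point >= 1 || high == low) {
    return(list(dist = "point", value = point))
  }
  s <- (high - low) / 3.92
  ## keep the variance admissible for a beta with this mean
  s <- min(s, 0.9 * sqrt(point * (1 - point)))
  nu <- point * (1 - point) / s^2 - 1
  list(dist = "beta", shape1 = point * nu, shape2 = (1 - point) * nu)
}

# one draw from a fitted spec
draw_spec <- function(spec) {
  if (spec$dist == "point") spec$value
  else stats::rbeta(1, spec$shape1, spec$shape2)
}

# beta draw around a proportion with the default +/-hw relative 95% interval
draw_prop <- function(point, hw) {
  draw_spec(fit_beta_from_range(point, max(0, point * (1 - hw)),
                                min(1, point * (1 + hw))))
}

# gamma draw with mean = point and cv = hw / 1.96
draw_cost <- function(point, hw) {
  if (point <= 0 || hw <= 0) return(point)
  cv <- hw / 1.96
  shape <- 1 / cv^2
  stats::rgamma(1, shape = shape, rate = shape / point)
}

# symmetric triangular draw around a mode; the support is shrunk symmetrically
# when `floor` binds, so the draw mean always equals the mode
draw_triangular <- function(mode, hw, floor = -Inf) {
  delta <- min(hw * abs(mode), mode - floor)
  if (delta <= 0) return(mode)
  a <- mode - delta
  b <- mode + delta
  u <- stats::runif(1)
  if (u < 0.5) a + sqrt(u * (b - a) * (mode - a))
  else b - sqrt((1 - u) * (b - a) * (b - mode))
}

derive_seed <- function(seed, draw_index) {
  ## mixed in double precision (exact below 2^53), reduced to a valid integer
  s <- ((as.double(seed) %% 2147483647) * 48271 +
          as.double(draw_index) * 9973) %% 2147483563
  as.integer(s) + 1L
}

#' Draw one perturbed parameter set
#'
#' Reproducible given `(seed, draw_index)`. PPH risks are drawn beta from
#' their printed uncertainty ranges; risk ratios triangular around the point
#' estimate (the support shrinks symmetrically where the floor of 1 binds, so
#' the mean stays at the point estimate); cost tiers gamma on their
#' nonnegative increments (monotone by construction, tier means preserved);
#' delivery-mix components, utilization shares, substandard proportions and
#' care proportions beta with the default relative half-width, with mixes
#' renormalized and substandard care proportions floored at the
#' quality-assured draw, so every draw satisfies the parameter invariants.
#'
#' @param params Base `pph_params` object.
#' @param draw_index Positive integer identifying the draw.
#' @param seed Integer random seed shared by the whole PSA.
#' @param rel_halfwidth Relative 95% half-width for inputs without printed
#'   ranges; defaults to `params$psa$default_rel_halfwidth`.
#' @return A validated `pph_params` object (uncalibrated).
#' @export
draw_params <- function(params, draw_index, seed,
                        rel_halfwidth = params$psa$default_rel_halfwidth) {
  set.seed(derive_seed(seed, draw_index))
  hw <- rel_halfwidth
  p <- params
  p$care$p_death_severe <- NULL
  p$calibration <- NULL

  p$delivery$urban_fraction <- draw_prop(p$delivery$urban_fraction, hw)
  for (r in names(p$delivery$weights)) {
    w <- unlist(p$delivery$weights[[r]])[STRATUM_KEYS]
    p$delivery$weights[[r]] <- as.list(vapply(w, draw_prop, 0, hw = hw))
  }
  p$delivery <- normalize_delivery_mix(p$delivery)

  for (block in names(p$utilization)) {
    u <- vapply(unlist(p$utilization[[block]]), draw_prop, 0, hw = hw)
    p$utilization[[block]] <- as.list(u / sum(u))
  }
  for (drug in names(p$quality)) {
    p$quality[[drug]] <- lapply(p$quality[[drug]], draw_prop, hw = hw)
  }

  p$risk_ratios$pph <- draw_triangular(p$risk_ratios$pph, hw, floor = 1)
  p$risk_ratios$severe <- draw_triangular(p$risk_ratios$severe, hw, floor = 1)

  for (reg in names(p$risks)) {
    for (mode in names(p$risks[[reg]])) {
      cell <- p$risks[[reg]][[mode]]
      p500 <- draw_spec(fit_beta_from_range(cell$p500, cell$p500_range[1],
                                            cell$p500_range[2]))
      p1000 <- draw_spec(fit_beta_from_range(cell$p1000, cell$p1000_range[1],
                                             cell$p1000_range[2]))
      p1000 <- min(p1000, p500)
      cell$p500 <- p500
      cell$p1000 <- p1000
      ## widen the stored ranges to keep the drawn values admissible
      cell$p500_range <- c(min(cell$p500_range[1], p500),
                           max(cell$p500_range[2], p500))
      cell$p1000_range <- c(min(cell$p1000_range[1], p1000),
                            max(cell$p1000_range[2], p1000))
      p$risks[[reg]][[mode]] <- cell
    }
  }

  qt <- draw_prop(p$care$additional_treatment$quality, hw)
  p$care$additional_treatment$quality <- qt
  p$care$additional_treatment$substandard <-
    max(qt, draw_prop(p$care$additional_treatment$substandard, hw))
  qb <- draw_prop(p$care$transfusion$quality, hw)
  p$care$transfusion$quality <- qb
  p$care$transfusion$substandard <-
    max(qb, draw_prop(p$care$transfusion$substandard, hw))
  p$care$surgery_severe_vaginal <- draw_prop(p$care$surgery_severe_vaginal, hw)
  p$care$referral_severe <- draw_prop(p$care$referral_severe, hw)
  p$care$diagnosed <- draw_prop(p$care$diagnosed, hw)

  for (loc in names(p$costs)) {
    for (mode in names(p$costs[[loc]])) {
      tiers <- unlist(p$costs[[loc]][[mode]])
      ## draw the nonnegative tier increments, so the drawn tiers stay
      ## monotone by construction and each tier keeps its point-estimate mean
      inc <- vapply(c(tiers[1], diff(tiers)), draw_cost, 0, hw = hw)
      p$costs[[loc]][[mode]] <- stats::setNames(as.list(cumsum(inc)),
                                                names(tiers))
    }
  }
  validate_params(p)
  p
}

PSA_OUTCOMES <- c("pph", "severe", "diagnosed_pph", "diagnosed_severe",
                  "additional_treatments", "transfusions", "deaths",
                  "total_burden", "oop_public", "oop_private",
                  "productivity_loss")

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter sets, recalibrates the death probability within
#' each draw, runs the requested scenarios on the same draw (common random
#' numbers), and summarizes each outcome and each within-draw difference from
#' baseline by mean and interquartile range.
#'
#' @param params Base `pph_params` object (the packaged Senegal set by
#'   default use [senegal_params()]).
#' @param n_draws Number of parameter draws (default from `params$psa`).
#' @param seed Integer seed controlling all draws.
#' @param scenario_ids Scenarios to evaluate; baseline (0) is always added.
#' @param rel_halfwidth See [draw_params()].
#' @param keep_draws If `TRUE`, the long draw-level table is returned too.
#' @return An object of class `pph_psa`: `summary` (per scenario x outcome:
#'   `mean`, `q25`, `q75`, `diff_mean`, `diff_q25`, `diff_q75`), `n_draws`,
#'   `seed`, and optionally `draws`.
#' @export
run_psa <- function(params, n_draws = params$psa$n_draws, seed = 1L,
                    scenario_ids = c(0L, 1L),
                    rel_halfwidth = params$psa$default_rel_halfwidth,
                    keep_draws = FALSE) {
  stopifnot(n_draws >= 2)
  ids <- sort(unique(c(0L, as.integer(scenario_ids))))
  scen <- lapply(ids, make_scenario)
  vals <- array(NA_real_,
                dim = c(n_draws, length(ids), length(PSA_OUTCOMES)),
                dimnames = list(NULL, as.character(ids), PSA_OUTCOMES))
  for (d in seq_len(n_draws)) {
    pd <- draw_params(params, d, seed, rel_halfwidth)
    pd <- calibrate(pd)
    for (j in seq_along(ids)) {
      vals[d, j, ] <- run_cohort(pd, scen[[j]])$totals[PSA_OUTCOMES]
    }
  }
  rows <- list()
  for (j in seq_along(ids)) {
    for (o in PSA_OUTCOMES) {
      v <- vals[, j, o]
      dv <- v - vals[, 1, o]
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
      dq <- stats::quantile(dv, c(0.25, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario_id = ids[j], outcome = o,
        mean = mean(v), q25 = q[1], q75 = q[2],
        diff_mean = mean(dv), diff_q25 = dq[1], diff_q75 = dq[2])
    }
  }
  out <- list(summary = do.call(rbind, rows), n_draws = n_draws, seed = seed,
              scenario_ids = ids)
  if (keep_draws) {
    long <- expand.grid(draw = seq_len(n_draws), scenario_id = ids,
                        outcome = PSA_OUTCOMES, stringsAsFactors = FALSE)
    long$value <- as.vector(vals)
    out$draws <- long
  }
  structure(out, class = "pph_psa")
}

#' @export
print.pph_psa <- function(x, ...) {
  cat("<pph_psa>", x$n_draws, "draws, seed", x$seed, "- scenarios",
      paste(x$scenario_ids, collapse = ", "), "\n")
  base <- x$summary[x$summary$scenario_id == 0 &
                      x$summary$outcome %in% c("pph", "severe", "deaths"), ]
  for (i in seq_len(nrow(base))) {
    cat(sprintf("  %s: mean %.0f (IQR %.0f-%.0f)\n", base$outcome[i],
                base$mean[i], base$q25[i], base$q75[i]))
  }
  invisible(x)
}
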