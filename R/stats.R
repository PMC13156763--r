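## Group statistics over per-step micro-parameters: per-fish quartile
## stratification, left/right asymmetry, and linear mixed-model comparison.

#' Stratify steps within each fish by a parameter's quartiles
#'
#' Within each fish, steps at or below the first quartile of `parameter` are
#' labeled `low`, at or above the third quartile `high`, the rest `mid`
#' (lowest 25 % / mid 50 % / highest 25 %). Quartiles use linear
#' interpolation between order statistics (quantile type 7) and are computed
#' independently per fish, so one fish's labels never depend on another's
#' data. A fish with fewer than 4 steps is labeled all-`mid` with a warning.
#'
#' @param table data.frame with at least `fish`, and the column named by
#'   `parameter`.
#' @param parameter Name of the stratifying column.
#' @return `table` with an added/overwritten `stratum` factor
#'   (`low`/`mid`/`high`).
#' @export
stratify_steps <- function(table, parameter = "speed_change") {
  if (!parameter %in% names(table)) stop("no column '", parameter, "'")
  stopifnot("fish" %in% names(table))
  table$stratum <- factor("mid", levels = c("low", "mid", "high"))
  for (f in unique(table$fish)) {
    sel <- table$fish == f
    x <- table[[parameter]][sel]
    if (sum(!is.na(x)) < 4) {
      warning("fish ", f, " has < 4 steps; all labeled mid")
      next
    }
    q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7)
    if (q[1] == q[2]) next                      # degenerate spread: all mid
    lab <- ifelse(x <= q[1], "low", ifelse(x >= q[2], "high", "mid"))
    table$stratum[sel] <- factor(lab, levels = levels(table$stratum))
  }
  table
}

#' Left/right asymmetry index
#'
#' `(R - L) / (R + L)` on magnitudes: +1 fully right-biased, -1 fully
#' left-biased, 0 symmetric. Undefined (NA) when both sides are zero.
#'
#' @param right_total,left_total Non-negative per-side aggregates
#'   (vectorized).
#' @return Index in `[-1, 1]`, or NA where `R + L = 0`.
#' @export
asymmetry_index <- function(right_total, left_total) {
  r <- abs(right_total)
  l <- abs(left_total)
  ifelse(r + l > 0, (r - l) / (r + l), NA_real_)
}

#' Per-fish asymmetry table from direction-labeled episodes
#'
#' For each fish and parameter, aggregates the parameter over left- and
#' right-direction episodes (as totals or per-episode means) and returns the
#' [asymmetry_index()] of the two sides.
#'
#' @param episodes data.frame with `fish`, `direction` ("left"/"right") and
#'   the parameter columns.
#' @param parameters Character vector of column names.
#' @param mode `"total"` (sum of magnitudes) or `"mean"` (mean magnitude).
#' @return data.frame: fish, parameter, right, left, asymmetry.
#' @export
asymmetry_table <- function(episodes, parameters, mode = c("total", "mean")) {
  mode <- match.arg(mode)
  agg <- if (mode == "total") function(x) sum(abs(x), na.rm = TRUE)
         else function(x) mean(abs(x), na.rm = TRUE)
  out <- list()
  for (f in unique(episodes$fish)) for (p in parameters) {
    sub <- episodes[episodes$fish == f, ]
    r <- agg(sub[[p]][sub$direction == "right"])
    l <- agg(sub[[p]][sub$direction == "left"])
    if (!is.finite(r)) r <- 0
    if (!is.finite(l)) l <- 0
    out[[length(out) + 1]] <- data.frame(
      fish = f, parameter = p, right = r, left = l,
      asymmetry = asymmetry_index(r, l))
  }
  do.call(rbind, out)
}

#' Compare one step parameter between two groups with a mixed model
#'
#' Fits `value ~ group + (1 | fish)` by REML and tests the group fixed
#' effect. With repeated steps per fish the random intercept absorbs
#' between-fish variation; the p-value uses Satterthwaite denominator
#' degrees of freedom (essential at typical cohort sizes of ~6 fish per
#' group, where an infinite-df Wald test is anticonservative; `method =
#' "wald"` gives the plain Wald z test for compatibility). If either group
#' has fewer than 2 fish, or the fit fails, the function falls back to a
#' Welch t test on fish means with a prominent warning.
#'
#' @param values Numeric response (one per step).
#' @param group Two-level factor/character (one per step).
#' @param fish Fish identifier (one per step).
#' @param method `"satterthwaite"` (default) or `"wald"`.
#' @return One-row data.frame: estimate (second group level minus first),
#'   se, p, n_steps, n_fish, method.
#' @export
mixed_model_compare <- function(values, group, fish,
                                method = c("satterthwaite", "wald")) {
  method <- match.arg(method)
  keep <- is.finite(values) & !is.na(group) & !is.na(fish)
  d <- data.frame(value = values[keep], group = factor(group[keep]),
                  fish = factor(fish[keep]))
  if (nlevels(d$group) != 2) stop("need exactly two groups")
  nfish <- tapply(d$fish, d$group, function(x) length(unique(x)))
  fallback <- function(why) {
    warning("mixed model unavailable (", why,
            "); falling back to a t test on fish means")
    fm <- aggregate(value ~ fish + group, d, mean)
    if (any(table(fm$group) < 2))
      return(data.frame(estimate = NA_real_, se = NA_real_, p = NA_real_,
                        n_steps = nrow(d),
                        n_fish = length(unique(d$fish)),
                        method = "insufficient"))
    tt <- t.test(value ~ group, fm)
    data.frame(estimate = -diff(tt$estimate)[[1]], se = tt$stderr,
               p = tt$p.value, n_steps = nrow(d),
               n_fish = length(unique(d$fish)), method = "fish_mean_t")
  }
  if (any(nfish < 2)) return(fallback("fewer than 2 fish in a group"))
  fit <- tryCatch(
    if (method == "satterthwaite")
      lmerTest::lmer(value ~ group + (1 | fish), data = d, REML = TRUE)
    else
      lme4::lmer(value ~ group + (1 | fish), data = d, REML = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback("fit error"))
  co <- if (method == "satterthwaite") {
    s <- summary(fit)$coefficients
    c(est = s[2, "Estimate"], se = s[2, "Std. Error"], p = s[2, "Pr(>|t|)"])
  } else {
    s <- summary(fit)$coefficients
    z <- s[2, "Estimate"] / s[2, "Std. Error"]
    c(est = s[2, "Estimate"], se = s[2, "Std. Error"],
      p = 2 * pnorm(-abs(z)))
  }
  data.frame(estimate = unname(co["est"]), se = unname(co["se"]),
             p = unname(co["p"]), n_steps = nrow(d),
             n_fish = length(unique(d$fish)), method = method)
}

#' Batch comparison of step parameters, unstratified and per stratum
#'
#' For each parameter, compares the two groups on all steps and within each
#' stratum of `stratifier` (low / mid / high, per-fish quartiles via
#' [stratify_steps()]). Raw per-comparison p-values are reported;
#' Benjamini-Hochberg adjusted values are appended when `adjust = TRUE`.
#'
#' @param table Step table: `fish`, `group`, parameter columns.
#' @param parameters Character vector of parameter columns to test.
#' @param stratifier Column used for stratification.
#' @param method Passed to [mixed_model_compare()].
#' @param adjust Add a BH-adjusted `p_adj` column (off by default).
#' @return data.frame with one row per parameter x {all, low, mid, high};
#'   deterministic row order.
#' @export
batch_compare <- function(table, parameters, stratifier = "speed_change",
                          method = "satterthwaite", adjust = FALSE) {
  table <- stratify_steps(table, stratifier)
  strata <- c("all", "low", "mid", "high")
  out <- list()
  for (p in parameters) for (s in strata) {
    sub <- if (s == "all") table else table[table$stratum == s, , drop = FALSE]
    sub <- sub[is.finite(sub[[p]]), , drop = FALSE]
    res <- if (nrow(sub) == 0 ||
               length(unique(sub$group)) < 2) {
      warning("empty stratum '", s, "' for ", p)
      data.frame(estimate = NA_real_, se = NA_real_, p = NA_real_,
                 n_steps = nrow(sub),
                 n_fish = length(unique(sub$fish)), method = "empty")
    } else
      suppressWarnings(
        mixed_model_compare(sub[[p]], sub$group, sub$fish, method = method))
    out[[length(out) + 1]] <- cbind(data.frame(parameter = p, stratum = s),
                                    res)
  }
  out <- do.call(rbind, out)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Simulate a two-group step table
#'
#' Step-level generative model used for calibration and power analysis of
#' [mixed_model_compare()]: each fish has a Gaussian random intercept
#' (`fish_sd`), each step adds Gaussian noise (`step_sd`), and each step
#' carries an independent log-normal `speed_change` used for stratification.
#' A group effect of `effect` (in units of the response) is added to steps
#' of the second group — to all steps, or only to steps above the fish's
#' third `speed_change` quartile when `effect_stratum = "high"`.
#'
#' @param n_fish Length-2 fish counts per group.
#' @param steps_per_fish Steps per fish.
#' @param fish_sd,step_sd Between-fish and within-fish standard deviations.
#' @param effect Group effect size (response units).
#' @param effect_stratum `"all"` or `"high"`.
#' @param seed Integer seed.
#' @return data.frame: fish, group, step, speed_change, value.
#' @export
simulate_step_table <- function(n_fish = c(6, 7), steps_per_fish = 150,
                                fish_sd = 0.3, step_sd = 1, effect = 0,
                                effect_stratum = c("all", "high"),
                                seed = 1L) {
  effect_stratum <- match.arg(effect_stratum)
  set.seed(seed)
  rows <- list()
  fid <- 0
  for (g in 1:2) for (f in seq_len(n_fish[g])) {
    fid <- fid + 1
    b <- rnorm(1, 0, fish_sd)
    sc <- exp(rnorm(steps_per_fish, log(30), 0.5))
    val <- b + rnorm(steps_per_fish, 0, step_sd)
    if (g == 2 && effect != 0) {
      if (effect_stratum == "all") val <- val + effect
      else val <- val + effect * (sc >= quantile(sc, 0.75, type = 7))
    }
    rows[[fid]] <- data.frame(
      fish = sprintf("f%02d", fid),
      group = c("vehicle", "treated")[g],
      step = seq_len(steps_per_fish),
      speed_change = sc, value = val)
  }
  do.call(rbind, rows)
}
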