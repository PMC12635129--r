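# Mixed-design (split-plot) ANOVA layer: one between-subjects factor (age
# or cluster), one within-subjects factor (the six 2-min phases), partial
# eta squared with noncentral-F confidence intervals, simple main effects
# with Bonferroni-corrected thresholds, Tukey HSD post-hocs, through-origin
# regression and the conventional 1.5x learning criterion.

#' Assemble a long-format table for the mixed ANOVA
#'
#' @param subject Subject identifiers (one between level per subject).
#' @param between Between-subjects factor (e.g. age group or cluster).
#' @param within Within-subjects factor (e.g. phase B, P1..P5).
#' @param value Response (mean displacement rate, mm/s).
#' @return A `long_table` data frame with those four columns.
#' @export
long_table <- function(subject, between, within, value) {
  out <- data.frame(subject = factor(subject), between = factor(between),
                    within = factor(within), value = value)
  tab <- table(out$subject, out$within)
  if (any(tab != 1))
    mk_error("each subject needs exactly one value per within level",
             "mobilekin_incomplete_design")
  if (any(rowSums(table(out$subject, out$between) > 0) != 1))
    mk_error("each subject must sit in exactly one between level",
             "mobilekin_incomplete_design")
  class(out) <- c("long_table", "data.frame")
  out
}

#' Mixed-design ANOVA
#'
#' Classical split-plot partitioning via `stats::aov` with an
#' `Error(subject)` stratum: the between factor is tested against the
#' between-subjects error (df = n - g), the within factor and the
#' interaction against the subject-by-within residual (df = (p-1)(n-g)).
#' No sphericity correction is applied, matching the uncorrected df
#' convention of the design. Partial \eqn{\eta^2} = SS_effect /
#' (SS_effect + SS_error) with a 95% CI from noncentral-F inversion.
#'
#' @param data A [long_table()].
#' @return A `mixed_anova` list: `table` (data frame with effect, ss, df,
#'   ms, F, p, partial_eta_sq, eta_ci_lo, eta_ci_hi), `errors` (between /
#'   within error ss, df, ms), `data`.
#' @export
mixed_anova <- function(data) {
  if (!inherits(data, "long_table"))
    data <- long_table(data$subject, data$between, data$within, data$value)
  if (nlevels(data$between) < 2)
    mk_error("need at least two between levels",
             "mobilekin_incomplete_design")
  fit <- aov(value ~ between * within + Error(subject), data = data)
  s <- summary(fit)
  b <- as.data.frame(s[["Error: subject"]][[1]])
  w <- as.data.frame(s[["Error: Within"]][[1]])
  rn <- function(df) trimws(rownames(df))
  pick <- function(df, nm) df[match(nm, rn(df)), ]
  eb <- pick(b, "Residuals"); ew <- pick(w, "Residuals")
  if (eb$`Mean Sq` <= 0 || ew$`Mean Sq` <= 0)
    mk_error("zero error variance", "mobilekin_degenerate_variance")
  rows <- list(between = list(pick(b, "between"), eb),
               within = list(pick(w, "within"), ew),
               interaction = list(pick(w, "between:within"), ew))
  tab <- do.call(rbind, lapply(names(rows), function(nm) {
    eff <- rows[[nm]][[1]]; err <- rows[[nm]][[2]]
    Fv <- eff$`Mean Sq` / err$`Mean Sq`
    p <- pf(Fv, eff$Df, err$Df, lower.tail = FALSE)
    eta <- eff$`Sum Sq` / (eff$`Sum Sq` + err$`Sum Sq`)
    ci <- partial_eta_ci(Fv, eff$Df, err$Df)
    data.frame(effect = nm, ss = eff$`Sum Sq`, df = eff$Df,
               ms = eff$`Mean Sq`, F = Fv, p = p, partial_eta_sq = eta,
               eta_ci_lo = ci[1], eta_ci_hi = ci[2])
  }))
  structure(list(table = tab,
                 errors = list(
                   between = list(ss = eb$`Sum Sq`, df = eb$Df,
                                  ms = eb$`Mean Sq`),
                   within = list(ss = ew$`Sum Sq`, df = ew$Df,
                                 ms = ew$`Mean Sq`)),
                 data = data),
            class = "mixed_anova")
}

#' 95% confidence interval for partial eta squared
#'
#' Inverts the noncentral F distribution: the interval bounds are the
#' noncentrality parameters under which the observed F sits at the 97.5th
#' and 2.5th percentiles, converted via
#' \eqn{\eta^2_p = \lambda / (\lambda + df_1 + df_2 + 1)} and truncated
#' below at zero.
#'
#' @param F Observed F statistic.
#' @param df1,df2 Numerator and denominator df.
#' @param conf Confidence level (default 0.95).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
partial_eta_ci <- function(F, df1, df2, conf = 0.95) {
  alpha <- (1 - conf) / 2
  F <- min(F, 1e6)  # the CI saturates near 1 long before this
  ncp_for <- function(target) {
    p0 <- pf(F, df1, df2, ncp = 0)
    if (is.na(p0) || p0 < target) return(0)
    hi <- max(10, 2 * F * df1)
    repeat {
      ph <- pf(F, df1, df2, ncp = hi)
      if (is.na(ph) || ph <= target || hi > 1e10) break
      hi <- hi * 2
    }
    uniroot(function(l) {
      p <- pf(F, df1, df2, ncp = l)
      if (is.na(p)) p <- 0
      p - target
    }, c(0, hi), tol = 1e-8)$root
  }
  lam <- c(ncp_for(1 - alpha), ncp_for(alpha))
  pmax(0, lam / (lam + df1 + df2 + 1))
}

#' Simple main effects after a significant interaction
#'
#' Slices the design one way and tests the other factor within each slice,
#' using the omnibus mixed-model error terms: the within factor (per
#' between level) is tested against the subject-by-within residual, the
#' between factor (per within level) against the between-subjects error.
#' The significance threshold is Bonferroni-corrected to `alpha / #slices`.
#'
#' @param fit A [mixed_anova()] result.
#' @param direction `"within-at-between"` or `"between-at-within"`.
#' @param alpha Family-wise threshold before correction (default 0.01).
#' @return Data frame with one row per slice: slice, ss, df1, df2, F, p,
#'   partial_eta_sq, threshold, significant.
#' @export
simple_main_effects <- function(fit,
                                direction = c("within-at-between",
                                              "between-at-within"),
                                alpha = 0.01) {
  direction <- match.arg(direction)
  d <- fit$data
  if (direction == "within-at-between") {
    slices <- levels(d$between); err <- fit$errors$within
    factor_of <- function(sl) d$within[d$between == sl]
    values_of <- function(sl) d$value[d$between == sl]
  } else {
    slices <- levels(d$within); err <- fit$errors$between
    factor_of <- function(sl) d$between[d$within == sl]
    values_of <- function(sl) d$value[d$within == sl]
  }
  rows <- lapply(slices, function(sl) {
    f <- droplevels(factor_of(sl)); v <- values_of(sl)
    gm <- mean(v)
    cell <- tapply(v, f, mean); ncell <- tapply(v, f, length)
    ss <- sum(ncell * (cell - gm)^2)
    df1 <- nlevels(f) - 1
    Fv <- (ss / df1) / err$ms
    p <- pf(Fv, df1, err$df, lower.tail = FALSE)
    data.frame(slice = sl, ss = ss, df1 = df1, df2 = err$df, F = Fv, p = p,
               partial_eta_sq = ss / (ss + err$ss))
  })
  out <- do.call(rbind, rows)
  out$threshold <- alpha / length(slices)
  out$significant <- out$p < out$threshold
  out
}

#' Tukey honestly-significant-difference test
#'
#' Pairwise comparisons via the studentised range: for levels i, j with
#' means \eqn{m_i, m_j},
#' \eqn{q = |m_i - m_j| / \sqrt{(MS_e/2)(1/n_i + 1/n_j)}} (Tukey-Kramer for
#' unequal n), with family-wise p from `ptukey`. By default the error term
#' is the one-way residual mean square; pass the omnibus within-subject
#' error to compare repeated-measures levels.
#'
#' @param value Numeric response.
#' @param level Factor of group labels.
#' @param error_ms,error_df Error mean square and df; defaults to the
#'   one-way residual.
#' @param alpha Rejection threshold (default 0.01).
#' @return A `posthoc_table` data frame: level_a, level_b, mean_diff, se,
#'   q, p_adj, reject.
#' @export
tukey_hsd <- function(value, level, error_ms = NULL, error_df = NULL,
                      alpha = 0.01) {
  level <- droplevels(factor(level))
  k <- nlevels(level)
  if (k < 2) mk_error("need at least 2 levels", "mobilekin_invalid_spec")
  ns <- tapply(value, level, length)
  if (any(ns < 2))
    mk_error("every level needs at least 2 observations",
             "mobilekin_insufficient_data")
  means <- tapply(value, level, mean)
  if (is.null(error_ms)) {
    error_df <- length(value) - k
    error_ms <- sum((value - means[level])^2) / error_df
  }
  pairs <- utils::combn(levels(level), 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(error_ms / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    diff <- means[[j]] - means[[i]]
    q <- abs(diff) / se
    data.frame(level_a = i, level_b = j, mean_diff = diff, se = se, q = q,
               p_adj = ptukey(q, k, error_df, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out$reject <- out$p_adj < alpha
  class(out) <- c("posthoc_table", "data.frame")
  out
}

#' Least-squares regression through the origin
#'
#' Fits \eqn{y = \beta x} with no intercept: \eqn{\hat\beta = \sum x y /
#' \sum x^2}, optionally per group (as when one line is fitted per age
#' group in baseline-vs-play scatter plots).
#'
#' @param x,y Numeric vectors (e.g. baseline and play block means).
#' @param group Optional grouping factor; one coefficient per group.
#' @return Named numeric coefficient(s).
#' @export
origin_regression <- function(x, y, group = NULL) {
  one <- function(x, y) {
    sxx <- sum(x^2)
    if (sxx == 0)
      mk_error("all x are zero", "mobilekin_degenerate_baseline")
    sum(x * y) / sxx
  }
  if (is.null(group)) return(c(coef = one(x, y)))
  vapply(split(seq_along(x), group),
         function(i) one(x[i], y[i]), numeric(1))
}

#' Conventional learning criterion
#'
#' An infant counts as a learner when any play-block mean of the
#' connected-arm baseline ratio reaches `threshold` (>= convention at the
#' boundary). The customary threshold is an increase to 1.5 times the
#' baseline level.
#'
#' @param blocks Data frame with columns `block` and `mean` (connected-arm
#'   ratio block means, e.g. from [block_means()]).
#' @param threshold Learning threshold (default 1.5).
#' @param play_blocks Which blocks count (default P1..P5).
#' @return Logical scalar.
#' @export
learner_flag <- function(blocks, threshold = 1.5,
                         play_blocks = c("P1", "P2", "P3", "P4", "P5")) {
  any(blocks$mean[blocks$block %in% play_blocks] >= threshold)
}
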