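# Nitrogen-efficiency statistics and treatment-table inference:
# NUE/NAE/NPE, percent-change reporting, one-way ANOVA with Duncan's
# multiple-range letter display.

#' Nitrogen use efficiency (NUE, %)
#'
#' NUE = (AN - AN0) / SN x 100, where AN is accumulated plant N uptake
#' under the fertilised treatment, AN0 the uptake of the zero-N control
#' and SN the fertiliser N dose (all in the same mass units, e.g.
#' g pot^-1).
#'
#' @param an,an0,sn numeric (recycled); `sn` must be positive.
#' @return NUE in percent.
#' @export
nue <- function(an, an0, sn) {
  if (any(sn <= 0)) stop("`sn` (fertiliser N dose) must be positive")
  (an - an0) / sn * 100
}

#' Nitrogen agronomic efficiency (NAE, kg grain per kg N)
#'
#' NAE = (GN - GN0) / SN: extra grain dry weight per unit fertiliser N.
#'
#' @param gn,gn0,sn numeric (recycled); `sn` must be positive.
#' @return NAE in kg kg^-1 of N.
#' @export
nae <- function(gn, gn0, sn) {
  if (any(sn <= 0)) stop("`sn` (fertiliser N dose) must be positive")
  (gn - gn0) / sn
}

#' Nitrogen physiological efficiency (NPE, kg yield per kg N uptake)
#'
#' NPE = (YN - YN0) / (AN - AN0): extra yield per unit extra plant N.
#' Undefined (returned as `NA` with a warning) when the uptake difference
#' is zero.
#'
#' @param yn,yn0,an,an0 numeric (recycled).
#' @return NPE in kg kg^-1 of N, `NA` where AN = AN0.
#' @export
npe <- function(yn, yn0, an, an0) {
  den <- an - an0
  out <- ifelse(den == 0, NA_real_, (yn - yn0) / den)
  if (any(den == 0))
    warning("NPE undefined where plant N uptake equals the control uptake")
  out
}

#' Percent change against a reference, reported to one decimal
#'
#' (value - reference) / reference x 100, rounded half away from zero to
#' `digits` decimals — the convention of printed agronomic tables. Set
#' `raw = TRUE` for the unrounded value.
#'
#' @param value,reference numeric (recycled); `reference` must be
#'   nonzero.
#' @param digits decimals for reporting (default 1).
#' @param raw return the unrounded percentage.
#' @return percent change.
#' @export
percent_change <- function(value, reference, digits = 1, raw = FALSE) {
  if (any(reference == 0)) stop("`reference` must be nonzero")
  pc <- (value - reference) / reference * 100
  if (raw) pc else round_half_up(pc, digits)
}

#' One-way ANOVA with Duncan's multiple-range letter display
#'
#' Fits a one-way ANOVA and separates treatment means with Duncan's
#' multiple range test: groups are ordered by mean; the critical range
#' for a span of p means is q(alpha_p, p, df_error) * sqrt(MSE / n_h)
#' with protection level alpha_p = 1 - (1 - alpha)^(p - 1) and n_h the
#' harmonic mean group size; studentized-range quantiles come from
#' [stats::qtukey()], not printed tables. Two groups share a letter
#' exactly when their range (and every enclosing range) fails to exceed
#' its critical range.
#'
#' @param values numeric replicate measurements.
#' @param groups treatment label per value (>= 2 groups, each with >= 2
#'   replicates).
#' @param alpha significance level (default 0.05).
#' @return object of class `duncan_test`: list with `anova` (F, df, p),
#'   `groups` (data frame sorted by decreasing mean: group, n, mean,
#'   letters), `critical_ranges` (per span), `mse`, `df_error`, `alpha`.
#' @export
anova_duncan <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  tab <- table(g)
  if (any(tab < 2)) stop("every group needs at least 2 replicates")
  fit <- aov(values ~ g)
  an <- anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  means <- sort(tapply(values, g, mean), decreasing = TRUE)
  k <- length(means)
  n_h <- k / sum(1 / tab)
  se <- sqrt(mse / n_h)
  ranges <- c(NA_real_, vapply(2:k, function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    qtukey(1 - alpha_p, p, dfe) * se
  }, numeric(1)))
  # Duncan protection: scan spans widest-first; a non-significant span
  # declares every enclosed pair homogeneous
  hom <- diag(TRUE, k)
  if (k >= 2) for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (hom[i, j]) next
      if (means[i] - means[j] <= ranges[span]) {
        for (a in i:(j - 1)) for (b in (a + 1):j) hom[a, b] <- hom[b, a] <- TRUE
      }
    }
  }
  # letters from maximal homogeneous intervals in mean order
  int_end <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && hom[i, j + 1]) j <- j + 1
    as.integer(j)
  }, integer(1))
  lett <- rep("", k)
  max_end <- 0L
  cur <- 0L
  for (i in seq_len(k)) {
    if (int_end[i] > max_end || i > max_end) {
      cur <- cur + 1L
      idx <- i:int_end[i]
      lett[idx] <- paste0(lett[idx], letters[cur])
      max_end <- int_end[i]
    }
  }
  structure(list(
    anova = data.frame(F = an[1, "F value"], df1 = an[1, "Df"],
                       df2 = dfe, p = an[1, "Pr(>F)"]),
    groups = data.frame(group = names(means), n = as.integer(tab[names(means)]),
                        mean = as.numeric(means), letters = lett,
                        stringsAsFactors = FALSE, row.names = NULL),
    critical_ranges = ranges,
    mse = mse, df_error = dfe, alpha = alpha
  ), class = "duncan_test")
}

#' @export
print.duncan_test <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  cat(sprintf("Duncan's multiple range test (alpha = %g):\n", x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Nitrogen-efficiency summary of an agronomic table
#'
#' Computes replicate-level NUE, NAE and NPE for every fertilised
#' treatment against the zero-N control means, separates treatments with
#' [anova_duncan()], and reports treatment means plus the percent change
#' against `reference` (rounded half-up to one decimal; raw values are
#' kept alongside).
#'
#' @param agronomy data frame with columns `treatment`, `grain_yield`,
#'   `biomass`, `n_uptake`, `n_dose` (one row per replicate), as produced
#'   by [simulate_agronomy()] or [read_table_tsv()].
#' @param control label of the zero-N control treatment.
#' @param reference treatment against which percent changes are reported.
#' @param alpha significance level for the letter displays.
#' @return list of class `efficiency_result`: `replicates` (per-replicate
#'   efficiencies), `summary` (treatment x statistic means with percent
#'   changes), `duncan` (letter displays per efficiency statistic).
#' @export
nitrogen_efficiency <- function(agronomy, control = "control",
                                reference = "CRU", alpha = 0.05) {
  need <- c("treatment", "grain_yield", "biomass", "n_uptake", "n_dose")
  if (!all(need %in% colnames(agronomy)))
    stop("`agronomy` needs columns: ", paste(need, collapse = ", "))
  if (!control %in% agronomy$treatment)
    stop("control treatment `", control, "` absent")
  ctl <- agronomy[agronomy$treatment == control, ]
  if (any(ctl$n_dose != 0)) stop("the control must have zero N dose")
  an0 <- mean(ctl$n_uptake)
  gn0 <- mean(ctl$grain_yield)
  fert <- agronomy[agronomy$treatment != control, , drop = FALSE]
  if (any(fert$n_dose <= 0)) stop("fertilised treatments need a positive N dose")
  reps <- data.frame(
    treatment = fert$treatment,
    NUE = nue(fert$n_uptake, an0, fert$n_dose),
    NAE = nae(fert$grain_yield, gn0, fert$n_dose),
    NPE = suppressWarnings(npe(fert$grain_yield, gn0, fert$n_uptake, an0)),
    stringsAsFactors = FALSE
  )
  stats_ <- c("NUE", "NAE", "NPE")
  means <- do.call(rbind, lapply(split(reps[stats_], reps$treatment), colMeans))
  duncan <- NULL
  if (length(unique(reps$treatment)) >= 2)
    duncan <- lapply(setNames(stats_, stats_), function(s)
      anova_duncan(reps[[s]], reps$treatment, alpha = alpha))
  summary <- data.frame(treatment = rownames(means), means,
                        row.names = NULL, stringsAsFactors = FALSE)
  if (reference %in% summary$treatment) {
    ref <- summary[summary$treatment == reference, stats_]
    for (s in stats_) {
      summary[[paste0(s, "_change_raw")]] <-
        percent_change(summary[[s]], ref[[s]], raw = TRUE)
      summary[[paste0(s, "_change")]] <-
        percent_change(summary[[s]], ref[[s]])
    }
  }
  structure(list(replicates = reps, summary = summary, duncan = duncan,
                 control_means = c(AN0 = an0, GN0 = gn0),
                 reference = reference),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat("Nitrogen-efficiency summary (percent change vs ", x$reference, "):\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
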