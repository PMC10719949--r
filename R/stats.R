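#' Paired two-tailed t-test on matched electrode densities
#'
#' Standard paired t statistic for stroke vs mirrored-contralateral electrode
#' densities. When every pairwise difference is exactly zero the statistic is
#' reported as t = 0, p = 1; a nonzero constant difference has no valid t
#' statistic and raises an error.
#'
#' @param strokeVals,contraVals equal-length numeric vectors (length >= 2),
#'   paired by electrode.
#' @return list with \code{t}, \code{p} (two-tailed), \code{df}.
#' @export
pairedTTest <- function(strokeVals, contraVals) {
  if (length(strokeVals) != length(contraVals))
    stop("paired t-test needs equal-length samples")
  if (length(strokeVals) < 2) stop("paired t-test needs at least 2 pairs")
  d <- strokeVals - contraVals
  if (all(d == 0))
    return(list(t = 0, p = 1, df = length(d) - 1L))
  if (stats::sd(d) == 0)
    stop("pairwise differences have zero variance; t statistic undefined")
  ht <- stats::t.test(strokeVals, contraVals, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' One-way ANOVA across medication groups
#'
#' Classic equal-variance one-way ANOVA of densities across groups. When the
#' within-group variance is zero in every group the F statistic is undefined
#' and the result is flagged degenerate (F = NaN) rather than reported as a
#' silent number.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return list with \code{F}, \code{p}, \code{degenerate}.
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2) stop("one-way ANOVA needs at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  vals <- unlist(groups)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (within == 0) {
    warning("zero within-group variance; ANOVA F undefined (degenerate)")
    return(list(F = NaN, p = NaN, degenerate = TRUE))
  }
  ht <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
  list(F = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Effect-size class of a Cohen's d value
#'
#' Thresholds 0.20 / 0.50 / 0.80 on |d| read as small / medium / large;
#' below 0.20 the effect is reported negligible.
#'
#' @param d Cohen's d.
#' @return one of \code{"negligible"}, \code{"small"}, \code{"medium"},
#'   \code{"large"}.
#' @export
classifyEffectSize <- function(d) {
  a <- abs(d)
  if (!is.finite(a)) return(NA_character_)
  if (a >= 0.80) "large" else if (a >= 0.50) "medium"
  else if (a >= 0.20) "small" else "negligible"
}

#' Linear mixed-effects model of density on electrode class
#'
#' Fits, by maximum likelihood, density ~ electrode class (0 = contralateral,
#' 1 = stroke) with random intercept, electrode slope and medication-group
#' terms by patient, delegating the fit to \pkg{lme4} (p-value for the fixed
#' electrode effect via the Satterthwaite approximation of \pkg{lmerTest}).
#' When the full random structure is singular or fails to converge the model
#' falls back, with a warning, to a random intercept + electrode slope and
#' finally to an intercept-only random structure.
#'
#' R-squared is the squared correlation between fitted and observed
#' densities (an overall-model convention). Cohen's d standardizes the fixed
#' electrode effect by the square root of the summed random-effect variances
#' plus the residual variance (\code{standardizer = "total"}) or by the
#' residual standard deviation alone (\code{standardizer = "residual"}).
#'
#' @param table long-format data.frame with columns \code{patient},
#'   \code{medication_group}, \code{electrode_class} (0/1 or a factor with
#'   levels contralateral/stroke), \code{density}.
#' @param standardizer denominator of Cohen's d, \code{"total"} or
#'   \code{"residual"}.
#' @return list with \code{estimate} (fixed electrode effect), \code{p},
#'   \code{r2}, \code{d}, \code{magnitude} (effect-size class),
#'   \code{formula} (the random structure actually used) and
#'   \code{singular}.
#' @export
fitMixedModel <- function(table, standardizer = c("total", "residual")) {
  standardizer <- match.arg(standardizer)
  stopifnot(all(c("patient", "medication_group", "electrode_class",
                  "density") %in% names(table)))
  if (length(unique(table$patient)) < 2)
    stop("mixed model needs at least 2 patients")
  tab <- table
  tab$electrode_class <- if (is.numeric(tab$electrode_class))
    tab$electrode_class else as.numeric(factor(tab$electrode_class)) - 1
  tab$patient <- factor(tab$patient)
  tab$medication_group <- factor(tab$medication_group)

  forms <- c(
    "density ~ electrode_class + (1 + electrode_class + medication_group | patient)",
    "density ~ electrode_class + (1 + electrode_class | patient)",
    "density ~ electrode_class + (1 | patient)")
  if (nlevels(tab$medication_group) < 2) forms <- forms[-1]
  fit <- NULL; used <- NA_character_; singular <- FALSE
  for (f in forms) {
    m <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(stats::as.formula(f), data = tab, REML = FALSE))),
      error = function(e) NULL)
    if (is.null(m)) next
    if (lme4::isSingular(m, tol = 1e-4) && f != forms[length(forms)]) {
      singular <- TRUE
      next
    }
    fit <- m; used <- f
    break
  }
  if (is.null(fit)) stop("mixed model could not be fitted")
  if (singular)
    warning("full random structure singular; fell back to: ", used)

  co <- stats::coef(summary(fit))
  est <- co["electrode_class", "Estimate"]
  p <- co["electrode_class", "Pr(>|t|)"]
  r2 <- stats::cor(stats::fitted(fit), tab$density)^2
  vc <- lme4::VarCorr(fit)
  ranVar <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  resVar <- attr(vc, "sc")^2
  denom <- if (standardizer == "total") sqrt(ranVar + resVar) else sqrt(resVar)
  d <- est / denom
  list(estimate = est, p = p, r2 = r2, d = d,
       magnitude = classifyEffectSize(d), formula = used,
       singular = singular)
}
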