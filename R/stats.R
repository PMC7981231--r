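#' Fit the nested two-level treatment model
#'
#' REML linear mixed-effects model in cell-means form: one fixed
#' coefficient per treatment level (no global intercept, so estimates are
#' directly the treatment means), random intercepts for site and for plot
#' within site, independent residuals. Degrees of freedom and p-values
#' for the fixed effects use the Satterthwaite method; this convention is
#' fixed for reproducibility.
#'
#' @param obs data.frame with columns `site`, `plot`, `treatment` and the
#'   response (default column `y`).
#' @param response name of the response column.
#' @param covariate optional name of a continuous covariate column to
#'   include as a fixed effect alongside the treatment means.
#' @param ddf denominator-degrees-of-freedom method for the treatment
#'   F-test and the Tukey contrasts: `"kenward-roger"` (default; the
#'   small-sample adjustment matters because the plot-level variance is
#'   estimated from few plots) or `"satterthwaite"`.
#' @return A `treatment_fit`: list with `model` (the lmerModLmerTest
#'   object), `fixed` (term, estimate, se, df, p), `varcomp` (grp,
#'   sd, variance), `response`, `data`.
#' @export
fit_treatment_model <- function(obs, response = "y", covariate = NULL,
                                ddf = c("kenward-roger", "satterthwaite")) {
  ddf <- match.arg(ddf)
  need <- c("site", "plot", "treatment", response, covariate)
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("obs lacks columns: ", paste(miss, collapse = ", "))
  obs <- obs[stats::complete.cases(obs[, need]), , drop = FALSE]
  obs$treatment <- factor(obs$treatment)
  obs$site <- factor(obs$site)
  obs$plot <- factor(paste(obs$site, obs$plot, sep = ":"))
  if (!is.null(covariate) && stats::var(obs[[covariate]]) == 0)
    stop("covariate '", covariate, "' is constant")
  one_level <- nlevels(obs$treatment) < 2L
  rhs <- paste(c(if (one_level) "1" else c("0", "treatment"), covariate,
                 "(1 | site)", "(1 | plot)"), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  if (ddf == "kenward-roger" &&
      !requireNamespace("pbkrtest", quietly = TRUE)) {
    ddf <- "satterthwaite"                # graceful fallback
  }
  fit <- withCallingHandlers(
    lmerTest::lmer(fml, data = obs, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = FALSE)),
    message = function(m) invokeRestart("muffleMessage"))
  sm <- summary(fit)$coefficients     # Satterthwaite df via lmerTest
  fixed <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      p = sm[, "Pr(>|t|)"], row.names = NULL)
  fixed$term <- sub("^treatment", "", fixed$term)
  if (one_level)
    fixed$term[fixed$term == "(Intercept)"] <- levels(obs$treatment)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- data.frame(grp = sub("^plot$", "plot:site", vc$grp),
                        variance = vc$vcov, sd = vc$sdcor)
  structure(list(model = fit, fixed = fixed, varcomp = varcomp,
                 response = response, covariate = covariate, ddf = ddf,
                 data = obs),
            class = "treatment_fit")
}

#' @export
print.treatment_fit <- function(x, ...) {
  cat("nested two-level mixed model (REML), response:", x$response, "\n")
  print(x$fixed, digits = 4)
  cat("variance components:\n")
  print(x$varcomp, digits = 4)
  invisible(x)
}

#' ANOVA for the treatment factor of a fitted nested model
#'
#' Joint F-test that all treatment cell means are equal, conditional on
#' the random site / plot-within-site structure. Denominator df follow
#' the fit's `ddf` convention (Kenward-Roger by default).
#'
#' @param fit a [fit_treatment_model()] result.
#' @return data.frame: term, F, df1, df2, p.
#' @export
treatment_anova <- function(fit) {
  tl <- levels(fit$data$treatment)
  if (length(tl) < 2L) stop("single-treatment data: no contrast to test")
  if (fit$ddf == "kenward-roger") {
    rhs0 <- paste(c("1", fit$covariate, "(1 | site)", "(1 | plot)"),
                  collapse = " + ")
    fml0 <- stats::as.formula(paste(fit$response, "~", rhs0))
    fit0 <- withCallingHandlers(
      lmerTest::lmer(fml0, data = fit$data, REML = TRUE,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore",
                       calc.derivs = FALSE)),
      message = function(m) invokeRestart("muffleMessage"))
    kr <- pbkrtest::KRmodcomp(fit$model, fit0)$stats
    return(data.frame(term = "treatment", F = kr$Fstat, df1 = kr$ndf,
                      df2 = kr$ddf, p = kr$p.value))
  }
  fe <- lme4::fixef(fit$model)
  k <- length(tl)
  L <- matrix(0, k - 1L, length(fe),
              dimnames = list(NULL, names(fe)))
  for (m in 2:k) {
    L[m - 1L, paste0("treatment", tl[1L])] <- -1
    L[m - 1L, paste0("treatment", tl[m])] <- 1
  }
  ct <- lmerTest::contest(fit$model, L, joint = TRUE)
  data.frame(term = "treatment", F = ct$`F value`, df1 = ct$NumDF,
             df2 = ct$DenDF, p = ct$`Pr(>F)`)
}

#' Tukey honest-significance contrasts between treatments
#'
#' All pairwise treatment differences on the mixed-model estimated
#' marginal means with family-wise (Tukey) adjusted p-values.
#'
#' @param fit a [fit_treatment_model()] result.
#' @return data.frame: contrast, estimate, se, df, t, p_adj.
#' @export
tukey_contrasts <- function(fit) {
  if (nlevels(fit$data$treatment) < 2L)
    stop("at least two treatment levels required")
  emm <- emmeans::emmeans(fit$model, "treatment", lmer.df = fit$ddf)
  pr <- summary(emmeans::contrast(emm, method = "pairwise"),
                adjust = "tukey")
  data.frame(contrast = as.character(pr$contrast), estimate = pr$estimate,
             se = pr$SE, df = pr$df, t = pr$t.ratio, p_adj = pr$p.value)
}

#' Attribute-on-box-dimension nested model
#'
#' The drivers-of-complexity analysis: a stem/crown/growth attribute as
#' response, the continuous box dimension (or any covariate) plus the
#' treatment cell means as fixed effects, with the same nested random
#' structure. The output schema (term, estimate, SE, p) is one row per
#' fixed effect.
#'
#' @param obs per-tree table with site, plot, treatment, the attribute
#'   and the covariate columns.
#' @param attribute response column name.
#' @param covariate covariate column name (default `"box_dimension"`).
#' @return A `treatment_fit` whose `fixed` table carries an `attribute`
#'   column.
#' @export
attribute_model <- function(obs, attribute, covariate = "box_dimension") {
  fit <- fit_treatment_model(obs, response = attribute, covariate = covariate)
  fit$fixed <- cbind(attribute = attribute, fit$fixed)
  fit
}

#' Pearson correlations with box dimension, per treatment
#'
#' Pearson's r between a focal variable (default box dimension) and each
#' attribute, computed separately within every treatment, with two-sided
#' p-values; `sig` marks p < .001 and `strong` flags |r| > 0.50.
#'
#' @param trees per-tree table with a `treatment` column.
#' @param attributes attribute column names to correlate.
#' @param with focal column (default `"box_dimension"`).
#' @return data.frame: attribute, treatment, n, r, p, sig, strong.
#' @export
correlations_by_treatment <- function(trees, attributes,
                                      with = "box_dimension") {
  stopifnot(with %in% names(trees))
  res <- list()
  for (tr in unique(trees$treatment)) {
    sub <- trees[trees$treatment == tr, , drop = FALSE]
    for (a in attributes) {
      ok <- stats::complete.cases(sub[[a]], sub[[with]])
      n <- sum(ok)
      if (n < 3L || stats::var(sub[[a]][ok]) == 0 ||
          stats::var(sub[[with]][ok]) == 0) {
        res[[length(res) + 1L]] <- data.frame(
          attribute = a, treatment = tr, n = n, r = NA_real_, p = NA_real_,
          sig = NA, strong = NA)
        next
      }
      ct <- stats::cor.test(sub[[a]][ok], sub[[with]][ok])
      res[[length(res) + 1L]] <- data.frame(
        attribute = a, treatment = tr, n = n, r = unname(ct$estimate),
        p = ct$p.value, sig = ct$p.value < 0.001,
        strong = abs(ct$estimate) > 0.50)
    }
  }
  do.call(rbind, res)
}

#' Impute tally-tree heights with a per-plot Naslund curve
#'
#' Fits the monotone DBH-height allometry `h = 1.3 + d^2 / (a + b d)^2`
#' to the sample trees of each plot (least squares on the linearizing
#' transform `d / sqrt(h - 1.3) = a + b d`) and predicts heights for the
#' tally trees. Plots with fewer than 3 sample trees fall back to a
#' pooled fit across plots, with a warning.
#'
#' @param sample_trees data.frame: plot, dbh_cm, height_m (> 1.3 m).
#' @param tally_trees data.frame: plot, dbh_cm.
#' @return `tally_trees` with a `height_m` column added.
#' @export
estimate_tally_heights <- function(sample_trees, tally_trees) {
  stopifnot(all(c("plot", "dbh_cm", "height_m") %in% names(sample_trees)),
            all(c("plot", "dbh_cm") %in% names(tally_trees)))
  if (any(sample_trees$height_m <= 1.3))
    stop("sample-tree heights must exceed breast height (1.3 m)")
  naslund_fit <- function(d, h) {
    yt <- d / sqrt(h - 1.3)
    stats::coef(stats::lm(yt ~ d))
  }
  naslund_pred <- function(cf, d) 1.3 + d^2 / (cf[1] + cf[2] * d)^2
  pooled <- naslund_fit(sample_trees$dbh_cm, sample_trees$height_m)
  out <- numeric(nrow(tally_trees))
  for (pl in unique(tally_trees$plot)) {
    s <- sample_trees[sample_trees$plot == pl, ]
    idx <- tally_trees$plot == pl
    if (nrow(s) < 3L) {
      warning("plot ", pl, " has fewer than 3 sample trees; using pooled fit")
      cf <- pooled
    } else {
      cf <- naslund_fit(s$dbh_cm, s$height_m)
    }
    out[idx] <- naslund_pred(cf, tally_trees$dbh_cm[idx])
  }
  tally_trees$height_m <- out
  tally_trees
}
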