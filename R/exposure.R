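#' Standardize serum resistin
#'
#' Resistin concentrations are normalized by a logarithm transformation
#' and divided by the sample SD of the logged values, so effects are
#' expressed per SD of log-resistin. Following the study convention the
#' logged values are not centered by default (centering changes
#' percent-of-reference-mean summaries but leaves hazard ratios
#' untouched).
#'
#' @param values resistin concentrations (ng/ml), all positive.
#' @param center logical; subtract the mean of the logged values before
#'   scaling (default `FALSE`).
#' @return Numeric vector with attribute `sd` (the SD of log values
#'   used) and, when centering, attribute `center`.
#' @examples
#' z <- standardize_resistin(exp(1:3))
#' sd(z)          # exactly 1
#' attr(z, "sd")  # SD of the logged values
#' @export
standardize_resistin <- function(values, center = FALSE) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad) > 0)
    stop("resistin values must be positive; offending rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  lv <- log(values)
  s <- stats::sd(lv, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("log-resistin SD is zero or undefined")
  out <- if (center) (lv - mean(lv, na.rm = TRUE)) / s else lv / s
  attr(out, "sd") <- s
  if (center) attr(out, "center") <- mean(lv, na.rm = TRUE)
  out
}

# assemble the analysis data.frame used by exposure and survival fits
.analysis_frame <- function(table, response, grs = NULL,
                            coding = NULL, covariates = character(0),
                            cohort_term = TRUE) {
  df <- data.frame(.y = response)
  for (cv in covariates) {
    if (!cv %in% names(table)) stop("missing covariate column: ", cv)
    x <- table[[cv]]
    if (is.character(x)) x <- factor(x)
    df[[cv]] <- x
  }
  if (cohort_term && length(unique(table$cohort)) > 1)
    df$cohort <- factor(table$cohort)
  if (!is.null(grs)) {
    if (identical(coding, "categorical")) df$grs <- grs$category
    else df$grs <- grs$score
  }
  df
}

#' Fit the exposure-stage linear model
#'
#' Ordinary least squares of standardized log-resistin on the genotype
#' risk score — dummy-coded categories with score 0 as reference
#' (`coding = "categorical"`) or the integer allele count
#' (`coding = "continuous"`) — plus optional covariates and, when more
#' than one cohort is present, fixed cohort indicators. Numeric
#' covariates and binary indicators are centered internally so the
#' intercept estimates the adjusted mean outcome of the reference group.
#'
#' The overall score p-value is a joint F-test of all category dummies
#' for the categorical coding and the slope t-test for the continuous
#' coding. AIC is the Gaussian `2k - 2 logL` with the residual variance
#' counted in `k`.
#'
#' @param table cohort data.frame.
#' @param grs a [build_grs()] profile on the same rows.
#' @param coding `"categorical"` or `"continuous"`.
#' @param covariates character vector of adjustment columns.
#' @param response standardized exposure vector; defaults to
#'   `standardize_resistin(table$resistin)`.
#' @return Object of class `exposure_fit`: coefficients, covariance,
#'   residual SD, AIC, `n`, coding, `overall_p`, and the underlying
#'   `lm` fit.
#' @export
fit_exposure_model <- function(table, grs,
                               coding = c("categorical", "continuous"),
                               covariates = character(0),
                               response = standardize_resistin(table$resistin)) {
  coding <- match.arg(coding)
  df <- .analysis_frame(table, as.numeric(response), grs, coding, covariates)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (coding == "categorical") df$grs <- droplevels(df$grs)
  ng <- length(unique(df$grs))
  if (ng < 2) stop("fewer than 2 distinct risk-score values in the data")

  # center adjustment terms so the intercept is the adjusted reference mean
  for (cv in c(covariates, if ("cohort" %in% names(df)) "cohort")) {
    x <- df[[cv]]
    if (is.factor(x)) {
      mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
      mm <- scale(mm, center = TRUE, scale = FALSE)
      colnames(mm) <- paste0(cv, "_", levels(x)[-1])
      df[[cv]] <- NULL
      df <- cbind(df, mm)
    } else {
      df[[cv]] <- as.numeric(x) - mean(as.numeric(x))
    }
  }

  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (coding == "categorical") {
    fit0 <- stats::update(fit, . ~ . - grs)
    overall_p <- stats::anova(fit0, fit)[2, "Pr(>F)"]
  } else {
    overall_p <- summary(fit)$coefficients["grs", "Pr(>|t|)"]
  }
  structure(list(
    coding = coding,
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    sigma = summary(fit)$sigma,
    aic = stats::AIC(fit),
    n = nrow(df),
    overall_p = overall_p,
    lm_fit = fit
  ), class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  cat(sprintf("Exposure model (%s coding): n = %d, AIC = %.1f, overall p = %.3g\n",
              x$coding, x$n, x$aic, x$overall_p))
  invisible(x)
}

#' Choose between categorical and continuous score coding by AIC
#'
#' Returns the fit with the smaller AIC; exact ties go to the continuous
#' coding (fewer parameters).
#'
#' @param fit_cat,fit_cont [fit_exposure_model()] objects fitted on the
#'   same rows with categorical and continuous coding.
#' @return The chosen `exposure_fit`, with attribute `chosen` set to its
#'   coding.
#' @export
compare_codings <- function(fit_cat, fit_cont) {
  if (fit_cat$coding != "categorical" || fit_cont$coding != "continuous")
    stop("arguments must be a categorical and a continuous fit, in order")
  if (fit_cat$n != fit_cont$n)
    stop("fits use different numbers of rows (", fit_cat$n, " vs ",
         fit_cont$n, ")")
  chosen <- if (fit_cat$aic < fit_cont$aic) fit_cat else fit_cont
  attr(chosen, "chosen") <- chosen$coding
  attr(chosen, "aic") <- c(categorical = fit_cat$aic,
                           continuous = fit_cont$aic)
  chosen
}

#' Percent change of the adjusted log-resistin mean per score category
#'
#' For each non-reference category g the percent change versus the
#' reference (score 0) group is \eqn{100 \beta_g / \mu_0}, where
#' \eqn{\mu_0} is the model intercept (the adjusted reference mean of
#' standardized log-resistin). Standard errors use the first-order delta
#' method with gradient \eqn{(100/\mu_0, -100\beta_g/\mu_0^2)} applied to
#' the \eqn{(\beta_g, \mu_0)} covariance block; 95% confidence limits are
#' the estimate plus/minus 1.959964 SE.
#'
#' @param fit a categorical [fit_exposure_model()].
#' @param mu_tol smallest admissible `|intercept|`; below it the percent
#'   change is ill-defined and an error is raised.
#' @return data.frame with one row per category (reference row first,
#'   exactly 0 with SE 0) and columns `category`, `percent`, `se`, `lo`,
#'   `hi`.
#' @export
percent_change_means <- function(fit, mu_tol = 1e-6) {
  if (fit$coding != "categorical")
    stop("percent_change_means requires a categorical fit")
  beta <- fit$coefficients
  V <- fit$vcov
  mu0 <- beta[["(Intercept)"]]
  if (abs(mu0) < mu_tol)
    stop("reference mean within tolerance of zero; percent change undefined")
  idx <- grep("^grs", names(beta))
  cats <- sub("^grs", "", names(beta)[idx])
  zq <- stats::qnorm(0.975)
  rows <- lapply(seq_along(idx), function(j) {
    i <- idx[j]
    b <- beta[[i]]
    pc <- 100 * b / mu0
    grad <- c(100 / mu0, -100 * b / mu0^2)
    Vb <- V[c(i, 1), c(i, 1)]   # (beta_g, mu0) block
    se <- sqrt(drop(t(grad) %*% Vb %*% grad))
    data.frame(category = cats[j], percent = pc, se = se,
               lo = pc - zq * se, hi = pc + zq * se,
               stringsAsFactors = FALSE)
  })
  ref <- data.frame(category = "0", percent = 0, se = 0, lo = 0, hi = 0,
                    stringsAsFactors = FALSE)
  out <- rbind(ref, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
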