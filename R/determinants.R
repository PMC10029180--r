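# Socio-economic determinant models: covariate derivation, binary
# logistic regression for MDD-W, multiple linear regression for MAR,
# with collinearity (VIF), goodness-of-fit and influence diagnostics.

#' Derive analysis covariates from raw woman-level records
#'
#' Raw CSV schema: `woman_id,age_years,village,marital,education,`
#' `occupation,income,household_size,decision_q1,decision_q2,`
#' `decision_q3,height_m,weight_kg,food_secure,energy_kcal`.
#'
#' Derivations: age bands 15-24 / 25-34 / 35-49; household income
#' quartiles cut at the sample's rank quartiles (lowest quartile =
#' lowest income); household size split at 5 (`<=5` vs `>5`); a 0-3
#' decision-making score summed over the three decision items (own
#' health care, large purchases, visiting family), with a
#' decision-making role attributed only at the full score of 3; WHO BMI
#' bands (underweight < 18.5, normal 18.5-24.99, overweight/obese >= 25)
#' from measured height and weight.
#'
#' @param raw Data frame with the schema above.
#' @return Tibble of analysis covariates (one row per woman) with
#'   factors at the model's reference levels.
#' @export
derive_covariates <- function(raw) {
  raw <- tibble::as_tibble(raw)
  req <- c("woman_id", "age_years", "village", "marital", "education",
           "occupation", "income", "household_size", "decision_q1",
           "decision_q2", "decision_q3", "height_m", "weight_kg",
           "food_secure", "energy_kcal")
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stop("covariate record missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(raw$age_years < 15 | raw$age_years > 49)) {
    stop("age outside the 15-49 reproductive-age range", call. = FALSE)
  }
  if (any(raw$height_m <= 0 | raw$weight_kg <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  dec <- as.matrix(raw[, c("decision_q1", "decision_q2", "decision_q3")])
  if (!all(dec %in% 0:1)) {
    stop("decision items must be 0/1", call. = FALSE)
  }
  bmi <- raw$weight_kg / raw$height_m^2
  # rank quartiles: robust to ties and to tiny samples
  qrt <- dplyr::ntile(raw$income, 4)
  tibble::tibble(
    woman_id = as.character(raw$woman_id),
    age_years = raw$age_years,
    age_band = cut(raw$age_years, c(15, 24, 34, 49),
                   labels = c("15-24", "25-34", "35-49"),
                   include.lowest = TRUE),
    village = factor(raw$village),
    marital = factor(raw$marital, levels = c("unmarried", "married")),
    education = factor(raw$education,
                       levels = c("none", "primary", "secondary")),
    occupation = factor(raw$occupation, levels = c("housewife", "other")),
    income = raw$income,
    income_quartile = factor(c("lowest", "second", "third", "highest")[qrt],
                             levels = c("lowest", "second", "third",
                                        "highest")),
    household_size = raw$household_size,
    household_size_band = factor(ifelse(raw$household_size <= 5, "<=5", ">5"),
                                 levels = c(">5", "<=5")),
    decision_score = as.integer(rowSums(dec)),
    decision_role = factor(ifelse(rowSums(dec) == 3, "yes", "no"),
                           levels = c("no", "yes")),
    bmi = bmi,
    bmi_category = factor(
      dplyr::case_when(bmi < 18.5 ~ "underweight",
                       bmi < 25 ~ "normal",
                       TRUE ~ "overweight"),
      levels = c("normal", "underweight", "overweight")),
    food_secure = factor(ifelse(as.logical(raw$food_secure),
                                "secure", "insecure"),
                         levels = c("insecure", "secure")),
    energy_kcal = raw$energy_kcal)
}

# default model term sets (order mirrors the reporting layout)
mddw_model_terms <- function() {
  c("age_band", "village", "marital", "education", "occupation",
    "income_quartile", "household_size_band", "decision_role",
    "bmi_category", "food_secure")
}
mar_model_terms <- function() {
  c("energy_kcal", "age_band", "household_size_band", "decision_role",
    "mddw_met", "education", "bmi_category")
}

# keep terms that exist and actually vary in this sample
usable_terms <- function(data, terms) {
  keep <- vapply(terms, function(tm) {
    tm %in% names(data) && length(unique(data[[tm]])) > 1
  }, logical(1))
  dropped <- terms[!keep]
  if (length(dropped)) {
    message("dropping constant or absent term(s): ",
            paste(dropped, collapse = ", "))
  }
  terms[keep]
}

# generalized VIF per term; flagged when the squared df-adjusted GVIF
# exceeds the collinearity threshold (default 2)
vif_diagnostics <- function(fit, threshold = 2) {
  labels <- attr(stats::terms(fit), "term.labels")
  if (length(labels) < 2) {
    return(tibble::tibble(term = labels, gvif = NA_real_, df = NA_real_,
                          gvif_adj = NA_real_, flagged = FALSE))
  }
  v <- car::vif(fit)
  if (is.matrix(v)) {
    tibble::tibble(term = rownames(v), gvif = v[, 1], df = v[, 2],
                   gvif_adj = v[, 3], flagged = v[, 3]^2 > threshold)
  } else {
    tibble::tibble(term = names(v), gvif = unname(v), df = 1,
                   gvif_adj = sqrt(unname(v)), flagged = unname(v) > threshold)
  }
}

# reference level of every factor term in a model frame
reference_levels <- function(data, terms) {
  refs <- lapply(terms, function(tm) {
    if (is.factor(data[[tm]])) levels(data[[tm]])[1] else NULL
  })
  names(refs) <- terms
  purrr::compact(refs)
}

#' Binary logistic regression for the determinants of MDD-W
#'
#' Fits `mddw_met ~ covariates` by maximum likelihood and reports
#' adjusted odds ratios with Wald 95% confidence intervals (computed on
#' the log-odds scale and exponentiated). Collinearity is screened with
#' generalized VIFs (flag above 2) and model fit with a Pearson
#' goodness-of-fit statistic, either on individual observations
#' (`gof_binning = "none"`, degrees of freedom n - p) or on deciles of
#' fitted risk (`"deciles"`).
#'
#' @param covariates Tibble from [derive_covariates()].
#' @param outcomes Logical vector, `TRUE` when the woman met MDD-W.
#' @param terms Model terms; defaults to the full determinant set
#'   (age band, village, marital status, education, occupation, income
#'   quartile, household-size band, decision-making role, BMI category,
#'   food security). Constant terms are dropped with a message.
#' @param conf_level Confidence level for the intervals.
#' @param vif_threshold Collinearity flag threshold.
#' @param gof_binning `"none"` or `"deciles"`.
#' @return Object of class `wradiet_fit`: list with `model`
#'   (`"logistic_mddw"`), `terms` (tibble: term, level, estimate — the
#'   odds ratio —, ci_lo, ci_hi, p_value), `reference_levels`,
#'   `diagnostics` (VIF table, GOF statistic/df/p-value, convergence and
#'   separation warnings) and `fit` (the underlying `glm`).
#' @export
fit_mddw_logistic <- function(covariates, outcomes,
                              terms = mddw_model_terms(),
                              conf_level = 0.95, vif_threshold = 2,
                              gof_binning = c("none", "deciles")) {
  gof_binning <- match.arg(gof_binning)
  outcomes <- as.logical(outcomes)
  stopifnot(length(outcomes) == nrow(covariates))
  if (length(unique(outcomes)) < 2) {
    stop("outcome has a single class; cannot fit a logistic model",
         call. = FALSE)
  }
  terms <- usable_terms(covariates, terms)
  data <- dplyr::mutate(covariates[, terms, drop = FALSE],
                        .outcome = outcomes)
  if (nrow(data) <= length(terms) + 1) {
    stop("too few observations for the requested model", call. = FALSE)
  }
  fit <- stats::glm(stats::reformulate(terms, ".outcome"),
                    family = stats::binomial(), data = data)
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    stop("rank-deficient design (aliased coefficients): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  res <- tibble::tibble(
    term = rownames(sm),
    estimate = exp(est),
    ci_lo = exp(est - z * se),
    ci_hi = exp(est + z * se),
    p_value = sm[, "Pr(>|z|)"])
  res <- res[res$term != "(Intercept)", ]

  warnings <- character()
  if (!fit$converged) warnings <- c(warnings, "IWLS did not converge")
  sep <- rownames(sm)[abs(sm[, "Estimate"]) > 10 | sm[, "Std. Error"] > 10]
  sep <- setdiff(sep, "(Intercept)")
  if (length(sep)) {
    warnings <- c(warnings, paste0("possible separation in term(s): ",
                                   paste(sep, collapse = ", ")))
  }

  gof <- pearson_gof(fit, binning = gof_binning)
  structure(list(
    model = "logistic_mddw",
    terms = res,
    reference_levels = reference_levels(data, terms),
    diagnostics = list(vif = vif_diagnostics(fit, vif_threshold),
                       gof = gof, warnings = warnings),
    fit = fit), class = "wradiet_fit")
}

# Pearson goodness of fit for a binomial glm
pearson_gof <- function(fit, binning = "none") {
  if (binning == "none") {
    x2 <- sum(stats::residuals(fit, type = "pearson")^2)
    df <- stats::df.residual(fit)
  } else {
    p <- stats::fitted(fit)
    y <- fit$y
    g <- cut(p, breaks = unique(stats::quantile(p, seq(0, 1, 0.1))),
             include.lowest = TRUE)
    obs <- tapply(y, g, sum)
    exp_ <- tapply(p, g, sum)
    n_g <- tapply(y, g, length)
    x2 <- sum((obs - exp_)^2 / (exp_ * (1 - exp_ / n_g)))
    df <- length(obs) - 2
  }
  list(statistic = x2, df = df,
       p_value = stats::pchisq(x2, df, lower.tail = FALSE),
       binning = binning)
}

#' Multiple linear regression for the determinants of MAR
#'
#' Fits the mean adequacy ratio on the determinant set by ordinary
#' least squares and reports coefficients with 95% confidence intervals,
#' generalized VIFs (flag above 2), a residual-normality summary
#' (Shapiro-Wilk plus moments), and influence screens: cases with
#' Cook's distance above 1 and cases with leverage above the cutoff.
#'
#' @param covariates Tibble from [derive_covariates()]; a logical or
#'   factor `mddw_met` column may be bound in beforehand.
#' @param mar_values Numeric vector in `[0, 1]`.
#' @param terms Model terms; defaults to energy intake, age band,
#'   household-size band, decision-making role, MDD-W, education and
#'   BMI category.
#' @param leverage_cutoff `"2p_over_n"` (default: twice the number of
#'   model parameters over n) or `"fixed"` (use `leverage_fixed`,
#'   default 0.05, retained for comparability with reports that quote a
#'   fixed leverage cut).
#' @param leverage_fixed Fixed leverage cutoff value.
#' @inheritParams fit_mddw_logistic
#' @return Object of class `wradiet_fit` with raw coefficients in
#'   `terms`, plus `diagnostics` (VIF, residual normality, Cook's
#'   distance and leverage case listings).
#' @export
fit_mar_linear <- function(covariates, mar_values,
                           terms = mar_model_terms(),
                           conf_level = 0.95, vif_threshold = 2,
                           leverage_cutoff = c("2p_over_n", "fixed"),
                           leverage_fixed = 0.05) {
  leverage_cutoff <- match.arg(leverage_cutoff)
  stopifnot(length(mar_values) == nrow(covariates))
  covariates <- tibble::as_tibble(covariates)
  if ("mddw_met" %in% names(covariates) &&
      is.logical(covariates$mddw_met)) {
    covariates$mddw_met <- factor(ifelse(covariates$mddw_met,
                                         "adequate", "inadequate"),
                                  levels = c("inadequate", "adequate"))
  }
  terms <- usable_terms(covariates, terms)
  data <- dplyr::mutate(covariates[, terms, drop = FALSE],
                        .outcome = mar_values)
  if (nrow(data) <= length(terms) + 1) {
    stop("too few observations for the requested model", call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(terms, ".outcome"), data = data)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    stop("rank-deficient design: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "),
         call. = FALSE)
  }
  ci <- stats::confint(fit, level = conf_level)
  sm <- summary(fit)$coefficients
  res <- tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                        ci_lo = ci[, 1], ci_hi = ci[, 2],
                        p_value = sm[, "Pr(>|t|)"])
  res <- res[res$term != "(Intercept)", ]

  r <- stats::residuals(fit)
  normality <- list(
    shapiro_p = if (length(r) >= 3 && length(r) <= 5000 &&
                    stats::sd(r) > 0)
      stats::shapiro.test(r)$p.value else NA_real_,
    mean = mean(r), sd = stats::sd(r),
    skewness = mean((r - mean(r))^3) / stats::sd(r)^3)

  n <- nrow(data)
  p <- length(stats::coef(fit))
  hat_cut <- if (leverage_cutoff == "fixed") leverage_fixed else 2 * p / n
  cooks <- stats::cooks.distance(fit)
  hats <- stats::hatvalues(fit)
  structure(list(
    model = "linear_mar",
    terms = res,
    reference_levels = reference_levels(data, terms),
    diagnostics = list(
      vif = vif_diagnostics(fit, vif_threshold),
      residual_normality = normality,
      cooks_over_1 = which(cooks > 1),
      leverage_cutoff = hat_cut,
      high_leverage = which(hats > hat_cut)),
    fit = fit), class = "wradiet_fit")
}

#' @export
print.wradiet_fit <- function(x, ...) {
  cat("<wradiet_fit> ", x$model, "\n", sep = "")
  print(x$terms, n = Inf)
  flagged <- x$diagnostics$vif$term[x$diagnostics$vif$flagged]
  if (length(flagged)) {
    cat("VIF flag (>2):", paste(flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cochran's sample size for estimating a proportion
#'
#' `n = ceiling(z^2 * p * (1 - p) / d^2)` — the classic sample-size
#' formula for a prevalence estimate at absolute precision `d`.
#'
#' @param p Anticipated proportion, in (0, 1).
#' @param z Standard-normal quantile (1.96 for 95% confidence).
#' @param d Absolute precision (default 0.05).
#' @return Integer sample size.
#' @export
#' @examples
#' cochran_sample_size(0.132)  # 177
cochran_sample_size <- function(p, z = 1.96, d = 0.05) {
  if (!(p > 0 && p < 1)) stop("p must be in (0, 1)", call. = FALSE)
  if (d <= 0) stop("d must be > 0", call. = FALSE)
  as.integer(ceiling(z^2 * p * (1 - p) / d^2))
}
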