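#' Average daily gain
#'
#' Body-weight gain over the fattening period divided by the number of
#' fattening days, in kg/day.
#'
#' @param weight_gain_kg Numeric vector of weight gains (kg); negative gains
#'   are allowed with a warning.
#' @param fattening_days Positive number of days on feed.
#' @return Numeric vector of ADG values (kg/day).
#' @export
compute_adg <- function(weight_gain_kg, fattening_days) {
  if (any(fattening_days <= 0)) stop("fattening_days must be positive")
  if (any(weight_gain_kg < 0)) warning("negative weight gain; ADG will be negative")
  weight_gain_kg / fattening_days
}

#' Adjust phenotypes by a fixed-effects linear model
#'
#' Fits, per trait, an ordinary least-squares model with farm, year and sex
#' as categorical fixed effects and weight before fattening and fattening
#' days as covariates, and returns the residuals as the adjusted phenotype.
#' Reference-level factor coding is used; any full-rank coding yields the
#' same residuals. Rows with missing values in the trait or the design are
#' dropped (with a message); their adjusted value is `NA`.
#'
#' @param pheno Phenotype tibble with `sample_id`, the design columns and the
#'   trait columns.
#' @param traits Character vector of trait column names to adjust.
#' @param fixed Categorical fixed-effect column names.
#' @param covariates Numeric covariate column names.
#' @return Tibble: `sample_id` plus one adjusted column per trait (same
#'   names as `traits`).
#' @export
adjust_phenotypes <- function(pheno, traits = c("NMW", "CW", "ADG", "LW"),
                              fixed = c("farm", "year", "sex"),
                              covariates = c("weight_before_fattening",
                                             "fattening_days")) {
  stopifnot("sample_id" %in% names(pheno))
  missing_cols <- setdiff(c(traits, fixed, covariates), names(pheno))
  if (length(missing_cols) > 0) {
    stop("phenotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  keep_fixed <- fixed[vapply(fixed, function(f)
    length(unique(na.omit(pheno[[f]]))) > 1, TRUE)]
  keep_cov <- covariates[vapply(covariates, function(f)
    var(pheno[[f]], na.rm = TRUE) > 0, TRUE)]
  if (length(keep_fixed) == 0 && length(keep_cov) == 0) {
    stop("no usable design columns: all factors constant and covariates degenerate")
  }
  rhs <- paste(c(sprintf("factor(%s)", keep_fixed), keep_cov), collapse = " + ")
  out <- tibble(sample_id = as.character(pheno$sample_id))
  for (tr in traits) {
    form <- stats::as.formula(paste0("`", tr, "` ~ ", rhs))
    cc <- complete.cases(pheno[, c(tr, keep_fixed, keep_cov)])
    if (sum(!cc) > 0) {
      message(sprintf("%s: dropped %d row(s) with missing values", tr, sum(!cc)))
    }
    fit <- lm(form, data = pheno[cc, ])
    if (any(is.na(coef(fit)))) {
      stop(sprintf("rank-deficient design for %s: collinear column(s) %s", tr,
                   paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
    }
    vals <- rep(NA_real_, nrow(pheno))
    vals[cc] <- resid(fit)
    out[[tr]] <- vals
  }
  out
}
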