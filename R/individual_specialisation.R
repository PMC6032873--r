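#' Classify one insect as a single- or multi-plant visitor
#'
#' An individual is a "single-plant visitor" when its dominant pollen taxon
#' accounts for at least `threshold_percent` of its identified reads; the
#' threshold is inclusive (exactly 90.0 is "single") and defaults to 90
#' because some heterospecific carry-over (pollen picked up from stigmas or
#' the wider environment) makes perfectly pure loads unrealistic. Ties for
#' the dominant taxon are broken lexicographically and flagged.
#'
#' @param profile A `pollen_profile` from [profile_insect()].
#' @param threshold_percent Inclusive dominance threshold (default 90).
#' @return List of class `visitor_classification`: `insect_id`, `top_taxon`,
#'   `top_percent`, `visitor_class` (`"single"` or `"multi"`),
#'   `threshold_percent`, `tie`.
#' @export
classify_individual <- function(profile, threshold_percent = 90) {
  stopifnot(inherits(profile, "pollen_profile"))
  if (profile$excluded)
    stop("cannot classify an excluded profile (no identified reads): ",
         profile$insect_id)
  pc <- profile$percents
  top <- max(pc)
  winners <- sort(names(pc)[pc == top])
  structure(list(insect_id = profile$insect_id,
                 top_taxon = winners[1],
                 top_percent = unname(top),
                 visitor_class = if (top >= threshold_percent) "single" else "multi",
                 threshold_percent = threshold_percent,
                 tie = length(winners) > 1),
            class = "visitor_classification")
}

#' Classify every insect in a tidy profile table
#'
#' @param profiles Tidy profile table from [profile_insects()].
#' @param threshold_percent Inclusive dominance threshold (default 90).
#' @return Data.frame `insect_id`, `insect_species`, `sex`, `site`, `period`,
#'   `top_taxon`, `top_percent`, `visitor_class`, `tie`.
#' @export
classify_individuals <- function(profiles, threshold_percent = 90) {
  ids <- unique(profiles$insect_id)
  out <- lapply(ids, function(id) {
    p <- profiles[profiles$insect_id == id, , drop = FALSE]
    top <- max(p$percent)
    winners <- sort(p$taxon[p$percent == top])
    data.frame(insect_id = id, insect_species = p$insect_species[1],
               sex = p$sex[1], site = p$site[1], period = p$period[1],
               top_taxon = winners[1], top_percent = top,
               visitor_class = if (top >= threshold_percent) "single" else "multi",
               tie = length(winners) > 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Summarise visitor classifications by period
#'
#' For each period and each threshold, counts and percentages of insects
#' whose dominant-taxon percentage meets the (inclusive) threshold, plus a
#' decile binning of dominant-taxon percentages for histogram-style
#' reporting.
#'
#' @param classifications Output of [classify_individuals()].
#' @param thresholds Dominance thresholds in percent (default `c(90, 60)`).
#' @return List with `threshold_table` (`period`, `threshold`, `n_total`,
#'   `n_at_or_above`, `percent`) and `decile_table` (`period`, `bin`,
#'   `count`); periods with no insects are absent from both.
#' @export
classification_summary <- function(classifications, thresholds = c(90, 60)) {
  periods <- unique(classifications$period)
  tt <- list(); dt <- list()
  breaks <- seq(0, 100, by = 10)
  labels <- sprintf("(%d,%d]", breaks[-length(breaks)], breaks[-1])
  for (p in periods) {
    cl <- classifications[classifications$period == p, , drop = FALSE]
    n <- nrow(cl)
    if (n == 0) next
    for (th in thresholds) {
      k <- sum(cl$top_percent >= th)
      tt[[length(tt) + 1L]] <- data.frame(
        period = p, threshold = th, n_total = n, n_at_or_above = k,
        percent = 100 * k / n, stringsAsFactors = FALSE)
    }
    bins <- cut(cl$top_percent, breaks = breaks, labels = labels,
                include.lowest = TRUE)
    cnt <- table(bins)
    dt[[length(dt) + 1L]] <- data.frame(
      period = p, bin = names(cnt), count = as.integer(cnt),
      stringsAsFactors = FALSE)
  }
  list(threshold_table = do.call(rbind, c(tt, make.row.names = FALSE)),
       decile_table = do.call(rbind, c(dt, make.row.names = FALSE)))
}

#' Binomial mixed-effects model for visitor class
#'
#' Logistic model of single- versus multi-plant visitor status with period
#' and sex as fixed effects and crossed Gaussian random intercepts for site
#' and insect species, fitted by maximising the Laplace-approximated marginal
#' likelihood (lme4's adaptive scheme with one quadrature node, the standard
#' choice for crossed designs). The response is coded single = 1, multi = 0;
#' period is coded early = 0, late = 1 and sex female = 0, male = 1, so a
#' positive period coefficient means single-plant visiting is more common
#' late.
#'
#' With `constrain_zero_variance = TRUE` both random-effect variances are
#' fixed at zero and the model reduces exactly to ordinary logistic
#' regression fitted by iteratively reweighted least squares.
#'
#' @param data Data.frame with columns `visitor_class` (`"single"`/`"multi"`
#'   or 0/1), `period` (`"early"`/`"late"`), `sex` (`"F"`/`"M"`), `site`,
#'   `species` (or `insect_species`).
#' @param constrain_zero_variance Fit the variance-zero (plain logistic)
#'   model instead (default `FALSE`).
#' @return List of class `glmm_fit`: `coefficients` (data.frame `term`,
#'   `estimate`, `se`, `z`, `p`), `varcomp` (named vector of random-intercept
#'   variances), `logLik`, `converged`, `model`.
#' @export
fit_binomial_glmm <- function(data, constrain_zero_variance = FALSE) {
  if (!"species" %in% names(data) && "insect_species" %in% names(data))
    data$species <- data$insect_species
  req <- c("visitor_class", "period", "sex", "site", "species")
  if (!all(req %in% names(data)))
    stop("data missing required columns: ",
         paste(setdiff(req, names(data)), collapse = ", "))
  y <- if (is.numeric(data$visitor_class)) as.integer(data$visitor_class) else
    as.integer(data$visitor_class == "single")
  if (length(unique(y)) < 2)
    stop("complete separation: all responses identical, model is not estimable")
  d <- data.frame(y = y,
                  period_late = as.integer(data$period == "late"),
                  sex_male = as.integer(data$sex == "M"),
                  site = factor(data$site),
                  species = factor(data$species))
  if (length(unique(d$period_late)) < 2 || length(unique(d$sex_male)) < 2)
    stop("each fixed effect needs at least 2 observed levels")

  if (constrain_zero_variance) {
    fit <- glm(y ~ period_late + sex_male, family = binomial(), data = d)
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        z = sm[, 3], p = sm[, 4], stringsAsFactors = FALSE,
                        row.names = NULL)
    return(structure(list(coefficients = coefs,
                          varcomp = c(site = 0, species = 0),
                          logLik = as.numeric(logLik(fit)),
                          converged = fit$converged, model = fit),
                     class = "glmm_fit"))
  }

  fit <- NULL
  warn <- character(0)
  withCallingHandlers(
    fit <- lme4::glmer(y ~ period_late + sex_male + (1 | site) + (1 | species),
                       family = binomial(), data = d, nAGQ = 1L),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], stringsAsFactors = FALSE,
                      row.names = NULL)
  vc <- lme4::VarCorr(fit)
  varcomp <- c(site = as.numeric(vc$site), species = as.numeric(vc$species))
  structure(list(coefficients = coefs, varcomp = varcomp,
                 logLik = as.numeric(logLik(fit)),
                 converged = length(warn) == 0, warnings = warn,
                 model = fit),
            class = "glmm_fit")
}
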