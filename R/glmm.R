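#' Specify a binomial mixed model for a gaze-discrimination design
#'
#' Defines the model fitted to trial-level correct/incorrect responses:
#' test fixed factors (with all their interactions), control fixed factors
#' (block, and within-block trial nested in block as a per-block linear
#' slope), and crossed random factors with uncorrelated random slopes.
#'
#' Factor coding is treatment contrasts with reference levels chimpanzee
#' species, the lowest stimulus level present, and normal polarity; stimulus
#' level is categorical.
#'
#' @param test Character vector of test fixed factors, from `"species"`,
#'   `"level"`, `"polarity"`, `"phase"`.
#' @param random Character vector of random factors, from `"participant"`,
#'   `"stimulus_id"`, `"session_id"`. Empty for a plain logistic regression.
#' @param slopes Random-slope set for the first random factor: `"none"`
#'   (intercepts only), or `"full"` (an uncorrelated slope for each test
#'   factor, dummy-coded). Correlations between slopes and intercepts are
#'   never estimated.
#' @param interactions Include all interactions among test factors (default
#'   TRUE).
#' @param controls Include the control fixed factors (default TRUE).
#' @return A `model_spec` list.
#' @seealso [spec_study1_exp1()], [fit_glmm()]
#' @export
model_spec <- function(test, random = character(0),
                       slopes = c("none", "full"),
                       interactions = TRUE, controls = TRUE) {
  slopes <- match.arg(slopes)
  ok_test <- c("species", "level", "polarity", "phase")
  ok_rand <- c("participant_id", "stimulus_id", "session_id")
  if (!all(test %in% ok_test))
    stop("test factors must be among: ", paste(ok_test, collapse = ", "))
  if (!all(random %in% ok_rand))
    stop("random factors must be among: ", paste(ok_rand, collapse = ", "))
  fixed <- stats::reformulate(
    paste(test, collapse = if (interactions) " * " else " + "))
  structure(list(test = test, random = random, slopes = slopes,
                 interactions = interactions, controls = controls,
                 fixed_terms = attr(stats::terms(fixed), "term.labels")),
            class = "model_spec")
}

#' Canned model specifications for the three designs
#'
#' `spec_study1_exp1()`: species x level, random participant and stimulus
#' individual. `spec_study1_exp2()`: species x level x polarity, same random
#' factors. `spec_study2()`: species only (level is adapted within sessions
#' and deliberately not modeled), random stimulus individual and session;
#' with `phase = TRUE` the species x phase interaction model used to compare
#' test phases of the ABA design.
#'
#' @param slopes Passed to [model_spec()].
#' @param controls Passed to [model_spec()].
#' @return A `model_spec`.
#' @export
spec_study1_exp1 <- function(slopes = "none", controls = TRUE)
  model_spec(c("species", "level"), c("participant_id", "stimulus_id"),
             slopes = slopes, controls = controls)

#' @rdname spec_study1_exp1
#' @export
spec_study1_exp2 <- function(slopes = "none", controls = TRUE)
  model_spec(c("species", "level", "polarity"),
             c("participant_id", "stimulus_id"),
             slopes = slopes, controls = controls)

#' @rdname spec_study1_exp1
#' @param phase Include the test-phase factor and its interaction with
#'   species (ABA-design comparison).
#' @export
spec_study2 <- function(phase = FALSE, slopes = "none", controls = TRUE)
  model_spec(if (phase) c("species", "phase") else "species",
             c("stimulus_id", "session_id"),
             slopes = slopes, controls = controls)

# Prepare the analysis frame: factor coding, control covariates, slope dummies
prepare_model_frame <- function(data, spec) {
  d <- as.data.frame(data)
  if (!"correct" %in% names(d)) stop("data must have a 'correct' column")
  d$correct <- as.integer(d$correct)
  relevel_if <- function(x, ref) {
    f <- factor(x)
    if (ref %in% levels(f)) stats::relevel(f, ref = ref) else f
  }
  if ("species" %in% names(d))
    d$species <- relevel_if(d$species, "chimpanzee")
  if ("level" %in% names(d))
    d$level <- factor(level_label(d$level),
                      levels = level_label(sort(unique(d$level))))
  if ("polarity" %in% names(d))
    d$polarity <- relevel_if(d$polarity, "normal")
  if ("phase" %in% names(d)) d$phase <- factor(d$phase)
  for (rf in spec$random)
    if (rf %in% names(d)) d[[rf]] <- factor(d[[rf]])
  if (spec$controls) {
    d$block_f <- factor(d$block)
    d$trial_c <- d$trial_in_block - mean(d$trial_in_block)
  }
  # numeric dummies for uncorrelated random slopes
  if (spec$slopes == "full") {
    for (tf in spec$test) {
      mm <- stats::model.matrix(stats::reformulate(tf), d)[, -1, drop = FALSE]
      cols <- paste0(".sl_", gsub("[^[:alnum:]]", "_", colnames(mm)))
      for (j in seq_along(cols)) d[[cols[j]]] <- mm[, j]
    }
  }
  d
}

slope_dummy_cols <- function(d) grep("^\\.sl_", names(d), value = TRUE)

build_formula <- function(spec, d, fixed_terms = spec$fixed_terms) {
  rhs <- fixed_terms
  if (spec$controls) rhs <- c(rhs, "block_f", "block_f:trial_c")
  if (length(rhs) == 0L) rhs <- "1"
  re <- character(0)
  if (length(spec$random) > 0L) {
    re <- paste0("(1 | ", spec$random, ")")
    if (spec$slopes == "full") {
      sl <- slope_dummy_cols(d)
      if (length(sl) > 0L)
        re <- c(re, paste0("(0 + ", sl, " | ", spec$random[1], ")"))
    }
  }
  stats::as.formula(paste("correct ~", paste(c(rhs, re), collapse = " + ")))
}

#' Fit a binomial GLMM (or logistic regression) to trial-level responses
#'
#' Fits the model defined by a [model_spec()] by maximum likelihood: a
#' binomial GLMM with crossed random effects via the Laplace approximation
#' (`lme4::glmer`) when random factors are present, or an ordinary logistic
#' regression (`stats::glm`) when the random-factor set is empty. Random
#' slopes, when requested, are entered as uncorrelated dummy-coded terms.
#'
#' @param data Trial-level data frame (as from [simulate_responses()]), with
#'   a 0/1 `correct` column and the factors named in the spec.
#' @param spec A [model_spec()].
#' @return A `fit_result` with elements `fit` (the underlying model object),
#'   `coefficients` (fixed effects with SEs), `ranef_sd` (random-effect SDs),
#'   `logLik`, `npar`, `nobs`, `converged`, `dispersion`, `spec`, `formula`.
#' @examples
#' plan <- build_study1_exp1(seed = 1)
#' resp <- simulate_responses(plan, observer_presets("species-only"), 6, seed = 2)
#' fit <- fit_glmm(resp, spec_study1_exp1(controls = FALSE))
#' fit$coefficients
#' @export
fit_glmm <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- prepare_model_frame(data, spec)
  for (rf in spec$random)
    if (nlevels(d[[rf]]) < 2L)
      stop("random factor '", rf, "' needs at least 2 levels")
  form <- build_formula(spec, d)
  fit_with_terms(d, spec, spec$fixed_terms, form)
}

fit_with_terms <- function(d, spec, fixed_terms,
                           form = build_formula(spec, d, fixed_terms)) {
  mixed <- length(spec$random) > 0L
  if (mixed) {
    fit <- suppressMessages(lme4::glmer(
      form, data = d, family = stats::binomial(),
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   calc.derivs = FALSE)))
    conv <- length(fit@optinfo$conv$lme4$messages) == 0L &&
      fit@optinfo$conv$opt == 0L
    vc <- lme4::VarCorr(fit)
    ranef_sd <- unlist(lapply(vc, function(m) attr(m, "stddev")))
    co <- summary(fit)$coefficients
  } else {
    fit <- stats::glm(form, data = d, family = stats::binomial())
    conv <- fit$converged
    if (conv && any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
      warning("very large coefficients: possible complete separation")
    ranef_sd <- numeric(0)
    co <- summary(fit)$coefficients
  }
  ll <- stats::logLik(fit)
  res <- structure(list(
    fit = fit,
    coefficients = co,
    ranef_sd = ranef_sd,
    logLik = as.numeric(ll),
    npar = attr(ll, "df"),
    nobs = stats::nobs(fit),
    converged = conv,
    spec = spec,
    fixed_terms = fixed_terms,
    formula = form,
    data = d),
    class = "fit_result")
  res$dispersion <- dispersion(res)
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Binomial", if (length(x$spec$random) > 0L) "GLMM (Laplace)"
      else "GLM", "fit\n")
  cat("  formula: ", deparse(x$formula), "\n")
  cat(sprintf("  logLik %.3f on %d parameters, n = %d, converged: %s\n",
              x$logLik, x$npar, x$nobs, x$converged))
  cat(sprintf("  dispersion: %.3f\n", x$dispersion))
  invisible(x)
}

#' Likelihood-ratio test of two nested fits
#'
#' chi^2 = 2 (logLik full - logLik reduced), df = difference in parameter
#' count, p from the upper chi^2 tail. The reduced model must be nested in
#' the full one; a chi^2 below -1e-6 raises an error (refit needed), smaller
#' negative values are clamped to zero.
#'
#' @param full,reduced `fit_result` objects on the same data.
#' @param term Optional label of the tested term, stored in the result.
#' @return An `lrt_result` with `chisq`, `df`, `p`, `term`.
#' @export
lrt <- function(full, reduced, term = NULL) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"))
  if (full$nobs != reduced$nobs)
    stop("models were fitted to different numbers of observations")
  if (reduced$npar > full$npar)
    stop("'reduced' has more parameters than 'full'; models must be nested")
  if (!full$converged || !reduced$converged)
    warning("likelihood-ratio test involves a non-converged fit")
  chisq <- 2 * (full$logLik - reduced$logLik)
  if (chisq < -1e-6)
    stop("negative likelihood-ratio statistic (", format(chisq),
         "); the reduced model reached a higher likelihood - refit needed")
  chisq <- max(chisq, 0)
  df <- full$npar - reduced$npar
  p <- if (df == 0L) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  if (is.null(term))
    term <- paste(setdiff(full$fixed_terms, reduced$fixed_terms),
                  collapse = " + ")
  structure(list(chisq = chisq, df = df, p = p, term = term),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT [%s]: chisq = %.3f, df = %d, p = %.4g\n",
              x$term, x$chisq, x$df, x$p))
  invisible(x)
}

term_order <- function(term) length(strsplit(term, ":", fixed = TRUE)[[1]])

#' Test terms with interaction pruning
#'
#' Implements the analysis protocol: test the highest-order interaction(s) by
#' likelihood-ratio test; when nonsignificant at `alpha`, drop them and test
#' the next-lower-order terms in the reduced model; when an interaction is
#' significant, retain it, stop testing the lower-order terms it contains,
#' and flag a simple-effects follow-up.
#'
#' @param data Trial-level data frame.
#' @param spec A [model_spec()] containing interactions.
#' @param alpha Significance level (pass e.g. `0.05 / 3` for a
#'   Bonferroni-corrected per-individual analysis).
#' @return A `prune_result`: list with `tests` (ordered `lrt_result`s, each
#'   with `significant` and `action`), `final_terms`, `final_fit`, and
#'   `simple_effects_needed`.
#' @export
prune_and_test <- function(data, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "model_spec"))
  d <- prepare_model_frame(data, spec)
  terms_now <- spec$fixed_terms
  tests <- list()
  simple_needed <- FALSE
  fit_now <- fit_with_terms(d, spec, terms_now)
  protected <- character(0)  # lower-order terms inside significant interactions

  for (ord in sort(unique(vapply(terms_now, term_order, 1L)),
                   decreasing = TRUE)) {
    layer <- terms_now[vapply(terms_now, term_order, 1L) == ord]
    layer <- setdiff(layer, protected)
    sig_layer <- character(0)
    for (tm in layer) {
      reduced <- fit_with_terms(d, spec, setdiff(terms_now, tm))
      res <- lrt(fit_now, reduced, term = tm)
      res$significant <- res$p < alpha
      res$action <- if (res$significant) "retained (significant)" else "dropped"
      tests[[length(tests) + 1L]] <- res
      if (res$significant) sig_layer <- c(sig_layer, tm)
    }
    dropped <- setdiff(layer, sig_layer)
    if (length(dropped) > 0L) {
      terms_now <- setdiff(terms_now, dropped)
      fit_now <- fit_with_terms(d, spec, terms_now)
    }
    if (length(sig_layer) > 0L && ord > 1L) {
      simple_needed <- TRUE
      protected <- unique(c(protected, unlist(
        lapply(sig_layer, function(tm) contained_terms(tm)))))
    }
  }
  structure(list(tests = tests, final_terms = terms_now, final_fit = fit_now,
                 simple_effects_needed = simple_needed),
            class = "prune_result")
}

contained_terms <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(character(0))
  combos <- unlist(lapply(seq_len(length(parts) - 1L), function(k)
    utils::combn(parts, k, paste, collapse = ":")))
  combos
}

#' @export
print.prune_result <- function(x, ...) {
  for (t in x$tests)
    cat(sprintf("  %-28s chisq = %7.3f  df = %d  p = %.4g  -> %s\n",
                t$term, t$chisq, t$df, t$p, t$action))
  cat("final terms:", paste(x$final_terms, collapse = ", "), "\n")
  if (x$simple_effects_needed)
    cat("significant interaction: simple-effects follow-up required\n")
  invisible(x)
}

#' Simple-effects tests after a significant interaction
#'
#' Within each combination of levels of the conditioning factor(s), tests the
#' focal factor by likelihood-ratio test at the supplied alpha (e.g.
#' `0.05 / 3` when correcting over three individuals).
#'
#' @param data Trial-level data frame.
#' @param focal The factor tested in each stratum (e.g. `"species"`).
#' @param split_by Character vector of conditioning factors (e.g.
#'   `c("polarity", "level")`).
#' @param random Random factors for the within-stratum models.
#' @param alpha Per-test significance level.
#' @param controls Include control fixed factors in stratum models.
#' @return A data frame, one row per stratum: the stratum levels, `chisq`,
#'   `df`, `p`, `significant`. Strata with a single observed outcome value
#'   or a single focal level are reported with `NA` statistics and a warning.
#' @export
simple_effects <- function(data, focal, split_by, random = character(0),
                           alpha = 0.05, controls = FALSE) {
  d <- as.data.frame(data)
  strata <- unique(d[split_by])
  strata <- strata[do.call(order, as.list(strata)), , drop = FALSE]
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    sel <- rep(TRUE, nrow(d))
    for (f in split_by) sel <- sel & d[[f]] == strata[i, f]
    sub <- d[sel, , drop = FALSE]
    row <- strata[i, , drop = FALSE]
    if (nrow(sub) == 0L || length(unique(sub[[focal]])) < 2L ||
        length(unique(sub$correct)) < 2L) {
      warning("stratum ", paste(unlist(row), collapse = "/"),
              " is empty or degenerate; test skipped")
      row$chisq <- NA_real_; row$df <- NA_integer_; row$p <- NA_real_
      row$significant <- NA
    } else {
      spec_f <- model_spec(focal, random = random, controls = controls)
      full <- fit_glmm(sub, spec_f)
      red <- fit_with_terms(prepare_model_frame(sub, spec_f), spec_f,
                            character(0))
      res <- lrt(full, red, term = focal)
      row$chisq <- res$chisq; row$df <- res$df; row$p <- res$p
      row$significant <- res$p < alpha
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  res
}

#' Pearson dispersion parameter of a fit
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom (observations minus parameters). Values near 1 indicate no
#' overdispersion.
#'
#' @param fit A `fit_result`.
#' @return The dispersion parameter (> 0).
#' @export
dispersion <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  pr <- stats::residuals(fit$fit, type = "pearson")
  sum(pr^2) / (fit$nobs - fit$npar)
}

#' Nonparametric bootstrap CI for a proportion correct
#'
#' Percentile confidence interval obtained by resampling whole units
#' (participants for the keypress task, sessions for the visual-search task)
#' with replacement and recomputing the proportion of correct trials.
#'
#' @param data Trial-level data frame with a `correct` column.
#' @param unit Name of the column identifying the resampling unit.
#' @param n_resamples Number of bootstrap resamples (default 2000).
#' @param seed Integer seed (the CI is reproducible given the seed).
#' @param conf Confidence level, default 0.95.
#' @return A `bootstrap_ci` list: `estimate`, `lower`, `upper`,
#'   `n_resamples`, `unit`, `seed`.
#' @export
bootstrap_ci <- function(data, unit, n_resamples = 2000L, seed = 1L,
                         conf = 0.95) {
  d <- as.data.frame(data)
  units <- unique(d[[unit]])
  if (length(units) < 2L)
    stop("need at least 2 resampling units, got ", length(units))
  set.seed(seed)
  by_unit <- split(d$correct, d[[unit]])
  stat <- vapply(seq_len(n_resamples), function(i) {
    take <- sample(names(by_unit), length(by_unit), replace = TRUE)
    v <- unlist(by_unit[take], use.names = FALSE)
    mean(v)
  }, numeric(1))
  qs <- stats::quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(estimate = mean(d$correct), lower = qs[1], upper = qs[2],
                 n_resamples = n_resamples, unit = unit, seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("proportion correct %.3f, 95%% CI [%.3f, %.3f] (%d resamples by %s)\n",
              x$estimate, x$lower, x$upper, x$n_resamples, x$unit))
  invisible(x)
}
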