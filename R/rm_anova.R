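#' Repeated-measures mixed ANOVA on an MPP table
#'
#' Fits the study's inferential model: fixed effects for dose, epoch and
#' their interaction, plus a random intercept per animal (compound-symmetric
#' within-animal covariance), by REML via \pkg{lme4}. Model-based cell means
#' and pooled standard errors are derived from the fixed-effect estimates
#' and their covariance; omnibus Wald F tests (sum-to-zero coding, i.e.
#' marginal "type III" tests on this balanced design) use the residual
#' (within) degrees of freedom.
#'
#' Input must be balanced within animal: every animal observed at every
#' epoch exactly once, each animal in exactly one dose group. Unbalanced
#' tables raise an explicit error rather than being silently dropped.
#' With a single epoch the random intercept is unidentifiable (one
#' observation per animal) and an ordinary fixed-effects ANOVA is fitted
#' instead, which makes the classical t/F identities exact.
#'
#' @param table Data frame with columns `animal_id`, `dose` (numeric),
#'   `epoch` (canonical labels), and the response column.
#' @param response Response column name, default `"mpp"`.
#' @param alpha Significance level for the omnibus protection rule.
#' @return An `rm_anova_fit` with components `means` (dose x epoch
#'   model-based means and pooled SEs), `omnibus` (term, F, df1, df2, p),
#'   `within_epoch` (dose-within-epoch simple-effect F per epoch),
#'   `residuals`, `df_resid`, `varcomp`, `omnibus_significant`, and the
#'   fitted model.
#' @export
fit_rm_anova <- function(table, response = "mpp", alpha = 0.05) {
  need <- c("animal_id", "dose", "epoch", response)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- data.frame(animal_id = as.character(table$animal_id),
                   dose_value = as.numeric(table$dose),
                   epoch = as.character(table$epoch),
                   y = as.numeric(table[[response]]),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$y))) stop("non-finite response values", call. = FALSE)
  if (!all(df$epoch %in% EPOCH_LEVELS))
    stop("unknown epoch label(s) in table", call. = FALSE)
  epochs <- intersect(EPOCH_LEVELS, unique(df$epoch))
  dose_levels <- sort(unique(df$dose_value))
  if (length(dose_levels) < 2) stop("need >= 2 doses", call. = FALSE)
  # each animal in exactly one dose group
  a2d <- unique(df[c("animal_id", "dose_value")])
  if (anyDuplicated(a2d$animal_id))
    stop("an animal appears in more than one dose group", call. = FALSE)
  if (min(table(a2d$dose_value)) < 2)
    stop("need >= 2 animals per dose", call. = FALSE)
  # balanced epochs within animal
  tab <- table(df$animal_id, df$epoch)
  if (any(tab != 1)) {
    bad <- rownames(tab)[rowSums(tab != 1) > 0]
    stop("unbalanced design: animal(s) without exactly one row per epoch: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$dose <- factor(df$dose_value, levels = dose_levels)
  df$epoch <- factor(df$epoch, levels = epochs)
  df$animal_id <- factor(df$animal_id)
  # canonical row order: fit output must be invariant to input permutation
  df <- df[order(df$animal_id, df$epoch), , drop = FALSE]
  rownames(df) <- NULL

  one_epoch <- length(epochs) == 1L
  fixed <- if (one_epoch) y ~ dose else y ~ dose * epoch
  contrasts_arg <- if (one_epoch) list(dose = "contr.sum") else
    list(dose = "contr.sum", epoch = "contr.sum")
  trms <- terms(fixed)
  X <- model.matrix(fixed, df, contrasts.arg = contrasts_arg)
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effect design (rank deficient)", call. = FALSE)

  meta_one <- function(col) {
    v <- unique(as.character(table[[col]]))
    if (length(v) == 1) v else NA_character_
  }
  meta <- list(genotype = if ("genotype" %in% names(table)) meta_one("genotype") else NA_character_,
               drug = if ("drug" %in% names(table)) meta_one("drug") else NA_character_)

  degenerate <- var(df$y) == 0
  if (degenerate) {
    beta <- c(df$y[1], numeric(ncol(X) - 1L)); names(beta) <- colnames(X)
    V <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
    res <- numeric(nrow(df))
    varcomp <- c(animal = 0, residual = 0)
    model <- NULL
  } else if (one_epoch) {
    model <- lm(fixed, df, contrasts = contrasts_arg)
    beta <- coef(model)
    V <- vcov(model)
    res <- residuals(model)
    varcomp <- c(animal = NA_real_, residual = summary(model)$sigma^2)
  } else {
    mixed <- y ~ dose * epoch + (1 | animal_id)
    model <- lme4::lmer(mixed, data = df, REML = TRUE,
                        contrasts = contrasts_arg,
                        control = lme4::lmerControl(calc.derivs = FALSE))
    beta <- lme4::fixef(model)
    V <- as.matrix(vcov(model))
    res <- residuals(model)
    vc <- lme4::VarCorr(model)
    varcomp <- c(animal = as.numeric(vc$animal_id),
                 residual = attr(vc, "sc")^2)
  }
  df_resid <- nrow(df) - length(beta)
  # between-within df partitioning (split-plot convention): contrasts among
  # dose groups are between-animal and take the between-subject error df;
  # within-animal terms (epoch, dose:epoch) take the residual df. For
  # single-epoch lm fits the two coincide.
  df_between <- nlevels(df$animal_id) - length(dose_levels)

  # omnibus Wald F per fixed term
  asn <- attr(X, "assign")
  labels <- attr(trms, "term.labels")
  omnibus <- do.call(rbind, lapply(seq_along(labels), function(t) {
    idx <- which(asn == t)
    q <- length(idx)
    Fv <- if (degenerate) 0 else {
      b <- beta[idx]
      as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE], b)) / q
    }
    df2 <- if (labels[t] == "dose") df_between else df_resid
    data.frame(term = labels[t], F = Fv, df1 = q, df2 = df2,
               p = pf(Fv, q, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))

  # model-based cell means with pooled SEs
  grid <- expand.grid(dose = factor(dose_levels, levels = dose_levels),
                      epoch = factor(epochs, levels = epochs))
  Xg <- model.matrix(delete.response(trms), grid,
                     contrasts.arg = contrasts_arg)
  means <- data.frame(dose = as.numeric(as.character(grid$dose)),
                      epoch = as.character(grid$epoch),
                      mean = as.numeric(Xg %*% beta),
                      se = sqrt(pmax(rowSums((Xg %*% V) * Xg), 0)),
                      stringsAsFactors = FALSE)

  # dose-within-epoch simple-effect F per epoch (the second protection
  # layer): joint test of all dose-vs-vehicle contrasts at one epoch, free
  # of the baseline epoch's variance structure
  cellX <- function(d, e) {
    nd <- data.frame(dose = factor(d, levels = dose_levels),
                     epoch = factor(e, levels = epochs))
    model.matrix(delete.response(trms), nd, contrasts.arg = contrasts_arg)[1, ]
  }
  within_epoch <- do.call(rbind, lapply(epochs, function(e) {
    L <- t(vapply(dose_levels[-1],
                  function(d) cellX(d, e) - cellX(dose_levels[1], e),
                  numeric(length(beta))))
    q <- nrow(L)
    Fv <- if (degenerate) 0 else {
      lb <- as.numeric(L %*% beta)
      as.numeric(t(lb) %*% solve(L %*% V %*% t(L), lb)) / q
    }
    data.frame(epoch = e, F = Fv, df1 = q, df2 = df_between,
               p = pf(Fv, q, df_between, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))

  # protection gate, layer 1: the dose x epoch interaction F (a
  # within-animal contrast). The between-animal dose main effect is
  # deliberately NOT part of the gate: its Wald F with residual df runs
  # liberal and would leak null flags. Any real treatment pattern here is
  # an interaction by design (no dose effect pre-injection). Single-epoch
  # fits have no interaction and gate on the dose F itself.
  gate_term <- if ("dose:epoch" %in% omnibus$term) "dose:epoch" else "dose"
  omnibus_significant <- !degenerate &&
    omnibus$p[omnibus$term == gate_term] <= alpha

  structure(list(model = model, means = means, omnibus = omnibus,
                 within_epoch = within_epoch,
                 beta = beta, vcov = V, df_resid = df_resid,
                 df_between = df_between,
                 varcomp = varcomp, residuals = as.numeric(res),
                 data = df, terms = trms, contrasts = contrasts_arg,
                 dose_levels = dose_levels, epochs = epochs,
                 response = response, alpha = alpha,
                 omnibus_significant = omnibus_significant,
                 degenerate = degenerate, meta = meta),
            class = "rm_anova_fit")
}

#' @export
print.rm_anova_fit <- function(x, ...) {
  cat(sprintf("<rm_anova_fit> %s: %d doses x %d epochs, %d animals, %d obs\n",
              x$response, length(x$dose_levels), length(x$epochs),
              nlevels(x$data$animal_id), nrow(x$data)))
  cat(sprintf("  variance components: animal %.4g, residual %.4g; residual df %d\n",
              x$varcomp[["animal"]], x$varcomp[["residual"]], x$df_resid))
  print(x$omnibus, row.names = FALSE, digits = 4)
  invisible(x)
}

cell_contrast <- function(fit, dose, epoch) {
  nd <- data.frame(dose = factor(dose, levels = fit$dose_levels),
                   epoch = factor(epoch, levels = fit$epochs))
  model.matrix(delete.response(fit$terms), nd,
               contrasts.arg = fit$contrasts)[1, ]
}

#' Fisher-LSD comparison of a dose against a reference at one epoch
#'
#' Two-sided t-type comparison of model-based means, using the mixed model's
#' pooled standard error with between-animal (split-plot "between-within")
#' degrees of freedom, since dose contrasts compare disjoint groups of
#' animals. The protected-LSD
#' rule follows the classical omnibus / simple-effects / pairwise chain: a
#' comparison is flagged significant only when (1) the omnibus dose x epoch
#' interaction F, (2) the dose-within-epoch simple-effect F at the compared
#' epoch, and (3) the pairwise p are all significant at `alpha`.
#' Unprotected p-values are always reported.
#'
#' @param fit An [fit_rm_anova()] result.
#' @param epoch Epoch label present in the fit.
#' @param dose Dose to compare.
#' @param reference_dose Reference; defaults to the lowest dose (vehicle).
#' @param alpha Significance level; defaults to the fit's.
#' @return A `comparison_result`: mean difference, SE, t, df, p,
#'   `significant` flag.
#' @export
lsd_compare <- function(fit, epoch, dose, reference_dose = NULL,
                        alpha = fit$alpha) {
  stopifnot(inherits(fit, "rm_anova_fit"))
  if (is.null(reference_dose)) reference_dose <- min(fit$dose_levels)
  if (!epoch %in% fit$epochs)
    stop("epoch not in fit: ", epoch, call. = FALSE)
  if (!dose %in% fit$dose_levels || !reference_dose %in% fit$dose_levels)
    stop("dose not in fit: ", setdiff(c(dose, reference_dose),
                                      fit$dose_levels)[1], call. = FALSE)
  if (dose == reference_dose) {
    diff <- 0; se <- 0; tval <- 0; p <- 1
  } else {
    cc <- cell_contrast(fit, dose, epoch) - cell_contrast(fit, reference_dose, epoch)
    diff <- as.numeric(cc %*% fit$beta)
    se <- sqrt(max(as.numeric(t(cc) %*% fit$vcov %*% cc), 0))
    if (se == 0) { tval <- 0; p <- 1 }
    else {
      tval <- diff / se
      p <- 2 * pt(-abs(tval), fit$df_between)
    }
  }
  within_p <- fit$within_epoch$p[fit$within_epoch$epoch == epoch]
  structure(list(genotype = fit$meta$genotype, drug = fit$meta$drug,
                 epoch = epoch, dose = dose, reference_dose = reference_dose,
                 diff = diff, se = se, t = tval, df = fit$df_between, p = p,
                 significant = fit$omnibus_significant &&
                   within_p <= alpha && p <= alpha,
                 alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s: dose %s vs %s: diff %.3f +/- %.3f, t(%d) = %.3f, p = %.4g%s\n",
              x$epoch, format(x$dose), format(x$reference_dose), x$diff,
              x$se, x$df, x$t, x$p, if (x$significant) " *" else ""))
  invisible(x)
}

#' Residual normality diagnostics
#'
#' Shapiro-Wilk test plus normal quantile-plot coordinates for the fit's
#' residuals, the parametric-model check used before trusting the ANOVA
#' p-values. For more than 5000 residuals (the Shapiro-Wilk limit) an
#' evenly-thinned subset is tested.
#'
#' @param fit An [fit_rm_anova()] result.
#' @return A `normality_report`: `W`, `p_value`, and `qq` (data frame of
#'   theoretical vs observed quantiles).
#' @export
check_residual_normality <- function(fit) {
  stopifnot(inherits(fit, "rm_anova_fit"))
  r <- fit$residuals
  if (length(r) < 3) stop("need >= 3 residuals", call. = FALSE)
  if (sd(r) == 0)
    stop("degenerate sample: residuals are constant", call. = FALSE)
  r_test <- if (length(r) > 5000)
    r[round(seq(1, length(r), length.out = 5000))] else r
  sw <- shapiro.test(r_test)
  qq <- qqnorm(r, plot.it = FALSE)
  structure(list(W = unname(sw$statistic), p_value = sw$p.value,
                 qq = data.frame(theoretical = qq$x, observed = qq$y)),
            class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("<normality_report> Shapiro-Wilk W = %.4f, p = %.4g (n = %d)\n",
              x$W, x$p_value, nrow(x$qq)))
  invisible(x)
}

star_codes <- function(p, significant) {
  ifelse(!significant, "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p <= 0.05, "*", ""))))
}

#' Tabulate an experiment's effects
#'
#' Collects LSD comparisons into a results table mirroring the figure
#' annotations: per epoch and dose, the model-based mean with pooled SE, the
#' difference from vehicle, the LSD p-value and significance stars
#' (p < 0.05 / 0.01 / 0.001, shown only when the protected flag holds).
#'
#' @param fit An [fit_rm_anova()] result.
#' @param comparisons List of [lsd_compare()] results from that fit.
#' @return Data frame with columns `genotype, drug, epoch, dose,
#'   reference_dose, mean, pooled_se, diff_vs_vehicle, t, df, p, significant,
#'   stars`; header-only when `comparisons` is empty.
#' @export
summarize_experiment <- function(fit, comparisons = list()) {
  stopifnot(inherits(fit, "rm_anova_fit"))
  cols <- data.frame(genotype = character(), drug = character(),
                     epoch = character(), dose = numeric(),
                     reference_dose = numeric(), mean = numeric(),
                     pooled_se = numeric(), diff_vs_vehicle = numeric(),
                     t = numeric(), df = integer(), p = numeric(),
                     significant = logical(), stars = character(),
                     stringsAsFactors = FALSE)
  if (length(comparisons) == 0) return(cols)
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(inherits(cmp, "comparison_result"))
    m <- fit$means[fit$means$dose == cmp$dose & fit$means$epoch == cmp$epoch, ]
    data.frame(genotype = cmp$genotype, drug = cmp$drug, epoch = cmp$epoch,
               dose = cmp$dose, reference_dose = cmp$reference_dose,
               mean = m$mean, pooled_se = m$se, diff_vs_vehicle = cmp$diff,
               t = cmp$t, df = cmp$df, p = cmp$p,
               significant = cmp$significant,
               stars = star_codes(cmp$p, cmp$significant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$epoch, EPOCH_LEVELS), out$dose), ]
  rownames(out) <- NULL
  out
}

format_fit_summary <- function(fit, normality = NULL) {
  c(sprintf("Repeated-measures mixed ANOVA on %s", fit$response),
    sprintf("  genotype: %s, drug: %s", fit$meta$genotype, fit$meta$drug),
    sprintf("  %d doses x %d epochs, %d animals, %d observations",
            length(fit$dose_levels), length(fit$epochs),
            nlevels(fit$data$animal_id), nrow(fit$data)),
    sprintf("  variance components: animal %.5g, residual %.5g",
            fit$varcomp[["animal"]], fit$varcomp[["residual"]]),
    sprintf("  residual df: %d", fit$df_resid),
    "  omnibus Wald F tests:",
    sprintf("    %-12s F(%d, %d) = %8.3f, p = %.4g", fit$omnibus$term,
            fit$omnibus$df1, fit$omnibus$df2, fit$omnibus$F, fit$omnibus$p),
    if (!is.null(normality))
      sprintf("  residual normality: Shapiro-Wilk W = %.4f, p = %.4g",
              normality$W, normality$p_value))
}
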