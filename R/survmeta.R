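#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie correction (via
#' `survival::coxph`, convergence tolerance 1e-9, up to 50 iterations),
#' returning per-covariate hazard ratios with Wald 95% confidence intervals
#' and p-values. Monotone likelihood (separation) is flagged and the
#' coefficient capped.
#'
#' @param records data.frame with columns `time` (> 0), `event` (0/1) and
#'   the covariates.
#' @param covariates covariate column names; default all columns other than
#'   `sample`, `time`, `event`.
#' @return a `cox_fit` object: `table` (beta, se, HR, CI_low, CI_high, p),
#'   `loglik`, `n`, `n_events`.
#' @export
cox_fit <- function(records, covariates = NULL) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop("times must be > 0")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(records$event) < 1) stop("need at least one event")
  if (is.null(covariates))
    covariates <- setdiff(names(records), c("sample", "time", "event"))
  if (length(covariates) == 0) stop("no covariates")
  for (cv in covariates) {
    v <- records[[cv]]
    if (length(unique(v)) < 2) stop(sprintf("no variation in covariate '%s'", cv))
  }
  X <- model.matrix(~., data = records[, covariates, drop = FALSE])[, -1, drop = FALSE]
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("rank-deficient covariates (duplicated or collinear columns)")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  sep <- !is.na(beta) & abs(beta) > 15
  if (any(sep)) {
    warning("possible separation (monotone likelihood); coefficient capped: ",
            paste(names(beta)[sep], collapse = ", "))
    beta[sep] <- sign(beta[sep]) * 15
  }
  tab <- data.frame(term = names(beta), beta = beta, se = se,
                    HR = exp(beta),
                    CI_low = exp(beta - 1.96 * se),
                    CI_high = exp(beta + 1.96 * se),
                    p = 2 * pnorm(-abs(beta / se)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(table = tab, loglik = fit$loglik, n = fit$n,
              n_events = fit$nevent, separation = any(sep))
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox fit: n = %d, events = %d\n", x$n, x$n_events))
  tab <- x$table
  tab$HR <- signif(tab$HR, digits)
  tab$CI_low <- signif(tab$CI_low, digits)
  tab$CI_high <- signif(tab$CI_high, digits)
  tab$p <- signif(tab$p, digits)
  print(tab[, c("term", "HR", "CI_low", "CI_high", "p")], row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier estimate
#'
#' Product-limit survival curve; censored subjects leave the risk set after
#' their time.
#'
#' @param records data.frame with `time` and `event`.
#' @return data.frame (`time`, `surv`, `n_risk`, `n_event`), a right-
#'   continuous non-increasing step function with S(0) = 1.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
             n_event = sf$n.event)
}

fp_terms <- function(x, powers) {
  out <- lapply(seq_along(powers), function(i) {
    p <- powers[i]
    v <- if (p == 0) log(x) else x^p
    if (i == 2 && powers[1] == powers[2]) v <- v * log(x)
    v
  })
  mat <- do.call(cbind, out)
  colnames(mat) <- paste0("fp", seq_along(powers))
  mat
}

#' Fractional-polynomial Cox hazard shape for a continuous covariate
#'
#' Candidate powers {-2, -1, -0.5, 0, 0.5, 1, 2, 3} (0 meaning log; a
#' repeated power p contributes x^p and x^p log x). With `df = 4` the best
#' two-term (FP2) model is found and reduced by the standard closed-test
#' sequence at level `alpha`: FP2 vs no-x (4 df), FP2 vs linear (3 df), FP2
#' vs best FP1 (2 df), each by partial-likelihood ratio. The fitted relative
#' hazard over x is normalized to 1 at the median of x.
#'
#' @param records survival data.frame (`time`, `event`, covariates).
#' @param x_name continuous covariate of interest (>= 5 distinct values;
#'   shifted positive internally if needed).
#' @param adjusters additional covariates always kept in the model.
#' @param df degrees of freedom of the FP search (4 = FP2).
#' @param alpha level of the closed test.
#' @return an `fp_hazard` object: selected `powers` (NULL if x dropped,
#'   `1` if linear), `p_overall` (FP2 vs null), the closed-test table and a
#'   `curve` data.frame (x, relative hazard).
#' @export
fp_hazard_shape <- function(records, x_name, adjusters = character(0),
                            df = 4, alpha = 0.05) {
  x <- records[[x_name]]
  if (length(unique(x)) < 5) stop("need >= 5 distinct covariate values")
  shift <- if (min(x) <= 0) -min(x) + 1 else 0
  xs <- x + shift
  if (min(xs) <= 0) stop("covariate not positive after shift")
  powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  dev <- function(terms) {
    dat <- cbind(records[, c("time", "event", adjusters), drop = FALSE],
                 as.data.frame(terms))
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(c(sprintf("`%s`", adjusters), colnames(terms)), collapse = " + ")))
    fit <- survival::coxph(fml, data = dat, ties = "efron")
    -2 * fit$loglik[length(fit$loglik)]
  }
  null_dev <- if (length(adjusters)) {
    dat <- records[, c("time", "event", adjusters), drop = FALSE]
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(sprintf("`%s`", adjusters), collapse = " + ")))
    -2 * survival::coxph(fml, data = dat, ties = "efron")$loglik[2]
  } else {
    f0 <- survival::coxph(survival::Surv(time, event) ~ 1, data = records)
    -2 * f0$loglik[1]
  }
  # best FP1
  fp1 <- lapply(powers, function(p) list(powers = p, dev = dev(fp_terms(xs, p))))
  best1 <- fp1[[which.min(vapply(fp1, `[[`, numeric(1), "dev"))]]
  # best FP2 over unordered pairs incl. repeats
  pairs <- subset(expand.grid(p1 = powers, p2 = powers), p1 <= p2)
  fp2 <- lapply(seq_len(nrow(pairs)), function(i) {
    pw <- c(pairs$p1[i], pairs$p2[i])
    list(powers = pw, dev = dev(fp_terms(xs, pw)))
  })
  best2 <- fp2[[which.min(vapply(fp2, `[[`, numeric(1), "dev"))]]
  lin_dev <- dev(fp_terms(xs, 1))
  p_null <- pchisq(null_dev - best2$dev, df = 4, lower.tail = FALSE)
  p_lin <- pchisq(lin_dev - best2$dev, df = 3, lower.tail = FALSE)
  p_fp1 <- pchisq(best1$dev - best2$dev, df = 2, lower.tail = FALSE)
  sel <- if (p_null >= alpha) NULL
  else if (p_lin >= alpha) 1
  else if (p_fp1 >= alpha) best1$powers
  else best2$powers
  grid <- seq(min(xs), max(xs), length.out = 100)
  curve <- data.frame(x = grid - shift, rel_hazard = 1)
  if (!is.null(sel)) {
    terms <- fp_terms(xs, sel)
    dat <- cbind(records[, c("time", "event", adjusters), drop = FALSE],
                 as.data.frame(terms))
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(c(sprintf("`%s`", adjusters), colnames(terms)), collapse = " + ")))
    fit <- survival::coxph(fml, data = dat, ties = "efron")
    b <- coef(fit)[colnames(terms)]
    lp <- drop(fp_terms(grid, sel) %*% b)
    lp_med <- drop(fp_terms(median(xs), sel) %*% b)
    curve$rel_hazard <- exp(lp - lp_med)
  }
  out <- list(powers = sel, p_overall = p_null,
              closed_test = data.frame(
                comparison = c("FP2 vs null", "FP2 vs linear", "FP2 vs FP1"),
                df = c(4, 3, 2), p = c(p_null, p_lin, p_fp1)),
              best_fp2 = best2$powers, best_fp1 = best1$powers,
              shift = shift, curve = curve)
  class(out) <- "fp_hazard"
  out
}

#' @export
print.fp_hazard <- function(x, ...) {
  sel <- if (is.null(x$powers)) "none (x dropped)" else
    paste(x$powers, collapse = ", ")
  cat(sprintf("fractional-polynomial Cox shape: selected powers = %s (overall p = %.3g)\n",
              sel, x$p_overall))
  invisible(x)
}

#' Fixed-effect (inverse-variance) meta-analysis of log hazard ratios
#'
#' Weights `w_i = SE_i^-2`; combined `logHR = sum(w logHR) / sum(w)` with
#' `SE = sum(w)^-1/2` and a z-based p-value. `method = "DL"` adds the
#' DerSimonian-Laird between-study variance to the weights.
#'
#' @param studies data.frame with columns `logHR`, `SE` (and optionally
#'   `study` labels).
#' @param method `"fixed"` or `"DL"`.
#' @return a `meta_result`: per-study table and combined estimate
#'   (`logHR`, `SE`, `HR`, `CI_low`, `CI_high`, `p`).
#' @export
meta_fixed <- function(studies, method = c("fixed", "DL")) {
  method <- match.arg(method)
  stopifnot(all(c("logHR", "SE") %in% names(studies)))
  if (any(studies$SE <= 0)) stop("SE must be > 0")
  if (nrow(studies) < 2) {
    warning("single study: combined estimate equals the study")
  }
  w <- studies$SE^-2
  tau2 <- 0
  if (method == "DL" && nrow(studies) >= 2) {
    ybar <- sum(w * studies$logHR) / sum(w)
    Q <- sum(w * (studies$logHR - ybar)^2)
    k <- nrow(studies)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w <- 1 / (studies$SE^2 + tau2)
  }
  est <- sum(w * studies$logHR) / sum(w)
  se <- sum(w)^-0.5
  out <- list(studies = studies, method = method, tau2 = tau2,
              combined = data.frame(
                logHR = est, SE = se, HR = exp(est),
                CI_low = exp(est - 1.96 * se), CI_high = exp(est + 1.96 * se),
                p = 2 * pnorm(-abs(est / se))))
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effect meta-analysis of %d studies\n",
              if (x$method == "fixed") "fixed" else "random (DL)",
              nrow(x$studies)))
  with(x$combined, cat(sprintf(
    "  combined HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    HR, CI_low, CI_high, p)))
  invisible(x)
}

#' Forest-plot data for a meta-analysis
#'
#' Per-study and combined rows in one table, suitable for TSV export.
#'
#' @param x a `meta_result`.
#' @return data.frame (`study`, `logHR`, `SE`, `HR`, `CI_low`, `CI_high`).
#' @export
forest_data <- function(x) {
  stopifnot(inherits(x, "meta_result"))
  st <- x$studies
  lab <- if ("study" %in% names(st)) as.character(st$study) else
    paste0("study", seq_len(nrow(st)))
  rbind(
    data.frame(study = lab, logHR = st$logHR, SE = st$SE, HR = exp(st$logHR),
               CI_low = exp(st$logHR - 1.96 * st$SE),
               CI_high = exp(st$logHR + 1.96 * st$SE)),
    data.frame(study = "combined", logHR = x$combined$logHR,
               SE = x$combined$SE, HR = x$combined$HR,
               CI_low = x$combined$CI_low, CI_high = x$combined$CI_high))
}

#' Cohen's kappa for inter-rater agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` from a square cross-tabulation of two
#' raters.
#'
#' @param table square contingency matrix.
#' @return kappa.
#' @export
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table)) stop("table must be square")
  tot <- sum(table)
  if (tot <= 0) stop("empty table")
  po <- sum(diag(table)) / tot
  pe <- sum(rowSums(table) * colSums(table)) / tot^2
  if (pe >= 1) stop("kappa undefined: expected agreement is 1")
  (po - pe) / (1 - pe)
}

#' Overall and trend tests for a 2 x K clinical table
#'
#' Overall association by Pearson chi-square (K - 1 df, no continuity
#' correction); ordered trend by the Cochran-Armitage test with the given
#' ordinal scores (two-sided).
#'
#' @param table 2 x K count matrix (rows: outcome; columns: ordered groups).
#' @param scores K ordinal scores, default equally spaced `0:(K-1)`.
#' @return list with `chi2_p` and `trend_p`.
#' @export
contingency_tests <- function(table, scores = NULL) {
  table <- as.matrix(table)
  if (nrow(table) != 2) stop("table must have 2 rows")
  if (any(table < 0)) stop("negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin")
  if (is.null(scores)) scores <- seq_len(ncol(table)) - 1
  chi2_p <- suppressWarnings(chisq.test(table, correct = FALSE)$p.value)
  tr <- suppressWarnings(prop.trend.test(table[2, ], colSums(table),
                                         score = scores))
  list(chi2_p = chi2_p, trend_p = tr$p.value)
}

#' Column percentages of a clinical cross-tabulation
#'
#' Percentage of each cell within its column, as printed in
#' clinicopathologic characteristics tables.
#'
#' @param counts count matrix.
#' @param digits rounding digits.
#' @return matrix of percentages.
#' @export
column_percent <- function(counts, digits = 1) {
  counts <- as.matrix(counts)
  round(sweep(counts, 2, colSums(counts), "/") * 100, digits)
}
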