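# Validation statistics: agreement between scoring variants, ROC/AUC with
# DeLong inference, Kruskal-Wallis group contrasts, and the logistic
# combination of HMR with defect scores.

as_case_logical <- function(labels, case = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.null(case)) {
    if (is.numeric(labels) && all(labels %in% c(0, 1)))
      return(labels == 1)
    stop("labels must be logical, 0/1, or accompanied by a 'case' level",
         call. = FALSE)
  }
  as.character(labels) == case
}

#' Agreement between two paired score series
#'
#' Pearson linear correlation plus Bland-Altman statistics of the paired
#' differences `x - y`: mean difference and 95% limits of agreement
#' (mean +/- 1.96 SD of the differences).
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @return An object of class `agreement_result`: `r`, `mean_diff`,
#'   `loa_lower`, `loa_upper`, `n`. `r` is `NA` (with a warning) when
#'   either series is constant; the limits of agreement are still returned.
#' @export
agreement <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must be paired (equal length)", call. = FALSE)
  if (length(x) < 3L || anyNA(x) || anyNA(y))
    stop("agreement needs >= 3 complete pairs", call. = FALSE)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for a constant series", call. = FALSE)
    NA_real_
  } else stats::cor(x, y)
  d <- x - y
  md <- mean(d)
  s <- stats::sd(d)
  structure(list(r = r, mean_diff = md,
                 loa_lower = md - 1.96 * s, loa_upper = md + 1.96 * s,
                 n = length(x)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "agreement (n = %d): r = %.3f; mean difference %.3f; 95%% LOA %.3f to %.3f\n",
    x$n, x$r, x$mean_diff, x$loa_lower, x$loa_upper))
  invisible(x)
}

# Mann-Whitney placement values of cases against controls (ties count 1/2);
# the backbone of the empirical AUC and of DeLong variance/covariance.
delong_placements <- function(cases, controls) {
  psi <- outer(cases, controls,
               function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi),   # one per case
       v01 = colMeans(psi),   # one per control
       auc = mean(psi))
}

orient_marker <- function(values, direction) {
  if (direction == "<") -values else values
}

#' ROC analysis of a diagnostic marker
#'
#' Empirical ROC: the AUC is the Mann-Whitney probability that a random
#' case outranks a random control (ties count 1/2), its 95% CI uses the
#' DeLong variance, and the default operating point maximizes the Youden
#' index (sensitivity + specificity - 1), with ties resolved towards the
#' more specific cutoff.
#'
#' @param values Marker values.
#' @param labels Case/control labels: logical (`TRUE` = case), 0/1, or any
#'   vector with `case` naming the case level.
#' @param direction `">"` if cases take higher marker values (defect
#'   scores), `"<"` if lower (HMR).
#' @param case Case level when `labels` is not logical/0-1.
#' @return An object of class `roc_result`: `auc`, `ci` (length 2),
#'   `cutoff`, `sensitivity`, `specificity`, `accuracy`, `direction`,
#'   `n_cases`, `n_controls`. A positive call is `value >= cutoff` when
#'   `direction == ">"` and `value <= cutoff` otherwise.
#' @export
roc <- function(values, labels, direction = c(">", "<"), case = NULL) {
  direction <- match.arg(direction)
  values <- as.numeric(values)
  is_case <- as_case_logical(labels, case)
  if (length(values) != length(is_case) || anyNA(values) || anyNA(is_case))
    stop("values and labels must be complete and of equal length",
         call. = FALSE)
  m <- sum(is_case); n <- sum(!is_case)
  if (m == 0L || n == 0L)
    stop("degenerate labels: need at least one case and one control",
         call. = FALSE)
  v <- orient_marker(values, direction)
  pl <- delong_placements(v[is_case], v[!is_case])
  auc_var <- (if (m > 1) stats::var(pl$v10) else 0) / m +
             (if (n > 1) stats::var(pl$v01) else 0) / n
  ci <- pmin(pmax(pl$auc + c(-1, 1) * 1.96 * sqrt(auc_var), 0), 1)
  # operating points: positive iff oriented value >= t
  thr <- sort(unique(v))
  sens <- vapply(thr, function(t) mean(v[is_case] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(v[!is_case] < t), numeric(1))
  youden <- sens + spec - 1
  best <- max(which(youden == max(youden)))   # ties -> more specific cutoff
  cutoff <- if (direction == "<") -thr[best] else thr[best]
  acc <- (sens[best] * m + spec[best] * n) / (m + n)
  structure(list(auc = pl$auc, ci = ci, var = auc_var, cutoff = cutoff,
                 sensitivity = sens[best], specificity = spec[best],
                 accuracy = acc, direction = direction,
                 n_cases = m, n_controls = n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC (%d cases / %d controls): AUC %.3f (95%% CI %.3f-%.3f)\n",
    x$n_cases, x$n_controls, x$auc, x$ci[1], x$ci[2]))
  cat(sprintf(
    "  cutoff %s %.4g: sensitivity %.0f%%, specificity %.0f%%, accuracy %.0f%%\n",
    if (x$direction == ">") ">=" else "<=", x$cutoff,
    100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

#' DeLong test comparing two paired AUCs
#'
#' Tests the AUC difference of two markers measured on the same subjects,
#' using the covariance of their Mann-Whitney placement values. Symmetric
#' in the two markers.
#'
#' @param values_a,values_b Paired marker values on identical subjects.
#' @param labels,case As in [roc()].
#' @param direction_a,direction_b Orientation of each marker.
#' @return List with `auc_a`, `auc_b`, `delta`, `z`, `p`. Identical
#'   oriented markers give `p = 1`.
#' @export
compare_rocs <- function(values_a, values_b, labels,
                         direction_a = ">", direction_b = ">",
                         case = NULL) {
  a <- orient_marker(as.numeric(values_a), match.arg(direction_a, c(">", "<")))
  b <- orient_marker(as.numeric(values_b), match.arg(direction_b, c(">", "<")))
  is_case <- as_case_logical(labels, case)
  if (length(a) != length(b) || length(a) != length(is_case))
    stop("pairing error: markers and labels must align subject by subject",
         call. = FALSE)
  m <- sum(is_case); n <- sum(!is_case)
  if (m < 2L || n < 2L)
    stop("need >= 2 cases and >= 2 controls for the paired test",
         call. = FALSE)
  pa <- delong_placements(a[is_case], a[!is_case])
  pb <- delong_placements(b[is_case], b[!is_case])
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
               (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (var_delta <= 0) {
    z <- 0
    p <- if (abs(delta) < 1e-12) 1 else 0
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z, p = p)
}

#' Kruskal-Wallis contrast of a marker across disease groups
#'
#' Wraps the tie-corrected Kruskal-Wallis rank test and adds per-group
#' summaries plus Holm-adjusted pairwise Wilcoxon flags.
#'
#' @param values Marker values.
#' @param groups Group labels (>= 2 groups, each non-empty).
#' @param alpha Significance level for the flags.
#' @param pairwise Compute Holm-adjusted pairwise Wilcoxon flags? Disable
#'   for large simulation loops where only the omnibus test matters.
#' @return An object of class `group_contrast`: `H`, `df`, `p`,
#'   `summaries` (per-group n/mean/median/sd), `pairwise` (data frame of
#'   pairs with adjusted p and flag), `significant`.
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05, pairwise = TRUE) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("grouping error: need >= 2 groups", call. = FALSE)
  if (any(table(groups) == 0L))
    stop("grouping error: empty group", call. = FALSE)
  if (length(unique(values)) == 1L) {
    # all observations tied: no evidence of any group shift
    kt <- list(statistic = c(H = 0), parameter = c(df = nlevels(groups) - 1),
               p.value = 1)
  } else {
    kt <- stats::kruskal.test(values, groups)
  }
  sm <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               median = stats::median(v), sd = stats::sd(v))
  }))
  pw <- NULL
  if (pairwise && all(table(groups) >= 2L)) {
    pt <- suppressWarnings(
      stats::pairwise.wilcox.test(values, groups, p.adjust.method = "holm",
                                  exact = FALSE))$p.value
    idx <- which(!is.na(pt), arr.ind = TRUE)
    pw <- data.frame(group_a = rownames(pt)[idx[, 1]],
                     group_b = colnames(pt)[idx[, 2]],
                     p_adj = pt[idx])
    pw$significant <- pw$p_adj < alpha
  }
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, summaries = sm, pairwise = pw,
                 significant = kt$p.value < alpha),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g%s\n",
              x$H, x$df, x$p, if (x$significant) " *" else ""))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Combine HMR and defect score in a multivariable logistic model
#'
#' Maximum-likelihood logistic regression of case status on the HMR and a
#' summed defect score (fitted by iteratively reweighted least squares via
#' `stats::glm`). The in-sample predicted probability serves as the
#' combined diagnostic marker, e.g. for a subsequent [roc()] call. The two
#' nested single-predictor deviances are reported for comparison; the
#' combined deviance can never exceed either.
#'
#' @param hmr Standardized HMR per subject.
#' @param score Summed defect score per subject.
#' @param labels,case As in [roc()].
#' @return An object of class `combined_model`: `coefficients` (intercept,
#'   hmr, score), `fitted` (probabilities), `deviance`, `deviance_hmr`,
#'   `deviance_score`, `converged`, `separation`, `n`.
#' @export
fit_combined <- function(hmr, score, labels, case = NULL) {
  y <- as_case_logical(labels, case)
  hmr <- as.numeric(hmr); score <- as.numeric(score)
  if (anyNA(hmr) || anyNA(score) || anyNA(y))
    stop("no missing values allowed", call. = FALSE)
  if (stats::sd(hmr) == 0 || stats::sd(score) == 0)
    stop("both predictors must be non-constant", call. = FALSE)
  df <- data.frame(y = y, hmr = hmr, score = score)
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  fit <- withCallingHandlers(
    stats::glm(y ~ hmr + score, family = stats::binomial(), data = df,
               control = ctrl),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!fit$converged)
    stop("logistic fit did not converge", call. = FALSE)
  p <- stats::fitted(fit)
  separation <- all(p[y] > 1 - 1e-6) && all(p[!y] < 1e-6)
  if (separation)
    warning("perfect separation detected; coefficients are unstable",
            call. = FALSE)
  fit1 <- withCallingHandlers(
    stats::glm(y ~ hmr, family = stats::binomial(), data = df,
               control = ctrl),
    warning = function(w) invokeRestart("muffleWarning"))
  fit2 <- withCallingHandlers(
    stats::glm(y ~ score, family = stats::binomial(), data = df,
               control = ctrl),
    warning = function(w) invokeRestart("muffleWarning"))
  structure(list(coefficients = stats::setNames(stats::coef(fit),
                                                c("intercept", "hmr",
                                                  "score")),
                 fitted = as.numeric(p),
                 deviance = stats::deviance(fit),
                 deviance_hmr = stats::deviance(fit1),
                 deviance_score = stats::deviance(fit2),
                 converged = fit$converged, separation = separation,
                 n = length(y)),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat(sprintf("combined logistic model (n = %d)%s\n", x$n,
              if (x$separation) " [perfect separation]" else ""))
  print(round(x$coefficients, 4))
  cat(sprintf("deviance: combined %.2f | HMR only %.2f | score only %.2f\n",
              x$deviance, x$deviance_hmr, x$deviance_score))
  invisible(x)
}
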