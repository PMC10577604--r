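# Association layer: rank-sum group comparisons with Benjamini-Hochberg
# correction, median-split Kaplan-Meier with log-rank tests, Spearman
# correlation, and multivariate Cox regression against FLIPI.

#' Two-sided unpaired rank-sum comparison of two groups
#'
#' The Wilcoxon rank-sum (Mann-Whitney) test. When both groups have at most
#' `exact_max` observations the two-sided p value is computed by full
#' enumeration of all arrangements of the pooled (tie-averaged) ranks,
#' measuring extremity as the deviation of the rank sum from its null
#' expectation; otherwise the tie-corrected normal approximation of
#' [stats::wilcox.test()] is used.
#'
#' @param x,y Numeric vectors (missing values removed).
#' @param exact_max Enumeration cutoff per group.
#' @return List of class `fl_test`: `statistic` (rank sum of `x`), `p`,
#'   `method`, group medians and sizes.
#' @export
compare_groups <- function(x, y, exact_max = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("a group is empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    EW <- n1 * (N + 1) / 2
    sums <- utils::combn(N, n1, FUN = function(i) sum(r[i]))
    p <- mean(abs(sums - EW) >= abs(W - EW) - 1e-9)
    method <- "exact enumeration"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    method <- "normal approximation (tie-corrected)"
  }
  structure(list(statistic = W, p = p, method = method,
                 median_x = stats::median(x), median_y = stats::median(y),
                 n = c(n1, n2)),
            class = "fl_test")
}

#' @export
print.fl_test <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): W = %g, p = %.4g\n", x$method,
              x$statistic, x$p))
  cat(sprintf("  medians %.4g vs %.4g (n = %d, %d)\n", x$median_x,
              x$median_y, x$n[1L], x$n[2L]))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement;
#' order-preserving. Inputs outside (0, 1] are an error.
#'
#' @param p Vector of raw p values.
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Exact p for n <= 9 without ties, t approximation otherwise.
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @return List: `r`, `p`, `n`; `r` is `NA` for constant input.
#' @export
spearman_assoc <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  ties <- anyDuplicated(x) || anyDuplicated(y)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (length(x) <= 9L && !ties)))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-group log-rank test
#'
#' The standard (unweighted) log-rank statistic, with the chi-squared
#' p value or a label-permutation p value.
#'
#' @param time,event Survival times and event indicators (1 = event).
#' @param group Two-level grouping vector.
#' @param p_method `"asymptotic"` or `"permutation"`.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation draw.
#' @return List: `chisq`, `p`, observed/expected events per group.
#' @export
logrank_test <- function(time, event, group, p_method = c("asymptotic",
                                                          "permutation"),
                         n_perm = 10000L, seed = 1L) {
  p_method <- match.arg(p_method)
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2L) stop("group must have exactly two levels")
  stat <- logrank_chisq(time, event, g)
  if (p_method == "asymptotic") {
    p <- stats::pchisq(stat$chisq, df = 1L, lower.tail = FALSE)
  } else {
    p <- withr::with_seed(as.integer(seed), {
      hits <- sum(replicate(n_perm,
        logrank_chisq(time, event, sample(g))$chisq >= stat$chisq - 1e-12))
      (1 + hits) / (1 + n_perm)
    })
  }
  c(stat, list(p = p, p_method = p_method))
}

logrank_chisq <- function(time, event, g) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; g <- g[ord]
  ut <- unique(time[event == 1L])
  O1 <- E1 <- V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1L)
    d <- sum(event == 1L & time == t)
    d1 <- sum(event == 1L & time == t & g == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1L) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1L)
  }
  chisq <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chisq = chisq, observed = O1, expected = E1, var = V)
}

#' Median-split survival comparison
#'
#' Patients with feature value above the cohort median form the high arm,
#' the rest (ties included) the low arm; with even n and distinct values the
#' split is exactly 50/50. Kaplan-Meier curves are estimated per arm and the
#' arms compared by a two-tailed log-rank test.
#'
#' @param values Per-patient feature values.
#' @param time,event Survival endpoint (e.g. time to progression in years).
#' @param p_method,n_perm,seed Passed to [logrank_test()].
#' @return Object of class `fl_km`: `arm` factor, `fit`
#'   ([survival::survfit()] on the two arms), `logrank`, per-arm median
#'   survival (NA when not reached).
#' @export
median_split_km <- function(values, time, event,
                            p_method = "asymptotic", n_perm = 10000L,
                            seed = 1L) {
  if (length(unique(stats::na.omit(values))) < 2L)
    stop("degenerate split: all feature values equal")
  med <- stats::median(values, na.rm = TRUE)
  arm <- factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
  if (min(table(arm)) < 2L) stop("fewer than 2 patients in an arm")
  fit <- survival::survfit(survival::Surv(time, event) ~ arm)
  lr <- logrank_test(time, event, arm, p_method = p_method,
                     n_perm = n_perm, seed = seed)
  med_surv <- summary(fit)$table[, "median"]
  structure(list(arm = arm, median_cut = med, fit = fit, logrank = lr,
                 median_survival = med_surv,
                 time = time, event = event),
            class = "fl_km")
}

#' @export
print.fl_km <- function(x, ...) {
  cat(sprintf("Median-split survival comparison (cut at %.4g)\n", x$median_cut))
  cat(sprintf("  arms: low n = %d, high n = %d\n", sum(x$arm == "low"),
              sum(x$arm == "high")))
  cat(sprintf("  log-rank chi-squared = %.3f, p = %.4g (%s)\n",
              x$logrank$chisq, x$logrank$p, x$logrank$p_method))
  invisible(x)
}

#' @export
plot.fl_km <- function(x, xlab = "Time (years)",
                       ylab = "Progression-free fraction", ...) {
  graphics::plot(x$fit, col = c("#D55E00", "#0072B2"), lwd = 2,
                 xlab = xlab, ylab = ylab, ...)
  graphics::legend("bottomleft", legend = levels(x$arm),
                   col = c("#D55E00", "#0072B2"), lwd = 2, bty = "n")
  graphics::mtext(sprintf("log-rank p = %.3g", x$logrank$p), side = 3,
                  adj = 1, cex = 0.8)
  invisible(x)
}

#' Multivariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit (Efron tie handling) via [survival::coxph()],
#' reporting hazard ratios with Wald 95% confidence intervals. FLIPI enters
#' as an ordinal 0/1/2 score by default, or one-hot encoded.
#'
#' @param features Data frame of continuous covariates (one column each).
#' @param time,event Survival endpoint.
#' @param flipi Optional factor/character with levels low/intermediate/high.
#' @param flipi_encoding `"ordinal"` or `"onehot"`.
#' @return Object of class `fl_cox`: coefficient table (coef, hr, ci_lo,
#'   ci_hi, p), `n`, `n_events`, `converged` flag.
#' @export
cox_multivariate <- function(features, time, event, flipi = NULL,
                             flipi_encoding = c("ordinal", "onehot")) {
  flipi_encoding <- match.arg(flipi_encoding)
  dat <- as.data.frame(features)
  if (!is.null(flipi)) {
    flipi <- factor(flipi, levels = c("low", "intermediate", "high"))
    if (any(is.na(flipi))) stop("flipi must be low/intermediate/high")
    if (flipi_encoding == "ordinal") dat$flipi <- as.integer(flipi) - 1L
    else {
      dat$flipi_intermediate <- as.integer(flipi == "intermediate")
      dat$flipi_high <- as.integer(flipi == "high")
    }
  }
  n_events <- sum(event == 1L)
  if (n_events < ncol(dat) + 1L)
    stop("too few events (", n_events, ") for ", ncol(dat), " covariates")
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ .,
                    data = cbind(dat, time = time, event = event)[,
                      c(names(dat), "time", "event")],
                    ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lo = s$conf.int[, "lower .95"],
                    ci_hi = s$conf.int[, "upper .95"],
                    se = s$coefficients[, "se(coef)"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(list(table = tab, n = length(time), n_events = n_events,
                 converged = converged, fit = fit),
            class = "fl_cox")
}

#' @export
print.fl_cox <- function(x, ...) {
  cat(sprintf("Multivariate Cox regression: n = %d, events = %d%s\n", x$n,
              x$n_events,
              if (!x$converged) "  [WARNING: did not converge cleanly]" else ""))
  tab <- x$table
  tab$hr <- signif(tab$hr, 3); tab$ci_lo <- signif(tab$ci_lo, 3)
  tab$ci_hi <- signif(tab$ci_hi, 3); tab$p <- signif(tab$p, 3)
  print(tab[, c("term", "coef", "hr", "ci_lo", "ci_hi", "p")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the full association suite over per-patient features
#'
#' For every feature x compartment: (i) rank-sum comparison of relapsed
#' versus non-relapsed patients, BH-corrected within the feature's family
#' per compartment (densities and co-localizations form separate families);
#' (ii) median-split Kaplan-Meier with log-rank; (iii) Cox regression of the
#' feature (continuous) plus FLIPI; when several features are supplied, a
#' joint Cox model with all of the compartment's features plus FLIPI is
#' also fitted. Features missing in more than half the patients are dropped
#' with a warning; missing values are excluded pairwise per test.
#'
#' @param data Data frame with patient_id, ttp_years, event, flipi and
#'   feature columns named `<feature>_<compartment>`.
#' @param features Character vector of feature base names.
#' @param compartments Compartments to analyze.
#' @param families Optional named character vector feature -> family; by
#'   default features whose name starts with `"mh"` form the
#'   `"colocalization"` family and the rest the `"density"` family.
#' @return Data frame of class `fl_associations`, one row per feature x
#'   compartment, with test statistics, BH-adjusted p values, log-rank p
#'   and Cox hazard ratios; BH family metadata is attached as an attribute.
#' @export
run_association_suite <- function(data, features,
                                  compartments = c("intra", "inter"),
                                  families = NULL) {
  stopifnot(nrow(data) >= 10L, sum(data$event) >= 1L)
  if (is.null(families))
    families <- stats::setNames(
      ifelse(startsWith(features, "mh"), "colocalization", "density"),
      features)
  rows <- list()
  for (comp in compartments) {
    for (f in features) {
      col <- paste0(f, "_", comp)
      if (!col %in% names(data)) stop("missing feature column: ", col)
      v <- data[[col]]
      if (mean(is.na(v)) > 0.5) {
        warning("feature ", col, " dropped: >50% missing")
        next
      }
      ok <- !is.na(v)
      cg <- compare_groups(v[ok & data$event == 1L], v[ok & data$event == 0L])
      km <- tryCatch(
        median_split_km(v[ok], data$ttp_years[ok], data$event[ok]),
        error = function(e) NULL)
      cx <- tryCatch(
        cox_multivariate(stats::setNames(data.frame(v[ok]), f),
                         data$ttp_years[ok], data$event[ok],
                         flipi = data$flipi[ok]),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, compartment = comp, family = unname(families[f]),
        n = sum(ok),
        median_relapse = cg$median_x, median_no_relapse = cg$median_y,
        statistic = cg$statistic, p_raw = cg$p,
        logrank_p = if (is.null(km)) NA_real_ else km$logrank$p,
        cox_hr = if (is.null(cx)) NA_real_ else cx$table$hr[1L],
        cox_ci_lo = if (is.null(cx)) NA_real_ else cx$table$ci_lo[1L],
        cox_ci_hi = if (is.null(cx)) NA_real_ else cx$table$ci_hi[1L],
        cox_p = if (is.null(cx)) NA_real_ else cx$table$p[1L],
        cox_converged = if (is.null(cx)) NA else cx$converged)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  for (comp in unique(out$compartment)) for (fam in unique(out$family)) {
    sel <- out$compartment == comp & out$family == fam
    if (any(sel)) out$p_bh[sel] <- bh_adjust(out$p_raw[sel])
  }
  # joint model: all of a compartment's features plus FLIPI
  out$cox_joint_hr <- out$cox_joint_p <- NA_real_
  if (length(features) >= 2L) {
    for (comp in compartments) {
      cols <- paste0(features, "_", comp)
      cols <- cols[cols %in% names(data)]
      ok <- stats::complete.cases(data[, cols, drop = FALSE])
      cx <- tryCatch(
        cox_multivariate(stats::setNames(data[ok, cols, drop = FALSE],
                                         features),
                         data$ttp_years[ok], data$event[ok],
                         flipi = data$flipi[ok]),
        error = function(e) NULL)
      if (!is.null(cx)) {
        for (i in seq_along(features)) {
          sel <- out$feature == features[i] & out$compartment == comp
          out$cox_joint_hr[sel] <- cx$table$hr[i]
          out$cox_joint_p[sel] <- cx$table$p[i]
        }
      }
    }
  }
  attr(out, "bh_family_rule") <-
    "BH applied within family x compartment (densities and co-localizations separately)"
  class(out) <- c("fl_associations", class(out))
  out
}

#' @export
plot.fl_associations <- function(x, alpha = 0.05, ...) {
  lab <- paste(x$feature, x$compartment, sep = "\n")
  lp <- -log10(x$p_bh)
  bp <- graphics::barplot(lp, names.arg = lab, las = 2, cex.names = 0.7,
                          ylab = expression(-log[10] ~ "BH-adjusted p"),
                          col = ifelse(x$p_bh < alpha, "#D55E00", "grey70"),
                          ...)
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(bp)
}
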