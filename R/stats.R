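#' Aggregate a climate grid to spatial units
#'
#' Unweighted mean of the grid cells whose centers fall inside each unit;
#' units containing no cell centers are kept with NA values and flagged.
#'
#' @param grid a `climate_grid`.
#' @param regions one `region_lattice`, or a named list of them.
#' @return data frame `scale, unit, bio1, bio12, n_cells, missing`.
#' @export
aggregate_climate <- function(grid, regions) {
  stopifnot(inherits(grid, "climate_grid"))
  if (inherits(regions, "region_lattice")) regions <- list(regions)
  out <- lapply(regions, function(rg) {
    rg <- rg[order(rg$id), , drop = FALSE]
    unit <- rep(NA_character_, nrow(grid))
    for (r in seq_len(nrow(rg))) {
      hit <- is.na(unit) & in_rect(grid$lon, grid$lat, rg[r, ])
      unit[hit] <- rg$id[r]
    }
    sc <- attr(rg, "scale"); if (is.null(sc)) sc <- "scale"
    res <- data.frame(scale = sc, unit = rg$id)
    f <- factor(unit, levels = rg$id)
    res$bio1 <- as.numeric(tapply(grid$bio1, f, mean))
    res$bio12 <- as.numeric(tapply(grid$bio12, f, mean))
    res$n_cells <- as.integer(table(f))
    res$missing <- res$n_cells == 0
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Small-sample corrected AIC
#'
#' AICc = AIC + 2k(k+1)/(n-k-1), where k counts every estimated parameter
#' (intercept, slopes, and the Gaussian residual variance). Undefined (NA)
#' when n <= k + 1.
#'
#' @param fit an `lm`/`glm` fit, or a list with `AIC`, `k`, `n`.
#' @return the AICc value.
#' @export
aicc <- function(fit) {
  if (inherits(fit, c("lm", "glm"))) {
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")
    n <- stats::nobs(fit)
    a <- stats::AIC(fit)
  } else {
    a <- fit$AIC; k <- fit$k; n <- fit$n
  }
  if (n <= k + 1) return(NA_real_)
  a + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a regression with a coefficient table and AICc
#'
#' Wraps [stats::glm()] with a tidy coefficient summary plus AIC/AICc, the
#' unit of model comparison used throughout the statistics layer.
#'
#' @param data data frame.
#' @param formula model formula.
#' @param family a [stats::family()]; Gaussian by default (the responses
#'   here, NRI/NTI, are unbounded).
#' @return list of class `model_fit`: `formula, family, coefficients`
#'   (term, estimate, se, statistic, p), `logLik, AIC, AICc, n, k, fit`.
#' @export
fit_glm <- function(data, formula, family = stats::gaussian()) {
  fit <- stats::glm(formula, data = data, family = family)
  if (fit$rank < ncol(stats::model.matrix(fit)))
    stop("rank-deficient design in ", deparse(formula), call. = FALSE)
  sm <- summary(fit)$coefficients
  ll <- stats::logLik(fit)
  out <- list(formula = formula, family = family$family,
              coefficients = data.frame(term = rownames(sm),
                                        estimate = sm[, 1], se = sm[, 2],
                                        statistic = sm[, 3], p = sm[, 4],
                                        row.names = NULL),
              logLik = as.numeric(ll), AIC = stats::AIC(fit),
              k = attr(ll, "df"), n = stats::nobs(fit), fit = fit)
  out$AICc <- aicc(fit)
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Model:", deparse(x$formula), sprintf("(%s, n=%d)\n", x$family, x$n))
  print(x$coefficients, digits = 4)
  cat(sprintf("AIC %.3f  AICc %.3f  logLik %.3f  k %d\n",
              x$AIC, x$AICc, x$logLik, x$k))
  invisible(x)
}

#' Choose presence- vs abundance-based metrics by AICc
#'
#' Fits the same model (default: metric ~ community_type) to the NRI and NTI
#' columns of each data mode's results and selects the mode with the lower
#' summed AICc; ties go to abundance.
#'
#' @param results `phylostruct` results covering both data modes.
#' @param rhs right-hand side of the comparison model.
#' @return list `mode` ("presence"/"abundance"), `aicc` (named totals),
#'   `delta`, `tie`, `fits` (per mode x metric).
#' @export
select_data_mode <- function(results, rhs = "community_type") {
  res <- if (inherits(results, "phylostruct")) results$results else results
  res <- res[res$usable & res$ses_defined, , drop = FALSE]
  modes <- c("presence", "abundance")
  if (!all(modes %in% res$data_mode))
    stop("results must contain both presence and abundance modes",
         call. = FALSE)
  fits <- list()
  totals <- stats::setNames(numeric(2), modes)
  for (m in modes) {
    dm <- res[res$data_mode == m, , drop = FALSE]
    for (metric in c("NRI", "NTI")) {
      f <- fit_glm(dm, stats::as.formula(paste(metric, "~", rhs)))
      if (is.na(f$AICc))
        stop("undefined AICc for mode ", m, ", metric ", metric, call. = FALSE)
      fits[[paste(m, metric, sep = ".")]] <- f
      totals[m] <- totals[m] + f$AICc
    }
  }
  tie <- isTRUE(all.equal(totals["presence"], totals["abundance"],
                          check.attributes = FALSE))
  mode <- if (tie || totals["abundance"] <= totals["presence"]) "abundance"
          else "presence"
  if (tie) msg("select_data_mode: AICc tie; abundance selected by convention")
  list(mode = mode, aicc = totals,
       delta = abs(unname(totals[1] - totals[2])), tie = tie, fits = fits)
}

#' Two-way ANOVA with Type-II sums of squares
#'
#' Tests both main effects and their interaction for a response over two
#' crossed factors (community type and spatial scale in the standard use),
#' using Type-II sums of squares (equal to Type-I in balanced designs).
#' P-values are Holm-adjusted across the three terms.
#'
#' @param data data frame.
#' @param response,factor_a,factor_b column names.
#' @return data frame of class `anova_result`: `term, sum_sq, df1, df2, F,
#'   p_raw, p_adj, method` plus a `degenerate` attribute flagging zero
#'   residual variance.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  for (f in c(factor_a, factor_b)) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2)
      stop("factor '", f, "' needs >= 2 levels", call. = FALSE)
  }
  if (any(table(data[[factor_a]], data[[factor_b]]) == 0))
    stop("empty factor-combination cell", call. = FALSE)
  fml <- stats::as.formula(paste(response, "~", factor_a, "*", factor_b))
  fit <- stats::lm(fml, data = data)
  sse <- sum(stats::residuals(fit)^2)
  degenerate <- sse < .Machine$double.eps * max(1, sum(data[[response]]^2))
  tab <- if (degenerate) suppressWarnings(stats::anova(fit))
         else car::Anova(fit, type = 2)
  terms <- rownames(tab)[rownames(tab) != "Residuals"]
  df2 <- tab["Residuals", "Df"]
  out <- data.frame(term = terms,
                    sum_sq = tab[terms, "Sum Sq"],
                    df1 = tab[terms, "Df"], df2 = df2,
                    F = if (degenerate) rep(0, length(terms))
                        else tab[terms, "F value"],
                    p_raw = if (degenerate) rep(NA_real_, length(terms))
                            else tab[terms, "Pr(>F)"])
  out$p_adj <- if (degenerate) NA_real_ else stats::p.adjust(out$p_raw, "holm")
  out$method <- "two-way ANOVA, Type-II SS, Holm"
  attr(out, "degenerate") <- degenerate
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Pairwise post hoc comparisons with Holm adjustment
#'
#' All pairwise two-sample comparisons between group levels, Welch t by
#' default (pooled-variance t via `welch = FALSE`), with step-down Holm
#' adjustment across the family of comparisons.
#'
#' @param values numeric response.
#' @param groups grouping vector (>= 2 levels, each with >= 2 observations).
#' @param welch use the unequal-variance t test.
#' @return data frame `group1, group2, estimate, t, df, p_raw, p_adj,
#'   method`.
#' @export
posthoc_pairwise <- function(values, groups, welch = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs >= 2 observations", call. = FALSE)
  prs <- utils::combn(levels(groups), 2)
  rows <- apply(prs, 2, function(p) {
    tt <- stats::t.test(values[groups == p[1]], values[groups == p[2]],
                        var.equal = !welch)
    data.frame(group1 = p[1], group2 = p[2],
               estimate = unname(diff(rev(tt$estimate))),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, "holm")
  out$method <- if (welch) "Welch t, Holm" else "pooled t, Holm"
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with the t approximation
#'
#' Pearson correlation of mid-ranks (average ranks under ties), with the
#' p-value from the asymptotic t approximation.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return data frame `rho, p, n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("zero variance in ranks", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  data.frame(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Per-stratum climate regressions of the phylogenetic metrics
#'
#' Within each (community type, scale, metric) stratum, regresses the metric
#' on each climate covariate separately (metric ~ BIO1 and metric ~ BIO12),
#' reporting slope, its sign, p-value and AICc. Strata too small for AICc
#' (n <= k + 1) are skipped with a message.
#'
#' @param results `phylostruct` results (one data mode).
#' @param covariates table from [aggregate_climate()].
#' @param metrics which metrics to regress.
#' @return data frame `community_type, scale, metric, covariate, n, slope,
#'   slope_sign, se, p, AIC, AICc`.
#' @export
climate_regressions <- function(results, covariates,
                                metrics = c("NRI", "NTI")) {
  res <- if (inherits(results, "phylostruct")) results$results else results
  res <- res[res$usable & res$ses_defined, , drop = FALSE]
  dat <- merge(res, covariates, by = c("scale", "unit"))
  dat <- dat[!dat$missing, , drop = FALSE]
  if (!nrow(dat)) stop("no joined rows between results and covariates",
                       call. = FALSE)
  rows <- list()
  for (ct in unique(dat$community_type)) for (sc in unique(dat$scale)) {
    stratum <- dat[dat$community_type == ct & dat$scale == sc, , drop = FALSE]
    if (!nrow(stratum)) next
    for (metric in metrics) for (cov in c("bio1", "bio12")) {
      if (nrow(stratum) <= 4) {  # n <= k + 1 with k = 3 (int., slope, sigma)
        msg("climate_regressions: stratum ", ct, "/", sc,
            " too small (n=", nrow(stratum), "); skipped")
        next
      }
      if (stats::var(stratum[[cov]]) == 0) {
        msg("climate_regressions: constant ", cov, " in ", ct, "/", sc,
            "; skipped")
        next
      }
      f <- fit_glm(stratum, stats::as.formula(paste(metric, "~", cov)))
      co <- f$coefficients[2, ]
      rows[[length(rows) + 1L]] <- data.frame(
        community_type = ct, scale = sc, metric = metric, covariate = cov,
        n = f$n, slope = co$estimate, slope_sign = sign(co$estimate),
        se = co$se, p = co$p, AIC = f$AIC, AICc = f$AICc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlations of metrics between community types
#'
#' For every pair of community types at each scale, correlates the per-unit
#' metric values across the units where both types are defined.
#'
#' @param results `phylostruct` results (one data mode).
#' @param types community types to compare (default the three single-status
#'   ones).
#' @param metrics which metrics to correlate.
#' @return data frame `type1, type2, scale, metric, rho, p, n`.
#' @export
cross_type_correlations <- function(results,
                                    types = c("Inv", "Nat", "Int"),
                                    metrics = c("NRI", "NTI")) {
  res <- if (inherits(results, "phylostruct")) results$results else results
  res <- res[res$usable & res$ses_defined &
               res$community_type %in% types, , drop = FALSE]
  rows <- list()
  prs <- utils::combn(types, 2)
  for (sc in unique(res$scale)) for (j in seq_len(ncol(prs))) {
    a <- res[res$scale == sc & res$community_type == prs[1, j], ]
    b <- res[res$scale == sc & res$community_type == prs[2, j], ]
    m <- merge(a, b, by = "unit", suffixes = c("_1", "_2"))
    for (metric in metrics) {
      x <- m[[paste0(metric, "_1")]]; y <- m[[paste0(metric, "_2")]]
      if (length(x) < 3 || stats::var(rank(x)) == 0 ||
          stats::var(rank(y)) == 0) next
      s <- spearman_cor(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        type1 = prs[1, j], type2 = prs[2, j], scale = sc, metric = metric,
        rho = s$rho, p = s$p, n = s$n)
    }
  }
  if (!length(rows))
    return(data.frame(type1 = character(), type2 = character(),
                      scale = character(), metric = character(),
                      rho = numeric(), p = numeric(), n = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
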