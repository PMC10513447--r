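test_that("climate aggregation averages cell centers per unit", {
  grid <- simulate_climate_grid(c(0, 2, 0, 2), c(2, 2), temp_gradient = 0,
                                temp_at_equator = 10, precip_gradient = 0,
                                precip_base = 3, noise_sd = 0, seed = 1)
  regs <- simulate_regions(c(0, 2, 0, 2), c(sc = 1))
  agg <- aggregate_climate(grid, regs)
  expect_equal(agg$bio1, 10)
  expect_equal(agg$bio12, 3)
  # unit covering cells valued 1 and 3 averages to 2
  grid2 <- grid; grid2$bio1 <- c(1, 1, 3, 3)  # left column 1,3; right 1,3
  halves <- data.frame(id = c("L", "R"), xmin = c(0, 1), xmax = c(1, 2),
                       ymin = 0, ymax = 2)
  attr(halves, "scale") <- "h"; class(halves) <- c("region_lattice",
                                                   "data.frame")
  agg2 <- aggregate_climate(grid2, list(h = halves))
  expect_equal(agg2$bio1, c(2, 2))
  # unit outside the grid is flagged missing
  far <- data.frame(id = "far", xmin = 10, xmax = 11, ymin = 10, ymax = 11)
  attr(far, "scale") <- "f"; class(far) <- c("region_lattice", "data.frame")
  agg3 <- aggregate_climate(grid, list(f = far))
  expect_true(agg3$missing)
  expect_true(is.na(agg3$bio1))
})

test_that("AICc follows the small-sample correction formula", {
  expect_equal(aicc(list(AIC = 10, k = 2, n = 10)), 10 + 12 / 7)
  expect_true(is.na(aicc(list(AIC = 10, k = 4, n = 5))))
  set.seed(1)
  df <- data.frame(x = 1:10, y = rnorm(10))
  fit <- fit_glm(df, y ~ x)
  expect_equal(aicc(fit$fit), fit$AIC + 2 * 3 * 4 / (10 - 3 - 1))
})

test_that("regression fits recover exact relations and are exchangeable", {
  df <- data.frame(x = 1:10)
  df$y <- 2 * df$x + 1
  fit <- fit_glm(df, y ~ x)
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_lt(sum(residuals(fit$fit)^2), 1e-18)
  shuffled <- fit_glm(df[sample(10), ], y ~ x)
  expect_equal(shuffled$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-10)
  df$z <- df$x * 2
  expect_error(fit_glm(df, y ~ x + z), "rank-deficient")
})

test_that("data-mode selection picks the lower summed AICc, ties to abundance", {
  set.seed(2)
  base <- data.frame(scale = "s", unit = paste0("u", 1:40),
                     community_type = rep(c("Inv", "Nat"), 20),
                     n_taxa = 5L, mpd_obs = 1, null_mean_mpd = 1,
                     null_sd_mpd = 1, mntd_obs = 1, null_mean_mntd = 1,
                     null_sd_mntd = 1, usable = TRUE, ses_defined = TRUE)
  pres <- base; pres$data_mode <- "presence"
  pres$NRI <- rnorm(40, sd = 4); pres$NTI <- rnorm(40, sd = 4)
  ab <- base; ab$data_mode <- "abundance"
  ab$NRI <- rep(c(1, 2), 20) + rnorm(40, sd = 0.1)
  ab$NTI <- rep(c(0, 1), 20) + rnorm(40, sd = 0.1)
  sel <- select_data_mode(rbind(pres, ab))
  expect_equal(sel$mode, "abundance")  # far tighter fit => lower AICc
  expect_equal(sel$delta,
               abs(sel$aicc[["presence"]] - sel$aicc[["abundance"]]))
  # identical tables: tie resolved to abundance and flagged
  tie_ab <- pres; tie_ab$data_mode <- "abundance"
  sel2 <- suppressMessages(select_data_mode(rbind(pres, tie_ab)))
  expect_true(sel2$tie)
  expect_equal(sel2$mode, "abundance")
})

test_that("balanced two-way ANOVA reproduces textbook sums of squares", {
  df <- data.frame(y = 1:8, A = rep(c("a1", "a2"), each = 4),
                   B = rep(c("b1", "b1", "b2", "b2"), 2))
  out <- two_way_anova(df, "y", "A", "B")
  expect_equal(out$F[out$term == "A"], 64)
  expect_equal(out$F[out$term == "B"], 16)
  expect_equal(out$F[out$term == "A:B"], 0)
  expect_equal(out$df1, c(1, 1, 1))
  expect_equal(unique(out$df2), 4)
  # balanced designs: Type-II equals sequential Type-I sums of squares
  t1 <- anova(lm(y ~ A * B, df))
  expect_equal(out$sum_sq, t1[c("A", "B", "A:B"), "Sum Sq"],
               tolerance = 1e-9)
})

test_that("two-way ANOVA flags degenerate input and rejects empty cells", {
  const <- data.frame(y = rep(5, 8), A = rep(c("a", "b"), each = 4),
                      B = rep(c("c", "d"), 4))
  out <- two_way_anova(const, "y", "A", "B")
  expect_true(attr(out, "degenerate"))
  expect_equal(out$F, c(0, 0, 0))
  holes <- data.frame(y = 1:4, A = c("a", "a", "b", "b"),
                      B = c("c", "c", "c", "c"))
  expect_error(two_way_anova(holes, "y", "A", "B"), "2 levels")
  holes2 <- data.frame(y = 1:6, A = c("a", "a", "a", "a", "b", "b"),
                       B = c("c", "c", "d", "d", "c", "c"))
  expect_error(two_way_anova(holes2, "y", "A", "B"), "empty")
})

test_that("pairwise post hocs carry Holm-adjusted p-values", {
  set.seed(3)
  g <- rep(c("a", "b", "c"), each = 10)
  v <- rnorm(30) + rep(c(0, 1, 3), each = 10)
  out <- posthoc_pairwise(v, g)
  expect_equal(nrow(out), 3)
  expect_equal(out$p_adj, oracle_holm(out$p_raw))
  # adjusted p non-decreasing in raw-p order
  expect_true(all(diff(out$p_adj[order(out$p_raw)]) >= 0))
  # single comparison: adjusted equals raw
  one <- posthoc_pairwise(v[g != "c"], g[g != "c"])
  expect_equal(one$p_adj, one$p_raw)
  expect_error(posthoc_pairwise(c(1, 2, 3), c("a", "a", "b")),
               ">= 2 observations")
})

test_that("Spearman correlation matches rank arithmetic and is monotone-invariant", {
  expect_equal(spearman_cor(1:3, c(10, 20, 300))$rho, 1)
  expect_equal(spearman_cor(1:3, c(300, 20, 10))$rho, -1)
  expect_equal(spearman_cor(1:4, c(1, 3, 2, 4))$rho, 0.8)
  set.seed(4)
  x <- rnorm(25); y <- rnorm(25)
  r0 <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, r0$rho)
  expect_equal(spearman_cor(x, 3 * y + 5)$p, r0$p)
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("climate regressions recover a planted slope and keep strata independent", {
  set.seed(5)
  n <- 60
  cov <- data.frame(scale = "s", unit = paste0("u", 1:n),
                    bio1 = runif(n, 0, 20), bio12 = runif(n, 0, 100),
                    missing = FALSE)
  res <- data.frame(scale = "s", unit = cov$unit,
                    community_type = rep(c("Inv", "Nat"), each = n / 2),
                    data_mode = "abundance", n_taxa = 5L,
                    mpd_obs = 1, null_mean_mpd = 1, null_sd_mpd = 1,
                    NRI = 0.5 * cov$bio1 + rnorm(n, sd = 0.4),
                    mntd_obs = 1, null_mean_mntd = 1, null_sd_mntd = 1,
                    NTI = rnorm(n), usable = TRUE, ses_defined = TRUE)
  fits <- climate_regressions(res, cov, metrics = "NRI")
  inv_b1 <- fits[fits$community_type == "Inv" & fits$covariate == "bio1", ]
  expect_lt(abs(inv_b1$slope - 0.5), 2 * inv_b1$se)
  # deleting one stratum leaves the other's fit unchanged
  fits_inv <- climate_regressions(res[res$community_type == "Inv", ], cov,
                                  metrics = "NRI")
  expect_equal(fits_inv[fits_inv$covariate == "bio1", "slope"], inv_b1$slope)
  # constant covariate within a stratum is skipped with a message
  cov2 <- cov; cov2$bio1 <- 1
  expect_message(
    out2 <- climate_regressions(res, cov2, metrics = "NRI"),
    "constant")
  expect_false(any(out2$covariate == "bio1"))
})

test_that("cross-type correlations pair units within scales", {
  set.seed(6)
  units <- paste0("u", 1:20)
  mk <- function(ct, nri) data.frame(
    scale = "s", unit = units, community_type = ct, data_mode = "abundance",
    n_taxa = 4L, mpd_obs = 1, null_mean_mpd = 1, null_sd_mpd = 1, NRI = nri,
    mntd_obs = 1, null_mean_mntd = 1, null_sd_mntd = 1, NTI = rnorm(20),
    usable = TRUE, ses_defined = TRUE)
  base <- rnorm(20)
  res <- rbind(mk("Inv", base), mk("Nat", base + rnorm(20, sd = 0.01)),
               mk("Int", rnorm(20)))
  out <- cross_type_correlations(res)
  invnat <- out[out$type1 == "Inv" & out$type2 == "Nat" & out$metric == "NRI", ]
  expect_gt(invnat$rho, 0.9)
  expect_equal(invnat$n, 20)
})
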