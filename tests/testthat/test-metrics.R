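test_that("MPD matches hand-computed values in both weightings", {
  d <- patristic(toy_tree())
  expect_equal(mpd(d), 20 / 6)
  expect_equal(mpd(d, c("A", "B", "C"), c(A = 2, B = 1, C = 1),
                   weighted = TRUE), 3.2)
  # equal abundances: weighting cancels
  expect_equal(mpd(d, abundance = setNames(rep(3, 4), rownames(d)),
                   weighted = TRUE), mpd(d))
  expect_error(mpd(d, "A"), ">= 2 taxa")
})

test_that("MNTD matches hand-computed values in both weightings", {
  d <- patristic(toy_tree())
  expect_equal(mntd(d), 2)
  expect_equal(mntd(d, c("A", "B", "C"), c(A = 2, B = 1, C = 1),
                    weighted = TRUE), 2.5)
  # two-taxon community: the only neighbor is the only pair
  expect_equal(mntd(d, c("A", "C")), mpd(d, c("A", "C")))
})

test_that("MPD/MNTD agree with brute-force loops on random communities", {
  set.seed(17)
  for (i in 1:100) {
    tr <- ape::rtree(sample(4:12, 1))
    d <- patristic(tr)
    k <- sample(2:ape::Ntip(tr), 1)
    taxa <- sample(tr$tip.label, k)
    ab <- sample(1:6, k, replace = TRUE)
    ds <- d[taxa, taxa]
    expect_equal(mpd(d, taxa), oracle_mpd(ds), tolerance = 1e-12)
    expect_equal(mpd(d, taxa, setNames(ab, taxa), weighted = TRUE),
                 oracle_mpd(ds, ab), tolerance = 1e-12)
    expect_equal(mntd(d, taxa), oracle_mntd(ds), tolerance = 1e-12)
    expect_equal(mntd(d, taxa, setNames(ab, taxa), weighted = TRUE),
                 oracle_mntd(ds, ab), tolerance = 1e-12)
  }
})

test_that("MPD/MNTD match picante in both weightings", {
  skip_if_not_installed("picante")
  set.seed(23)
  for (i in 1:20) {
    tr <- ape::rtree(10)
    d <- patristic(tr)
    taxa <- sample(tr$tip.label, 6)
    ab <- sample(1:5, 6, replace = TRUE)
    samp <- matrix(0, 1, 10, dimnames = list("u", tr$tip.label))
    samp[1, taxa] <- ab
    expect_equal(mpd(d, taxa), picante::mpd(samp, d)[1], tolerance = 1e-10)
    # picante keeps the zero-distance diagonal (a_i^2 terms) in its weighted
    # denominator; convert between the two conventions before comparing
    conv <- (sum(ab)^2 - sum(ab^2)) / sum(ab)^2
    expect_equal(mpd(d, taxa, setNames(ab, taxa), weighted = TRUE) * conv,
                 picante::mpd(samp, d, abundance.weighted = TRUE)[1],
                 tolerance = 1e-10)
    expect_equal(mntd(d, taxa), picante::mntd(samp, d)[1], tolerance = 1e-10)
    expect_equal(mntd(d, taxa, setNames(ab, taxa), weighted = TRUE),
                 picante::mntd(samp, d, abundance.weighted = TRUE)[1],
                 tolerance = 1e-10)
  }
})

test_that("tip shuffle over the whole pool is a no-op for the full community", {
  d <- patristic(toy_tree())
  nd <- null_distribution(d, rownames(d), replicates = 50, seed = 1)
  expect_true(all(abs(nd$mpd - mpd(d)) < 1e-12))
  expect_true(all(abs(nd$mntd - mntd(d)) < 1e-12))
})

test_that("null support on the toy tree is {2,4} with probabilities 1/3, 2/3", {
  d <- patristic(toy_tree())
  nd <- null_distribution(d, c("A", "B"), replicates = 6000, seed = 2)
  expect_true(all(nd$mpd %in% c(2, 4)))
  expect_lt(abs(mean(nd$mpd == 2) - 1 / 3), 0.03)
  nd2 <- null_distribution(d, c("A", "B"), replicates = 100, seed = 9)
  nd3 <- null_distribution(d, c("A", "B"), replicates = 100, seed = 9)
  expect_identical(nd2, nd3)
  expect_error(null_distribution(d, c(rownames(d), "E"), replicates = 5),
               "taxa not in")
})

test_that("SES has the clustering sign convention and undefined flag", {
  expect_equal(ses(5, c(4, 5, 6))$ses, 0)
  # observed below the null mean => positive (clustering)
  expect_gt(ses(3, c(4, 5, 6))$ses, 0)
  flat <- ses(1, c(2, 2, 2))
  expect_false(flat$defined)
  expect_true(is.na(flat$ses))
  # population sd: -(2 - 10/3) / (2*sqrt(2)/3) = sqrt(2) on the exhaustive null
  exact_null <- c(2, 2, 4, 4, 4, 4)
  expect_equal(ses(2, exact_null)$ses, sqrt(2))
  expect_error(ses(1, numeric(0)), ">= 2")
})

test_that("exhaustive null moments are exact on the toy tree", {
  d <- patristic(toy_tree())
  ex <- ses_exhaustive(d, 2, "mpd")
  expect_equal(ex$mean, 10 / 3)
  expect_equal(ex$sd, 2 * sqrt(2) / 3)
  expect_equal(ex$n_subsets, 6)
  expect_equal(ses_exhaustive(d, 4, "mpd")$sd, 0)
  big <- patristic(ape::rtree(40))
  expect_error(ses_exhaustive(big, 20), "enumeration refused")
})

test_that("Monte-Carlo null moments converge to the exhaustive moments", {
  set.seed(31)
  tr <- ape::rcoal(8)
  d <- patristic(tr)
  for (k in c(3, 5)) for (stat in c("mpd", "mntd")) {
    ex <- ses_exhaustive(d, k, stat)
    taxa <- sample(tr$tip.label, k)
    nd <- null_distribution(d, taxa, replicates = 4999, seed = 7)[[stat]]
    se <- ex$sd / sqrt(length(nd))
    expect_lt(abs(mean(nd) - ex$mean), 3 * se)
  }
})

test_that("NRI and NTI are invariant under uniform branch-length scaling", {
  tr <- simulate_yule_tree(30, seed = 4)
  tr10 <- tr; tr10$edge.length <- tr$edge.length * 10
  asm <- data.frame(scale = "s", unit = "u", community_type = "Inv",
                    species = tr$tip.label[1:8], abundance = c(3, 1, 2, 1, 5, 1, 2, 4))
  a <- phylo_structure(tr, asm, "abundance", replicates = 299, seed = 11)
  b <- phylo_structure(tr10, asm, "abundance", replicates = 299, seed = 11)
  expect_equal(a$results$NRI, b$results$NRI, tolerance = 1e-10)
  expect_equal(a$results$NTI, b$results$NTI, tolerance = 1e-10)
  expect_equal(b$results$mpd_obs, 10 * a$results$mpd_obs, tolerance = 1e-10)
})

test_that("presence mode equals abundance mode at unit counts; NRI=NTI for pairs", {
  tr <- simulate_yule_tree(20, seed = 6)
  asm <- data.frame(scale = "s", unit = "u", community_type = "Inv",
                    species = tr$tip.label[c(2, 5, 9, 14)], abundance = 1L)
  both <- phylo_structure(tr, asm, "both", replicates = 199, seed = 3)
  res <- both$results
  # identical null seeds are not guaranteed across modes; compare observed
  expect_equal(res$mpd_obs[1], res$mpd_obs[2])
  expect_equal(res$mntd_obs[1], res$mntd_obs[2])
  pair <- data.frame(scale = "s", unit = "u", community_type = "Inv",
                     species = tr$tip.label[c(3, 17)], abundance = c(2L, 7L))
  ps <- phylo_structure(tr, pair, "abundance", replicates = 499, seed = 5)
  expect_equal(ps$results$NRI, ps$results$NTI, tolerance = 1e-12)
})

test_that("phylostruct keeps flagged assemblages and errors on missing species", {
  tr <- simulate_yule_tree(10, seed = 2)
  asm <- rbind(
    data.frame(scale = "s", unit = "u1", community_type = "Inv",
               species = tr$tip.label[1:3], abundance = 1L),
    data.frame(scale = "s", unit = "u2", community_type = "Inv",
               species = tr$tip.label[4], abundance = 2L))
  ps <- phylo_structure(tr, asm, "presence", replicates = 99, seed = 1)
  expect_equal(nrow(ps$results), 2)
  expect_false(ps$results$usable[ps$results$unit == "u2"])
  expect_true(is.na(ps$results$NRI[ps$results$unit == "u2"]))
  bad <- asm; bad$species[1] <- "ghost"
  expect_error(phylo_structure(tr, bad, "presence", replicates = 9),
               "ghost")
  expect_output(print(ps), "tip-shuffle")
  expect_s3_class(summary(ps), "data.frame")
})

test_that("NRI from phylostruct matches picante ses.mpd observed values", {
  skip_if_not_installed("picante")
  tr <- simulate_yule_tree(25, seed = 8)
  taxa <- tr$tip.label[c(1, 4, 7, 12, 20)]
  asm <- data.frame(scale = "s", unit = "u", community_type = "Inv",
                    species = taxa, abundance = 1L)
  ps <- phylo_structure(tr, asm, "presence", replicates = 999, seed = 13)
  samp <- matrix(0, 2, 25, dimnames = list(c("u", "v"), tr$tip.label))
  samp[, taxa] <- 1
  pic <- picante::ses.mpd(samp, patristic(tr), null.model = "taxa.labels",
                          runs = 999)
  expect_equal(ps$results$mpd_obs, pic$mpd.obs[1], tolerance = 1e-10)
  # independent Monte-Carlo runs of the same null: z-scores agree loosely
  expect_lt(abs(ps$results$NRI - (-pic$mpd.obs.z[1])), 0.3)
})

test_that("anomalies obey the definition and the sign conventions", {
  res <- data.frame(
    scale = "s", unit = "u",
    community_type = c("All", "Inv", "Nat"),
    data_mode = "abundance", n_taxa = c(6L, 3L, 3L),
    mpd_obs = 1, null_mean_mpd = 1, null_sd_mpd = 1,
    NRI = c(1.0, 1.5, 0.25),
    mntd_obs = 1, null_mean_mntd = 1, null_sd_mntd = 1,
    NTI = c(0.5, 0.5, -0.5),
    usable = TRUE, ses_defined = TRUE)
  an <- anomalies(res)
  get <- function(ct, m) an$anomaly[an$community_type == ct & an$metric == m]
  expect_equal(get("Inv", "NRI"), -0.5)
  expect_equal(get("Inv", "NTI"), 0)       # subset equals All: anomaly 0
  expect_equal(get("Nat", "NRI"), 0.75)
  flipped <- anomalies(res, "subset_minus_all")
  expect_equal(flipped$anomaly, -an$anomaly)
})
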