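#' Mean pairwise phylogenetic distance (MPD)
#'
#' Unweighted: the mean patristic distance over all unordered pairs of taxa.
#' Abundance-weighted: pair-product weighting,
#' sum(a_i a_j d_ij) / sum(a_i a_j) over i < j.
#'
#' @param d patristic distance matrix whose row/col names include the taxa.
#' @param taxa taxa of the assemblage (default: all rows of `d`).
#' @param abundance positive counts, named by or aligned with `taxa`.
#' @param weighted use abundance weighting.
#' @return a single numeric value in branch-length units.
#' @export
mpd <- function(d, taxa = rownames(d), abundance = NULL, weighted = FALSE) {
  ds <- submatrix(d, taxa)
  k <- length(taxa)
  if (k < 2) stop("MPD needs >= 2 taxa", call. = FALSE)
  if (!weighted) return(sum(ds) / (k * (k - 1)))
  a <- align_abund(abundance, taxa)
  num <- as.numeric(t(a) %*% ds %*% a)        # diag(ds)=0, counts i!=j twice
  den <- sum(a)^2 - sum(a^2)
  num / den
}

#' Mean nearest taxon distance (MNTD)
#'
#' Unweighted: the mean, over taxa, of the distance to the nearest other
#' taxon in the assemblage. Abundance-weighted:
#' sum(a_i * nn_i) / sum(a_i).
#'
#' @inheritParams mpd
#' @return a single numeric value in branch-length units.
#' @export
mntd <- function(d, taxa = rownames(d), abundance = NULL, weighted = FALSE) {
  ds <- submatrix(d, taxa)
  k <- length(taxa)
  if (k < 2) stop("MNTD needs >= 2 taxa", call. = FALSE)
  diag(ds) <- Inf
  nn <- apply(ds, 1, min)
  if (!weighted) return(mean(nn))
  a <- align_abund(abundance, taxa)
  sum(a * nn) / sum(a)
}

submatrix <- function(d, taxa) {
  missing <- setdiff(taxa, rownames(d))
  if (length(missing))
    stop("taxa not in distance matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  d[taxa, taxa, drop = FALSE]
}

align_abund <- function(abundance, taxa) {
  if (is.null(abundance)) return(rep(1, length(taxa)))
  a <- if (!is.null(names(abundance))) abundance[taxa] else abundance
  if (length(a) != length(taxa) || anyNA(a) || any(a <= 0))
    stop("abundance must be positive and cover every taxon", call. = FALSE)
  as.numeric(a)
}

# Both statistics for one index set into dfull, abundances in taxon order.
stats_for_idx <- function(dfull, idx, a, weighted) {
  ds <- dfull[idx, idx, drop = FALSE]
  k <- length(idx)
  if (weighted) {
    mpd_v <- as.numeric(t(a) %*% ds %*% a) / (sum(a)^2 - sum(a^2))
  } else {
    mpd_v <- sum(ds) / (k * (k - 1))
  }
  diag(ds) <- Inf
  nn <- apply(ds, 1, min)
  mntd_v <- if (weighted) sum(a * nn) / sum(a) else mean(nn)
  c(mpd = mpd_v, mntd = mntd_v)
}

#' Tip-shuffle null distribution of MPD and MNTD
#'
#' Implements the classic "shuffle species names across all tips of the
#' phylogeny" randomization: each replicate relabels every tip of the full
#' tree by a uniform random permutation and recomputes the statistics for
#' the (relabeled) assemblage, keeping its original abundances. Because the
#' permutation is over the whole tree, this is equivalent to mapping the
#' assemblage onto a uniform random sample of distinct tips.
#'
#' @param dfull patristic matrix over the whole phylogeny (the null pool).
#' @param taxa assemblage taxa (subset of the pool).
#' @param abundance positive counts (carried through each replicate).
#' @param weighted abundance weighting flag applied to both statistics.
#' @param replicates number of shuffles (default 9999).
#' @param seed integer seed.
#' @return list with numeric vectors `mpd` and `mntd`, each of length
#'   `replicates`.
#' @export
null_distribution <- function(dfull, taxa, abundance = NULL, weighted = FALSE,
                              replicates = 9999, seed = NULL) {
  stopifnot(replicates >= 1)
  n <- nrow(dfull)
  k <- length(taxa)
  submatrix(dfull, taxa)  # validates taxa membership first
  if (k > n) stop("assemblage larger than the null pool", call. = FALSE)
  if (k < 2) stop("assemblage needs >= 2 taxa", call. = FALSE)
  a <- align_abund(abundance, taxa)
  with_seed(seed, {
    out_mpd <- numeric(replicates)
    out_mntd <- numeric(replicates)
    for (r in seq_len(replicates)) {
      idx <- sample.int(n, k)
      s <- stats_for_idx(dfull, idx, a, weighted)
      out_mpd[r] <- s[1]; out_mntd[r] <- s[2]
    }
    list(mpd = out_mpd, mntd = out_mntd)
  })
}

#' Standardized effect size with the NRI/NTI sign convention
#'
#' Returns -(obs - mean(null)) / sd(null), the sd taken in population form
#' (denominator N), so positive values indicate phylogenetic clustering
#' (observed distances smaller than the null expectation). When the null sd
#' is zero the value is flagged undefined (NA) rather than reported as 0.
#'
#' @param obs observed statistic.
#' @param null numeric vector of null replicates (length >= 2).
#' @return list with `ses`, `null_mean`, `null_sd`, `defined`.
#' @export
ses <- function(obs, null) {
  if (length(null) < 2) stop("need >= 2 null replicates", call. = FALSE)
  m <- mean(null)
  s <- sqrt(mean((null - m)^2))
  if (s == 0) return(list(ses = NA_real_, null_mean = m, null_sd = s,
                          defined = FALSE))
  list(ses = -(obs - m) / s, null_mean = m, null_sd = s, defined = TRUE)
}

#' Exact tip-shuffle null moments by exhaustive enumeration
#'
#' For unweighted statistics the tip shuffle reduces to a uniform choice of
#' a k-subset of tips, so the exact null mean and (population) sd can be
#' computed by enumerating all subsets. Intended as a small-tree oracle for
#' the Monte-Carlo null.
#'
#' @param dfull patristic matrix over the whole phylogeny.
#' @param k assemblage size.
#' @param stat `"mpd"` or `"mntd"`.
#' @return list with `mean`, `sd` (population form) and `n_subsets`.
#' @export
ses_exhaustive <- function(dfull, k, stat = c("mpd", "mntd")) {
  stat <- match.arg(stat)
  n <- nrow(dfull)
  stopifnot(k >= 2, k <= n)
  n_sub <- choose(n, k)
  if (n_sub > 1e6) stop("more than 1e6 subsets; enumeration refused",
                        call. = FALSE)
  subsets <- utils::combn(n, k)
  vals <- apply(subsets, 2, function(idx)
    stats_for_idx(dfull, idx, rep(1, k), weighted = FALSE)[[stat]])
  m <- mean(vals)
  list(mean = m, sd = sqrt(mean((vals - m)^2)), n_subsets = n_sub)
}

#' Fit phylogenetic community structure (NRI/NTI) to assemblages
#'
#' The central estimator of the package: for every usable assemblage
#' (>= 2 species, all on the tree) it computes observed MPD and MNTD,
#' their tip-shuffle null moments, and the standardized effect sizes
#' NRI = -SES(MPD) and NTI = -SES(MNTD), in presence (unweighted) and/or
#' abundance (weighted) mode. The null pool is always the whole supplied
#' phylogeny.
#'
#' @param tree a `phylo` object containing every assemblage species.
#' @param assemblages long data frame from [build_assemblages()]
#'   (`scale, unit, community_type, species, abundance`); multiple scales
#'   may be row-bound together.
#' @param data_mode `"abundance"`, `"presence"`, or `"both"`.
#' @param replicates tip-shuffle replicates (default 9999; reduce for
#'   desk-scale runs).
#' @param seed integer seed for the null model.
#' @return an object of class `phylostruct`: a list with `results` (one row
#'   per assemblage x mode; unusable assemblages kept with `usable = FALSE`),
#'   `replicates`, `seed`, `n_tips`, and the matched call. Column order of
#'   `results`: scale, unit, community_type, data_mode, n_taxa, mpd_obs,
#'   null_mean_mpd, null_sd_mpd, NRI, mntd_obs, null_mean_mntd,
#'   null_sd_mntd, NTI, usable, ses_defined.
#' @seealso [anomalies()], [ses()], [null_distribution()]
#' @export
phylo_structure <- function(tree, assemblages,
                            data_mode = c("abundance", "presence", "both"),
                            replicates = 9999, seed = NULL) {
  data_mode <- match.arg(data_mode)
  modes <- if (data_mode == "both") c("presence", "abundance") else data_mode
  stopifnot(inherits(tree, "phylo"))
  need <- c("scale", "unit", "community_type", "species", "abundance")
  if (!all(need %in% names(assemblages)))
    stop("assemblages need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(unique(assemblages$species), tree$tip.label)
  if (length(missing))
    stop("species missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dfull <- patristic(tree)
  key <- interaction(assemblages$scale, assemblages$unit,
                     assemblages$community_type, drop = TRUE)
  groups <- split(assemblages, key)
  rows <- vector("list", length(groups) * length(modes))
  i <- 0L
  for (g in groups) {
    taxa <- g$species
    abund <- g$abundance
    for (mode in modes) {
      i <- i + 1L
      base <- data.frame(scale = g$scale[1], unit = g$unit[1],
                         community_type = g$community_type[1],
                         data_mode = mode, n_taxa = length(taxa))
      if (length(taxa) < 2) {
        rows[[i]] <- cbind(base, mpd_obs = NA_real_, null_mean_mpd = NA_real_,
                           null_sd_mpd = NA_real_, NRI = NA_real_,
                           mntd_obs = NA_real_, null_mean_mntd = NA_real_,
                           null_sd_mntd = NA_real_, NTI = NA_real_,
                           usable = FALSE, ses_defined = FALSE)
        next
      }
      weighted <- mode == "abundance"
      obs <- stats_for_idx(dfull, match(taxa, rownames(dfull)),
                           align_abund(abund, taxa), weighted)
      nd <- null_distribution(dfull, taxa, abund, weighted, replicates,
                              seed = derive_seed(seed, i))
      s_mpd <- ses(obs[["mpd"]], nd$mpd)
      s_mntd <- ses(obs[["mntd"]], nd$mntd)
      rows[[i]] <- cbind(base,
                         mpd_obs = obs[["mpd"]],
                         null_mean_mpd = s_mpd$null_mean,
                         null_sd_mpd = s_mpd$null_sd, NRI = s_mpd$ses,
                         mntd_obs = obs[["mntd"]],
                         null_mean_mntd = s_mntd$null_mean,
                         null_sd_mntd = s_mntd$null_sd, NTI = s_mntd$ses,
                         usable = TRUE,
                         ses_defined = s_mpd$defined && s_mntd$defined)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, replicates = replicates, seed = seed,
                 n_tips = ape::Ntip(tree), call = match.call()),
            class = "phylostruct")
}

#' Phylogenetic anomalies between the full community and its status subsets
#'
#' The anomaly contrasts NRI (and NTI) of the all-status community of a unit
#' against each single- or paired-status subset of the same unit. Under the
#' default `"all_minus_subset"` convention a negative NRI anomaly for, say,
#' the Nat subset means the full community (which adds the other statuses)
#' is less clustered than the subset alone.
#'
#' @param x a `phylostruct` object or its `results` data frame.
#' @param convention `"all_minus_subset"` (default) or `"subset_minus_all"`.
#' @return data frame `scale, unit, community_type, data_mode, metric,
#'   anomaly, sign_convention` with one row per defined (All, subset) pair
#'   and metric.
#' @export
anomalies <- function(x, convention = c("all_minus_subset",
                                        "subset_minus_all")) {
  convention <- match.arg(convention)
  res <- if (inherits(x, "phylostruct")) x$results else x
  res <- res[res$usable & res$ses_defined, , drop = FALSE]
  all_rows <- res[res$community_type == "All", , drop = FALSE]
  sub_rows <- res[res$community_type != "All", , drop = FALSE]
  merged <- merge(sub_rows, all_rows[c("scale", "unit", "data_mode",
                                       "NRI", "NTI")],
                  by = c("scale", "unit", "data_mode"),
                  suffixes = c("", "_all"))
  if (!nrow(merged))
    return(data.frame(scale = character(), unit = character(),
                      community_type = character(), data_mode = character(),
                      metric = character(), anomaly = numeric(),
                      sign_convention = character()))
  sgn <- if (convention == "all_minus_subset") 1 else -1
  long <- rbind(
    data.frame(merged[c("scale", "unit", "community_type", "data_mode")],
               metric = "NRI", anomaly = sgn * (merged$NRI_all - merged$NRI)),
    data.frame(merged[c("scale", "unit", "community_type", "data_mode")],
               metric = "NTI", anomaly = sgn * (merged$NTI_all - merged$NTI)))
  long$sign_convention <- convention
  long <- long[order(long$scale, long$unit, long$community_type,
                     long$data_mode, long$metric), ]
  rownames(long) <- NULL
  long
}

#' Write a metric-result table as CSV
#'
#' Fixed column order: scale, unit, community_type, data_mode, n_taxa,
#' mpd_obs, null_mean_mpd, null_sd_mpd, NRI, mntd_obs, null_mean_mntd,
#' null_sd_mntd, NTI, usable, ses_defined.
#'
#' @param x a `phylostruct` or its results data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(x, path) {
  res <- if (inherits(x, "phylostruct")) x$results else x
  utils::write.csv(res, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
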