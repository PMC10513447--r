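#' Simulate an ultrametric pure-birth (Yule) species tree
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (per unit branch length, > 0); expected
#'   tree heights scale as 1/birth_rate.
#' @param seed integer seed for reproducibility.
#' @return a `phylo` tree with tips labeled `sp001`, `sp002`, ...
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  stopifnot(birth_rate > 0)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Evolve a trait along a tree under Brownian motion
#'
#' The trait at each node equals the parent's value plus a Normal(0,
#' sigma2 * branch length) increment; tip values are returned. Used to give
#' species phylogenetically conserved climate optima, so close relatives
#' share similar niches.
#'
#' @param tree a `phylo` object.
#' @param sigma2 nonnegative Brownian rate (trait units squared per unit
#'   branch length).
#' @param root_value trait value at the root.
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
brownian_trait <- function(tree, sigma2, root_value = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (sigma2 < 0) stop("sigma2 must be nonnegative", call. = FALSE)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  vals <- numeric(nnode)
  root <- ntip + 1L
  vals[root] <- root_value
  ord <- reorder(tree, "cladewise")
  with_seed(seed, {
    incr <- stats::rnorm(nrow(ord$edge), 0, sqrt(sigma2 * ord$edge.length))
    for (i in seq_len(nrow(ord$edge)))
      vals[ord$edge[i, 2]] <- vals[ord$edge[i, 1]] + incr[i]
  })
  stats::setNames(vals[seq_len(ntip)], tree$tip.label)
}

#' Assign invasion-stage statuses to species
#'
#' Labels every tip introduced / naturalized / invasive. Counts follow the
#' requested proportions under largest-remainder rounding. In
#' `"clade_biased"` mode the invasive labels are concentrated inside the
#' smallest clade large enough to hold them, emulating a lineage-restricted
#' invasive pool; remaining statuses are assigned at random.
#'
#' @param tips character vector of species labels.
#' @param proportions three nonnegative numbers summing to 1, in the order
#'   (introduced, naturalized, invasive). Default mirrors a national alien
#'   flora of 706 species split 165/222/319.
#' @param mode `"random"` or `"clade_biased"`.
#' @param tree required for `"clade_biased"`.
#' @param seed integer seed.
#' @return named character vector (names = tips) with values in
#'   `c("introduced", "naturalized", "invasive")`.
#' @export
assign_statuses <- function(tips,
                            proportions = c(introduced = 165, naturalized = 222,
                                            invasive = 319) / 706,
                            mode = c("random", "clade_biased"),
                            tree = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (length(proportions) != 3 || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be three nonnegative numbers summing to 1",
         call. = FALSE)
  n <- length(tips)
  counts <- largest_remainder(proportions, n)
  statuses <- c("introduced", "naturalized", "invasive")
  with_seed(seed, {
    if (mode == "random") {
      lab <- sample(rep(statuses, counts))
    } else {
      if (is.null(tree)) stop("clade_biased mode requires a tree", call. = FALSE)
      stopifnot(setequal(tips, tree$tip.label))
      ntip <- ape::Ntip(tree)
      n_inv <- counts[3]
      sizes <- vapply((ntip + 1):(ntip + tree$Nnode),
                      function(nd) length(tips_below(tree, nd)), integer(1))
      eligible <- which(sizes >= n_inv)
      pick <- eligible[sizes[eligible] == min(sizes[eligible])]
      if (length(pick) > 1) pick <- sample(pick, 1)
      clade_tips <- tree$tip.label[tips_below(tree, ntip + pick)]
      inv <- sample(clade_tips, n_inv)
      rest <- setdiff(tips, inv)
      lab <- character(n); names(lab) <- tips
      lab[inv] <- "invasive"
      lab[rest] <- sample(rep(statuses[1:2], counts[1:2]))
      return(lab)
    }
    stats::setNames(lab, tips)
  })
}

largest_remainder <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Partition an extent into rectangular spatial units at several scales
#'
#' Each scale is an independent lattice of disjoint rectangles tiling the
#' extent (the scales are different partitions, not nested), mirroring an
#' analysis run at habitat-type, climate-class, province and ecoregion
#' tiers. The default unit counts are 7, 16, 34 and 47.
#'
#' @param extent numeric vector `c(xmin, xmax, ymin, ymax)` (lon/lat box).
#' @param counts named integer vector of units per scale.
#' @return named list (one element per scale) of data frames with columns
#'   `id, xmin, xmax, ymin, ymax`, each of class `region_lattice`.
#' @export
simulate_regions <- function(extent,
                             counts = c(mht = 7, kgc = 16, pro = 34, eco = 47)) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  if (any(counts < 1)) stop("each scale needs >= 1 unit", call. = FALSE)
  if (is.null(names(counts))) names(counts) <- paste0("scale", counts)
  out <- lapply(seq_along(counts), function(k) {
    m <- as.integer(counts[k])
    nrows <- max(1L, floor(sqrt(m)))
    per_row <- rep(m %/% nrows, nrows)
    extra <- m %% nrows
    if (extra > 0) per_row[seq_len(extra)] <- per_row[seq_len(extra)] + 1L
    ybreaks <- seq(extent[3], extent[4], length.out = nrows + 1)
    rows <- lapply(seq_len(nrows), function(r) {
      xbreaks <- seq(extent[1], extent[2], length.out = per_row[r] + 1)
      data.frame(xmin = xbreaks[-length(xbreaks)], xmax = xbreaks[-1],
                 ymin = ybreaks[r], ymax = ybreaks[r + 1])
    })
    df <- do.call(rbind, rows)
    df <- cbind(id = sprintf("%s_u%02d", names(counts)[k], seq_len(m)), df)
    attr(df, "scale") <- names(counts)[k]
    class(df) <- c("region_lattice", "data.frame")
    df
  })
  stats::setNames(out, names(counts))
}

#' Simulate a smooth climate grid
#'
#' A rectangular lattice of cells carrying a temperature surrogate (BIO1,
#' degrees C-like, linear in latitude) and a precipitation surrogate (BIO12,
#' mm-like, linear in longitude), each plus iid Gaussian noise.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)`.
#' @param n_cells integer vector `c(nx, ny)` (a single number is used for
#'   both axes).
#' @param temp_gradient BIO1 change per degree latitude (default -0.55, a
#'   temperate-zone lapse of temperature with latitude).
#' @param precip_gradient BIO12 change per degree longitude.
#' @param temp_at_equator,precip_base intercepts of the two fields.
#' @param noise_sd standard deviation of cell-level noise (same for both
#'   fields, in each field's units).
#' @param seed integer seed.
#' @return data frame of class `climate_grid` with columns
#'   `cell, xmin, xmax, ymin, ymax, lon, lat, bio1, bio12` (lon/lat are cell
#'   centers).
#' @export
simulate_climate_grid <- function(extent, n_cells = c(30, 30),
                                  temp_gradient = -0.55, precip_gradient = 8,
                                  temp_at_equator = 28, precip_base = 400,
                                  noise_sd = 0.5, seed = NULL) {
  stopifnot(length(extent) == 4, all(n_cells >= 1))
  if (length(n_cells) == 1) n_cells <- rep(n_cells, 2)
  xb <- seq(extent[1], extent[2], length.out = n_cells[1] + 1)
  yb <- seq(extent[3], extent[4], length.out = n_cells[2] + 1)
  cells <- expand.grid(ix = seq_len(n_cells[1]), iy = seq_len(n_cells[2]))
  grid <- data.frame(
    cell = seq_len(nrow(cells)),
    xmin = xb[cells$ix], xmax = xb[cells$ix + 1],
    ymin = yb[cells$iy], ymax = yb[cells$iy + 1])
  grid$lon <- (grid$xmin + grid$xmax) / 2
  grid$lat <- (grid$ymin + grid$ymax) / 2
  with_seed(seed, {
    grid$bio1 <- temp_at_equator + temp_gradient * grid$lat +
      stats::rnorm(nrow(grid), 0, noise_sd)
    grid$bio12 <- precip_base + precip_gradient * grid$lon +
      stats::rnorm(nrow(grid), 0, noise_sd)
  })
  class(grid) <- c("climate_grid", "data.frame")
  grid
}

#' Simulate occurrence records under Gaussian climate filtering
#'
#' Each species' points fall in grid cells with probability proportional to
#' a Gaussian kernel of the cell's BIO1 around the species' climate optimum
#' (width = the species' tolerance), uniformly within the chosen cell. With
#' optima evolved by Brownian motion this induces environmental filtering:
#' nearby cells host phylogenetically close species.
#'
#' @param tree a `phylo` tree (defines the species set).
#' @param statuses named status vector from [assign_statuses()].
#' @param optima named numeric vector of per-species climate optima (BIO1
#'   units), e.g. from [brownian_trait()].
#' @param tolerance niche breadth (BIO1 units, > 0); scalar or per-species
#'   named vector.
#' @param grid a `climate_grid`.
#' @param points_per_species records per species (default 124, a typical
#'   cleaned-occurrence density per species in national-scale alien floras).
#' @param seed integer seed.
#' @return data frame with columns `species, lon, lat, status`.
#' @export
simulate_occurrences <- function(tree, statuses, optima, tolerance = 3,
                                 grid, points_per_species = 124, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(grid, "climate_grid"))
  sp <- tree$tip.label
  if (!all(sp %in% names(statuses))) stop("statuses missing for some species",
                                          call. = FALSE)
  if (!all(sp %in% names(optima))) stop("optima missing for some species",
                                        call. = FALSE)
  tol <- if (length(tolerance) == 1)
    stats::setNames(rep(tolerance, length(sp)), sp) else tolerance
  if (any(tol[sp] <= 0)) stop("tolerance must be > 0", call. = FALSE)
  with_seed(seed, {
    recs <- lapply(sp, function(s) {
      logw <- stats::dnorm(grid$bio1, optima[s], tol[s], log = TRUE)
      w <- exp(logw - max(logw))
      if (!any(is.finite(w)) || sum(w) == 0)
        stop("zero total placement probability for ", s, call. = FALSE)
      k <- sample.int(nrow(grid), points_per_species, replace = TRUE, prob = w)
      data.frame(
        species = s,
        lon = stats::runif(points_per_species, grid$xmin[k], grid$xmax[k]),
        lat = stats::runif(points_per_species, grid$ymin[k], grid$ymax[k]),
        status = unname(statuses[s]))
    })
    do.call(rbind, recs)
  })
}

#' Simulate a complete synthetic invasion dataset
#'
#' Convenience wrapper chaining the generators: Yule tree, Brownian climate
#' optima, invasion statuses (clade-biased invasives by default, so the
#' invasive pool is lineage-restricted), multi-scale region lattices, a
#' smooth climate grid, and climate-filtered occurrences. Defaults emulate a
#' national alien flora: 706 species in proportions 165/222/319, four
#' spatial scales of 7/16/34/47 units, ~124 records per species over a
#' China-like extent.
#'
#' @param n_species number of species.
#' @param proportions status proportions (introduced, naturalized, invasive).
#' @param status_mode `"clade_biased"` (default) or `"random"`.
#' @param extent lon/lat box, default `c(73, 135, 18, 53)`.
#' @param region_counts units per scale.
#' @param n_cells climate grid resolution.
#' @param sigma2 Brownian rate of the climate optimum.
#' @param tolerance niche breadth (BIO1 units).
#' @param points_per_species records per species.
#' @param temp_gradient,precip_gradient,noise_sd climate field parameters.
#' @param seed master seed; stage seeds are derived from it.
#' @return list with elements `tree, statuses, optima, tolerance, grid,
#'   regions, occurrences, seed`.
#' @export
simulate_invasion_dataset <- function(n_species = 706,
                                      proportions = c(introduced = 165,
                                                      naturalized = 222,
                                                      invasive = 319) / 706,
                                      status_mode = "clade_biased",
                                      extent = c(73, 135, 18, 53),
                                      region_counts = c(mht = 7, kgc = 16,
                                                        pro = 34, eco = 47),
                                      n_cells = c(40, 30),
                                      sigma2 = 25, tolerance = 3,
                                      points_per_species = 124,
                                      temp_gradient = -0.55,
                                      precip_gradient = 8,
                                      noise_sd = 0.5,
                                      seed = 1L) {
  tree <- simulate_yule_tree(n_species, birth_rate = 1,
                             seed = derive_seed(seed, 1))
  # scale the Brownian rate to tree height so niche spread is comparable
  # across tree sizes: tip optima sd ~ sqrt(sigma2) regardless of height
  height <- max(node_depths(tree)[seq_len(ape::Ntip(tree))])
  grid <- simulate_climate_grid(extent, n_cells,
                                temp_gradient = temp_gradient,
                                precip_gradient = precip_gradient,
                                noise_sd = noise_sd,
                                seed = derive_seed(seed, 2))
  optima <- brownian_trait(tree, sigma2 / height,
                           root_value = mean(grid$bio1),
                           seed = derive_seed(seed, 3))
  statuses <- assign_statuses(tree$tip.label, proportions,
                              mode = status_mode, tree = tree,
                              seed = derive_seed(seed, 4))
  regions <- simulate_regions(extent, region_counts)
  occ <- simulate_occurrences(tree, statuses, optima, tolerance, grid,
                              points_per_species,
                              seed = derive_seed(seed, 5))
  list(tree = tree, statuses = statuses, optima = optima,
       tolerance = tolerance, grid = grid, regions = regions,
       occurrences = occ, seed = seed)
}
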