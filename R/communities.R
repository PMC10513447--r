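STATUS_LEVELS <- c("introduced", "naturalized", "invasive")

COMMUNITY_TYPES <- list(
  Inv    = "invasive",
  Nat    = "naturalized",
  Int    = "introduced",
  InvNat = c("invasive", "naturalized"),
  InvInt = c("invasive", "introduced"),
  NatInt = c("naturalized", "introduced"),
  All    = c("invasive", "naturalized", "introduced"))

check_occurrences <- function(occ) {
  need <- c("species", "lon", "lat", "status")
  if (!all(need %in% names(occ)))
    stop("occurrence table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(occ$lat < -90 | occ$lat > 90) || any(occ$lon < -180 | occ$lon > 180))
    stop("coordinates out of range", call. = FALSE)
  bad <- setdiff(unique(occ$status), STATUS_LEVELS)
  if (length(bad))
    stop("illegal status values: ", paste(bad, collapse = ", "), call. = FALSE)
  occ
}

#' Remove exact duplicate occurrence coordinates per species
#'
#' Keeps the first record of each (species, lon, lat) triple; coordinates
#' are compared exactly, so points differing in any decimal are retained.
#'
#' @param occ occurrence data frame (`species, lon, lat, status`).
#' @return the deduplicated data frame.
#' @export
dedupe_occurrences <- function(occ) {
  check_occurrences(occ)
  occ[!duplicated(occ[c("species", "lon", "lat")]), , drop = FALSE]
}

#' Spatially thin occurrence records
#'
#' Greedy per-species rarefaction: walking the records in order, a record is
#' kept iff it lies at least `min_dist_km` (great-circle, haversine on a
#' 6371-km sphere) from every previously kept record of the same species.
#' With `presort = TRUE` (default) records are first sorted by
#' (species, lon, lat) so the result is independent of input order.
#'
#' @param occ occurrence data frame.
#' @param min_dist_km minimum retained distance in km (default 5, matching
#'   a 2.5-arcminute climate grid resolution).
#' @param presort sort records by (species, lon, lat) before thinning.
#' @return the thinned data frame.
#' @export
thin_occurrences <- function(occ, min_dist_km = 5, presort = TRUE) {
  if (min_dist_km <= 0) stop("min_dist_km must be positive", call. = FALSE)
  check_occurrences(occ)
  if (presort) occ <- occ[order(occ$species, occ$lon, occ$lat), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(occ)), occ$species), function(ix) {
    if (length(ix) == 1L) return(ix)
    lon <- occ$lon[ix]; lat <- occ$lat[ix]
    kept <- 1L
    for (i in seq_along(ix)[-1]) {
      d <- haversine_km(lon[kept], lat[kept], lon[i], lat[i])
      if (all(d >= min_dist_km)) kept <- c(kept, i)
    }
    ix[kept]
  }), use.names = FALSE)
  occ[sort(keep), , drop = FALSE]
}

# TRUE for points inside [xmin,xmax] x [ymin,ymax] (closed bounds).
in_rect <- function(lon, lat, rect) {
  lon >= rect$xmin & lon <= rect$xmax & lat >= rect$ymin & lat <= rect$ymax
}

check_lattice_disjoint <- function(regions) {
  n <- nrow(regions)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (regions$xmin[i] < regions$xmax[j] && regions$xmax[i] > regions$xmin[j] &&
        regions$ymin[i] < regions$ymax[j] && regions$ymax[i] > regions$ymin[j])
      stop("overlapping region units: ", regions$id[i], ", ", regions$id[j],
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign occurrence records to spatial units, building a community matrix
#'
#' Counts each species' records per unit of one region partition. A point on
#' a shared boundary is assigned to the unit with the lexicographically
#' smallest id; points outside every unit are dropped (their count is kept
#' in the `n_dropped` attribute, the analog of removing points that fall in
#' the sea).
#'
#' @param occ occurrence data frame (deduplicated/thinned upstream).
#' @param regions a `region_lattice` data frame (`id, xmin, xmax, ymin,
#'   ymax`), units non-overlapping.
#' @return an integer matrix (units x species) of class `community_matrix`
#'   with attributes `scale` and `n_dropped`. Units with no records keep a
#'   row of zeros.
#' @export
assign_to_regions <- function(occ, regions) {
  check_occurrences(occ)
  stopifnot(is.data.frame(regions),
            all(c("id", "xmin", "xmax", "ymin", "ymax") %in% names(regions)))
  check_lattice_disjoint(regions)
  regions <- regions[order(regions$id), , drop = FALSE]
  species <- sort(unique(occ$species))
  mat <- matrix(0L, nrow(regions), length(species),
                dimnames = list(regions$id, species))
  unit <- rep(NA_character_, nrow(occ))
  for (r in seq_len(nrow(regions))) {
    hit <- is.na(unit) & in_rect(occ$lon, occ$lat, regions[r, ])
    unit[hit] <- regions$id[r]   # ids ascending: first match = smallest id
  }
  dropped <- sum(is.na(unit))
  if (dropped > 0)
    msg("assign_to_regions: ", dropped, " record(s) outside all units dropped")
  tab <- table(factor(unit, levels = regions$id),
               factor(occ$species, levels = species))
  mat[] <- as.integer(tab)
  attr(mat, "scale") <- attr(regions, "scale")
  attr(mat, "n_dropped") <- dropped
  class(mat) <- c("community_matrix", class(mat))
  mat
}

#' Build the seven status-defined assemblages per spatial unit
#'
#' For every unit, species present there are subset by invasion status into
#' the community types Inv, Nat, Int, their pairwise unions InvNat, InvInt,
#' NatInt, and All (every status). Abundances are the unit's occurrence
#' counts, carried unchanged. Assemblages with fewer than 2 species are
#' emitted but flagged unusable for the phylogenetic metrics.
#'
#' @param mat a `community_matrix`.
#' @param statuses named status vector covering every species in `mat`.
#' @return long data frame `scale, unit, community_type, species, abundance`
#'   with attribute `summary` (per unit x type species counts and usability).
#' @export
build_assemblages <- function(mat, statuses) {
  stopifnot(inherits(mat, "community_matrix"))
  species <- colnames(mat)
  missing <- setdiff(species, names(statuses))
  if (length(missing))
    stop("species without status: ", paste(missing, collapse = ", "),
         call. = FALSE)
  scale <- attr(mat, "scale")
  if (is.null(scale)) scale <- "scale"
  st <- statuses[species]
  rows <- list()
  for (u in rownames(mat)) {
    counts <- mat[u, ]
    present <- species[counts > 0]
    for (ct in names(COMMUNITY_TYPES)) {
      sel <- present[st[present] %in% COMMUNITY_TYPES[[ct]]]
      if (!length(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        scale = scale, unit = u, community_type = ct,
        species = sel, abundance = as.integer(counts[sel]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scale = character(), unit = character(),
               community_type = character(), species = character(),
               abundance = integer())
  rownames(out) <- NULL
  smry <- stats::aggregate(species ~ scale + unit + community_type, out, length)
  names(smry)[4] <- "n_species"
  smry$usable <- smry$n_species >= 2
  attr(out, "summary") <- smry
  out
}

#' Read/write occurrence CSV
#'
#' Plain UTF-8 comma-separated files with a header and columns
#' `species, lon, lat, status`.
#'
#' @param path file path.
#' @param occ occurrence data frame (for writing).
#' @return the occurrence data frame (reading) or `path` invisibly.
#' @export
read_occurrences_csv <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_occurrences(occ)
}

#' @rdname read_occurrences_csv
#' @export
write_occurrences_csv <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write region lattices as GeoJSON
#'
#' Each unit becomes a Polygon feature with properties `id` and `scale`;
#' all scales go into one FeatureCollection.
#'
#' @param regions named list of `region_lattice` data frames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  if (inherits(regions, "region_lattice")) regions <- list(regions)
  feats <- list()
  for (sc in names(regions)) {
    df <- regions[[sc]]
    for (i in seq_len(nrow(df))) {
      ring <- list(c(df$xmin[i], df$ymin[i]), c(df$xmax[i], df$ymin[i]),
                   c(df$xmax[i], df$ymax[i]), c(df$xmin[i], df$ymax[i]),
                   c(df$xmin[i], df$ymin[i]))
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(id = df$id[i], scale = sc),
        geometry = list(type = "Polygon", coordinates = list(ring)))
    }
  }
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read rectangular region lattices from GeoJSON
#'
#' Expects a FeatureCollection of axis-aligned rectangular Polygons carrying
#' `id` (and optionally `scale`) properties, the format written by
#' [write_regions_geojson()]. Non-rectangular polygons are rejected; convert
#' irregular geometries to a lattice upstream.
#'
#' @param path GeoJSON file.
#' @return named list of `region_lattice` data frames, one per scale.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  rows <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon features are supported", call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    if (length(unique(round(xs, 10))) != 2 || length(unique(round(ys, 10))) != 2)
      stop("feature '", f$properties$id,
           "' is not an axis-aligned rectangle", call. = FALSE)
    data.frame(id = f$properties$id,
               scale = if (is.null(f$properties$scale)) "scale"
                       else f$properties$scale,
               xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
  })
  df <- do.call(rbind, rows)
  out <- lapply(split(df, df$scale), function(d) {
    d2 <- d[setdiff(names(d), "scale")]
    rownames(d2) <- NULL
    attr(d2, "scale") <- d$scale[1]
    class(d2) <- c("region_lattice", "data.frame")
    d2
  })
  out[unique(df$scale)]
}

#' Export a community matrix as a long-format CSV
#'
#' Columns `scale, unit, species, count`, zero counts omitted.
#'
#' @param mat a `community_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_community_csv <- function(mat, path) {
  stopifnot(inherits(mat, "community_matrix"))
  idx <- which(mat > 0, arr.ind = TRUE)
  df <- data.frame(scale = attr(mat, "scale"),
                   unit = rownames(mat)[idx[, 1]],
                   species = colnames(mat)[idx[, 2]],
                   count = mat[idx])
  df <- df[order(df$unit, df$species), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
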