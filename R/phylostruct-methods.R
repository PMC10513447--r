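#' @export
print.phylostruct <- function(x, ...) {
  res <- x$results
  cat("Phylogenetic community structure (NRI/NTI, tip-shuffle null)\n")
  cat(sprintf("  null pool: %d tips; replicates: %d%s\n", x$n_tips,
              x$replicates,
              if (is.null(x$seed)) "" else sprintf("; seed: %s", x$seed)))
  cat(sprintf("  assemblages: %d (%d usable) across %d scale(s), modes: %s\n",
              nrow(res), sum(res$usable),
              length(unique(res$scale)),
              paste(unique(res$data_mode), collapse = ", ")))
  ok <- res[res$usable & res$ses_defined, , drop = FALSE]
  if (nrow(ok))
    cat(sprintf("  mean NRI: %.3f   mean NTI: %.3f\n",
                mean(ok$NRI), mean(ok$NTI)))
  invisible(x)
}

#' Summarize phylogenetic structure by community type and scale
#'
#' Mean and standard error of NRI and NTI per community type and per scale,
#' the standard summary used to compare invasion stages and spatial tiers.
#'
#' @param object a `phylostruct`.
#' @param by grouping columns of the results table.
#' @param ... unused.
#' @return data frame of group sizes, means and standard errors.
#' @export
summary.phylostruct <- function(object,
                                by = c("community_type", "scale", "data_mode"),
                                ...) {
  res <- object$results
  res <- res[res$usable & res$ses_defined, , drop = FALSE]
  if (!nrow(res)) return(data.frame())
  se <- function(v) stats::sd(v) / sqrt(length(v))
  agg <- stats::aggregate(res[c("NRI", "NTI")], res[by], function(v)
    c(n = length(v), mean = mean(v), se = se(v)))
  out <- cbind(agg[by],
               n = agg$NRI[, "n"],
               NRI_mean = agg$NRI[, "mean"], NRI_se = agg$NRI[, "se"],
               NTI_mean = agg$NTI[, "mean"], NTI_se = agg$NTI[, "se"])
  out[do.call(order, out[by]), , drop = FALSE]
}

#' @export
as.data.frame.phylostruct <- function(x, ...) x$results

#' Plot assemblages in NRI/NTI space
#'
#' Scatter of NTI against NRI, colored by community type, with the zero
#' lines separating clustering (positive) from overdispersion (negative).
#'
#' @param x a `phylostruct`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phylostruct <- function(x, ...) {
  res <- x$results
  res <- res[res$usable & res$ses_defined, , drop = FALSE]
  if (!nrow(res)) stop("no defined results to plot", call. = FALSE)
  types <- sort(unique(res$community_type))
  cols <- stats::setNames(grDevices::hcl.colors(max(3, length(types)),
                                                "Dark 3")[seq_along(types)],
                          types)
  graphics::plot(res$NRI, res$NTI, col = cols[res$community_type], pch = 19,
                 xlab = "NRI (clustering →)",
                 ylab = "NTI (clustering →)", ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey50")
  graphics::legend("topleft", legend = types, col = cols[types], pch = 19,
                   bty = "n", cex = 0.8)
  invisible(x)
}
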