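#' Frontier scope
#'
#' Names the reference technology used when scoring: the pooled
#' meta-frontier over all provinces, or a group frontier built from
#' one group's observations only.  Reference observations are pooled
#' over all years by default (one intertemporal frontier per scope);
#' `pooling = "per_year"` builds a separate frontier per calendar
#' year.
#'
#' @param kind `"meta"` or `"group"`.
#' @param grouping named character vector mapping every province to a
#'   group label; required when `kind = "group"`.
#' @param pooling `"pooled_years"` (default) or `"per_year"`.
#' @return a `frontier_scope` list.
#' @export
frontier_scope <- function(kind = c("meta", "group"), grouping = NULL,
                           pooling = c("pooled_years", "per_year")) {
  kind <- match.arg(kind)
  pooling <- match.arg(pooling)
  if (kind == "group" && is.null(grouping)) {
    stop_mraedid("group scope requires a grouping map", "grouping_error")
  }
  structure(list(kind = kind, grouping = grouping, pooling = pooling),
            class = "frontier_scope")
}

# province -> region map from the panel's region column
region_grouping <- function(panel) {
  df <- as.data.frame(panel)
  first <- !duplicated(df$province)
  stats::setNames(df$region[first], df$province[first])
}

#' Group- and meta-frontier efficiency tables
#'
#' `meta_efficiencies()` scores every unit-period against the
#' technology pooled over all provinces; `group_efficiencies()` scores
#' each unit-period only against its own group's observations (by
#' default the panel's region labels).  Because the meta reference set
#' contains every group set, meta scores can never exceed group scores.
#'
#' @param panel a `province_panel`.
#' @param grouping named vector province -> group label; defaults to
#'   the panel's `region` column.
#' @param pooling frontier pooling, see [frontier_scope()].
#' @param rts,tol passed to [score_all()].
#' @return an efficiency table (`province`, `year`, `scope`,
#'   `efficiency`).
#' @export
meta_efficiencies <- function(panel, pooling = "pooled_years",
                              rts = "CRS", tol = 1e-9) {
  score_all(panel, frontier_scope("meta", pooling = pooling),
            rts = rts, tol = tol)
}

#' @rdname meta_efficiencies
#' @export
group_efficiencies <- function(panel, grouping = NULL,
                               pooling = "pooled_years",
                               rts = "CRS", tol = 1e-9) {
  if (is.null(grouping)) grouping <- region_grouping(panel)
  if (pooling == "per_year") {
    sizes <- table(grouping)
    if (any(sizes == 1L)) {
      warning("group(s) with a single province under per-year pooling: ",
              paste(names(sizes)[sizes == 1L], collapse = ", "),
              " (score 1 by construction)")
    }
  }
  score_all(panel, frontier_scope("group", grouping, pooling),
            rts = rts, tol = tol)
}

#' Technology gap ratio
#'
#' Pairs meta- and group-frontier efficiencies per unit-period and
#' forms `TGR = e_meta / e_group`, the share of a group's best
#' practice that global best practice would still allow: 1 means the
#' group frontier touches the meta-frontier, smaller values measure
#' the group's technology gap.
#'
#' @param meta,group efficiency tables aligned on `(province, year)`.
#' @param tol tolerance above 1 before a ratio is treated as an error.
#' @return data frame `province`, `year`, `e_meta`, `e_group`, `tgr`
#'   (full precision; round at the reporting layer).
#' @export
technology_gap_ratio <- function(meta, group, tol = 1e-6) {
  need <- c("province", "year", "efficiency")
  stopifnot(all(need %in% names(meta)), all(need %in% names(group)))
  m <- meta[, need]; names(m)[3] <- "e_meta"
  g <- group[, need]; names(g)[3] <- "e_group"
  if (nrow(m) != nrow(g) ||
      !setequal(paste(m$province, m$year), paste(g$province, g$year))) {
    stop_mraedid("meta and group tables are not aligned on (province, year)",
                 "alignment_error")
  }
  out <- merge(m, g, by = c("province", "year"))
  if (any(out$e_group <= 0)) {
    bad <- out[out$e_group <= 0, ][1, ]
    stop_mraedid(sprintf("group efficiency is zero for (%s, %s)",
                         bad$province, bad$year), "division_error")
  }
  out$tgr <- out$e_meta / out$e_group
  over <- which(out$tgr > 1 + tol)
  if (length(over)) {
    bad <- out[over[1], ]
    stop_mraedid(sprintf("TGR above 1 by more than tol for (%s, %s): %.8f",
                         bad$province, bad$year, bad$tgr),
                 "tgr_error", list(rows = out[over, ]))
  }
  out <- out[order(out$province, out$year), ]
  rownames(out) <- NULL
  class(out) <- c("tgr_table", "data.frame")
  out
}

#' Regional summary of scores
#'
#' Time-averages a score per province, then takes the unweighted mean
#' over provinces within each region and overall.  Both averaging
#' orders coincide on a balanced panel.  Means are computed at full
#' precision and rounded (half away from zero) only for display.
#'
#' @param scores data frame with `province`, a value column and
#'   optionally `year`.
#' @param grouping named vector province -> region covering every
#'   province in `scores`.
#' @param value name of the value column (default `"efficiency"`,
#'   falling back to `"tgr"` if present).
#' @param digits display rounding.
#' @return data frame `region`, `n_provinces`, `mean` (rounded), with
#'   a final `Overall` row; unrounded means in column `mean_raw`.
#' @export
regional_summary <- function(scores, grouping, value = NULL, digits = 3) {
  value <- value %||% if ("efficiency" %in% names(scores)) "efficiency"
                      else "tgr"
  stopifnot(value %in% names(scores), "province" %in% names(scores))
  uncovered <- setdiff(unique(scores$province), names(grouping))
  if (length(uncovered)) {
    stop_mraedid(paste0("provinces without a region: ",
                        paste(uncovered, collapse = ", ")),
                 "grouping_error")
  }
  prov_mean <- tapply(scores[[value]], scores$province, mean)
  reg <- grouping[names(prov_mean)]
  if (any(table(reg) == 0)) {
    stop_mraedid("empty region", "empty_group_error")
  }
  reg_means <- tapply(prov_mean, reg, mean)
  out <- data.frame(region = c(names(reg_means), "Overall"),
                    n_provinces = c(as.integer(table(reg)[names(reg_means)]),
                                    length(prov_mean)),
                    mean_raw = c(as.numeric(reg_means), mean(prov_mean)),
                    stringsAsFactors = FALSE)
  out$mean <- round_half_away(out$mean_raw, digits)
  out
}

#' Distributional summary of one year's scores
#'
#' Mean, standard deviation, moment skewness and the Gaussian-kernel
#' mode location (Silverman's rule-of-thumb bandwidth) of the score
#' distribution in one year — the numerical summary behind
#' kernel-density-trend narratives (peak location and asymmetry).
#'
#' @param scores an efficiency table.
#' @param year calendar year to summarise.
#' @return list `year`, `n`, `mean`, `sd`, `skewness`, `mode`.
#' @export
density_summary <- function(scores, year) {
  x <- scores$efficiency[scores$year == year]
  if (length(x) < 2L) {
    stop_mraedid("need at least 2 observations in the year",
                 "insufficient_data_error")
  }
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- if (s2 > 0) mean((x - m)^3) / s2^1.5 else 0
  mode_loc <- if (stats::sd(x) > 0) {
    d <- stats::density(x, bw = "nrd0", kernel = "gaussian")
    d$x[which.max(d$y)]
  } else x[1]
  list(year = as.integer(year), n = length(x), mean = m,
       sd = stats::sd(x), skewness = skew, mode = mode_loc)
}
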