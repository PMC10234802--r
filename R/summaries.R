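#' Assign cells to clean-shift groups
#'
#' Served cells (positive bus VMT in both study years) are split at the
#' median of the clean-shift statistic, computed over served cells only;
#' values at or below the median form the lower group. Unserved cells form
#' the third group.
#'
#' @param tbl Analysis or exposure table with `served` and the clean-shift
#'   column.
#' @param definition `"broad"` or `"narrow"`.
#' @return Factor of length `nrow(tbl)` with levels `no_service`,
#'   `at_or_below_median`, `above_median`; the median is attached as
#'   attribute `median`.
#' @export
dichotomize_clean_shift <- function(tbl, definition = "broad") {
  col <- paste0("delta_prop_clean_", definition)
  if (!col %in% names(tbl)) stop("missing column ", col, call. = FALSE)
  if (!any(tbl$served)) {
    stop("no served cells: cannot compute a clean-shift median", call. = FALSE)
  }
  med <- stats::median(tbl[[col]][tbl$served])
  g <- ifelse(!tbl$served, "no_service",
              ifelse(tbl[[col]] <= med, "at_or_below_median", "above_median"))
  g <- factor(g, levels = c("no_service", "at_or_below_median", "above_median"))
  attr(g, "median") <- med
  g
}

#' Citywide fleet composition by year
#'
#' Shares of each fuel type, the post-cutoff vintage share, and the clean
#' share under both definitions, per study year.
#'
#' @param rosters Roster table (`depot_id`, `year`, `fuel_type`,
#'   `model_year`, `count`).
#' @param definitions Named list of `clean_definition`s.
#' @return data.frame with one row per (year, category): columns `year`,
#'   `category`, `share`, plus `total` buses that year.
#' @export
fleet_composition <- function(rosters, definitions = clean_definitions()) {
  years <- sort(unique(rosters$year))
  if (length(years) < 2) {
    stop("rosters must cover both study years", call. = FALSE)
  }
  cutoffs <- unlist(lapply(definitions, function(d) d$vintage_cutoff))
  rows <- list()
  for (y in years) {
    r <- rosters[rosters$year == y, ]
    total <- sum(r$count)
    if (total == 0) stop("empty roster for year ", y, call. = FALSE)
    for (f in bus_fuel_types) {
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, category = f,
        share = sum(r$count[r$fuel_type == f]) / total, total = total)
    }
    for (co in unique(cutoffs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, category = paste0("post_", co, "_vintage"),
        share = sum(r$count[r$model_year >= co]) / total, total = total)
    }
    for (nm in names(definitions)) {
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, category = paste0("clean_", nm),
        share = sum(r$count[is_clean(r$fuel_type, r$model_year,
                                     definitions[[nm]])]) / total,
        total = total)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Three-group descriptive summary
#'
#' Mean and sample (n-1) standard deviation of each requested column within
#' each clean-shift group, plus group sizes and truck-route prevalence as a
#' percentage. The clean shift itself is reported in percentage points.
#' Single-cell groups report a blank (NA) SD; empty groups report n = 0 and
#' blank statistics.
#'
#' @param groups Factor from [dichotomize_clean_shift()].
#' @param tbl The analysis table the groups were computed from.
#' @param columns Numeric columns to summarize (defaults to the standard
#'   descriptive set present in the table).
#' @return data.frame of class `fs_group_table`: one row per (group,
#'   variable) with `n`, `mean`, `sd`; prevalence rows use `mean` as percent.
#' @export
group_summary <- function(groups, tbl, columns = NULL) {
  stopifnot(length(groups) == nrow(tbl))
  if (is.null(columns)) {
    cand <- c(grep("^delta_prop_clean_", names(tbl), value = TRUE),
              grep("^clean_vmt_", names(tbl), value = TRUE),
              grep("^total_vmt_", names(tbl), value = TRUE),
              "stop_proxy", "traffic_vmt", "d_no", "d_no2", "d_bc")
    columns <- intersect(cand, names(tbl))
  }
  rows <- list()
  for (g in levels(groups)) {
    sel <- groups == g
    n <- sum(sel)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, variable = "n_cells", n = n, mean = n, sd = NA_real_)
    prev <- if (n > 0 && "truck_route" %in% names(tbl)) {
      100 * mean(tbl$truck_route[sel])
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, variable = "truck_route_pct", n = n, mean = prev,
      sd = NA_real_)
    for (col in columns) {
      x <- tbl[[col]][sel]
      scale <- if (startsWith(col, "delta_prop_clean_")) 100 else 1
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = if (scale == 100) paste0(col, "_pct") else col,
        n = n,
        mean = if (n > 0) mean(x) * scale else NA_real_,
        sd = if (n > 1) stats::sd(x) * scale else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fs_group_table", "data.frame")
  out
}

#' @export
print.fs_group_table <- function(x, digits = 2, ...) {
  wide <- stats::reshape(
    as.data.frame(x)[, c("group", "variable", "mean", "sd")],
    direction = "wide", idvar = "variable", timevar = "group")
  cat("Per-group mean (SD):\n")
  print(wide, digits = digits, row.names = FALSE)
  invisible(x)
}
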