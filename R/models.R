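#' Assemble the per-cell analysis table
#'
#' Joins exposure, covariate and pollutant-change tables on `cell_id` and
#' derives the regression terms: `delta_prop_clean` (under both definitions
#' where present), `log_total_traffic = log1p(traffic in meters)`,
#' `truck_route`, and `log_bus_vmt_2009 = log1p(first-year total bus VMT in
#' meters)`. The log1p offset accommodates the zeros of unserved cells; the
#' unit (meters) and offset are recorded in the table attributes because
#' coefficient scale depends on both.
#'
#' @param exposure Exposure table from [compute_cell_exposure()].
#' @param covariates Covariate table from [generate_covariates()] (or any
#'   table with `cell_id`, `truck_route`, `traffic_vmt`).
#' @param surfaces Pollutant-change table (`cell_id` plus outcome columns).
#' @param year1 First study year (names the bus-VMT adjustment column).
#' @param sample `"all_cells"` (default: unserved cells enter with zero bus
#'   VMT and zero clean shift) or `"served_only"`.
#' @return data.frame, one row per included cell, with attributes
#'   `log_offset`, `vmt_unit`, `sample`.
#' @export
build_analysis_table <- function(exposure, covariates, surfaces,
                                 year1 = 2009,
                                 sample = c("all_cells", "served_only")) {
  sample <- match.arg(sample)
  tbl <- merge(exposure, covariates, by = "cell_id")
  tbl <- merge(tbl, surfaces, by = "cell_id")
  if (nrow(tbl) != nrow(exposure)) {
    stop("join mismatch: ", nrow(exposure), " exposure rows vs ",
         nrow(tbl), " joined rows", call. = FALSE)
  }
  tbl <- tbl[order(tbl$cell_id), ]
  tbl$log_total_traffic <- log1p(tbl$traffic_vmt)
  tbl$log_bus_vmt_2009 <- log1p(tbl[[paste0("total_vmt_", year1)]])
  if (sample == "served_only") tbl <- tbl[tbl$served, ]
  rownames(tbl) <- NULL
  attr(tbl, "log_offset") <- 1
  attr(tbl, "vmt_unit") <- "meters"
  attr(tbl, "sample") <- sample
  tbl
}

#' Regression terms for Models 1-3
#'
#' Model 1 is the clean shift alone; Model 2 adds total traffic volume (log)
#' and truck-route presence; Model 3 further adjusts for first-year total bus
#' traffic (log).
#'
#' @param model Integer 1, 2 or 3.
#' @return Character vector of term names (intercept excluded).
#' @export
model_terms <- function(model) {
  switch(as.character(model),
         "1" = "delta_prop_clean",
         "2" = c("delta_prop_clean", "log_total_traffic", "truck_route"),
         "3" = c("delta_prop_clean", "log_total_traffic", "truck_route",
                 "log_bus_vmt_2009"),
         stop("model must be 1, 2 or 3", call. = FALSE))
}

#' Fit the Model 1/2/3 suite for each pollutant change
#'
#' Fits the spatial error model for every requested pollutant and model
#' specification under one clean definition, and returns a tidy coefficients
#' table (the machine-readable analog of a published coefficients table:
#' estimate, 95% Wald interval, significance at p < 0.05, lambda, log-
#' likelihood, n). A model that fails to fit is recorded with an error
#' message and does not abort the suite.
#'
#' @param tbl Analysis table from [build_analysis_table()].
#' @param w An `fs_weights` matching the full grid that `tbl` was built on.
#' @param pollutants Outcome column names (default the three synthetic
#'   surfaces `d_no`, `d_no2`, `d_bc`).
#' @param models Integer subset of 1:3.
#' @param definition `"broad"` or `"narrow"`: selects the clean-shift column.
#' @param ev Optional precomputed eigenvalues of `w$W`.
#' @return List with `table` (data.frame of coefficients), `fits` (nested
#'   list of `sem_fit` objects), `errors` (named character).
#' @export
fit_model_suite <- function(tbl, w, pollutants = c("d_no", "d_no2", "d_bc"),
                            models = 1:3, definition = "broad", ev = NULL) {
  dpc_col <- paste0("delta_prop_clean_", definition)
  if (!dpc_col %in% names(tbl)) {
    stop("analysis table lacks column ", dpc_col, call. = FALSE)
  }
  if (w$n != nrow(tbl)) {
    # served_only subsets need weights restricted to the retained cells;
    # callers fit on the full grid by default
    stop("weights dimension (", w$n, ") does not match table rows (",
         nrow(tbl), ")", call. = FALSE)
  }
  if (is.null(ev)) ev <- weights_eigenvalues(w)
  rows <- list(); fits <- list(); errors <- character(0)
  for (poll in pollutants) {
    fits[[poll]] <- list()
    for (m in models) {
      terms <- model_terms(m)
      cols <- ifelse(terms == "delta_prop_clean", dpc_col, terms)
      X <- cbind(`(Intercept)` = 1, as.matrix(tbl[, cols, drop = FALSE]))
      colnames(X) <- c("(Intercept)", terms)
      key <- paste0(poll, "_model", m)
      fit <- tryCatch(sem_fit(tbl[[poll]], X, w, ev = ev),
                      error = function(e) conditionMessage(e))
      if (is.character(fit)) {
        errors[[key]] <- fit
        next
      }
      fits[[poll]][[paste0("model", m)]] <- fit
      z <- fit$coefficients / fit$se
      rows[[key]] <- data.frame(
        pollutant = poll, model = m, definition = definition,
        term = names(fit$coefficients),
        estimate = unname(fit$coefficients), se = unname(fit$se),
        ci_low = unname(fit$ci95[, "lower"]),
        ci_high = unname(fit$ci95[, "upper"]),
        p_value = 2 * stats::pnorm(-abs(z)),
        significant = 2 * stats::pnorm(-abs(z)) < 0.05,
        lambda = fit$lambda, loglik = fit$loglik, n = fit$n
      )
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, fits = fits, errors = errors)
}
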