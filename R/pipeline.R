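#' Run the full case-crossover analysis pipeline
#'
#' Convenience wrapper chaining the pipeline stages: compute segregation
#' scores from the census table, attach modifier values to the event
#' records, build time-stratified matched sets with lag-window exposure
#' covariates, and fit the conditional logistic model.
#'
#' @param events Event records (`record_id`, `death_date`,
#'   `block_group_id`, `race`, ...). If `cell_id` is absent, records are
#'   assigned their nearest grid cell from `lon`/`lat` columns or, when
#'   those are missing too, from block-group coordinates in `census`.
#' @param census Census race-count table (optionally with `lon`, `lat`).
#' @param exposure Long gridded exposure table.
#' @param spec A [cc_model_spec()]; default fits the unmodified model.
#' @param lags Exposure window, default two-day mean `c(0, 1)`.
#' @param pm25_max Optional daily PM2.5 ceiling (ug/m3); when given, the
#'   design is filtered with [restrict_below_threshold()] before fitting.
#' @return List with `fit` (a `cc_fit`), `design` (long matched-set
#'   table), and `scores` (segregation scores).
#' @export
cc_analysis <- function(events, census, exposure, spec = cc_model_spec(),
                        lags = c(0, 1), pm25_max = NULL) {
  scores <- segregation_scores(census)
  records <- merge(events, scores, by = "block_group_id", all.x = TRUE)
  if (!"cell_id" %in% names(records)) {
    cells <- exposure[!duplicated(exposure$cell_id),
                      c("cell_id", "lon", "lat")]
    if (all(c("lon", "lat") %in% names(events))) {
      records$cell_id <- assign_nearest_cell(records$lon, records$lat,
                                             cells)
    } else if (all(c("lon", "lat") %in% names(census))) {
      bg_cell <- assign_nearest_cell(census$lon, census$lat, cells)
      records$cell_id <- bg_cell[match(records$block_group_id,
                                       census$block_group_id)]
    } else {
      stop("no cell_id on records and no coordinates to assign one")
    }
  }
  design <- build_matched_sets(records, exposure, lags = lags)
  if (!is.null(pm25_max)) {
    design <- restrict_below_threshold(design, pm25_max)
  }
  fit <- fit_cc_model(design, spec)
  list(fit = fit, design = design, scores = scores)
}
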