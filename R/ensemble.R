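#' Select ensemble members by TSS
#'
#' Keeps every single model whose held-out TSS reaches `tss_min` and builds
#' the weighted-mean ensemble: member j gets normalized weight
#' `w_j = TSS_j / sum_j TSS_j`.
#'
#' @param scoreboard Tibble with one row per single model, columns `model`
#'   (list column of fitted `sdm_model`s) and `tss` (held-out TSS); the
#'   output of [run_model_battery()].
#' @param tss_min Minimum TSS for membership (default 0.7).
#' @return An `ensemble_model`: `members` (list of `sdm_model`), `tss`
#'   (member TSS scores), `weights` (normalized), `tss_min`.
#' @export
select_ensemble_members <- function(scoreboard, tss_min = 0.7) {
  assert_that(nrow(scoreboard) > 0, "scoreboard is empty")
  keep <- scoreboard$tss >= tss_min
  if (!any(keep))
    stop("no-members error: no single model reached TSS >= ", tss_min,
         " (max was ", round(max(scoreboard$tss), 3),
         "); review the threshold or the battery", call. = FALSE)
  members <- scoreboard$model[keep]
  tss <- scoreboard$tss[keep]
  structure(list(members = members, tss = tss, weights = tss / sum(tss),
                 tss_min = tss_min),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d members (TSS >= %g), TSS range [%.3f, %.3f]\n",
              length(x$members), x$tss_min, min(x$tss), max(x$tss)))
  invisible(x)
}

#' TSS-weighted ensemble prediction
#'
#' For each row i the ensemble suitability is the weighted mean of member
#' predictions, `sum_j TSS_j * p_ij / sum_j TSS_j` — a convex combination,
#' so always inside the members' range.
#'
#' @param ensemble An `ensemble_model`.
#' @param table Rows carrying every member's training variables.
#' @return Numeric probability vector.
#' @export
ensemble_predict <- function(ensemble, table) {
  if (nrow(table) == 0) return(numeric(0))
  preds <- vapply(ensemble$members, predict_suitability,
                  numeric(nrow(table)), table = table)
  if (nrow(table) == 1) preds <- matrix(preds, nrow = 1)
  as.numeric(preds %*% ensemble$weights)
}

# Map containers -------------------------------------------------------------

new_map <- function(values, grid, period_tag, provenance,
                    class_name, threshold = NULL) {
  structure(list(grid = grid, values = values, period_tag = period_tag,
                 provenance = provenance, threshold = threshold),
            class = class_name)
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<suitability_map> '%s' (%s): %d x %d, range [%.3f, %.3f]\n",
              x$period_tag, x$provenance, nrow(x$values), ncol(x$values),
              min(v), max(v)))
  invisible(x)
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> '%s': %d suitable of %d data cells (threshold %.3f)\n",
              x$period_tag, sum(x$values == 1, na.rm = TRUE),
              sum(!is.na(x$values)), x$threshold))
  invisible(x)
}

#' @export
as_tibble.suitability_map <- function(x, ...) map_to_tibble(x)
#' @export
as_tibble.binary_map <- function(x, ...) map_to_tibble(x)

map_to_tibble <- function(map) {
  cells <- which(!t(is.na(map$values))) - 1L
  cc <- cell_center(map$grid, cells)
  rc <- cell_rowcol(map$grid, cells)
  vals <- map$values[cbind(rc$row + 1L, rc$col + 1L)]
  tibble::tibble(cell = cells, x = cc$x, y = cc$y, value = vals)
}

#' Project a model or ensemble over a raster stack
#'
#' Predicts suitability for every non-nodata cell of the stack; nodata
#' propagates. Projecting onto the training-period stack reproduces
#' [ensemble_predict()] at sampled cells bit-identically.
#'
#' @param model_or_ensemble `sdm_model` or `ensemble_model`.
#' @param stack An [env_stack()] supplying every needed layer.
#' @return A `suitability_map`.
#' @export
project_map <- function(model_or_ensemble, stack) {
  cells <- which(!t(stack$nodata)) - 1L
  tbl <- extract_at_cells(stack, cells, labels = rep(NA_integer_, length(cells)))
  p <- if (inherits(model_or_ensemble, "ensemble_model"))
    ensemble_predict(model_or_ensemble, tbl)
  else predict_suitability(model_or_ensemble, tbl)
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  rc <- cell_rowcol(stack$grid, tbl$cell)
  vals[cbind(rc$row + 1L, rc$col + 1L)] <- p
  prov <- if (inherits(model_or_ensemble, "ensemble_model")) "ensemble"
          else model_or_ensemble$algorithm_id
  new_map(vals, stack$grid, stack$period_tag, prov, "suitability_map")
}

#' Permutation variable importance
#'
#' For each variable and shuffle, the variable's column alone is permuted and
#' the importance contribution is `1 - r` between original and
#' shuffled-input predictions (Pearson): 0 means no influence. For an
#' ensemble the same permutation is applied to every member, per-member
#' scores are combined by the ensemble's TSS weights into a per-shuffle
#' score, and the mean and SD are taken over shuffles.
#'
#' @param model `sdm_model` or `ensemble_model`.
#' @param table Evaluation rows (>= 3).
#' @param n_shuffles Permutations per variable (default 5).
#' @param seed Integer seed.
#' @return An `importance_scores` tibble: `variable`, `mean`, `sd`, with
#'   attributes `n_shuffles` and `seed`.
#' @export
permutation_importance <- function(model, table, n_shuffles = 5, seed = 1) {
  assert_that(nrow(table) >= 3, "need at least 3 rows")
  assert_that(n_shuffles >= 1, "n_shuffles must be >= 1")
  members <- if (inherits(model, "ensemble_model")) model$members else list(model)
  weights <- if (inherits(model, "ensemble_model")) model$weights else 1
  vars <- unique(unlist(lapply(members, `[[`, "variables")))
  orig <- lapply(members, predict_suitability, table = table)

  one_minus_r <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant prediction vector; importance recorded as 0")
      return(0)
    }
    1 - stats::cor(a, b)
  }

  rows <- purrr::map_dfr(vars, function(v) {
    per_shuffle <- vapply(seq_len(n_shuffles), function(s) {
      perm <- withr::with_seed(derive_seed(seed, s * 1000L + match(v, vars)),
                               sample(nrow(table)))
      shuffled <- table
      shuffled[[v]] <- shuffled[[v]][perm]
      member_scores <- vapply(seq_along(members), function(j) {
        if (!v %in% members[[j]]$variables) return(0)  # unused variable: exactly 0
        one_minus_r(orig[[j]], predict_suitability(members[[j]], shuffled))
      }, 0)
      sum(member_scores * weights)
    }, 0)
    tibble::tibble(variable = v, mean = mean(per_shuffle),
                   sd = if (n_shuffles > 1) stats::sd(per_shuffle) else 0)
  })
  structure(rows, n_shuffles = n_shuffles, seed = seed,
            class = c("importance_scores", class(rows)))
}

#' Coefficient-of-variation uncertainty map
#'
#' Per-cell SD/mean (sample SD) of the member suitability maps: where the
#' selected single models disagree relative to their mean, CV is high.
#' Cells with mean 0 become nodata; their count is attached as attribute
#' `n_zero_mean` (with a warning if positive).
#'
#' @param member_maps List of >= 2 `suitability_map`s on one grid.
#' @return A `suitability_map`-like `cv_map` whose values are CVs (>= 0,
#'   unbounded above).
#' @export
uncertainty_map <- function(member_maps) {
  assert_that(length(member_maps) >= 2, "need at least 2 member maps")
  g <- member_maps[[1]]$grid
  for (m in member_maps[-1])
    if (!grids_identical(m$grid, g))
      stop("alignment error: member maps are on different grids", call. = FALSE)
  arr <- vapply(member_maps, function(m) as.vector(m$values),
                numeric(length(member_maps[[1]]$values)))
  k <- length(member_maps)
  mu_v <- rowMeans(arr)
  sd_v <- sqrt(rowSums((arr - mu_v)^2) / (k - 1))
  mu <- matrix(mu_v, g$n_rows, g$n_cols)
  cv <- matrix(sd_v / mu_v, g$n_rows, g$n_cols)
  zero <- !is.na(mu) & mu == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with mean 0 set to nodata in CV map")
    cv[zero] <- NA_real_
  }
  out <- new_map(cv, g, member_maps[[1]]$period_tag, "cv", "cv_map")
  attr(out, "n_zero_mean") <- sum(zero)
  out
}

#' @export
print.cv_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<cv_map> '%s': %d x %d, CV range [%.3f, %.3f]\n",
              x$period_tag, nrow(x$values), ncol(x$values), min(v), max(v)))
  invisible(x)
}

#' Binarize a suitability map at a threshold
#'
#' Cells with suitability `>= threshold` become 1 (suitable); nodata
#' propagates. In the pipeline the threshold is the ensemble's max-TSS
#' cutoff, and it is always recorded on the result.
#'
#' @param map A `suitability_map`.
#' @param threshold Cutoff in `[0, 1]`.
#' @return A `binary_map`.
#' @export
binarize_map <- function(map, threshold) {
  assert_that(threshold >= 0 && threshold <= 1, "threshold must be in [0,1]")
  vals <- ifelse(is.na(map$values), NA_real_,
                 as.numeric(map$values >= threshold))
  new_map(vals, map$grid, map$period_tag, map$provenance, "binary_map",
          threshold = threshold)
}

#' Range expansion and contraction between two binary maps
#'
#' Compares current and future binary suitability on one grid:
#' expansion = cells suitable only in the future, contraction = cells
#' suitable only currently, unchanged = suitable in both; each converted to
#' km2 by the per-cell area. The identities
#' `unchanged + contraction = current suitable area` and
#' `unchanged + expansion = future suitable area` hold by construction.
#'
#' @param current_bin,future_bin `binary_map`s on the same grid with the
#'   same nodata mask.
#' @param cell_area_km2 Scalar cell area, or a matrix of per-cell areas
#'   (e.g. cosine-latitude-corrected for geographic grids).
#' @return A `range_change_summary`: one-row tibble with `expansion_km2`,
#'   `contraction_km2`, `unchanged_km2`, `current_km2`, `future_km2`,
#'   `cell_area_km2`, `from`, `to`.
#' @export
range_change <- function(current_bin, future_bin, cell_area_km2) {
  if (!grids_identical(current_bin$grid, future_bin$grid))
    stop("alignment error: binary maps are on different grids", call. = FALSE)
  if (!identical(is.na(current_bin$values), is.na(future_bin$values)))
    stop("alignment error: binary maps have different nodata masks", call. = FALSE)
  a <- if (is.matrix(cell_area_km2)) cell_area_km2
       else matrix(cell_area_km2, nrow(current_bin$values), ncol(current_bin$values))
  cur <- current_bin$values == 1
  fut <- future_bin$values == 1
  area <- function(mask) sum(a[which(mask)], na.rm = TRUE)
  out <- tibble::tibble(
    expansion_km2 = area(fut & !cur),
    contraction_km2 = area(cur & !fut),
    unchanged_km2 = area(cur & fut),
    current_km2 = area(cur),
    future_km2 = area(fut),
    cell_area_km2 = if (is.matrix(cell_area_km2)) NA_real_ else cell_area_km2,
    from = current_bin$period_tag, to = future_bin$period_tag)
  structure(out, class = c("range_change_summary", class(out)))
}

#' Per-row cell areas for a geographic grid
#'
#' Approximate km2 cell areas with the cosine-latitude correction, returned
#' as a full matrix for use as `cell_area_km2` in [range_change()].
#'
#' @param grid A geographic [grid_def()] (cell size in degrees).
#' @return Matrix of per-cell areas (km2).
#' @export
geographic_cell_areas <- function(grid) {
  km_per_deg <- 111.32
  lat <- grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  row_area <- (grid$cell_size * km_per_deg)^2 * cos(lat * pi / 180)
  matrix(rep(row_area, grid$n_cols), grid$n_rows, grid$n_cols)
}

#' @export
tidy.ensemble_model <- function(x, ...) {
  tibble::tibble(
    member = seq_along(x$members),
    algorithm = vapply(x$members, `[[`, "", "algorithm_id"),
    run_id = vapply(x$members, `[[`, 1L, "run_id"),
    pa_replicate_id = vapply(x$members, `[[`, 1L, "pa_replicate_id"),
    tss = x$tss, weight = x$weights)
}

#' @export
glance.ensemble_model <- function(x, ...) {
  tibble::tibble(n_members = length(x$members), tss_min = x$tss_min,
                 mean_member_tss = mean(x$tss), max_member_tss = max(x$tss))
}
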