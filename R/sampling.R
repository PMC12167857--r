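#' Clean raw occurrence records
#'
#' Collapses exact coordinate duplicates, drops records with non-finite or
#' out-of-range coordinates (latitude beyond +/-90 or longitude beyond
#' +/-180 on geographic grids), and drops records falling outside the grid.
#' Removal counts per class are attached as attribute `removals`.
#'
#' @param raw_records Data frame with columns `x`, `y` and optionally
#'   `species`, `source`.
#' @param grid A [grid_def()] the records must fall on.
#' @param species_tag Species label recorded on the result (defaults to the
#'   first `species` value, if present).
#' @return An `occurrence_set`: a tibble with columns `x`, `y`, `source`,
#'   `cell`, carrying `species_tag` and `grid` as attributes.
#' @export
clean_occurrences <- function(raw_records, grid, species_tag = NULL) {
  raw <- tibble::as_tibble(raw_records)
  assert_that(all(c("x", "y") %in% names(raw)), "raw records need x and y columns")
  n0 <- nrow(raw)
  if (!"source" %in% names(raw)) raw$source <- NA_character_
  species_tag <- species_tag %||%
    (if ("species" %in% names(raw)) as.character(raw$species[1]) else "unknown")

  finite <- is.finite(raw$x) & is.finite(raw$y)
  in_range <- finite
  if (is_geographic(grid))
    in_range <- finite & abs(raw$y) <= 90 & abs(raw$x) <= 180
  occ <- raw[in_range, ]
  n_erroneous <- n0 - nrow(occ)

  dup <- duplicated(occ[, c("x", "y")])
  occ <- occ[!dup, ]
  n_duplicate <- sum(dup)

  occ$cell <- xy_to_cell(grid, occ$x, occ$y)
  out_grid <- is.na(occ$cell)
  occ <- occ[!out_grid, ]
  n_out_of_grid <- sum(out_grid)

  if (nrow(occ) == 0)
    stop("empty-input error: no occurrence records survive cleaning", call. = FALSE)

  out <- occ[, c("x", "y", "source", "cell")]
  structure(out,
            species_tag = species_tag, grid = grid,
            removals = c(erroneous = n_erroneous, duplicate = n_duplicate,
                         out_of_grid = n_out_of_grid),
            class = c("occurrence_set", class(out)))
}

occ_grid <- function(occ) attr(occ, "grid")

new_occurrence_set <- function(tbl, template) {
  structure(tbl,
            species_tag = attr(template, "species_tag"),
            grid = occ_grid(template),
            removals = attr(template, "removals"),
            class = c("occurrence_set", setdiff(class(tbl), "occurrence_set")))
}

#' Rarefy occurrences to one record per grid cell
#'
#' Keeps the first record (in input order) in each occupied cell, so that at
#' most one observation falls inside any grid cell. Idempotent.
#'
#' @param occ An `occurrence_set` from [clean_occurrences()].
#' @return An `occurrence_set` with one row per occupied cell.
#' @export
rarefy_to_grid <- function(occ) {
  new_occurrence_set(occ[!duplicated(occ$cell), ], occ)
}

#' Spatially thin occurrences to a minimum inter-record distance
#'
#' Randomized greedy thinning in the spirit of spThin: repeatedly delete a
#' record with the most neighbours closer than `min_dist_km` (random
#' tie-break) until no pair violates the distance, repeat for `n_tries`
#' randomized passes, and keep the pass retaining the most records.
#' Deterministic under a fixed seed.
#'
#' @param occ An `occurrence_set`.
#' @param min_dist_km Minimum allowed distance between retained records, km
#'   (map units on planar grids). 0 disables thinning.
#' @param n_tries Number of randomized greedy passes.
#' @param seed Integer seed.
#' @return A thinned `occurrence_set`.
#' @export
spatial_thin <- function(occ, min_dist_km = 5, n_tries = 10, seed = 1) {
  assert_that(min_dist_km >= 0, "min_dist_km must be >= 0")
  n <- nrow(occ)
  if (min_dist_km == 0 || n < 2) return(occ)
  d <- point_distances(occ_grid(occ), cbind(occ$x, occ$y), cbind(occ$x, occ$y))
  close <- d < min_dist_km
  diag(close) <- FALSE
  best <- NULL
  withr::with_seed(seed, {
    for (try in seq_len(n_tries)) {
      keep <- rep(TRUE, n)
      deg <- rowSums(close)
      while (any(deg[keep] > 0)) {
        worst <- which(keep & deg == max(deg[keep]))
        victim <- if (length(worst) > 1) sample(worst, 1) else worst
        keep[victim] <- FALSE
        deg <- deg - close[, victim]
      }
      if (is.null(best) || sum(keep) > sum(best)) best <- keep
    }
  })
  new_occurrence_set(occ[best, ], occ)
}

#' Build a surface range envelope from presence environments
#'
#' The SRE is the rectangular environmental envelope bounded, per continuous
#' variable, by the empirical `q` and `1 - q` quantiles of the presence
#' values (linear-interpolation quantile definition). Cells whose values fall
#' inside every variable's bounds are "presence-like".
#'
#' @param presence_table Data frame of presence rows; only numeric
#'   (continuous) columns enter the envelope — `label`/`cell` bookkeeping
#'   columns and factors are ignored.
#' @param q Quantile level in `[0, 0.5)`; `q = 0` gives the min/max envelope.
#' @return An `sre_envelope`: tibble with columns `variable`, `lower`,
#'   `upper`, plus attribute `q`.
#' @export
build_sre_envelope <- function(presence_table, q = 0.025) {
  assert_that(q >= 0 && q < 0.5, "q must be in [0, 0.5)")
  tbl <- tibble::as_tibble(presence_table)
  tbl <- tbl[, setdiff(names(tbl), c("label", "cell")), drop = FALSE]
  num <- tbl[, vapply(tbl, is.numeric, TRUE), drop = FALSE]
  assert_that(ncol(num) >= 1, "no continuous variables to build an envelope from")
  assert_that(nrow(num) >= 2, "need at least 2 presence rows")
  bounds <- purrr::imap_dfr(num, function(v, nm) {
    qs <- stats::quantile(v, c(q, 1 - q), type = 7, names = FALSE)
    tibble::tibble(variable = nm, lower = qs[1], upper = qs[2])
  })
  structure(bounds, q = q, class = c("sre_envelope", class(bounds)))
}

# TRUE where a row of environments falls inside the envelope in EVERY
# variable (i.e. is presence-like). Rows with NA count as outside.
envelope_inside <- function(envelope, table) {
  inside <- rep(TRUE, nrow(table))
  for (i in seq_len(nrow(envelope))) {
    v <- table[[envelope$variable[i]]]
    inside <- inside & !is.na(v) & v >= envelope$lower[i] & v <= envelope$upper[i]
  }
  inside
}

#' Sample pseudo-absence replicates outside the presence envelope
#'
#' The accessible background is every non-nodata cell within `buffer_km` of a
#' presence. Eligible pseudo-absence cells are background cells that are not
#' presences and whose environment falls outside the envelope in at least one
#' variable (too unlike the presences to be plausible habitat). Each
#' replicate draws `n` cells uniformly without replacement, with a
#' replicate-specific seed derived from the master seed.
#'
#' @param stack The [env_stack()] supplying environments and the nodata mask.
#' @param occ Presence `occurrence_set` (rarefied).
#' @param envelope An [build_sre_envelope()] result.
#' @param buffer_km Background radius around each presence (110 km mirrors
#'   beetle maximum daily dispersal estimates).
#' @param n Pseudo-absences per replicate.
#' @param n_reps Number of replicates.
#' @param seed Master integer seed; replicate r uses `seed + r`.
#' @return List of `pseudo_absence_set` tibbles (`replicate_id`, `cell`),
#'   each carrying its `seed` and the shared `n_eligible` as attributes.
#' @export
sample_pseudo_absences <- function(stack, occ, envelope, buffer_km = 110,
                                   n = 1000, n_reps = 10, seed = 1) {
  assert_that(n >= 1 && n_reps >= 1, "n and n_reps must be >= 1")
  grid <- stack$grid
  presence_cells <- unique(occ$cell)
  all_cells <- which(!t(stack$nodata)) - 1L
  if (!length(all_cells))
    stop("configuration error: stack has no data cells", call. = FALSE)

  d <- cell_distances(grid, all_cells, presence_cells)
  background <- all_cells[apply(d, 1, min) <= buffer_km]
  if (!length(background))
    stop("configuration error: empty background (buffer too small?)", call. = FALSE)

  candidates <- setdiff(background, presence_cells)
  env <- extract_at_cells(stack, candidates,
                          labels = rep(NA_integer_, length(candidates)))
  eligible <- env$cell[!envelope_inside(envelope, env)]
  if (length(eligible) < n)
    stop("shortfall error: only ", length(eligible),
         " eligible pseudo-absence cells for n = ", n, call. = FALSE)

  purrr::map(seq_len(n_reps), function(r) {
    rep_seed <- derive_seed(seed, r)
    cells <- withr::with_seed(rep_seed, sample(eligible, n, replace = FALSE))
    structure(tibble::tibble(replicate_id = r, cell = as.integer(cells)),
              seed = rep_seed, n_eligible = length(eligible),
              class = c("pseudo_absence_set", "tbl_df", "tbl", "data.frame"))
  })
}

#' Repeated stratified 70:30 calibration splits
#'
#' Each run is an independent uniform split of the sample-table rows into
#' training and evaluation partitions. Splits are stratified by the
#' presence/pseudo-absence label so both classes appear in every partition,
#' and the total training size is exactly `round(train_frac * N)`.
#'
#' @param sample_table Design matrix with a `label` column (from
#'   [extract_at_cells()]).
#' @param train_frac Training fraction in (0, 1); 0.7 gives the 70:30 design.
#' @param n_runs Number of repeated splits.
#' @param seed Integer seed; run r uses `seed + r`.
#' @return List of `calibration_split` objects: `run_id`, integer row index
#'   vectors `train` and `test`.
#' @export
make_cv_splits <- function(sample_table, train_frac = 0.7, n_runs = 3, seed = 1) {
  assert_that(train_frac > 0 && train_frac < 1, "train_frac must be in (0,1)")
  N <- nrow(sample_table)
  assert_that(N >= 4, "need at least 4 rows to split")
  lab <- sample_table$label
  i1 <- which(lab == 1); i0 <- which(lab == 0)
  n_train <- round(train_frac * N)
  n1_train <- max(1L, min(length(i1) - 1L, round(train_frac * length(i1))))
  n0_train <- n_train - n1_train
  n0_train <- max(1L, min(length(i0) - 1L, n0_train))
  purrr::map(seq_len(n_runs), function(r) {
    run_seed <- derive_seed(seed, r)
    withr::with_seed(run_seed, {
      tr <- c(sample(i1, n1_train), sample(i0, n0_train))
    })
    structure(list(run_id = r, train = sort(tr), test = setdiff(seq_len(N), tr)),
              class = "calibration_split")
  })
}
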