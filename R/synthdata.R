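# Virtual species: environmental stacks with known cross-correlation, a
# known logistic niche, presence-only sampling proportional to suitability,
# and additively shifted "future" scenarios. Everything downstream of data
# acquisition can be exercised against these knowns.

# Box moving-average smoothing (separable), window half-width w; edge
# windows shrink rather than pad.
box1d <- function(v, w) {
  if (w < 1) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - w - 1L)
  hi <- pmin(n, seq_len(n) + w)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

box_smooth <- function(m, w) {
  m <- t(apply(m, 1, box1d, w = w))
  apply(m, 2, box1d, w = w)
}

#' Simulate a spatially autocorrelated environmental stack
#'
#' Continuous layers are smoothed Gaussian noise fields (moving-average
#' kernel of scale `smoothness`) orthogonalized and then mixed through the
#' Cholesky factor of the target correlation matrix, so the empirical
#' cross-correlations between layers match `cross_corr` exactly. One
#' categorical layer (`crop_class`, the crop-dominance analog) is built by
#' quantile-binning an additional hidden smooth field — independent of the
#' continuous set — into `n_categories` equal-area labels.
#'
#' @param grid A [grid_def()].
#' @param n_continuous Number of continuous layers (>= 2), named
#'   `env_1 ... env_k`.
#' @param smoothness Moving-average kernel half-width in cells (> 0);
#'   larger values give smoother, more autocorrelated fields.
#' @param cross_corr Either a scalar correlation applied to every layer
#'   pair or a full `n_continuous x n_continuous` correlation matrix. Must
#'   be positive semidefinite.
#' @param n_categories Labels for the categorical layer (0 disables it).
#' @param seed Integer seed; same seed, same stack.
#' @param layer_means,layer_sds Optional per-layer location/scale applied
#'   after mixing (defaults: means `10, 20, ...`, sds 1).
#' @param period_tag Stack tag, default `"current"`.
#' @return An [env_stack()].
#' @export
simulate_env_stack <- function(grid, n_continuous = 6, smoothness = 5,
                               cross_corr = 0.3, n_categories = 4, seed = 1,
                               layer_means = NULL, layer_sds = NULL,
                               period_tag = "current") {
  assert_that(n_continuous >= 2, "need at least 2 continuous layers")
  assert_that(smoothness > 0, "smoothness must be > 0")
  k <- n_continuous
  sigma <- if (is.matrix(cross_corr)) cross_corr
           else matrix(cross_corr, k, k) + diag(1 - cross_corr, k)
  L <- tryCatch(chol(sigma), error = function(e)
    stop("configuration error: cross-correlation matrix is not positive ",
         "semidefinite", call. = FALSE))

  w <- max(1L, round(smoothness))
  n_fields <- k + (n_categories > 0)
  fields <- withr::with_seed(seed, lapply(seq_len(n_fields), function(i)
    box_smooth(matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols), w)))

  Z <- vapply(fields, as.vector, numeric(n_cells(grid)))
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z)) * sqrt(nrow(Z) - 1)  # exactly uncorrelated, unit sd
  X <- Q[, seq_len(k), drop = FALSE] %*% L

  mus <- layer_means %||% (10 * seq_len(k))
  sds <- layer_sds %||% rep(1, k)
  layers <- lapply(seq_len(k), function(i)
    env_layer(paste0("env_", i),
              matrix(mus[i] + sds[i] * X[, i], grid$n_rows, grid$n_cols),
              "continuous"))
  if (n_categories > 0) {
    hidden <- Q[, k + 1]
    breaks <- stats::quantile(hidden, seq(0, 1, length.out = n_categories + 1),
                              type = 7)
    codes <- as.integer(cut(hidden, breaks = breaks, include.lowest = TRUE))
    layers <- c(layers, list(env_layer(
      "crop_class", matrix(as.numeric(codes), grid$n_rows, grid$n_cols),
      "categorical")))
  }
  env_stack(layers, grid, period_tag)
}

# Niche definition -----------------------------------------------------------

#' One term of a virtual-species response
#'
#' @param variable Layer name.
#' @param shape `"linear"`, `"gaussian"`, `"hinge"`, `"categorical"` or
#'   `"none"`.
#' @param beta Coefficient multiplying the shaped response.
#' @param slope Slope for `linear` (response `slope * x`).
#' @param optimum,width Centre and width (> 0) for `gaussian`
#'   (`exp(-(x - optimum)^2 / (2 width^2))`) and knot/scale for `hinge`
#'   (`pmax(0, (x - optimum) / width)`).
#' @param level_effects Named numeric vector of per-label effects for
#'   `categorical`.
#' @return A response term list.
#' @export
response_term <- function(variable, shape, beta = 1, slope = 1,
                          optimum = 0, width = 1, level_effects = NULL) {
  shape <- match.arg(shape, c("linear", "gaussian", "hinge", "categorical", "none"))
  if (shape == "gaussian") assert_that(width > 0, "gaussian width must be > 0")
  if (shape == "categorical")
    assert_that(!is.null(level_effects), "categorical terms need level_effects")
  list(variable = variable, shape = shape, beta = beta, slope = slope,
       optimum = optimum, width = width, level_effects = level_effects)
}

#' Assemble a virtual-species response specification
#'
#' The true suitability is `plogis(intercept + sum_k beta_k f_k(x_k))`
#' cell-wise, with `f_k` given by each term's shape.
#'
#' @param intercept Baseline log-odds.
#' @param terms List of [response_term()]s; at least one with shape other
#'   than `"none"`.
#' @return A `response_spec`.
#' @export
response_spec <- function(intercept = 0, terms = list()) {
  shapes <- vapply(terms, `[[`, "", "shape")
  assert_that(any(shapes != "none"),
              "at least one term must have a shape other than 'none'")
  structure(list(intercept = intercept, terms = terms), class = "response_spec")
}

eval_term <- function(term, x) {
  switch(term$shape,
    none = rep(0, length(x)),
    linear = term$slope * as.numeric(x),
    gaussian = exp(-(as.numeric(x) - term$optimum)^2 / (2 * term$width^2)),
    hinge = pmax(0, (as.numeric(x) - term$optimum) / term$width),
    categorical = {
      eff <- term$level_effects[as.character(as.vector(x))]
      eff[is.na(eff)] <- 0
      unname(eff)
    })
}

#' Define a virtual species on a stack
#'
#' Evaluates the logistic niche cell-wise over the stack, producing the true
#' suitability surface every downstream stage can be validated against.
#'
#' @param stack An [env_stack()].
#' @param spec A [response_spec()]; each term's variable must be a layer.
#' @return A `virtual_species_truth`: `spec`, `grid`, `period_tag`, and
#'   `suitability` (matrix in `[0, 1]`, nodata propagated).
#' @export
define_virtual_species <- function(stack, spec) {
  vars <- vapply(spec$terms, `[[`, "", "variable")
  missing <- setdiff(vars, layer_names(stack))
  if (length(missing))
    stop("schema error: response variables not in stack: ",
         paste(missing, collapse = ", "), call. = FALSE)
  eta <- matrix(spec$intercept, stack$grid$n_rows, stack$grid$n_cols)
  for (term in spec$terms) {
    v <- stack$layers[[term$variable]]$values
    eta <- eta + term$beta * matrix(eval_term(term, v), nrow(eta), ncol(eta))
  }
  suit <- stats::plogis(eta)
  suit[stack$nodata] <- NA_real_
  structure(list(spec = spec, grid = stack$grid,
                 period_tag = stack$period_tag, suitability = suit),
            class = "virtual_species_truth")
}

#' Sample presence-only occurrences from a virtual species
#'
#' Cells are drawn without replacement with probability proportional to
#' `suitability * bias_field` — presence-only sampling with optional
#' detection/effort bias (the kind spatial thinning is meant to mitigate).
#'
#' @param truth A `virtual_species_truth`.
#' @param n_target Number of occurrence records wanted.
#' @param bias_field Optional matrix of relative sampling effort (defaults
#'   to uniform).
#' @param seed Integer seed.
#' @param species_tag Label recorded on the result.
#' @return An `occurrence_set` of cell-centre records. If fewer than
#'   `n_target` cells have positive probability, all of them are returned
#'   with a warning.
#' @export
sample_virtual_occurrences <- function(truth, n_target, bias_field = NULL,
                                       seed = 1, species_tag = "virtual") {
  assert_that(n_target >= 1, "n_target must be >= 1")
  p <- truth$suitability
  if (!is.null(bias_field)) p <- p * bias_field
  pv <- as.vector(t(p))  # row-major, aligned with 0-based cell indices
  ok <- which(!is.na(pv) & pv > 0) - 1L
  if (!length(ok))
    stop("empty-sample error: suitability is zero everywhere", call. = FALSE)
  n <- min(n_target, length(ok))
  if (n < n_target)
    warning("only ", length(ok), " cells with positive probability; ",
            "returning all of them")
  cells <- withr::with_seed(seed,
    ok[sample.int(length(ok), n, replace = FALSE, prob = pv[ok + 1L])])
  cc <- cell_center(truth$grid, cells)
  tbl <- tibble::tibble(x = cc$x, y = cc$y, source = "virtual",
                        cell = as.integer(cells))
  structure(tbl, species_tag = species_tag, grid = truth$grid,
            removals = c(erroneous = 0L, duplicate = 0L, out_of_grid = 0L),
            class = c("occurrence_set", class(tbl)))
}

#' Shift a stack into a future scenario
#'
#' Applies per-layer additive offsets and/or multiplicative factors, with
#' optional added smooth noise, standing in for downscaled future climate
#' stacks. Categorical layers can be relabeled through a transition map.
#'
#' @param stack An [env_stack()].
#' @param shift_spec Named list keyed by layer name; each entry a list with
#'   any of `offset`, `factor`, `noise_sd` (smooth noise amplitude),
#'   `relabel` (named vector old label -> new label, categorical layers).
#' @param period_tag Tag for the shifted stack (e.g. `"2041-2070-ssp370"`).
#' @param seed Seed for the added noise.
#' @return The shifted [env_stack()] on the same grid.
#' @export
simulate_future_stack <- function(stack, shift_spec = list(),
                                  period_tag = "future", seed = 1) {
  missing <- setdiff(names(shift_spec), layer_names(stack))
  if (length(missing))
    stop("schema error: shift for missing layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  g <- stack$grid
  layers <- purrr::imap(stack$layers, function(ly, nm) {
    sh <- shift_spec[[nm]]
    if (is.null(sh)) return(ly)
    v <- ly$values
    if (ly$kind == "categorical") {
      if (!is.null(sh$relabel)) {
        new <- sh$relabel[as.character(v)]
        v <- matrix(ifelse(is.na(new), v, as.numeric(new)), nrow(v), ncol(v))
      }
    } else {
      v <- v * (sh$factor %||% 1) + (sh$offset %||% 0)
      if (!is.null(sh$noise_sd) && sh$noise_sd > 0) {
        noise <- withr::with_seed(derive_seed(seed, match(nm, names(stack$layers))),
          box_smooth(matrix(stats::rnorm(n_cells(g)), g$n_rows, g$n_cols), 2L))
        v <- v + sh$noise_sd * noise / stats::sd(noise)
      }
    }
    env_layer(nm, v, ly$kind)
  })
  env_stack(unname(layers), g, period_tag)
}

#' Desk-scale virtual-species benchmark
#'
#' The package's canonical end-to-end validation scenario: a 100 x 100
#' equal-area grid with six cross-correlated continuous layers plus one
#' categorical crop-dominance analog, a strong-signal species driven mainly
#' by the categorical layer (one favourable crop class) with a secondary
#' Gaussian response to a temperature-range analog, 300 presence records
#' sampled proportionally to suitability, and a "warm" scenario shifting
#' the Gaussian driver off its optimum. A ready-made pipeline configuration
#' (reduced battery: 3 PA replicates x 2 CV runs x 4 algorithms) is
#' attached so the whole pipeline runs in seconds.
#'
#' @param seed Master seed; every derived dataset and the config seed
#'   follow from it.
#' @param n_rows,n_cols Grid dimensions.
#' @param n_presences Occurrence records sampled.
#' @param pa_n,pa_reps,cv_runs,algorithms Battery configuration recorded in
#'   the attached config.
#' @param future_offset Additive shift applied to the Gaussian driver in
#'   the "warm" scenario (in layer units; +2 is about two within-layer SDs).
#' @return List: `stack`, `future` (shifted stack), `truth`
#'   (`virtual_species_truth`), `occurrences`, `dominant_variable`
#'   (`"crop_class"`), and `config` (validated, ready for
#'   [run_pipeline()]).
#' @export
virtual_species_benchmark <- function(seed = 1, n_rows = 100, n_cols = 100,
                                      n_presences = 300,
                                      pa_n = 300, pa_reps = 3, cv_runs = 2,
                                      algorithms = c("GLM", "RF", "MAXNET",
                                                     "XGBOOST"),
                                      future_offset = 2) {
  grid <- grid_def(0, n_rows, 1, n_rows, n_cols)
  stack <- simulate_env_stack(grid, n_continuous = 6, smoothness = 4,
                              cross_corr = 0.3, n_categories = 4,
                              seed = derive_seed(seed, 1))
  spec <- response_spec(intercept = -2, terms = list(
    response_term("crop_class", "categorical", beta = 1,
                  level_effects = c(`1` = -6, `2` = -6, `3` = -2, `4` = 6)),
    response_term("env_2", "gaussian", beta = 3, optimum = 20, width = 2)
  ))
  truth <- define_virtual_species(stack, spec)
  occ <- sample_virtual_occurrences(truth, n_presences,
                                    seed = derive_seed(seed, 2))
  future <- simulate_future_stack(stack,
                                  list(env_2 = list(offset = future_offset)),
                                  period_tag = "warm")
  config <- validate_config(list(
    occurrences = as.data.frame(occ[, c("x", "y", "source")]),
    stacks = list(current = stack, warm = future),
    pa_n = pa_n, pa_reps = pa_reps, cv_runs = cv_runs,
    thin_dist_km = 1.5, buffer_km = 40,
    algorithms = algorithms,
    seed = derive_seed(seed, 3)))
  list(stack = stack, future = future, truth = truth, occurrences = occ,
       dominant_variable = "crop_class", config = config)
}
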