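#' Replicated presence/background splits
#'
#' Draws `background_n` background points uniformly from the non-NODATA
#' cells of the stack, excluding cells holding presences, and produces
#' `runs` independent stratified 75/25 train/test splits (presences and
#' background split separately; the train fraction rounds down).
#'
#' @param points Tibble of presence coordinates (`lon`, `lat`).
#' @param stack A [raster_stack()].
#' @param background_n Background size (default 10 x presences).
#' @param train_frac Training fraction (default 0.75).
#' @param runs Number of replicate splits.
#' @param seed Integer seed; run r uses the derived seed `seed + r`.
#' @return A list of `runs` splits, each with tibbles `train_p`, `test_p`,
#'   `train_b`, `test_b` of cell-centre coordinates and layer values.
#' @export
split_presences <- function(points, stack, background_n = NULL,
                            train_frac = 0.75, runs = 5, seed = 1) {
  n_p <- nrow(points)
  if (n_p < 4) abort("need at least 4 presence points")
  background_n <- background_n %||% (10L * n_p)
  if (background_n < n_p) abort("background_n must be at least the number of presences")
  n_train <- floor(train_frac * n_p)
  if (n_train < 2 || n_train >= n_p) {
    abort("train fraction leaves too few training or test presences")
  }

  cells <- rs_cells(stack)
  vals <- rs_extract(stack, cells$lon, cells$lat)
  ok <- stats::complete.cases(vals)
  pres_cells <- rs_cell_of(stack, points$lon, points$lat)
  pres_key <- paste(pres_cells$row, pres_cells$col)
  candidate <- which(ok & !(paste(cells$row, cells$col) %in% pres_key))
  if (length(candidate) < background_n) {
    abort("not enough non-NODATA background cells")
  }
  pres <- dplyr::bind_cols(points[c("lon", "lat")],
                           rs_extract(stack, points$lon, points$lat))

  purrr::map(seq_len(runs), function(r) {
    with_seed(seed + r, {
      bg_idx <- sample(candidate, background_n)
      bg <- dplyr::bind_cols(cells[bg_idx, c("lon", "lat")], vals[bg_idx, ])
      tr_p <- sample.int(n_p, n_train)
      tr_b <- sample.int(background_n, floor(train_frac * background_n))
      list(
        train_p = pres[tr_p, ], test_p = pres[-tr_p, ],
        train_b = bg[tr_b, ], test_b = bg[-tr_b, ],
        run = r
      )
    })
  })
}

#' Surface range envelope model
#'
#' `sre_fit()` stores, per environmental layer, the empirical `q` and
#' `1 - q` quantiles (linear interpolation, `type = 7`) of the training
#' presences. `sre_predict()` scores a raster or a table of layer values:
#' a cell is suitable (1) iff every layer value lies within its envelope.
#'
#' @param train Tibble of training-presence layer values (columns named as
#'   the stack's layers).
#' @param layers Layer names to use (default: all numeric columns except
#'   `lon`/`lat`).
#' @param q Tail fraction trimmed at each end, `0 <= q < 0.5`.
#' @return An `sre_model` with the per-layer envelope bounds.
#' @export
sre_fit <- function(train, layers = NULL, q = 0.025) {
  if (q < 0 || q >= 0.5) abort("q must lie in [0, 0.5)")
  layers <- layers %||% setdiff(names(train)[vapply(train, is.numeric, TRUE)],
                                c("lon", "lat"))
  if (nrow(train) < 2) abort("need at least 2 training presences")
  env <- purrr::map(layers, function(l) {
    v <- train[[l]]
    if (is.null(v)) abort(paste0("training data lacks layer: ", l))
    quantile(v, c(q, 1 - q), na.rm = TRUE, names = FALSE, type = 7)
  })
  structure(list(bounds = setNames(env, layers), q = q), class = "sre_model")
}

#' @rdname sre_fit
#' @param object An `sre_model`.
#' @param newdata A [raster_stack()] or a tibble of layer values.
#' @return `sre_predict()`: a 0/1 matrix (for a stack) or vector (for a
#'   tibble); NODATA stays `NA`.
#' @export
sre_predict <- function(object, newdata) {
  lay <- names(object$bounds)
  if (inherits(newdata, "raster_stack")) {
    miss <- setdiff(lay, names(newdata$layers))
    if (length(miss) > 0) {
      abort(paste0("stack lacks layer(s): ", paste(miss, collapse = ", ")))
    }
    out <- matrix(1, newdata$nrow, newdata$ncol)
    for (l in lay) {
      b <- object$bounds[[l]]
      m <- newdata$layers[[l]]
      out <- out * (m >= b[1] & m <= b[2])
    }
    out * 1
  } else {
    miss <- setdiff(lay, names(newdata))
    if (length(miss) > 0) {
      abort(paste0("data lacks layer(s): ", paste(miss, collapse = ", ")))
    }
    ok <- rep(1, nrow(newdata))
    for (l in lay) {
      b <- object$bounds[[l]]
      ok <- ok * (newdata[[l]] >= b[1] & newdata[[l]] <= b[2])
    }
    as.numeric(ok)
  }
}

#' AUC and TSS evaluation of presence/background scores
#'
#' AUC is computed by the rank (Mann-Whitney) formula with tie correction;
#' TSS is the maximum over candidate thresholds of
#' sensitivity + specificity - 1, scoring a point as predicted-present when
#' its score is at least the threshold. Identical scores everywhere give
#' AUC = 0.5 and TSS = 0.
#'
#' @param scores_presence,scores_background Numeric score vectors, each
#'   non-empty.
#' @return A one-row tibble: `auc`, `tss`, `threshold`, `n_presence`,
#'   `n_background`.
#' @export
evaluate_sdm <- function(scores_presence, scores_background) {
  np <- length(scores_presence)
  nb <- length(scores_background)
  if (np < 1 || nb < 1) abort("need at least 1 presence and 1 background score")
  r <- rank(c(scores_presence, scores_background))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
  thresholds <- sort(unique(c(scores_presence, scores_background)))
  tss_at <- vapply(thresholds, function(t) {
    sens <- mean(scores_presence >= t)
    spec <- mean(scores_background < t)
    sens + spec - 1
  }, 0)
  best <- which.max(tss_at)
  tibble(
    auc = auc, tss = max(tss_at, 0), threshold = thresholds[best],
    n_presence = np, n_background = nb
  )
}

#' TSS-weighted ensemble of replicate predictions
#'
#' Replicates with TSS at or below `tss_min` are discarded; the remaining
#' predictions are averaged with weights proportional to their TSS
#' (renormalised).
#'
#' @param predictions List of prediction matrices (same dimensions).
#' @param evaluations Tibble with a `tss` column, one row per prediction.
#' @param tss_min Retention threshold (default 0.7, strict `>`).
#' @return A list with the consensus `raster` (matrix in \[0, 1\]),
#'   `weights`, and `retained` indices.
#' @export
sdm_ensemble <- function(predictions, evaluations, tss_min = 0.7) {
  tss <- evaluations$tss
  keep <- which(tss > tss_min)
  if (length(keep) == 0) {
    abort(sprintf(
      "no replicate exceeds TSS = %g; consider relaxing the threshold", tss_min
    ))
  }
  w <- tss[keep] / sum(tss[keep])
  acc <- predictions[[keep[1]]] * w[1]
  if (length(keep) > 1) {
    for (i in 2:length(keep)) acc <- acc + predictions[[keep[i]]] * w[i]
  }
  list(raster = acc, weights = w, retained = keep)
}

#' Project an envelope model onto another climate stack
#'
#' Applies the fitted envelope to a substituted raster stack (e.g. a
#' future scenario) and summarises the suitable-area change.
#'
#' @param object An `sre_model`.
#' @param current,future [raster_stack()]s sharing the model's layer names.
#' @return A list: `prediction` (0/1 matrix on the future stack),
#'   `area_now_km2`, `area_future_km2`, `change_km2`, `change_pct`.
#' @export
project_sdm <- function(object, current, future) {
  pred_now <- sre_predict(object, current)
  pred_fut <- sre_predict(object, future)
  a0 <- suitable_area_km2(current, pred_now)
  a1 <- suitable_area_km2(future, pred_fut)
  list(
    prediction = pred_fut,
    area_now_km2 = a0, area_future_km2 = a1,
    change_km2 = a1 - a0,
    change_pct = if (a0 > 0) 100 * (a1 - a0) / a0 else NA_real_
  )
}

#' End-to-end surface-range-envelope distribution model
#'
#' Convenience wrapper: replicated splits, envelope fits, AUC/TSS
#' evaluation on the held-out points, TSS-filtered consensus, and optional
#' projection onto a future stack.
#'
#' @param points Presence coordinates (`lon`, `lat`).
#' @param stack Current-climate [raster_stack()].
#' @param future Optional future [raster_stack()].
#' @param runs Replicate splits.
#' @param q Envelope tail fraction.
#' @param tss_min Consensus retention threshold.
#' @param seed Integer seed.
#' @param background_n Background size (default 10 x presences).
#' @return An `sdm_result`: `evaluations`, `ensemble`, `models`, and
#'   `projection` (or `NULL`).
#' @export
run_sre_sdm <- function(points, stack, future = NULL, runs = 5, q = 0.025,
                        tss_min = 0.7, seed = 1, background_n = NULL) {
  splits <- split_presences(points, stack,
    background_n = background_n, runs = runs, seed = seed
  )
  models <- purrr::map(splits, function(s) sre_fit(s$train_p, q = q))
  evals <- purrr::map2(models, splits, function(m, s) {
    evaluate_sdm(sre_predict(m, s$test_p), sre_predict(m, s$test_b))
  })
  evals <- dplyr::bind_rows(evals)
  evals$run <- seq_len(runs)
  preds <- purrr::map(models, sre_predict, newdata = stack)
  ens <- sdm_ensemble(preds, evals, tss_min = tss_min)
  projection <- NULL
  if (!is.null(future)) {
    best <- ens$retained[which.max(evals$tss[ens$retained])]
    projection <- project_sdm(models[[best]], stack, future)
  }
  structure(
    list(evaluations = evals, ensemble = ens, models = models,
         projection = projection, stack = stack),
    class = "sdm_result"
  )
}

#' @export
print.sdm_result <- function(x, ...) {
  cat(sprintf(
    "SRE distribution model: %d replicates, %d retained (TSS-filtered)\n",
    nrow(x$evaluations), length(x$ensemble$retained)
  ))
  print(x$evaluations)
  if (!is.null(x$projection)) {
    cat(sprintf(
      "projected suitable-area change: %.0f km2 (%.1f%%)\n",
      x$projection$change_km2, x$projection$change_pct
    ))
  }
  invisible(x)
}

#' @rdname run_sre_sdm
#' @param x An `sdm_result`.
#' @param ... Unused.
#' @export
tidy.sdm_result <- function(x, ...) x$evaluations

#' @rdname run_sre_sdm
#' @export
glance.sdm_result <- function(x, ...) {
  tibble(
    runs = nrow(x$evaluations),
    retained = length(x$ensemble$retained),
    mean_auc = mean(x$evaluations$auc),
    mean_tss = mean(x$evaluations$tss),
    area_now_km2 = if (is.null(x$projection)) NA_real_ else x$projection$area_now_km2,
    area_future_km2 = if (is.null(x$projection)) NA_real_ else x$projection$area_future_km2,
    change_pct = if (is.null(x$projection)) NA_real_ else x$projection$change_pct
  )
}
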