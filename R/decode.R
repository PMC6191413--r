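#' Integer offsets of a searchlight sphere
#'
#' All integer voxel offsets `(di, dj, dk)` with `di^2 + dj^2 + dk^2 <=
#' radius^2`.  Includes the centre and is symmetric under negation.
#'
#' @param radius_voxels sphere radius in voxels (>= 0); radius 3 yields the
#'   123-voxel searchlight used throughout.
#' @return integer matrix with columns `di, dj, dk`.
#' @export
sphere_offsets <- function(radius_voxels) {
  stopifnot(radius_voxels >= 0)
  r <- floor(radius_voxels)
  g <- as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
  g <- g[rowSums(g^2) <= radius_voxels^2, , drop = FALSE]
  rownames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Leave-one-run-out cross-validation folds
#'
#' One fold per run: fold `r` trains on every (run != r, stimulus) item and
#' tests on the two items of run `r`.  With 8 runs this gives 8 decoding
#' steps of 14 training and 2 test items each, and the test sets partition
#' all 16 items.
#'
#' @param runs vector of run identifiers (>= 2).
#' @param stimuli stimulus levels (default index/little).
#' @return list of folds, each a list with `train` and `test` data.frames of
#'   `(run, stimulus)` keys and the held-out `test_run`.
#' @export
make_folds <- function(runs, stimuli = STIMULI) {
  runs <- unique(runs)
  if (length(runs) < 2)
    stop("leave-one-run-out cross-validation needs at least 2 runs")
  items <- expand.grid(run = runs, stimulus = stimuli,
                       stringsAsFactors = FALSE)
  lapply(runs, function(r) {
    list(test_run = r,
         train = items[items$run != r, , drop = FALSE],
         test = items[items$run == r, , drop = FALSE])
  })
}

#' Decode stimulus identity from one neighbourhood's patterns
#'
#' Fits a linear soft-margin SVM (cost `C`, no feature scaling) per
#' cross-validation fold, labelling items by stimulus, and returns the
#' fraction of correctly classified test items over all folds.  The solver
#' works in the dual on the Gram matrix; decision ties (`f == 0`, e.g. when
#' training patterns are identical across classes) are resolved to the first
#' stimulus level (`"index"`), so uninformative balanced data scores 0.5.
#'
#' @param patterns numeric matrix, items x features.
#' @param items data.frame with columns `run` and `stimulus`, one row per
#'   pattern row.
#' @param folds folds from [make_folds()]; defaults to leave-one-run-out over
#'   the runs present.
#' @param cost SVM cost parameter `C`.
#' @param engine `"native"` (compiled SMO solver) or `"e1071"` (libsvm via
#'   \pkg{e1071}); both fit the same model, the second is retained as an
#'   independent cross-check.
#' @return accuracy as a fraction in `[0, 1]`, with attribute `decision`
#'   (per-item test decision values, native engine only).
#' @export
decode_neighbourhood <- function(patterns, items, folds = NULL, cost = 1,
                                 engine = c("native", "e1071")) {
  engine <- match.arg(engine)
  patterns <- as.matrix(patterns)
  if (anyNA(patterns) || any(!is.finite(patterns)))
    stop("patterns contain NA or non-finite features")
  stopifnot(nrow(patterns) == nrow(items),
            all(c("run", "stimulus") %in% names(items)))
  if (is.null(folds)) folds <- make_folds(unique(items$run))
  lev <- STIMULI[STIMULI %in% items$stimulus]
  if (length(lev) < 2) lev <- unique(items$stimulus)
  y <- ifelse(items$stimulus == lev[1], 1L, -1L)

  if (engine == "native") {
    # folds argument defines the partition; map test runs to item groups
    fold_of <- integer(nrow(items))
    for (f in seq_along(folds))
      fold_of[items$run == folds[[f]]$test_run] <- f
    if (any(fold_of == 0)) stop("folds do not cover every item")
    res <- decode_cv_cpp(patterns, y, fold_of, cost)
    structure(res$accuracy, decision = res$decision)
  } else {
    correct <- 0L
    total <- 0L
    for (f in folds) {
      tr <- items$run != f$test_run
      fit <- e1071::svm(patterns[tr, , drop = FALSE],
                        factor(items$stimulus[tr], levels = lev),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- predict(fit, patterns[!tr, , drop = FALSE])
      correct <- correct + sum(pred == items$stimulus[!tr])
      total <- total + sum(!tr)
    }
    correct / total
  }
}

# Neighbourhood index lists: for each mask voxel, the mask voxels inside its
# sphere (truncated at mask/grid boundaries), as indices into mask order.
neighbourhood_lists <- function(grid, radius_voxels) {
  offs <- sphere_offsets(radius_voxels)
  sh <- grid$shape
  mask_ix <- which(as.vector(grid$mask))
  pos_in_mask <- integer(prod(sh))
  pos_in_mask[mask_ix] <- seq_along(mask_ix)
  coords <- index_to_coords(mask_ix, sh)
  lapply(seq_along(mask_ix), function(v) {
    nb <- sweep(offs, 2, coords[v, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= sh[1] &
      nb[, 2] >= 1 & nb[, 2] <= sh[2] &
      nb[, 3] >= 1 & nb[, 3] <= sh[3]
    ix <- coords_to_index(nb[ok, , drop = FALSE], sh)
    p <- pos_in_mask[ix]
    p[p > 0L]
  })
}

#' Searchlight decoding map for one condition
#'
#' For every mask voxel, gathers the run-wise betas of the requested
#' condition from all voxels within `radius_voxels` (sphere truncated at the
#' mask boundary), decodes observed-stimulus identity with a linear SVM under
#' leave-one-run-out cross-validation, and assigns `accuracy - 0.5` to the
#' centre voxel.  With 8 runs each searchlight sees 16 patterns (8 index, 8
#' little) and accuracies move in steps of `1/16`.
#'
#' @param betas a `beta_set`.
#' @param condition condition label to decode within (must be present in the
#'   beta set).
#' @param radius_voxels searchlight radius in voxels.
#' @param cost SVM cost parameter.
#' @param neighbours optional precomputed [neighbourhood_lists()] (reused
#'   across subjects/conditions on a shared grid).
#' @return an `accuracy_map`: 3D array of accuracy-minus-chance values (`NA`
#'   outside the mask) plus grid, condition, subject and chance level (0.5).
#' @export
searchlight_map <- function(betas, condition, radius_voxels = 3, cost = 1,
                            neighbours = NULL) {
  conds <- dimnames(betas$beta)[[3]]
  if (!condition %in% conds)
    stop("condition '", condition, "' not present in beta set (has: ",
         paste(conds, collapse = ", "), ")")
  grid <- betas$grid
  runs <- dimnames(betas$beta)[[2]]
  mask_ix <- which(as.vector(grid$mask))

  # items x voxels matrix: run-major over (run, stimulus)
  B <- do.call(rbind, lapply(runs, function(r)
    rbind(betas$beta[mask_ix, r, condition, STIMULI[1]],
          betas$beta[mask_ix, r, condition, STIMULI[2]])))
  y <- rep(c(1L, -1L), times = length(runs))
  run_id <- rep(seq_along(runs), each = 2)
  if (anyNA(B)) stop("beta set contains NA values inside the mask")

  if (is.null(neighbours)) neighbours <- neighbourhood_lists(grid, radius_voxels)
  acc <- searchlight_cpp(B, neighbours, y, run_id, cost)

  vol <- array(NA_real_, dim = grid$shape)
  vol[mask_ix] <- acc - 0.5
  structure(list(data = vol, grid = grid, condition = condition,
                 subject_id = betas$subject_id, chance = 0.5),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  v <- x$data[!is.na(x$data)]
  cat(sprintf(paste0("accuracy map [%s, %s]: %d voxels, ",
                     "mean accuracy-chance %.3f (range %.3f..%.3f)\n"),
              x$subject_id, x$condition, length(v), mean(v), min(v), max(v)))
  invisible(x)
}
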