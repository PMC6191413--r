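#' Canonical double-gamma haemodynamic response function
#'
#' The standard canonical HRF: a gamma density peaking near 5 s minus one
#' sixth of a gamma density peaking near 15 s (shapes 6 and 16, unit rate).
#' Zero for `t <= 0`.
#'
#' @param t time in seconds (vectorised).
#' @return HRF values (arbitrary units).
#' @export
canonical_hrf <- function(t) {
  h <- ifelse(t <= 0, 0,
              dgamma(t, shape = 6, rate = 1) -
                dgamma(t, shape = 16, rate = 1) / 6)
  h
}

#' Sample the canonical HRF at the scanner TR
#'
#' @param TR_s repetition time in seconds (> 0).
#' @param duration_s kernel length in seconds.
#' @return numeric vector, the HRF sampled at `0, TR, 2 TR, ...` up to
#'   `duration_s`.
#' @export
hrf_kernel <- function(TR_s, duration_s = 32) {
  stopifnot(TR_s > 0, duration_s >= 0)
  canonical_hrf(seq(0, duration_s, by = TR_s))
}

#' Build a first-level design matrix for one run
#'
#' One event regressor per (condition, stimulus) cell present in the run's
#' events — the convention of modelling a separate regressor for each
#' stimulus type in each experimental condition in each run.  Events are
#' zero-duration impulses locked to the observed-stimulus onset, convolved
#' with the canonical HRF (for impulses the convolution is the sum of
#' onset-shifted HRFs evaluated at scan times).  A linear drift and a
#' constant column are appended, plus any user-supplied nuisance columns.
#'
#' @param events an `event_table` restricted to a single run.
#' @param n_scans number of scans in the run.
#' @param TR_s repetition time in seconds.
#' @param nuisance optional numeric matrix of extra nuisance regressors
#'   (`n_scans` rows), e.g. motion parameters in real-data mode.
#' @return an object of class `design_matrix`: the `n_scans x p` matrix `X`
#'   and a `columns` data.frame with `condition`, `stimulus` and `type`
#'   (`"event"` or `"nuisance"`) per column.
#' @export
build_design_matrix <- function(events, n_scans, TR_s, nuisance = NULL) {
  if (length(unique(events$run)) != 1)
    stop("build_design_matrix expects events from exactly one run")
  if (any(events$onset_s >= n_scans * TR_s))
    stop("event onsets extend past the end of the run")
  t_scan <- (seq_len(n_scans) - 1) * TR_s

  cells <- unique(events[, c("condition", "observed")])
  cells <- cells[order(match(cells$condition, CONDITIONS),
                       match(cells$observed, STIMULI)), ]
  X_ev <- vapply(seq_len(nrow(cells)), function(i) {
    on <- events$onset_s[events$condition == cells$condition[i] &
                           events$observed == cells$observed[i]]
    rowSums(vapply(on, function(o) canonical_hrf(t_scan - o),
                   numeric(n_scans)))
  }, numeric(n_scans))
  drift <- seq(-0.5, 0.5, length.out = n_scans)
  X <- cbind(X_ev, drift, 1)
  info <- data.frame(
    condition = c(cells$condition, NA, NA),
    stimulus = c(cells$observed, NA, NA),
    type = c(rep("event", nrow(cells)), "nuisance", "nuisance"),
    label = c(paste(cells$condition, cells$observed, sep = ":"),
              "drift", "constant"),
    stringsAsFactors = FALSE)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_scans)
    labs <- colnames(nuisance)
    if (is.null(labs)) labs <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
    info <- rbind(info, data.frame(condition = NA, stimulus = NA,
                                   type = "nuisance", label = labs))
  }
  colnames(X) <- info$label
  structure(list(X = X, columns = info, run = events$run[1], TR_s = TR_s),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design matrix: run %s, %d scans x %d regressors (%d event)\n",
              x$run, nrow(x$X), ncol(x$X), sum(x$columns$type == "event")))
  cat(" columns:", paste(x$columns$label, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate run-wise betas by ordinary least squares
#'
#' Fits each run's design matrix to every voxel's time series by OLS and
#' assembles the event-regressor coefficients into a `beta_set` keyed by
#' (run, condition, stimulus); nuisance coefficients are discarded.  No
#' temporal prewhitening is applied: OLS point estimates are unbiased under
#' serial correlation, and downstream analyses use the estimates, not their
#' standard errors.
#'
#' @param data a `timeseries_set` (see [simulate_timeseries()]), or a list of
#'   scans x voxels matrices with a `voxel_index` attribute per run.
#' @param designs list of [build_design_matrix()] results, one per run, in
#'   the same order as `data$runs`.
#' @return a `beta_set`.
#' @export
fit_glm <- function(data, designs) {
  stopifnot(inherits(data, "timeseries_set"),
            length(designs) == length(data$runs))
  runs <- names(data$runs)
  grid <- data$grid
  nvox <- prod(grid$shape)

  cell_list <- unique(do.call(rbind, lapply(designs, function(d)
    d$columns[d$columns$type == "event", c("condition", "stimulus")])))
  conditions <- intersect(CONDITIONS, unique(cell_list$condition))
  beta <- array(NA_real_,
                dim = c(nvox, length(runs), length(conditions), 2),
                dimnames = list(NULL, runs, conditions, STIMULI))

  for (r in seq_along(runs)) {
    d <- designs[[r]]
    Y <- data$runs[[r]]
    stopifnot(nrow(d$X) == nrow(Y))
    qx <- qr(d$X)
    if (qx$rank < ncol(d$X)) {
      drop_ix <- qx$pivot[(qx$rank + 1):ncol(d$X)]
      stop("design matrix for run ", runs[r], " is rank deficient; ",
           "collinear columns: ",
           paste(d$columns$label[drop_ix], collapse = ", "))
    }
    coefs <- qr.coef(qx, Y)   # p x nvox
    ev <- which(d$columns$type == "event")
    for (i in ev) {
      cond <- d$columns$condition[i]
      if (!cond %in% conditions) next
      beta[attr(Y, "voxel_index"), r, cond, d$columns$stimulus[i]] <-
        coefs[i, ]
    }
  }
  new_beta_set(beta, grid, data$events$subject_id[1])
}
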