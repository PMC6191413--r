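#' Define a voxel grid for simulation
#'
#' A small volumetric grid standing in for a (portion of a) brain volume.
#' Voxels are addressed by 1-based integer coordinates `(i, j, k)`.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param voxel_size_mm isotropic voxel edge length in millimetres.
#' @param mask logical array of dimension `shape`, or `NULL` for an all-true
#'   mask.  Must contain at least one true voxel.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size_mm = 3, mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), voxel_size_mm > 0)
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  stopifnot(identical(dim(mask), shape))
  if (!any(mask)) stop("mask must contain at least one voxel")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 mask = mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume grid %dx%dx%d, %g mm voxels, %d in mask\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size_mm,
              sum(x$mask)))
  invisible(x)
}

coords_to_index <- function(coords, shape) {
  coords <- matrix(as.integer(coords), ncol = 3)
  if (any(coords < 1) || any(coords > rep(shape, each = nrow(coords))))
    stop("voxel coordinates outside the grid")
  coords[, 1] + (coords[, 2] - 1L) * shape[1] +
    (coords[, 3] - 1L) * shape[1] * shape[2]
}

index_to_coords <- function(ix, shape) {
  ix <- as.integer(ix) - 1L
  cbind(i = ix %% shape[1] + 1L,
        j = (ix %/% shape[1]) %% shape[2] + 1L,
        k = ix %/% (shape[1] * shape[2]) + 1L)
}

#' Specify a simulated population code
#'
#' Describes how voxels respond to observed index/little finger movements and
#' how action-based expectation modulates those responses.  Informative
#' voxels carry a stimulus preference and respond with `baseline +
#' amp_preferred` to their preferred stimulus and `baseline +
#' amp_nonpreferred` to the other; non-informative voxels sit at baseline.
#' On congruent trials (where the observed outcome matches the executed,
#' hence expected, action) the evoked amplitude is scaled by `gain`:
#' under `sharpening` in voxels tuned *away* from the observed stimulus,
#' under `cancellation` in voxels tuned *towards* it, and not at all under
#' `null` (where `gain` is ignored).  Incongruent and no-move trials are
#' never modulated, so no-move responses carry tuning signal that can define
#' regions of interest independently of congruency.
#'
#' @param informative_region integer matrix (n x 3) of voxel coordinates
#'   inside the mask, or `NULL` for no informative voxels.
#' @param preference character vector (`"index"`/`"little"`), one per
#'   informative voxel.
#' @param baseline,amp_preferred,amp_nonpreferred response amplitudes in
#'   arbitrary signal units; `amp_preferred` must exceed `amp_nonpreferred`.
#' @param gain multiplicative modulation of the evoked amplitude on congruent
#'   trials, in `(0, 1]`.
#' @param hypothesis `"sharpening"`, `"cancellation"` or `"null"`.
#' @param noise_sd standard deviation of the trial-level response noise, in
#'   the same signal units.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(informative_region = NULL, preference = NULL,
                            baseline = 100, amp_preferred = 2,
                            amp_nonpreferred = 1, gain = 0.7,
                            hypothesis = c("sharpening", "cancellation",
                                           "null"),
                            noise_sd = 4) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(informative_region)) {
    informative_region <- matrix(integer(0), ncol = 3)
    preference <- character(0)
  } else {
    informative_region <- matrix(as.integer(informative_region), ncol = 3)
  }
  stopifnot(length(preference) == nrow(informative_region),
            all(preference %in% STIMULI),
            amp_preferred > amp_nonpreferred, amp_nonpreferred >= 0,
            gain > 0, gain <= 1, noise_sd >= 0)
  structure(list(informative_region = informative_region,
                 preference = preference, baseline = baseline,
                 amp_preferred = amp_preferred,
                 amp_nonpreferred = amp_nonpreferred,
                 gain = if (hypothesis == "null") 1 else gain,
                 hypothesis = hypothesis, noise_sd = noise_sd),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(paste0("population spec: %s, %d informative voxels, ",
                     "baseline %g, amps (%g, %g), gain %g, noise sd %g\n"),
              x$hypothesis, nrow(x$informative_region), x$baseline,
              x$amp_preferred, x$amp_nonpreferred, x$gain, x$noise_sd))
  invisible(x)
}

#' Default population spec: two compact informative blobs
#'
#' Places two cubic blobs of stimulus-tuned voxels on the grid (so that group
#' cluster inference has spatially contiguous targets), with preferences
#' assigned in a 50/50 checkerboard within each blob.
#'
#' @param grid a [volume_grid()].
#' @param hypothesis passed to [population_spec()].
#' @param blob_half half-width of each blob in voxels (1 gives 3x3x3 blobs).
#' @param ... further arguments to [population_spec()].
#' @return a `population_spec`.
#' @export
default_population_spec <- function(grid, hypothesis = "sharpening",
                                    blob_half = 1, ...) {
  sh <- grid$shape
  # blobs sit on the grid diagonal so their searchlight footprints (and
  # hence the suprathreshold regions) stay disconnected
  centres <- rbind(
    c(max(2, round(sh[1] / 4)), max(2, round(sh[2] / 4)), round(sh[3] / 2)),
    c(min(sh[1] - 1, round(3 * sh[1] / 4)),
      min(sh[2] - 1, round(3 * sh[2] / 4)), round(sh[3] / 2)))
  coords <- do.call(rbind, lapply(1:2, function(b) {
    as.matrix(expand.grid(
      i = pmax(1, centres[b, 1] - blob_half):pmin(sh[1], centres[b, 1] + blob_half),
      j = pmax(1, centres[b, 2] - blob_half):pmin(sh[2], centres[b, 2] + blob_half),
      k = pmax(1, centres[b, 3] - blob_half):pmin(sh[3], centres[b, 3] + blob_half)))
  }))
  coords <- coords[grid$mask[coords], , drop = FALSE]
  pref <- STIMULI[1 + rowSums(coords) %% 2]  # deterministic checkerboard
  population_spec(informative_region = coords, preference = pref,
                  hypothesis = hypothesis, ...)
}

#' Mean voxel response under a population-code hypothesis
#'
#' The deterministic part of a voxel's response to one trial.  Returns
#' `baseline + amplitude * g`, where the amplitude is `amp_preferred` if the
#' observed stimulus matches the voxel's preference and `amp_nonpreferred`
#' otherwise, and `g = gain` exactly when the trial is congruent and the
#' hypothesis targets this voxel (sharpening: tuned away from the observed
#' stimulus; cancellation: tuned towards it); otherwise `g = 1`.
#' A voxel with no preference (`NA`) returns `baseline` for every input.
#'
#' @param pref voxel preference (`"index"`, `"little"`, or `NA`); vectorised.
#' @param observed observed stimulus.
#' @param condition trial condition.
#' @param spec a [population_spec()].
#' @return numeric vector of mean responses in signal units.
#' @export
mean_response <- function(pref, observed, condition, spec) {
  stopifnot(observed %in% STIMULI, condition %in% CONDITIONS)
  amp <- ifelse(is.na(pref), 0,
                ifelse(pref == observed, spec$amp_preferred,
                       spec$amp_nonpreferred))
  modulated <- condition == "congruent" & !is.na(pref) &
    ((spec$hypothesis == "sharpening" & pref != observed) |
       (spec$hypothesis == "cancellation" & pref == observed))
  g <- ifelse(modulated, spec$gain, 1)
  spec$baseline + amp * g
}

# Per-voxel preference vector over the full grid (NA = non-informative).
preference_vector <- function(grid, spec) {
  pref <- rep(NA_character_, prod(grid$shape))
  if (nrow(spec$informative_region) > 0) {
    ix <- coords_to_index(spec$informative_region, grid$shape)
    if (any(!grid$mask[ix]))
      stop("informative_region contains voxels outside the mask")
    pref[ix] <- spec$preference
  }
  pref
}

new_beta_set <- function(beta, grid, subject_id) {
  structure(list(beta = beta, grid = grid, subject_id = subject_id),
            class = "beta_set")
}

#' @export
print.beta_set <- function(x, ...) {
  d <- dim(x$beta)
  cat(sprintf("beta set [%s]: %d voxels x %d runs, conditions: %s\n",
              x$subject_id, d[1], d[2],
              paste(dimnames(x$beta)[[3]], collapse = ", ")))
  invisible(x)
}

#' Extract one coefficient volume from a beta set
#'
#' @param betas a `beta_set`.
#' @param run run number.
#' @param condition,stimulus cell labels.
#' @return a 3D array on the set's grid (`NA` outside the mask).
#' @export
beta_volume <- function(betas, run, condition, stimulus) {
  array(betas$beta[, as.character(run), condition, stimulus],
        dim = betas$grid$shape)
}

# Trial counts per run x condition x stimulus cell; errors on empty cells.
cell_counts <- function(design, conditions, runs, cell_of) {
  counts <- table(factor(design$run, levels = runs),
                  factor(cell_of, levels = conditions),
                  factor(design$observed, levels = STIMULI))
  if (any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("design has no trials for run %s, condition %s, stimulus %s",
                 runs[empty[1]], conditions[empty[2]], STIMULI[empty[3]]))
  }
  counts
}

#' Simulate run-wise beta images directly from a population spec
#'
#' Shortcut around the time-series + GLM route: for every run x condition x
#' stimulus cell the simulated coefficient at a voxel is its
#' [mean_response()] plus Gaussian noise with standard deviation
#' `noise_sd / sqrt(m)`, where `m` is the number of trials in that cell for
#' that run — emulating the averaging of `m` noisy trial responses that a
#' first-level GLM performs.
#'
#' @param design an `event_table` for a single subject.
#' @param grid a [volume_grid()].
#' @param spec a [population_spec()].
#' @param seed integer seed; output is bit-reproducible.
#' @param split_by_task if `TRUE`, cells are condition x task (labelled
#'   `"condition:task"`), halving the trials behind each beta, as when
#'   decoding is run separately per judgement task.
#' @return a `beta_set`: coefficients indexed by (voxel, run, condition,
#'   stimulus), `NA` outside the mask.
#' @export
simulate_betas <- function(design, grid, spec, seed = 1,
                           split_by_task = FALSE) {
  stopifnot(inherits(spec, "population_spec"))
  if (length(unique(design$subject_id)) != 1)
    stop("simulate_betas expects a single-subject design")
  runs <- sort(unique(design$run))
  cell_of <- if (split_by_task)
    paste(design$condition, design$task, sep = ":") else design$condition
  conditions <- if (split_by_task)
    sort(unique(cell_of)) else intersect(CONDITIONS, unique(cell_of))
  counts <- cell_counts(design, conditions, runs, cell_of)

  pref <- preference_vector(grid, spec)
  nvox <- prod(grid$shape)
  mask <- as.vector(grid$mask)
  beta <- array(NA_real_,
                dim = c(nvox, length(runs), length(conditions), 2),
                dimnames = list(NULL, runs, conditions, STIMULI))
  with_seed(seed, {
    for (r in seq_along(runs)) for (cc in seq_along(conditions))
      for (s in 1:2) {
        cond <- sub(":.*$", "", conditions[cc])
        mu <- mean_response(pref[mask], STIMULI[s], cond, spec)
        m <- counts[r, cc, s]
        beta[mask, r, cc, s] <- mu +
          rnorm(sum(mask), 0, spec$noise_sd / sqrt(m))
      }
  })
  new_beta_set(beta, grid, design$subject_id[1])
}

#' Simulate BOLD-like time series from a population spec
#'
#' Per run, each voxel's series is `baseline` plus the sum over trials of the
#' evoked amplitude (its [mean_response()] minus baseline) times a canonical
#' double-gamma HRF shifted to the trial onset, plus an optional linear
#' drift and white Gaussian noise of standard deviation `noise_sd`.
#'
#' @inheritParams simulate_betas
#' @param TR_s repetition time in seconds.
#' @param n_scans scans per run, or `NULL` to cover the last onset plus the
#'   HRF tail.  If given, must cover every onset.
#' @param drift_slope linear drift amplitude over the run (signal units,
#'   start-to-end).
#' @return a `timeseries_set`: per run a scans x voxels matrix over mask
#'   voxels (attribute `voxel_index` maps columns to grid indices), plus
#'   `TR_s`, `grid` and the generating `events`.
#' @export
simulate_timeseries <- function(design, grid, spec, TR_s = 3.36, seed = 1,
                                n_scans = NULL, drift_slope = 0) {
  stopifnot(inherits(spec, "population_spec"))
  if (length(unique(design$subject_id)) != 1)
    stop("simulate_timeseries expects a single-subject design")
  runs <- sort(unique(design$run))
  pref <- preference_vector(grid, spec)
  mask_ix <- which(as.vector(grid$mask))
  pref_m <- pref[mask_ix]

  out <- with_seed(seed, lapply(runs, function(r) {
    ev <- design[design$run == r, ]
    ns <- if (is.null(n_scans))
      ceiling((max(ev$onset_s) + 32) / TR_s) else n_scans
    if (max(ev$onset_s) >= ns * TR_s)
      stop(sprintf("run %d duration (%d scans x %g s) shorter than its last onset (%g s)",
                   r, ns, TR_s, max(ev$onset_s)))
    t_scan <- (seq_len(ns) - 1) * TR_s
    # H[t, trial] = hrf(t - onset); Y = H %*% amplitudes
    H <- vapply(ev$onset_s, function(o) canonical_hrf(t_scan - o),
                numeric(ns))
    A <- vapply(seq_len(nrow(ev)), function(tr)
      mean_response(pref_m, ev$observed[tr], ev$condition[tr], spec) -
        spec$baseline,
      numeric(length(mask_ix)))
    y <- H %*% t(A) + spec$baseline +
      drift_slope * seq(0, 1, length.out = ns) +
      matrix(rnorm(ns * length(mask_ix), 0, spec$noise_sd),
             ns, length(mask_ix))
    attr(y, "voxel_index") <- mask_ix
    y
  }))
  names(out) <- runs
  structure(list(runs = out, TR_s = TR_s, grid = grid,
                 events = design),
            class = "timeseries_set")
}

#' @export
print.timeseries_set <- function(x, ...) {
  cat(sprintf("time-series set: %d runs, TR %g s, %d mask voxels, %s scans/run\n",
              length(x$runs), x$TR_s, ncol(x$runs[[1]]),
              paste(unique(vapply(x$runs, nrow, 1L)), collapse = "/")))
  invisible(x)
}
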