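# Shared fixtures: tiny grids, specs and hand-built containers.

tiny_grid <- function(n = 6, voxel = 3) volume_grid(rep(n, 3), voxel)

# A compact 2x2x2 informative block in the grid corner, half index- and
# half little-preferring.
tiny_spec <- function(hypothesis = "sharpening", n = 6, ...) {
  coords <- as.matrix(expand.grid(i = 2:3, j = 2:3, k = 2:3))
  pref <- rep(c("index", "little"), 4)
  population_spec(informative_region = coords, preference = pref,
                  hypothesis = hypothesis, ...)
}

tiny_design <- function(n_subjects = 1, n_runs = 8, trials = 48, seed = 1)
  make_design(n_subjects, n_runs, trials, seed = seed)

# Hand-built cluster set over given voxel coordinates (bypasses group
# inference, for unit-testing extraction code).
fake_cluster_set <- function(..., labels = NULL) {
  vox <- list(...)
  if (is.null(labels)) labels <- paste0("C", seq_along(vox))
  cls <- lapply(seq_along(vox), function(i) {
    v <- matrix(as.integer(vox[[i]]), ncol = 3)
    list(label = labels[i], voxels = v, size = nrow(v), peak_t = NA_real_,
         peak = v[1, ], p_fwe = NA_real_)
  })
  structure(cls, class = "cluster_set")
}

# Balanced item set for decoding tests: one index and one little item per run.
item_frame <- function(n_runs = 8)
  data.frame(run = rep(seq_len(n_runs), each = 2),
             stimulus = rep(c("index", "little"), n_runs),
             stringsAsFactors = FALSE)
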