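#' Classify each voxel's preferred stimulus from a t contrast
#'
#' Per voxel, a paired t statistic over the (run x condition) cells of
#' `beta(index) - beta(little)`; the sign classifies the voxel in a binary
#' fashion (`t > 0` index-preferring, `t < 0` little-preferring, `t = 0`
#' excluded — a measure-zero event under continuous noise).  By default all
#' conditions, including no-move, enter the contrast; `include_no_move =
#' FALSE` restricts it to the move conditions.
#'
#' @param betas a `beta_set` containing both stimuli.
#' @param include_no_move include no-move cells in the contrast (default).
#' @return a `tuning_map`: `t` (3D array), `preference` (3D character array:
#'   `"index"`, `"little"` or `NA` for excluded/out-of-mask), `df`, `grid`.
#' @export
voxel_preference <- function(betas, include_no_move = TRUE) {
  conds <- dimnames(betas$beta)[[3]]
  if (!include_no_move) conds <- setdiff(conds, "no_move")
  runs <- dimnames(betas$beta)[[2]]
  cells <- expand.grid(run = runs, condition = conds,
                       stringsAsFactors = FALSE)
  if (nrow(cells) < 2)
    stop("voxel preference needs at least 2 (run, condition) cells")
  D <- vapply(seq_len(nrow(cells)), function(i)
    betas$beta[, cells$run[i], cells$condition[i], "index"] -
      betas$beta[, cells$run[i], cells$condition[i], "little"],
    numeric(dim(betas$beta)[1]))
  n <- ncol(D)
  mu <- rowMeans(D)
  s <- sqrt(rowSums((D - mu)^2) / (n - 1))
  t <- mu / (s / sqrt(n))
  t[s == 0 & !is.na(s) & mu == 0] <- 0
  pref <- ifelse(t > 0, "index", ifelse(t < 0, "little", NA))
  sh <- betas$grid$shape
  structure(list(t = array(t, sh),
                 preference = array(pref, sh),
                 df = n - 1, grid = betas$grid),
            class = "tuning_map")
}

#' @export
print.tuning_map <- function(x, ...) {
  p <- x$preference[!is.na(x$preference)]
  cat(sprintf("tuning map: %d classified voxels (%d index, %d little), df %d\n",
              length(p), sum(p == "index"), sum(p == "little"), x$df))
  invisible(x)
}

#' Univariate signal by congruency and voxel preference
#'
#' For each subject, cluster, congruency condition and preference status,
#' averages the betas over runs, cluster voxels and stimuli, where
#' "preferred" means the observed stimulus matches the voxel's own preferred
#' stimulus (e.g. for an index-preferring voxel the congruent-trial beta to
#' an observed index movement is congruent-preferred).  Voxels with `t = 0`
#' are excluded; a cluster whose voxels are all excluded is an error.
#'
#' @param betas_list per-subject `beta_set`s (unsmoothed, native grid).
#' @param tunings_list per-subject `tuning_map`s on the same grids.
#' @param rois a `cluster_set`.
#' @param conditions congruency conditions to extract.
#' @return a `cell_table`: `subject_id`, `cluster`, `condition`,
#'   `preference` (`"preferred"`/`"nonpreferred"`), `value`.
#' @export
preference_signal_table <- function(betas_list, tunings_list, rois,
                                    conditions = c("congruent",
                                                   "incongruent")) {
  stopifnot(length(betas_list) == length(tunings_list), length(rois) > 0)
  rows <- list()
  for (s in seq_along(betas_list)) {
    bs <- betas_list[[s]]
    tm <- tunings_list[[s]]
    stopifnot(identical(bs$grid$shape, tm$grid$shape))
    runs <- dimnames(bs$beta)[[2]]
    for (cl in rois) {
      ix <- coords_to_index(cl$voxels, bs$grid$shape)
      pref <- tm$preference[ix]
      keep <- !is.na(pref)
      if (!any(keep))
        stop("cluster ", cl$label, " has no voxels with a stimulus ",
             "preference for subject ", bs$subject_id)
      ixk <- ix[keep]
      prefk <- pref[keep]
      for (cond in conditions) {
        # beta at each voxel for its preferred / non-preferred stimulus,
        # averaged over runs then voxels
        bi <- matrix(bs$beta[ixk, , cond, "index"], nrow = length(ixk))
        bl <- matrix(bs$beta[ixk, , cond, "little"], nrow = length(ixk))
        bp <- bi; bp[prefk == "little", ] <- bl[prefk == "little", ]
        bn <- bl; bn[prefk == "little", ] <- bi[prefk == "little", ]
        vox_pref <- rowMeans(bp)
        vox_nonp <- rowMeans(bn)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = bs$subject_id, cluster = cl$label,
          condition = cond,
          preference = c("preferred", "nonpreferred"),
          value = c(mean(vox_pref), mean(vox_nonp)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Test the sharpening vs cancellation signature
#'
#' Runs the cluster x congruency x preference repeated-measures ANOVA on a
#' preference signal table and the two post-hoc paired t tests comparing
#' congruent against incongruent signal within preferred and within
#' non-preferred voxels (collapsing over clusters).  The verdict is:
#' \describe{
#'   \item{sharpening}{congruent suppression only in voxels tuned away from
#'     the observed stimulus (non-preferred).}
#'   \item{cancellation}{congruent suppression only in voxels tuned towards
#'     it (preferred).}
#'   \item{mixed}{suppression in both.}
#'   \item{none}{suppression in neither.}
#' }
#' Suppression means a significant two-sided paired t at level `alpha` with
#' lower signal on congruent than incongruent trials.
#'
#' @param cell_table output of [preference_signal_table()].
#' @param alpha significance level for the post-hoc tests.
#' @return a `signature_result`: `verdict`, the `anova` table, the two
#'   post-hoc tests and the condition x preference means.
#' @export
sharpening_signature <- function(cell_table, alpha = 0.05) {
  multi_cluster <- length(unique(cell_table$cluster)) > 1
  factors <- c(if (multi_cluster) "cluster", "condition", "preference")
  anova <- rm_anova(cell_table, factors)

  subj_means <- function(pref) {
    tt <- cell_table[cell_table$preference == pref, ]
    agg <- aggregate(tt$value,
                     by = list(s = tt$subject_id, cond = tt$condition),
                     mean)
    list(con = agg$x[agg$cond == "congruent"][order(agg$s[agg$cond == "congruent"])],
         inc = agg$x[agg$cond == "incongruent"][order(agg$s[agg$cond == "incongruent"])])
  }
  pp <- subj_means("preferred")
  np <- subj_means("nonpreferred")
  t_pref <- paired_t(pp$con, pp$inc)
  t_nonp <- paired_t(np$con, np$inc)

  supp_pref <- t_pref$p < alpha && t_pref$mean_diff < 0
  supp_nonp <- t_nonp$p < alpha && t_nonp$mean_diff < 0
  verdict <- if (supp_pref && supp_nonp) "mixed"
  else if (supp_nonp) "sharpening"
  else if (supp_pref) "cancellation"
  else "none"

  means <- aggregate(cell_table$value,
                     by = list(condition = cell_table$condition,
                               preference = cell_table$preference), mean)
  names(means)[3] <- "value"
  structure(list(verdict = verdict, anova = anova,
                 t_preferred = t_pref, t_nonpreferred = t_nonp,
                 cell_means = means, alpha = alpha),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("population-code signature verdict:", x$verdict, "\n")
  cat(sprintf("  congruent vs incongruent, preferred:     t(%d) = %.3f, p = %.4g\n",
              x$t_preferred$df, x$t_preferred$t, x$t_preferred$p))
  cat(sprintf("  congruent vs incongruent, non-preferred: t(%d) = %.3f, p = %.4g\n",
              x$t_nonpreferred$df, x$t_nonpreferred$t, x$t_nonpreferred$p))
  invisible(x)
}
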