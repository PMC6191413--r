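#' Extract cluster-mean values per subject and cell
#'
#' Averages each subject's per-cell volumes (e.g. condition-wise accuracy
#' maps) over the voxels of each ROI cluster, yielding a fully crossed cell
#' table for repeated-measures analysis.
#'
#' @param maps list over subjects; each element a named list mapping a cell
#'   label to an `accuracy_map` or 3D array.  Compound cell labels such as
#'   `"congruent:finger_judgement"` are split on `":"` into the columns named
#'   by `factors`.
#' @param rois a `cluster_set`.
#' @param factors names for the factor columns encoded in the cell labels
#'   (default `"condition"`).
#' @return a `cell_table` data.frame: `subject_id`, `cluster`, one column per
#'   factor, `value`.
#' @export
extract_cluster_means <- function(maps, rois, factors = "condition") {
  if (length(rois) == 0) stop("cluster set is empty; nothing to extract")
  rows <- list()
  for (s in seq_along(maps)) {
    subj <- names(maps)[s]
    if (is.null(subj) || subj == "") subj <- sprintf("sub-%02d", s)
    for (cell in names(maps[[s]])) {
      m <- maps[[s]][[cell]]
      vol <- if (inherits(m, "accuracy_map")) m$data else m
      parts <- strsplit(cell, ":", fixed = TRUE)[[1]]
      if (length(parts) != length(factors))
        stop("cell label '", cell, "' does not match factors (",
             paste(factors, collapse = ", "), ")")
      for (cl in rois) {
        vals <- vol[cl$voxels]
        if (anyNA(vals))
          stop("cluster ", cl$label, " has voxels outside the volume mask")
        row <- data.frame(subject_id = subj, cluster = cl$label,
                          stringsAsFactors = FALSE)
        row[factors] <- as.list(parts)
        row$value <- mean(vals)
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  out
}

check_crossed <- function(table, factors, subject) {
  cells <- interaction(table[factors], drop = FALSE, sep = ":")
  counts <- table(table[[subject]], cells)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    msgs <- apply(bad, 1, function(b)
      paste0(rownames(counts)[b[1]], " x ", colnames(counts)[b[2]],
             " (", counts[b[1], b[2]], " values)"))
    stop("design not fully crossed; offending cells: ",
         paste(head(msgs, 5), collapse = "; "))
  }
  invisible(TRUE)
}

#' Repeated-measures ANOVA on a fully crossed within-subject table
#'
#' Standard within-subject sum-of-squares decomposition for 1-3 crossed
#' factors, fitted via `stats::aov` with `Error(subject/(A*B*...))` strata.
#' Each effect is tested against its own subject-by-effect interaction error
#' term; partial eta squared is `SS_effect / (SS_effect + SS_error)`.  No
#' sphericity correction is applied.
#'
#' @param table a `cell_table` (or any data.frame) with a subject column, the
#'   factor columns, and a value column; exactly one value per subject x
#'   cell.
#' @param factors character vector of 1-3 factor column names.
#' @param subject subject column name.
#' @param value value column name.
#' @return an `anova_table` data.frame: `effect`, `df_num`, `df_den`, `F`,
#'   `p`, `partial_eta_sq`.
#' @export
rm_anova <- function(table, factors, subject = "subject_id",
                     value = "value") {
  stopifnot(length(factors) >= 1, length(factors) <= 3,
            all(c(factors, subject, value) %in% names(table)))
  check_crossed(table, factors, subject)
  d <- data.frame(.subj = factor(table[[subject]]),
                  .y = table[[value]])
  for (f in factors) d[[f]] <- factor(table[[f]])

  rhs <- paste(factors, collapse = " * ")
  form <- stats::as.formula(
    paste0(".y ~ ", rhs, " + Error(.subj/(", rhs, "))"))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)

  out <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- rownames(tab)
    resid_ix <- grep("^Residuals", trimws(terms))
    if (length(resid_ix) == 0) next
    ss_err <- tab[resid_ix, "Sum Sq"]
    df_err <- tab[resid_ix, "Df"]
    for (i in setdiff(seq_along(terms), resid_ix)) {
      eff <- trimws(terms[i])
      out[[length(out) + 1]] <- data.frame(
        effect = eff,
        df_num = tab[i, "Df"],
        df_den = df_err,
        F = tab[i, "F value"],
        p = tab[i, "Pr(>F)"],
        partial_eta_sq = tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_err),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("anova_table", "data.frame")
  res
}

#' @export
print.anova_table <- function(x, ...) {
  cat("repeated-measures ANOVA\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-28s F(%d,%d) = %.3f, p = %.4g, pes = %.3f\n",
                x$effect[i], x$df_num[i], x$df_den[i], x$F[i], x$p[i],
                x$partial_eta_sq[i]))
  invisible(x)
}

#' Paired t test
#'
#' Two-sided paired t test on per-subject value pairs.  Zero-variance
#' differences give an infinite (or undefined) t and are flagged.
#'
#' @param x,y numeric vectors of equal length (>= 2), matched by subject.
#' @return list with `t`, `df`, `p`, `two_sided = TRUE`, `mean_diff`, and
#'   `flagged` (TRUE when the difference variance is zero).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  s <- sd(d)
  flagged <- s == 0
  t <- if (flagged) {
    if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else mean(d) / (s / sqrt(n))
  p <- if (flagged && t == 0) 1 else 2 * pt(-abs(t), df = n - 1)
  list(t = t, df = n - 1, p = p, two_sided = TRUE, mean_diff = mean(d),
       flagged = flagged)
}

#' Within-participant confidence-interval half-widths
#'
#' The display convention for repeated-measures condition means: the 95%
#' confidence interval of the per-subject difference between the factor's
#' two levels, divided by `sqrt(2)` so it can be drawn on each condition
#' mean: `half = t(0.975, n-1) * SD(diff) / sqrt(n) / sqrt(2)`.
#'
#' @param table a `cell_table` with subject, factor and value columns.
#' @param factor name of a two-level factor column.
#' @param conf confidence level.
#' @param subject,value column names.
#' @return data.frame with one row per cluster (or a single row if no
#'   `cluster` column) and the CI `half_width` applicable to both cells.
#' @export
within_subject_ci <- function(table, factor, conf = 0.95,
                              subject = "subject_id", value = "value") {
  levs <- unique(table[[factor]])
  if (length(levs) != 2)
    stop("within-participant CI is defined for the pairwise difference of ",
         "exactly 2 levels; '", factor, "' has ", length(levs))
  groups <- if ("cluster" %in% names(table) && factor != "cluster")
    split(table, table$cluster) else list(all = table)
  out <- lapply(names(groups), function(g) {
    tt <- groups[[g]]
    # collapse any remaining factors to one value per subject x level
    agg <- aggregate(tt[[value]],
                     by = list(s = tt[[subject]], l = tt[[factor]]), mean)
    wide <- merge(agg[agg$l == levs[1], c("s", "x")],
                  agg[agg$l == levs[2], c("s", "x")], by = "s")
    d <- wide[[2]] - wide[[3]]
    n <- length(d)
    data.frame(cluster = g,
               half_width = qt(1 - (1 - conf) / 2, n - 1) *
                 sd(d) / sqrt(n) / sqrt(2))
  })
  do.call(rbind, out)
}
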