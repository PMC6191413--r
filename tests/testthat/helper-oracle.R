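# Brute-force within-subject ANOVA oracle, coded independently of
# rm_anova(): sums of squares by inclusion-exclusion over cell means for a
# fully balanced design with one observation per subject x cell.

bf_subsets <- function(x)
  unlist(lapply(seq_along(x), function(k)
    utils::combn(x, k, simplify = FALSE)), recursive = FALSE)

bf_mean_over <- function(d, vars, value) {
  if (length(vars) == 0) return(rep(mean(d[[value]]), nrow(d)))
  stats::ave(d[[value]], interaction(d[vars], drop = TRUE))
}

bf_ss <- function(d, U, value) {
  th <- rep(0, nrow(d))
  for (T in c(list(character(0)), bf_subsets(U)))
    th <- th + (-1)^(length(U) - length(T)) * bf_mean_over(d, T, value)
  sum(th^2)
}

bf_rm_anova <- function(d, factors, subject = "subject_id",
                        value = "value") {
  df_of <- function(U)
    prod(vapply(U, function(f) length(unique(d[[f]])) - 1, 1))
  out <- lapply(bf_subsets(factors), function(E) {
    ssE <- bf_ss(d, E, value)
    dfE <- df_of(E)
    ssW <- bf_ss(d, c(E, subject), value)
    dfW <- df_of(c(E, subject))
    data.frame(effect = paste(E, collapse = ":"),
               df_num = dfE, df_den = dfW,
               F = (ssE / dfE) / (ssW / dfW),
               p = stats::pf((ssE / dfE) / (ssW / dfW), dfE, dfW,
                             lower.tail = FALSE),
               partial_eta_sq = ssE / (ssE + ssW),
               ss_effect = ssE, ss_error = ssW,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Random fully crossed within-subject table.
random_cell_table <- function(n_subj, levels_list, seed) {
  set.seed(seed)
  cells <- expand.grid(levels_list, stringsAsFactors = FALSE)
  d <- cells[rep(seq_len(nrow(cells)), each = n_subj), , drop = FALSE]
  d$subject_id <- rep(sprintf("s%02d", seq_len(n_subj)), nrow(cells))
  d$value <- rnorm(nrow(d))
  d
}
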