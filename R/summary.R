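# Cohort phenotype aggregation.
#
# The viability phenotypes: dead_fraction = Dead / all embryos (Empty
# incubators contain no embryo and are excluded from the denominator);
# normal_over_alive = Normal / (Normal + LateHatching + Unclear), the
# alive population. Interval phenotypes (bean-to-twitch, twitch-to-hatch,
# minutes, mean +/- SEM) are computed over Normal embryos only. Cohorts
# across conditions are compared through a per-phenotype z-scored
# clustergram.

#' Summarize a cohort of embryo records
#'
#' @param records Record tibble (one condition).
#' @param condition Condition label.
#' @return One-row tibble: condition, per-state counts, `dead_fraction`,
#'   `normal_over_alive`, interval means and SEMs over Normal embryos, and
#'   an `empty_cohort` flag (TRUE when no embryos remain after excluding
#'   Empty incubators).
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   incubator = 0:3, state = c("Normal", "Dead", "Unclear", "Empty"),
#'   bean_to_twitch_min = c(100, NA, NA, NA),
#'   twitch_to_hatch_min = c(300, NA, NA, NA))
#' summarize_cohort(recs, "control")
summarize_cohort <- function(records, condition = "condition") {
  counts <- vapply(.EMBRYO_STATES, function(s)
    sum(records$state == s, na.rm = TRUE), integer(1))
  n_embryo <- sum(counts[c("Normal", "Dead", "Unclear", "LateHatching")])
  alive <- sum(counts[c("Normal", "LateHatching", "Unclear")])
  nrm <- records[!is.na(records$state) & records$state == "Normal", ]
  msem <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    c(mean(x), if (length(x) > 1) sd(x) / sqrt(length(x)) else 0)
  }
  bt <- msem(nrm$bean_to_twitch_min)
  th <- msem(nrm$twitch_to_hatch_min)
  tibble::tibble(
    condition = condition,
    n_total = n_embryo,
    n_normal = counts[["Normal"]], n_dead = counts[["Dead"]],
    n_unclear = counts[["Unclear"]],
    n_late_hatching = counts[["LateHatching"]],
    n_empty = counts[["Empty"]],
    dead_fraction = if (n_embryo) counts[["Dead"]] / n_embryo else NA_real_,
    normal_over_alive = if (alive) counts[["Normal"]] / alive else NA_real_,
    bean_to_twitch_mean = bt[1], bean_to_twitch_sem = bt[2],
    twitch_to_hatch_mean = th[1], twitch_to_hatch_sem = th[2],
    empty_cohort = n_embryo == 0)
}

#' Build the normalized phenotype clustergram
#'
#' Rows are phenotypes, columns are conditions; entries are per-row
#' z-scores (population SD) of the cohort mean values, so each non-constant
#' row has mean 0 and unit variance; constant rows map to all zeros and
#' sort last. Rows and columns are ordered by average-linkage hierarchical
#' clustering under correlation distance (`1 - r`); conditions are
#' canonicalized by label first, so the ordering is invariant to the input
#' permutation, with label order breaking ties.
#'
#' @param summaries Tibble of [summarize_cohort()] rows (>= 2 conditions).
#' @param phenotypes Summary columns used as clustergram rows.
#' @return A list of class `clustergram`: `z` (phenotype x condition
#'   matrix in dendrogram order), `row_order`, `col_order`, and the
#'   `hclust` trees (`NULL` when too few non-constant rows/columns to
#'   cluster).
#' @export
build_clustergram <- function(summaries,
                              phenotypes = c("dead_fraction",
                                             "normal_over_alive",
                                             "bean_to_twitch_mean",
                                             "twitch_to_hatch_mean")) {
  if (nrow(summaries) < 2)
    stop("clustergram needs at least 2 conditions", call. = FALSE)
  summaries <- summaries[order(summaries$condition), ]
  m <- t(as.matrix(summaries[, phenotypes]))
  colnames(m) <- summaries$condition
  rownames(m) <- phenotypes

  z <- t(apply(m, 1, function(r) {
    s <- sqrt(pop_var(r))
    if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(z) <- dimnames(m)

  constant <- apply(z, 1, function(r) all(r == 0))
  row_hc <- col_hc <- NULL
  row_order <- rownames(z)
  if (sum(!constant) >= 2) {
    zz <- z[!constant, , drop = FALSE]
    row_hc <- hclust(as.dist(1 - cor(t(zz))), method = "average")
    row_order <- c(rownames(zz)[row_hc$order], rownames(z)[constant])
  }
  col_order <- colnames(z)
  if (ncol(z) >= 3 && sum(!constant) >= 2) {
    col_hc <- hclust(as.dist(1 - cor(z[!constant, , drop = FALSE])),
                     method = "average")
    col_order <- colnames(z)[col_hc$order]
  }
  structure(list(z = z[row_order, col_order, drop = FALSE],
                 row_order = row_order, col_order = col_order,
                 row_hclust = row_hc, col_hclust = col_hc),
            class = "clustergram")
}

#' @export
print.clustergram <- function(x, ...) {
  cat(sprintf("<clustergram> %d phenotypes x %d conditions\n",
              nrow(x$z), ncol(x$z)))
  print(round(x$z, 3))
  invisible(x)
}

#' @export
tidy.clustergram <- function(x, ...) {
  tibble::tibble(
    phenotype = rep(rownames(x$z), times = ncol(x$z)),
    condition = rep(colnames(x$z), each = nrow(x$z)),
    z = as.numeric(x$z))
}
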