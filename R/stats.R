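#' Relative mutation efficiency
#'
#' The frequency of resistant clones among regenerants, as a percentage
#' reported to two decimals.
#'
#' @param resistant Number of selection-resistant clones.
#' @param regenerants Number of regenerant clones (> 0).
#' @return `100 * resistant / regenerants`, rounded to 2 decimals.
#' @export
mutation_efficiency <- function(resistant, regenerants) {
  if (any(regenerants <= 0)) stop("regenerants must be > 0")
  if (any(resistant < 0) || any(resistant > regenerants)) {
    stop("resistant must lie in [0, regenerants]")
  }
  round(100 * resistant / regenerants, 2)
}

#' Compare per-plant variant counts between groups
#'
#' Kruskal-Wallis omnibus test over per-plant counts. For total sample size
#' up to `exact_n_max` the p-value comes from the exhaustive permutation null
#' of the (tie-corrected) H statistic — the asymptotic chi-square
#' approximation is poor for groups of 2-5 plants; above that the standard
#' chi-square approximation is used. Pairwise group contrasts are run the
#' same way.
#'
#' @param counts Data frame of per-plant counts.
#' @param value Column with the count (tidy-eval).
#' @param group Column with the group label (tidy-eval).
#' @param alpha Significance level for the `distinguishable` flag.
#' @param exact_n_max Largest total n for which the exact permutation null is
#'   used.
#' @return An object of class `kw_comparison`; see [tidy.kw_comparison()]
#'   and [glance.kw_comparison()].
#' @export
group_count_comparison <- function(counts, value, group, alpha = 0.05,
                                   exact_n_max = 8L) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  x <- dplyr::pull(counts, !!value)
  g <- as.character(dplyr::pull(counts, !!group))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- g[keep]
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes < 1L)) stop("every group needs at least one plant")

  omnibus <- kw_test(x, g, exact_n_max)
  groups <- sort(unique(g))
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(pr) {
    sel <- g %in% pr
    res <- kw_test(x[sel], g[sel], exact_n_max)
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   statistic = res$statistic, p_value = res$p_value,
                   method = res$method,
                   distinguishable = res$p_value < alpha)
  })
  structure(
    list(statistic = omnibus$statistic, p_value = omnibus$p_value,
         method = omnibus$method, alpha = alpha,
         distinguishable = omnibus$p_value < alpha,
         groups = groups, n = length(x),
         pairwise = dplyr::bind_rows(pairwise)),
    class = "kw_comparison"
  )
}

kw_test <- function(x, g, exact_n_max) {
  h_obs <- kw_statistic(x, g)
  if (length(x) <= exact_n_max) {
    p <- kw_exact_p(x, g, h_obs)
    list(statistic = h_obs, p_value = p, method = "exact permutation")
  } else {
    kt <- kruskal.test(x, factor(g))
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         method = "chi-square approximation")
  }
}

# tie-corrected Kruskal-Wallis H from ranks
kw_statistic <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  sums <- tapply(r, g, sum)
  sizes <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(sums^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction > 0) h <- h / correction
  h
}

# exhaustive permutation null: every distinct assignment of the observed
# values to the group-size pattern (multiset permutations of the labels)
kw_exact_p <- function(x, g, h_obs) {
  assignments <- multiset_permutations(g)
  h_perm <- vapply(assignments, function(lab) kw_statistic(x, lab),
                   numeric(1))
  mean(h_perm >= h_obs - 1e-9)
}

multiset_permutations <- function(g) {
  recurse <- function(remaining) {
    if (length(remaining) == 0L) return(list(character(0)))
    out <- list()
    for (lab in unique(remaining)) {
      rest <- remaining[-match(lab, remaining)]
      for (tail in recurse(rest)) {
        out[[length(out) + 1L]] <- c(lab, tail)
      }
    }
    out
  }
  recurse(sort(g))
}

#' @export
print.kw_comparison <- function(x, ...) {
  cat(sprintf(
    "<kw_comparison> H = %.4g, p = %.4g (%s, %d groups, n = %d)\n",
    x$statistic, x$p_value, x$method, length(x$groups), x$n))
  cat(if (x$distinguishable) "groups are distinguishable at alpha = "
      else "groups are not distinguishable at alpha = ", x$alpha, "\n",
      sep = "")
  invisible(x)
}

#' Tidiers for editaudit result objects
#'
#' `tidy()` on a `kw_comparison` returns the pairwise contrasts; `glance()`
#' returns the one-row omnibus summary. `tidy()` on a `variant_matrix`
#' returns the long site-by-sample state table.
#'
#' @param x A `kw_comparison` or `variant_matrix`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_editaudit
NULL

#' @rdname tidy_editaudit
#' @exportS3Method generics::tidy
tidy.kw_comparison <- function(x, ...) {
  x$pairwise
}

#' @rdname tidy_editaudit
#' @exportS3Method generics::glance
glance.kw_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 method = x$method, n_groups = length(x$groups), n = x$n,
                 alpha = x$alpha, distinguishable = x$distinguishable)
}

#' Spearman correlation of per-chromosome variant counts with lengths
#'
#' @param per_chrom_counts Tibble with columns `chrom` and `n` (variant
#'   counts), or a numeric vector of counts.
#' @param lengths Tibble with columns `chrom` and `length`, or a numeric
#'   vector aligned with `per_chrom_counts`.
#' @return Tibble with `rho`, `p_value`, `n_chroms`.
#' @export
chromosome_length_correlation <- function(per_chrom_counts, lengths) {
  if (is.data.frame(per_chrom_counts)) {
    joined <- dplyr::inner_join(per_chrom_counts, lengths, by = "chrom")
    counts <- joined$n
    lens <- joined$length
  } else {
    counts <- per_chrom_counts
    lens <- lengths
  }
  if (length(counts) < 3L) stop("need at least 3 chromosomes")
  ct <- suppressWarnings(cor.test(counts, lens, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_chroms = length(counts))
}

#' Headline aggregates over a per-plant count table
#'
#' Per-experiment means and sums of SNV and InDel counts, plus grand totals.
#' Counts are integers, so the means are exact rational arithmetic; an empty
#' experiment level yields `NA`, not 0.
#'
#' @param counts Per-plant count table with columns `experiment` (or
#'   `experiment_group`/`role` — pass the grouping column via `by`), `n_snv`,
#'   `n_indel`.
#' @param by Name of the grouping column (default `"experiment"`).
#' @return A list with `by_group` (tibble of per-group n, means and sums) and
#'   `totals` (one-row tibble with grand SNV, InDel and combined totals).
#' @export
headline_aggregates <- function(counts, by = "experiment") {
  if (!by %in% names(counts)) {
    stop("grouping column not found: ", by)
  }
  grp <- counts[[by]]
  if (!is.factor(grp)) grp <- factor(grp)
  by_group <- counts |>
    dplyr::mutate(.group = grp) |>
    dplyr::group_by(.data$.group, .drop = FALSE) |>
    dplyr::summarise(
      n_plants = sum(!is.na(.data$n_snv) | !is.na(.data$n_indel)),
      mean_snv = mean(.data$n_snv, na.rm = TRUE),
      mean_indel = mean(.data$n_indel, na.rm = TRUE),
      sum_snv = sum(.data$n_snv, na.rm = TRUE),
      sum_indel = sum(.data$n_indel, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_snv = ifelse(.data$n_plants == 0L, NA_real_, .data$mean_snv),
      mean_indel = ifelse(.data$n_plants == 0L, NA_real_, .data$mean_indel)
    ) |>
    dplyr::rename(!!by := ".group")
  totals <- tibble::tibble(
    total_snv = sum(counts$n_snv, na.rm = TRUE),
    total_indel = sum(counts$n_indel, na.rm = TRUE)
  )
  totals$total <- totals$total_snv + totals$total_indel
  list(by_group = by_group, totals = totals)
}
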