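# Stage 2: indicator value analysis of trait states over observation times
# and combinations of two and three times, per community, with permutation
# inference.
#
# For a trait state j and a single time t:
#   RA[t,j] = mean_x F[x,t,j] / sum_{t'} mean_x F[x,t',j]
#   RF[t,j] = #{x at t with F[x,t,j] > 0} / n_t
#   IV[t,j] = RA[t,j] * RF[t,j]
# For a time group C (site-group-combination extension), the RA numerator is
# the mean F over all releves in C, the denominator adds the single-time
# means of the times outside C; RF is the occupied fraction of C's releves.

#' Enumerate candidate time groups
#'
#' All non-empty subsets of the observed times up to `max_order` times per
#' group (not restricted to consecutive times), ordered by group size then
#' lexicographically — the order that also serves as the deterministic
#' tie-break in [best_group()].
#'
#' @param times Integer vector of observed time indices.
#' @param max_order Largest group size (default 3).
#' @return Object of class `time_grouping`: list with `groups` (list of
#'   integer vectors), `times`, and `membership` (logical groups x times
#'   matrix).
#' @export
enumerate_time_groups <- function(times, max_order = 3) {
  times <- sort(unique(as.integer(times)))
  if (max_order < 1) tb_error("tb_config_error", "max_order must be >= 1")
  groups <- list()
  for (k in seq_len(min(max_order, length(times)))) {
    cmb <- utils::combn(times, k, simplify = FALSE)
    groups <- c(groups, cmb)
  }
  membership <- t(vapply(groups, function(g) times %in% g,
                         logical(length(times))))
  colnames(membership) <- as.character(times)
  structure(list(groups = groups, times = times, membership = membership),
            class = "time_grouping")
}

#' @export
print.time_grouping <- function(x, ...) {
  cat(sprintf("time_grouping: %d candidate groups over %d times\n",
              length(x$groups), length(x$times)))
  invisible(x)
}

# per-time sufficient statistics of one trait-state column:
# n_t (releves), sum_t (sum of F), occ_t (releves with F > 0)
time_stats <- function(f, labels, times) {
  fac <- factor(labels, levels = times)
  n <- as.integer(table(fac))
  s <- vapply(split(f, fac), sum, 0)
  z <- vapply(split(f > 0, fac), sum, 0)
  list(n = n, sum = unname(s), occ = unname(z))
}

#' Relative abundance of a trait state in a time group
#'
#' Concentration of flowering: the mean flowering proportion over the
#' group's releves divided by that mean plus the single-time means of all
#' times outside the group. For a single time this is the time's mean over
#' the sum of all single-time means. Returns 0 when the trait state never
#' flowers.
#'
#' @param f Numeric vector of F values for the community's releves.
#' @param labels Integer time index of each releve.
#' @param times Observed times of the community.
#' @param group Integer vector (1-3 times) of the candidate group.
#' @return RA in [0, 1].
#' @export
relative_abundance <- function(f, labels, times, group) {
  if (length(group) == 0) tb_error("tb_config_error", "empty time group")
  st <- time_stats(f, labels, times)
  inb <- times %in% group
  num <- sum(st$sum[inb]) / sum(st$n[inb])
  means_out <- st$sum[!inb] / st$n[!inb]
  denom <- num + sum(means_out)
  if (denom <= 0) return(0)
  num / denom
}

#' Relative frequency of a trait state in a time group
#'
#' The fraction of the group's releves occupied by flowering of the trait
#' state (F > 0).
#'
#' @inheritParams relative_abundance
#' @return RF in [0, 1].
#' @export
relative_frequency <- function(f, labels, times, group) {
  if (length(group) == 0) tb_error("tb_config_error", "empty time group")
  st <- time_stats(f, labels, times)
  inb <- times %in% group
  sum(st$occ[inb]) / sum(st$n[inb])
}

#' Indicator value
#'
#' The product of relative abundance and relative frequency; ranges from 0
#' (no flowering of the trait state at the time in any plot) to 1 (all
#' carrier species in full bloom at the time in all plots).
#'
#' @param ra,rf Relative abundance and relative frequency, each in [0, 1].
#' @return IV in [0, 1].
#' @export
indicator_value <- function(ra, rf) {
  if (any(ra < 0 | ra > 1) || any(rf < 0 | rf > 1)) {
    tb_error("tb_config_error", "RA and RF must lie in [0, 1]")
  }
  ra * rf
}

# IV (and components) for every candidate group, vectorized over groups via
# the membership matrix; returns a data frame aligned with grouping$groups
iv_all_groups <- function(f, labels, grouping, stats = NULL) {
  st <- if (is.null(stats)) time_stats(f, labels, grouping$times) else stats
  M <- grouping$membership
  grp_n <- as.numeric(M %*% st$n)
  grp_sum <- as.numeric(M %*% st$sum)
  grp_occ <- as.numeric(M %*% st$occ)
  means <- st$sum / st$n
  total_mean <- sum(means)
  num <- grp_sum / grp_n
  denom <- num + (total_mean - as.numeric(M %*% means))
  ra <- ifelse(denom > 0, num / denom, 0)
  rf <- grp_occ / grp_n
  data.frame(ra = ra, rf = rf, iv = ra * rf)
}

#' Best (maximum-IV) time group for a trait state
#'
#' Scans every candidate group and returns the group with the maximum
#' indicator value. Ties are broken deterministically: smallest group size,
#' then lexicographically earliest time set (the enumeration order of
#' [enumerate_time_groups()]).
#'
#' @inheritParams relative_abundance
#' @param grouping An [enumerate_time_groups()] result.
#' @return List with `group`, `iv`, `ra`, `rf` and logical `all_zero` (true
#'   when the trait state never flowers, in which case IV = 0).
#' @export
best_group <- function(f, labels, grouping) {
  tab <- iv_all_groups(f, labels, grouping)
  i <- which.max(tab$iv)  # first max in size-then-lexicographic order
  list(group = grouping$groups[[i]], iv = tab$iv[i], ra = tab$ra[i],
       rf = tab$rf[i], all_zero = all(f == 0))
}

max_iv <- function(f, labels, grouping, stats = NULL) {
  max(iv_all_groups(f, labels, grouping, stats = stats)$iv)
}

# all distinct permutations of a small multiset (guarded by count)
multiset_permutations <- function(x, limit = 2e5) {
  tab <- table(x)
  total <- factorial(length(x)) / prod(factorial(tab))
  if (total > limit) {
    tb_error("tb_config_error",
             sprintf("exact enumeration needs %d permutations (> %d)",
                     total, limit))
  }
  rec <- function(pool) {
    if (length(pool) == 0) return(list(integer(0)))
    out <- list()
    for (v in unique(pool)) {
      rest <- pool[-match(v, pool)]
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(v, tail)
    }
    out
  }
  rec(sort(x))
}

#' Permutation test of the maximum indicator value
#'
#' Releve time-labels are permuted (freely across the community by default,
#' or within plots when `restricted = TRUE`); per permutation the maximum IV
#' over all candidate groups is recomputed. The Monte Carlo p-value uses the
#' add-one estimator `(1 + #[IV* >= IV_obs]) / (1 + n_perm)`, so p > 0
#' always. With `exact = TRUE` all distinct label arrangements are
#' enumerated and `p = #[IV* >= IV_obs] / #arrangements` (the identity
#' arrangement counts, so p > 0).
#'
#' @inheritParams best_group
#' @param n_perm Number of random permutations (default 4999).
#' @param seed Integer seed for reproducibility.
#' @param restricted Permute labels within plots only (repeated-measures
#'   design) instead of freely across the community.
#' @param plot_ids Releve plot identifiers; required when
#'   `restricted = TRUE`.
#' @param exact Enumerate all distinct label arrangements (small instances
#'   only).
#' @return List with `p_value`, `iv_obs`, `n_perm` (or `n_arrangements`).
#' @export
permutation_test_iv <- function(f, labels, grouping, n_perm = 4999,
                                seed = NULL, restricted = FALSE,
                                plot_ids = NULL, exact = FALSE) {
  if (length(unique(labels)) < 2) {
    tb_error("tb_config_error",
             "permutation test needs >= 2 distinct time labels")
  }
  obs <- max_iv(f, labels, grouping)
  if (exact) {
    perms <- multiset_permutations(labels)
    stats <- vapply(perms, function(lb) max_iv(f, lb, grouping), 0)
    return(list(p_value = mean(stats >= obs - 1e-12), iv_obs = obs,
                n_arrangements = length(perms)))
  }
  if (n_perm < 1) tb_error("tb_config_error", "n_perm must be >= 1")
  if (restricted && is.null(plot_ids)) {
    tb_error("tb_config_error", "restricted permutation needs plot_ids")
  }
  if (!is.null(seed)) set.seed(seed)
  ge <- 0L
  if (restricted) {
    idx_by_plot <- split(seq_along(labels), plot_ids)
  }
  for (b in seq_len(n_perm)) {
    lb <- labels
    if (restricted) {
      for (ii in idx_by_plot) lb[ii] <- lb[ii][sample.int(length(ii))]
    } else {
      lb <- labels[sample.int(length(labels))]
    }
    if (max_iv(f, lb, grouping) >= obs - 1e-12) ge <- ge + 1L
  }
  list(p_value = (1 + ge) / (1 + n_perm), iv_obs = obs, n_perm = n_perm)
}

#' Indicator value analysis per community
#'
#' Runs one ISA per community on the releves-by-trait-states matrix: for
#' every trait state, the maximum-IV time group over all candidate groups
#' (sizes 1..`max_order`), its RA/RF components, a permutation p-value for
#' the maximum IV, and the retention decision
#' `retained = (p < alpha) & (RA >= ra_min) & (RF >= rf_min)`.
#'
#' @param tm A [build_trait_matrix()] result.
#' @param alpha Significance level (default 0.05).
#' @param ra_min,rf_min Retention thresholds on the components (defaults 0.6
#'   and 0.25).
#' @param n_perm Permutations per test (default 4999).
#' @param max_order Largest candidate group size (default 3).
#' @param seed Integer seed.
#' @param restricted Restrict permutations within plots.
#' @param communities Subset of communities to analyse (default all).
#' @param states Optional data frame (`trait`, `state`) restricting the
#'   trait states analysed.
#' @return Data frame with one row per community x trait state: `community`,
#'   `trait`, `state`, `best_group` (comma-joined time indices), `iv`, `ra`,
#'   `rf`, `p_value`, `n_perm`, `retained`, sorted by community, trait,
#'   state.
#' @export
run_isa <- function(tm, alpha = 0.05, ra_min = 0.6, rf_min = 0.25,
                    n_perm = 4999, max_order = 3, seed = 1L,
                    restricted = FALSE, communities = NULL, states = NULL) {
  if (is.null(communities)) communities <- unique(tm$rows$community)
  st_tab <- tm$states
  if (!is.null(states)) {
    keep <- paste(st_tab$trait, st_tab$state) %in%
      paste(states$trait, states$state)
    st_tab <- st_tab[keep, , drop = FALSE]
  }
  out <- list()
  for (cm in communities) {
    in_cm <- tm$rows$community == cm
    labels <- tm$rows$time_index[in_cm]
    plot_ids <- tm$rows$plot_id[in_cm]
    times <- sort(unique(labels))
    if (length(times) < 2) {
      tb_error("tb_config_error",
               sprintf("community '%s' has < 2 observed times", cm))
    }
    grouping <- enumerate_time_groups(times, max_order = max_order)
    for (k in seq_len(nrow(st_tab))) {
      f <- tm$F[in_cm, st_tab$column[k]]
      bg <- best_group(f, labels, grouping)
      if (bg$all_zero) {
        p <- 1
      } else {
        p <- permutation_test_iv(
          f, labels, grouping, n_perm = n_perm,
          seed = seed + k + 1000L * match(cm, communities),
          restricted = restricted, plot_ids = plot_ids
        )$p_value
      }
      out[[length(out) + 1L]] <- data.frame(
        community = cm, trait = st_tab$trait[k], state = st_tab$state[k],
        best_group = paste(bg$group, collapse = ","),
        iv = bg$iv, ra = bg$ra, rf = bg$rf, p_value = p,
        n_perm = n_perm,
        retained = (p < alpha) && (bg$ra >= ra_min) && (bg$rf >= rf_min) &&
          !bg$all_zero,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$community, res$trait, res$state), ]
  rownames(res) <- NULL
  res
}
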