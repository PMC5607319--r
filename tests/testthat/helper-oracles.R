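# Independent oracles: direct transliterations of the defining formulas,
# written as plain double loops, never sharing code with the package
# internals they check.

# F for one trait state at every (plot, time): mean over flowering carrier
# species of n[x,t,i]/n[tot,i]
oracle_F <- function(obs, carrier_ids, plot, time) {
  vals <- c()
  for (sp in carrier_ids) {
    tot <- sum(obs$shoots_in_full_bloom[obs$plot_id == plot &
                                          obs$species_id == sp])
    n_xt <- sum(obs$shoots_in_full_bloom[obs$plot_id == plot &
                                           obs$species_id == sp &
                                           obs$time_index == time])
    if (tot > 0 && n_xt > 0) vals <- c(vals, n_xt / tot)
  }
  if (length(vals) == 0) 0 else mean(vals)
}

# RA of a time group from a community's F column: group mean over that
# group's releves divided by (group mean + single-time means outside)
oracle_ra <- function(f, labels, times, group) {
  grp_vals <- f[labels %in% group]
  num <- mean(grp_vals)
  denom <- num
  for (t in setdiff(times, group)) denom <- denom + mean(f[labels == t])
  if (denom <= 0) 0 else num / denom
}

oracle_rf <- function(f, labels, group) {
  in_grp <- labels %in% group
  sum(f[in_grp] > 0) / sum(in_grp)
}

# max IV over every subset of times of size 1..max_order, by explicit scan
oracle_best <- function(f, labels, times, max_order = 3) {
  best <- list(iv = -1)
  for (k in seq_len(min(max_order, length(times)))) {
    for (grp in utils::combn(times, k, simplify = FALSE)) {
      iv <- oracle_ra(f, labels, times, grp) * oracle_rf(f, labels, grp)
      if (iv > best$iv + 1e-14) best <- list(iv = iv, group = grp)
    }
  }
  best
}

# exact permutation p of the max IV: enumerate every distinct arrangement
# of the label multiset recursively
oracle_label_arrangements <- function(labels) {
  rec <- function(pool) {
    if (length(pool) == 0) return(list(integer(0)))
    out <- list()
    for (v in unique(pool)) {
      for (tail in rec(pool[-match(v, pool)])) {
        out[[length(out) + 1L]] <- c(v, tail)
      }
    }
    out
  }
  rec(sort(labels))
}

oracle_exact_p <- function(f, labels, times, max_order = 3) {
  obs <- oracle_best(f, labels, times, max_order)$iv
  arr <- oracle_label_arrangements(labels)
  ge <- 0
  for (lb in arr) {
    if (oracle_best(f, lb, times, max_order)$iv >= obs - 1e-12) ge <- ge + 1
  }
  ge / length(arr)
}
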