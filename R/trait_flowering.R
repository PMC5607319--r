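# Stage 1: shoot counts -> per-species flowering proportions -> trait-state
# mean flowering proportions F[x,t] on the releves-by-trait-states matrix.
#
# For species i in plot x at time t, the proportion is n[x,t,i] / n[tot,i],
# where n[tot,i] is the species' seasonal shoot total in that plot. For a
# trait state j, F[x,t] is the mean proportion over the S[x,t] species that
# carry j and are actually flowering at (x,t); F[x,t] = 0 where S[x,t] = 0.

#' Per-species flowering proportions within plots
#'
#' For every (plot, species) with a positive seasonal shoot total, the
#' proportion of the species' seasonal flowering shoots occurring at each of
#' the plot's observed times. Totals are per plot, never pooled across
#' plots. Species never in bloom in a plot have no profile there.
#'
#' @param study A validated `flowering_study`.
#' @return Data frame with columns `plot_id`, `species_id`, `time_index`,
#'   `proportion`, `seasonal_total` (only rows with positive counts are
#'   listed; proportions over a profile sum to 1). The attribute `excluded`
#'   lists (plot, species) pairs whose seasonal total was zero.
#' @export
species_proportions <- function(study) {
  obs <- study$observations
  if (any(obs$shoots_in_full_bloom < 0)) {
    stop("internal error: negative shoot count survived validation")
  }
  key <- paste(obs$plot_id, obs$species_id, sep = "\r")
  totals <- rowsum(obs$shoots_in_full_bloom, key)
  tot <- totals[match(key, rownames(totals)), 1]
  out <- data.frame(
    plot_id = obs$plot_id,
    species_id = obs$species_id,
    time_index = obs$time_index,
    proportion = obs$shoots_in_full_bloom / tot,
    seasonal_total = tot,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$plot_id, out$species_id, out$time_index), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(plot_id = character(),
                                      species_id = character())
  out
}

#' Trait-state column of flowering proportions
#'
#' Aggregates species proportions into the mean flowering proportion of one
#' trait state per releve. With `carriers = "flowering"` (the default) the
#' denominator counts only carrier species actually in bloom at (x, t); with
#' `carriers = "present"` it counts all carrier species with a positive
#' seasonal total in plot x, so carriers not in bloom dilute the mean.
#'
#' @param profiles Output of [species_proportions()].
#' @param traits Trait table (`species_id`, `trait`, `state`).
#' @param trait,state The trait state to aggregate.
#' @param rows Data frame with `plot_id`, `time_index` defining the releves
#'   (row order of the result).
#' @param carriers Denominator convention, `"flowering"` or `"present"`.
#' @return List with numeric vector `F` and integer vector `S` (support:
#'   number of contributing carrier species), aligned with `rows`.
#' @export
aggregate_trait_state <- function(profiles, traits, trait, state, rows,
                                  carriers = c("flowering", "present")) {
  carriers <- match.arg(carriers)
  sel <- traits$trait == trait & traits$state == state
  if (!trait %in% traits$trait || !any(sel)) {
    tb_error("tb_lookup_error",
             sprintf("unknown trait state %s=%s", trait, state))
  }
  carrier_ids <- unique(traits$species_id[sel])
  pr <- profiles[profiles$species_id %in% carrier_ids, , drop = FALSE]
  rkey <- paste(rows$plot_id, rows$time_index, sep = "\r")
  pkey <- paste(pr$plot_id, pr$time_index, sep = "\r")
  idx <- match(pkey, rkey)
  keep <- !is.na(idx)
  num <- rep(0, nrow(rows))
  S <- integer(nrow(rows))
  if (any(keep)) {
    sums <- rowsum(pr$proportion[keep], idx[keep])
    cnts <- rowsum(rep(1L, sum(keep)), idx[keep])
    at <- as.integer(rownames(sums))
    num[at] <- sums[, 1]
    S[at] <- cnts[, 1]
  }
  if (carriers == "present") {
    # denominator: carriers with a profile in the plot, flowering or not
    pp <- unique(pr[c("plot_id", "species_id")])
    per_plot <- table(pp$plot_id)
    S_all <- as.integer(per_plot[rows$plot_id])
    S_all[is.na(S_all)] <- 0L
    Fv <- ifelse(S_all > 0, num / S_all, 0)
    return(list(F = Fv, S = S_all))
  }
  Fv <- ifelse(S > 0, num / S, 0)
  list(F = Fv, S = S)
}

#' Build the releves-by-trait-states matrix
#'
#' One row per releve (plot x observed time), one column per declared trait
#' state, in deterministic order (trait, then state, lexicographic). Cell
#' values are mean flowering proportions in [0, 1]; a companion support
#' matrix `S` counts the contributing species per cell.
#'
#' @param study A validated `flowering_study`.
#' @param profiles Optional precomputed [species_proportions()].
#' @param states Optional data frame (`trait`, `state`) restricting the
#'   columns; defaults to every state present in the trait table.
#' @param carriers Denominator convention passed to
#'   [aggregate_trait_state()].
#' @return An object of class `trait_matrix`: list with matrix `F`, integer
#'   matrix `S`, data frame `rows` (`plot_id`, `time_index`, `community`)
#'   and data frame `states` (`trait`, `state`, `column`).
#' @export
build_trait_matrix <- function(study, profiles = NULL, states = NULL,
                               carriers = "flowering") {
  if (is.null(profiles)) profiles <- species_proportions(study)
  comm_of <- stats::setNames(study$plots$community, study$plots$plot_id)
  rows <- do.call(rbind, lapply(study$plots$plot_id, function(p) {
    ot <- observed_times(study, comm_of[[p]])
    data.frame(plot_id = p, time_index = ot, community = comm_of[[p]],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  if (is.null(states)) {
    states <- unique(study$traits[c("trait", "state")])
  }
  states <- states[order(states$trait, states$state), , drop = FALSE]
  states$column <- paste(states$trait, states$state, sep = ":")
  Fm <- matrix(0, nrow(rows), nrow(states),
               dimnames = list(paste(rows$plot_id, rows$time_index, sep = ":"),
                               states$column))
  Sm <- Fm
  for (k in seq_len(nrow(states))) {
    ag <- aggregate_trait_state(profiles, study$traits, states$trait[k],
                                states$state[k], rows, carriers = carriers)
    Fm[, k] <- ag$F
    Sm[, k] <- ag$S
  }
  structure(list(F = Fm, S = Sm, rows = rows, states = states),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d releves x %d trait states (%d communities)\n",
              nrow(x$F), ncol(x$F), length(unique(x$rows$community))))
  invisible(x)
}

#' Descriptive statistics of trait-state flowering proportions
#'
#' Per community, observation time and trait state: the number of plots, and
#' the mean, standard deviation, minimum and maximum of F over plots.
#'
#' @param tm A [build_trait_matrix()] result.
#' @return Long data frame with columns `community`, `time_index`, `trait`,
#'   `state`, `n`, `mean`, `sd`, `min`, `max`.
#' @export
descriptive_stats <- function(tm) {
  grp <- paste(tm$rows$community, tm$rows$time_index, sep = "\r")
  out <- list()
  for (k in seq_len(ncol(tm$F))) {
    v <- tm$F[, k]
    sp <- split(v, grp)
    lab <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
    out[[k]] <- data.frame(
      community = lab[, 1],
      time_index = as.integer(lab[, 2]),
      trait = tm$states$trait[k],
      state = tm$states$state[k],
      n = lengths(sp),
      mean = vapply(sp, mean, 0),
      sd = vapply(sp, stats::sd, 0),
      min = vapply(sp, min, 0),
      max = vapply(sp, max, 0),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$community, res$trait, res$state, res$time_index), ]
  rownames(res) <- NULL
  res
}
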