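# Stage 4: per-trait-state linear mixed-effects trend models.
#
# Fixed-effect candidates: soil temperature (T), soil relative humidity (H),
# canopy height (can), time (quantitative), and topographic position (top,
# whole-dataset models only). Random structure as specified for the design:
# random intercepts for topographic position and plot, by-plot random slopes
# for time and topographic position — with an automatic simplification
# ladder for structures the data cannot identify (a by-plot slope for a
# plot-constant factor is always singular). All fits use ML (not REML) so
# likelihood-ratio tests across fixed-effect structures are valid.

fixed_candidates <- function(scope) {
  if (scope == "whole") c("T", "H", "can", "time", "top")
  else c("T", "H", "can", "time")
}

random_ladder <- function(scope) {
  if (scope == "whole") {
    c("(1 | top) + (1 + time + top | plot_id)",
      "(1 | top) + (1 + time | plot_id)",
      "(1 | top) + (1 | plot_id)",
      "(1 | plot_id)")
  } else {
    c("(1 + time | plot_id)",
      "(1 | plot_id)")
  }
}

#' Assemble per-releve model data
#'
#' One row per releve: plot, topographic position (`top`), quantitative
#' `time`, environmental covariates `T`, `H`, `can`, and one response column
#' per trait state (syntactic names from the matrix columns).
#'
#' @param tm A [build_trait_matrix()] result.
#' @param study The source `flowering_study`.
#' @return Data frame; the attribute `response_columns` maps trait-state
#'   columns of `tm` to their (syntactic) column names here.
#' @export
assemble_model_data <- function(tm, study) {
  rows <- tm$rows
  ekey <- paste(study$env$plot_id, study$env$time_index)
  idx <- match(paste(rows$plot_id, rows$time_index), ekey)
  if (anyNA(idx)) {
    tb_error("tb_integrity_error", "releves without environmental records")
  }
  dat <- data.frame(
    plot_id = factor(rows$plot_id),
    top = factor(rows$community),
    time = as.numeric(rows$time_index),
    T = study$env$soil_temperature[idx],
    H = study$env$soil_relative_humidity[idx],
    can = study$env$canopy_height[idx],
    stringsAsFactors = FALSE
  )
  resp <- make.names(colnames(tm$F))
  resp <- make.unique(resp)
  for (k in seq_along(resp)) dat[[resp[k]]] <- tm$F[, k]
  attr(dat, "response_columns") <- stats::setNames(resp, colnames(tm$F))
  dat
}

fit_one_lmm <- function(response, fixed_terms, random_formula, data) {
  rhs <- paste(c(if (length(fixed_terms) > 0) fixed_terms else "1",
                 random_formula), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  withCallingHandlers(
    lme4::lmer(fml, data = data, REML = FALSE,
               control = lme4::lmerControl(
                 optimizer = "bobyqa",
                 check.conv.singular = "ignore",
                 calc.derivs = FALSE
               )),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' Fit a linear mixed-effects trend model
#'
#' Maximum-likelihood fit (REML off) of one trait-state response on the
#' requested fixed effects, with the design's random structure. If the full
#' random structure is singular or fails, a simplification ladder is walked
#' (drop the by-plot slope for topographic position, then the by-plot time
#' slope, then the topographic intercept; the plot intercept is dropped
#' last never) and the structure actually used is recorded.
#'
#' @param response Response column name in `data`.
#' @param data Output of [assemble_model_data()] (or a scope subset of it).
#' @param fixed_terms Character vector of fixed effects (subset of
#'   `T`, `H`, `can`, `time`, `top`); may be empty for the null model.
#' @param scope `"whole"` or a single-community scope (`"south"`,
#'   `"north"`, `"flat"`); governs the random-structure ladder and whether
#'   `top` is admissible.
#' @param random_formula Override the ladder with a fixed random-effects
#'   formula (used to hold the structure constant across LRT comparisons).
#' @return List of class `tb_lmm`: `fit` (the lmer object), `logLik`,
#'   `BIC`, `df`, `fixed_terms`, `random_formula`, `singular`,
#'   `simplified`.
#' @export
fit_lmm <- function(response, data, fixed_terms, scope = "whole",
                    random_formula = NULL) {
  if (scope != "whole" && "top" %in% fixed_terms) {
    tb_error("tb_config_error",
             "topographic position enters whole-dataset models only")
  }
  y <- data[[response]]
  if (is.null(y)) tb_error("tb_lookup_error",
                           sprintf("no response column '%s'", response))
  if (stats::sd(y) == 0) {
    tb_error("tb_degenerate_error",
             sprintf("response '%s' is constant; model not fitted", response))
  }
  ladder <- if (is.null(random_formula)) random_ladder(scope)
            else random_formula
  simplified <- FALSE
  fit <- NULL
  used <- NULL
  for (rf in ladder) {
    cand <- tryCatch(fit_one_lmm(response, fixed_terms, rf, data),
                     error = function(e) NULL)
    if (!is.null(cand) && !lme4::isSingular(cand, tol = 1e-4)) {
      fit <- cand
      used <- rf
      break
    }
    if (is.null(fit) && !is.null(cand)) {
      fit <- cand  # keep the first fit that at least converged
      used <- rf
    }
    simplified <- TRUE
  }
  if (is.null(fit)) {
    tb_error("tb_fit_error",
             sprintf("no random structure converged for '%s'", response))
  }
  singular <- lme4::isSingular(fit, tol = 1e-4)
  ll <- stats::logLik(fit)
  structure(list(
    fit = fit,
    logLik = as.numeric(ll),
    df = attr(ll, "df"),
    BIC = stats::BIC(fit),
    fixed_terms = fixed_terms,
    random_formula = used,
    response = response,
    scope = scope,
    singular = singular,
    simplified = simplified && used != ladder[1]
  ), class = "tb_lmm")
}

#' Likelihood-ratio test between nested ML fits
#'
#' @param full,null `tb_lmm` fits on identical rows, `null` nested in
#'   `full` (same random structure, fixed effects a subset).
#' @return List with `statistic` (`2 * (logLik_full - logLik_null)`), `df`
#'   (parameter difference) and `p_value` from the chi-squared reference.
#' @export
lrt <- function(full, null) {
  if (!all(null$fixed_terms %in% full$fixed_terms) ||
      null$random_formula != full$random_formula) {
    tb_error("tb_config_error", "models are not nested")
  }
  stat <- max(0, 2 * (full$logLik - null$logLik))
  df <- full$df - null$df
  p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  list(statistic = stat, df = df, p_value = p)
}

#' Backward elimination of fixed effects by likelihood-ratio tests
#'
#' Starting from the full candidate set, iteratively refits the model
#' without each remaining fixed effect, and drops the effect whose removal
#' gives the largest LRT p-value, provided that p >= `alpha`; stops when
#' every remaining removal is significant (p < `alpha`) or no terms remain.
#' The random structure is chosen once on the full model and held fixed.
#'
#' @inheritParams fit_lmm
#' @param candidates Fixed-effect candidates (default all admissible for
#'   the scope).
#' @param alpha Retention threshold (default 0.05).
#' @return List with `retained` (character vector), `final` (`tb_lmm` of
#'   the reduced model), `null` (`tb_lmm` with random effects only),
#'   `lrt_full_null` (final-vs-null test), `random_formula`, and `trace`
#'   (data frame of elimination steps).
#' @export
backward_eliminate <- function(response, data, scope = "whole",
                               candidates = NULL, alpha = 0.05) {
  if (is.null(candidates)) candidates <- fixed_candidates(scope)
  full0 <- fit_lmm(response, data, candidates, scope = scope)
  rf <- full0$random_formula
  current <- candidates
  cur_fit <- full0
  trace <- list()
  repeat {
    if (length(current) == 0) break
    drops <- lapply(current, function(tm) {
      red <- fit_lmm(response, data, setdiff(current, tm), scope = scope,
                     random_formula = rf)
      list(term = tm, fit = red, test = lrt(cur_fit, red))
    })
    ps <- vapply(drops, function(d) d$test$p_value, 0)
    i <- which.max(ps)
    if (ps[i] < alpha) break
    trace[[length(trace) + 1L]] <- data.frame(
      dropped = drops[[i]]$term, p_value = ps[i],
      stringsAsFactors = FALSE
    )
    current <- setdiff(current, drops[[i]]$term)
    cur_fit <- drops[[i]]$fit
  }
  null_fit <- fit_lmm(response, data, character(0), scope = scope,
                      random_formula = rf)
  list(
    retained = current,
    final = cur_fit,
    null = null_fit,
    lrt_full_null = lrt(cur_fit, null_fit),
    random_formula = rf,
    trace = if (length(trace) > 0) do.call(rbind, trace)
            else data.frame(dropped = character(), p_value = numeric())
  )
}

significance_class <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "n.s.")))
}

#' Fit trend models for every trait state and dataset scope
#'
#' Four models per trait state: the whole data set (scope `W`, with
#' topographic position among the candidates) and the three
#' single-community subsets (`S`, `N`, `F`), each reduced by backward
#' elimination and compared with the random-effects-only null model.
#' Per-model failures (degenerate responses, non-convergence) are recorded
#' as notes and the run continues.
#'
#' @param tm A [build_trait_matrix()] result.
#' @param study The source `flowering_study`.
#' @param states Optional data frame (`trait`, `state`) restricting the
#'   responses.
#' @param alpha Elimination threshold (default 0.05).
#' @return Data frame with one row per trait state x scope: retained model
#'   formula, BIC and logLik of the reduced (full) and null models, the
#'   full-vs-null LRT p-value, its significance class, the random structure
#'   used, and a `note` for skipped fits.
#' @export
run_all_models <- function(tm, study, states = NULL, alpha = 0.05) {
  dat <- assemble_model_data(tm, study)
  resp_map <- attr(dat, "response_columns")
  st_tab <- tm$states
  if (!is.null(states)) {
    keep <- paste(st_tab$trait, st_tab$state) %in%
      paste(states$trait, states$state)
    st_tab <- st_tab[keep, , drop = FALSE]
  }
  comms <- levels(dat$top)
  scopes <- c(stats::setNames("whole", "W"),
              stats::setNames(comms, toupper(substr(comms, 1, 1))))
  out <- list()
  for (k in seq_len(nrow(st_tab))) {
    col <- st_tab$column[k]
    resp <- resp_map[[col]]
    for (sc in names(scopes)) {
      scope <- scopes[[sc]]
      sub <- if (scope == "whole") dat else droplevels(
        dat[dat$top == scope, , drop = FALSE])
      row <- data.frame(
        trait = st_tab$trait[k], state = st_tab$state[k], scope = sc,
        model = NA_character_, bic_full = NA_real_, bic_null = NA_real_,
        loglik_full = NA_real_, loglik_null = NA_real_, p = NA_real_,
        signif = NA_character_, random = NA_character_, note = "",
        stringsAsFactors = FALSE
      )
      res <- tryCatch(
        backward_eliminate(resp, sub, scope = scope, alpha = alpha),
        tb_error = function(e) e, error = function(e) e
      )
      if (inherits(res, "condition")) {
        row$note <- conditionMessage(res)
      } else {
        row$model <- if (length(res$retained) > 0)
          paste(res$retained, collapse = " + ") else "(none)"
        row$bic_full <- res$final$BIC
        row$bic_null <- res$null$BIC
        row$loglik_full <- res$final$logLik
        row$loglik_null <- res$null$logLik
        row$p <- res$lrt_full_null$p_value
        row$signif <- significance_class(res$lrt_full_null$p_value)
        row$random <- res$random_formula
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
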