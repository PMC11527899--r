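# Mixed-effects inference on the HDR summary: backward elimination over
# position, timing, hemisphere and their two-way interactions, with a
# participant random intercept, followed by Tukey position contrasts.

model_terms_default <- function() {
  c("position", "timing", "hemisphere",
    "position:timing", "position:hemisphere", "timing:hemisphere")
}

prepare_model_data <- function(data) {
  data <- tibble::as_tibble(data)
  if ("timing" %in% names(data)) {
    data <- dplyr::filter(data, .data$timing %in% c("first", "last"))
  }
  for (v in intersect(c("participant", "position", "timing", "hemisphere"),
                      names(data))) {
    data[[v]] <- factor(data[[v]])
  }
  if (!"oxyhb" %in% names(data)) {
    stop("Model data needs an `oxyhb` response column.", call. = FALSE)
  }
  data
}

build_formula <- function(terms) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  stats::as.formula(paste("oxyhb ~", rhs, "+ (1 | participant)"))
}

term_factors <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# a term may be removed only if no retained higher-order term contains it
removable_terms <- function(terms) {
  vapply(terms, function(tm) {
    f <- term_factors(tm)
    !any(vapply(terms, function(other) {
      o <- term_factors(other)
      length(o) > length(f) && all(f %in% o)
    }, logical(1)))
  }, logical(1))
}

#' Fit the random-intercept linear mixed model
#'
#' REML fit of the HDR response on the given fixed-effect terms with a
#' participant random intercept, via `lmerTest::lmer` so that fixed-effect
#' tests use Satterthwaite degrees of freedom. Factors are coded with
#' sum-to-zero contrasts so that type-III term tests are meaningful in the
#' presence of interactions.
#'
#' @param data HDR summary tibble with `oxyhb`, `participant` and the factor
#'   columns named in `terms`. Rows with `timing == "all"` are excluded (the
#'   model's timing factor is first/last).
#' @param terms Character vector of fixed-effect terms (default: the three
#'   main effects and their two-way interactions).
#'
#' @return An `lmerModLmerTest` fit.
#' @export
fit_hdr_model <- function(data, terms = model_terms_default()) {
  data <- prepare_model_data(data)
  if (length(levels(data$participant)) < 2) {
    stop("Need at least 2 participants.", call. = FALSE)
  }
  facs <- intersect(unique(unlist(lapply(terms, term_factors))), names(data))
  if (length(facs) == 0) {
    return(lmerTest::lmer(build_formula(terms), data = data))
  }
  contr <- stats::setNames(as.list(rep("contr.sum", length(facs))), facs)
  lmerTest::lmer(build_formula(terms), data = data, contrasts = contr)
}

#' Backward elimination over the fixed-effect terms
#'
#' Starting from the full model (three main effects plus two-way
#' interactions), repeatedly removes the least significant removable term --
#' the removable term with the largest type-III p-value above `alpha`, where
#' a main effect is removable only after every interaction containing it has
#' been removed -- refitting after each removal, until every retained term is
#' significant at `alpha` or only the intercept remains. Only the final
#' (best-fitting) model is reported, along with the elimination path.
#'
#' @param data HDR summary tibble (see [fit_hdr_model()]).
#' @param alpha Significance level for retention (default 0.05).
#' @param terms Candidate fixed-effect terms.
#'
#' @return An `hdr_model` object: `fit` (final mixed model), `retained`,
#'   `path` (tibble of eliminated terms and their p-values), `anova` (final
#'   type-III table, if any terms remain), `alpha`, `data`, and
#'   `df_method = "Satterthwaite"`.
#' @export
backward_eliminate <- function(data, alpha = 0.05,
                               terms = model_terms_default()) {
  data <- prepare_model_data(data)
  current <- terms
  path <- list()
  fit <- fit_hdr_model(data, current)
  repeat {
    if (length(current) == 0) break
    at <- suppressMessages(stats::anova(fit, type = 3))
    pvals <- stats::setNames(at[["Pr(>F)"]], rownames(at))
    rem <- current[removable_terms(current)]
    rem_p <- pvals[rem]
    worst <- which.max(rem_p)
    if (length(worst) == 0 || rem_p[worst] <= alpha) break
    dropped <- rem[worst]
    path[[length(path) + 1]] <- tibble::tibble(
      step = length(path) + 1L, dropped = dropped,
      p_value = unname(rem_p[worst])
    )
    current <- setdiff(current, dropped)
    fit <- fit_hdr_model(data, current)
  }
  final_anova <- if (length(current) > 0) {
    suppressMessages(stats::anova(fit, type = 3))
  } else NULL
  structure(
    list(
      fit = fit,
      retained = current,
      path = if (length(path)) dplyr::bind_rows(path) else
        tibble::tibble(step = integer(), dropped = character(),
                       p_value = numeric()),
      anova = final_anova,
      coefficients = tibble::as_tibble(summary(fit)$coefficients,
                                       rownames = "term"),
      alpha = alpha,
      data = data,
      df_method = "Satterthwaite"
    ),
    class = "hdr_model"
  )
}

#' @export
print.hdr_model <- function(x, ...) {
  cat("<hdr_model> backward-elimination mixed model\n")
  cat("  retained terms:",
      if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(intercept only)", "\n")
  if (nrow(x$path) > 0) {
    cat("  eliminated:",
        paste(sprintf("%s (p=%.3f)", x$path$dropped, x$path$p_value),
              collapse = ", "), "\n")
  }
  if (!is.null(x$anova)) {
    cat("  final type-III tests (Satterthwaite df):\n")
    print(x$anova)
  }
  invisible(x)
}

#' Tukey-adjusted pairwise contrasts of a retained factor
#'
#' Estimated marginal means of the factor's levels (averaged over the other
#' retained factors on a balanced grid) and all pairwise differences with
#' studentized-range (Tukey) family-wise adjustment, via `emmeans`.
#'
#' @param model An `hdr_model` from [backward_eliminate()], or an `lmer` fit.
#' @param factor Factor to contrast (default `"position"`). For an
#'   `hdr_model` the factor must have been retained.
#'
#' @return List with `emmeans` (tibble of level, emmean, SE, df, CI) and
#'   `contrasts` (tibble of pair, estimate, SE, df, t, adjusted p).
#' @export
tukey_contrasts <- function(model, factor = "position") {
  if (inherits(model, "hdr_model")) {
    retained_mains <- model$retained[!grepl(":", model$retained, fixed = TRUE)]
    in_interactions <- unique(unlist(lapply(
      model$retained[grepl(":", model$retained, fixed = TRUE)], term_factors)))
    if (!factor %in% c(retained_mains, in_interactions)) {
      stop(sprintf(
        "`%s` was not retained by backward elimination; no contrasts computed.",
        factor), call. = FALSE)
    }
    fit <- model$fit
  } else {
    fit <- model
  }
  emm <- emmeans::emmeans(fit, specs = factor, lmer.df = "satterthwaite")
  prs <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  list(
    emmeans = tibble::as_tibble(as.data.frame(emm)),
    contrasts = tibble::as_tibble(as.data.frame(summary(prs)))
  )
}
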