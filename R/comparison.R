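#' Theoretical scaling-model predictions
#'
#' Exponents predicted by the three closed-form scaling models for each
#' trait: Metabolic Scaling Theory (MST: 2/3, 8/3, 8/3, 2), Stress
#' Similarity (STRESS: 1/2, 5/2, undefined, undefined) and Geometric
#' Similarity (GEOM: 1, 3, 3, 2), in the order length, aboveground mass,
#' stem mass, leaf mass. Predictions are exact rationals held at full
#' double precision.
#'
#' @return A 3 x 4 numeric matrix (models x traits), `NA` where a model
#'   makes no prediction.
#' @export
scaling_model_predictions <- function() {
  m <- rbind(
    MST = c(2 / 3, 8 / 3, 8 / 3, 2),
    GEOM = c(1, 3, 3, 2),
    STRESS = c(1 / 2, 5 / 2, NA, NA)
  )
  colnames(m) <- TRAITS
  m
}

#' Look up one theoretical exponent
#'
#' @param model `"MST"`, `"GEOM"` or `"STRESS"`.
#' @param trait One of [allom_traits()].
#' @return The predicted exponent, or `NA` where the model makes no
#'   prediction (STRESS for stem and leaf mass).
#' @export
#' @examples
#' theoretical_exponent("MST", "length")   # 2/3
#' theoretical_exponent("STRESS", "leaf_mass")  # NA
theoretical_exponent <- function(model, trait) {
  preds <- scaling_model_predictions()
  if (!model %in% rownames(preds)) {
    stop("unknown model '", model, "'", call. = FALSE)
  }
  if (!trait %in% colnames(preds)) {
    stop("unknown trait '", trait, "'", call. = FALSE)
  }
  preds[model, trait]
}

#' Credible-interval inclusion table
#'
#' One row per (trait, unit) where units are every tree, every species and
#' the global level; a theoretical model's prediction is "included" when it
#' lies inside the unit's equal-tailed 95% credible interval
#' (lower <= prediction <= upper). Flags are `NA` where the model makes no
#' prediction.
#'
#' @param summaries A `data.frame` of exponent summaries with columns
#'   trait, level, unit, lower, upper (e.g. from the internal
#'   `exponent_summaries()`, or assembled by hand).
#' @param models Character vector of model names (default all three).
#' @return The `summaries` table with one logical inclusion column per
#'   model (`included_MST`, ...).
#' @export
ci_inclusion_table <- function(summaries,
                               models = rownames(scaling_model_predictions())) {
  stopifnot(all(c("trait", "level", "unit", "lower", "upper") %in%
                  names(summaries)))
  missing_lv <- setdiff(c("tree", "species", "global"), summaries$level)
  if (length(missing_lv)) {
    stop("summaries are missing hierarchical level(s): ",
         paste(missing_lv, collapse = ", "), call. = FALSE)
  }
  preds <- scaling_model_predictions()
  out <- summaries
  for (m in models) {
    p <- preds[m, out$trait]
    out[[paste0("included_", m)]] <-
      ifelse(is.na(p), NA, out$lower <= p & p <= out$upper)
  }
  out
}

#' Inclusion percentages and best model
#'
#' For each theoretical model, the percentage of credible intervals (over
#' all traits and hierarchical levels) that include its prediction, the
#' percentage restricted to the two relationships all three models predict
#' (length and aboveground mass), and the best-supported model(s) — the
#' argmax of the overall percentage, reported as a set when tied. Cells
#' where a model makes no prediction are excluded from its denominator.
#'
#' @param inclusion A table from [ci_inclusion_table()].
#' @return A list with `percentages` (data.frame: model, included,
#'   n_defined, pct_overall, pct_length_agmass) and `best` (character
#'   vector).
#' @export
inclusion_percentage_and_best <- function(inclusion) {
  stopifnot(nrow(inclusion) > 0)
  models <- sub("^included_", "",
                grep("^included_", names(inclusion), value = TRUE))
  rows <- lapply(models, function(m) {
    f <- inclusion[[paste0("included_", m)]]
    def <- !is.na(f)
    sub <- inclusion$trait %in% c("length", "ag_mass") & def
    data.frame(
      model = m,
      included = sum(f[def]),
      n_defined = sum(def),
      pct_overall = 100 * sum(f[def]) / sum(def),
      pct_length_agmass = 100 * sum(f[sub]) / sum(sub),
      stringsAsFactors = FALSE
    )
  })
  pct <- do.call(rbind, rows)
  best <- pct$model[pct$pct_overall == max(pct$pct_overall)]
  list(percentages = pct, best = best)
}

#' Posterior probability that one species' exponent exceeds another's
#'
#' Fraction of pooled posterior draws for which the trait's scaling
#' exponent of `species_a` exceeds that of `species_b` (the posterior of
#' the exponent difference evaluated at zero).
#'
#' @param fit An `allom_hb` fit (or `allom_samples`).
#' @param trait One of [allom_traits()].
#' @param species_a,species_b Species ids.
#' @return Probability in [0, 1].
#' @export
contrast_probability <- function(fit, trait, species_a, species_b) {
  samples <- as_allom_samples(fit)
  trait <- match.arg(trait, TRAITS)
  for (s in c(species_a, species_b)) {
    if (!s %in% samples$species_ids) {
      stop("unknown species '", s, "'", call. = FALSE)
    }
  }
  d <- pooled_draws(samples, sprintf("b_sp[%s,%s]", species_a, trait)) -
    pooled_draws(samples, sprintf("b_sp[%s,%s]", species_b, trait))
  mean(d > 0)
}

#' Score the theoretical scaling models against a fit
#'
#' Builds the full credible-interval inclusion table (every tree, species
#' and the global level, for every trait), the per-model inclusion
#' percentages, the best-supported model(s), and all pairwise species
#' contrast probabilities per trait.
#'
#' @param fit An `allom_hb` fit.
#' @return An object of class `allom_comparison` with elements `inclusion`
#'   (the flagged CI table), `percentages`, `best` and `contrasts`.
#' @export
compare_scaling_models <- function(fit) {
  stopifnot(inherits(fit, "allom_hb"))
  summaries <- exponent_summaries(fit)
  inclusion <- ci_inclusion_table(summaries)
  scores <- inclusion_percentage_and_best(inclusion)
  sp <- fit$samples$species_ids
  contrasts <- NULL
  if (length(sp) >= 2) {
    pairs <- utils::combn(sp, 2)
    contrasts <- do.call(rbind, lapply(TRAITS, function(k) {
      data.frame(
        trait = k,
        species_a = pairs[1, ],
        species_b = pairs[2, ],
        prob_a_gt_b = vapply(seq_len(ncol(pairs)), function(j) {
          contrast_probability(fit, k, pairs[1, j], pairs[2, j])
        }, numeric(1)),
        stringsAsFactors = FALSE
      )
    }))
  }
  structure(
    list(inclusion = inclusion, percentages = scores$percentages,
         best = scores$best, contrasts = contrasts),
    class = "allom_comparison"
  )
}

#' @export
print.allom_comparison <- function(x, ...) {
  cat("Scaling-model comparison by 95% CI inclusion\n")
  cat("  CI rows per trait:",
      sum(x$inclusion$trait == x$inclusion$trait[1]), "\n\n")
  print(x$percentages, row.names = FALSE, digits = 3)
  cat("\nBest-supported model(s):", paste(x$best, collapse = ", "), "\n")
  if (!is.null(x$contrasts)) {
    cat("\nSpecies contrasts, P(b_a > b_b):\n")
    print(x$contrasts, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
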