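# Centrifugal water-fractionation analysis: per-force percentage weight
# loss, relative water content before and after spinning, and
# branch-removal contrasts on recovered water.

#' Centrifugation mass-balance record for one plant
#'
#' One plant's ledger across a schedule of centrifugal forces: its fully
#' saturated weight, the mass of water released at each force, its
#' oven-dry weight, and optionally an independently measured post-spin
#' weight.
#'
#' @param plant_id,species Identifiers.
#' @param treatment One of `"intact"`, `"no_pendent"`, `"no_spreading"`,
#'   `"no_branches"` (which branch types were dissected away before the
#'   run).
#' @param saturated_weight Weight before the first centrifugation (g).
#' @param forces Strictly increasing centrifugal forces (g-units).
#' @param released Water mass released at each force (g), same length as
#'   `forces`.
#' @param dry_weight Oven-dry weight (g, > 0).
#' @param post_spin_weight Optional measured weight after the final
#'   centrifugation (g); when absent it is derived as
#'   `saturated_weight - sum(released)`.
#' @return An object of class `centrifuge_record`.
#' @export
centrifuge_record <- function(plant_id, species, treatment = "intact",
                              saturated_weight, forces, released,
                              dry_weight, post_spin_weight = NULL) {
  treatment <- match.arg(treatment,
    c("intact", "no_pendent", "no_spreading", "no_branches"))
  if (is.null(saturated_weight) || is.na(saturated_weight))
    stop("`saturated_weight` is required (g)")
  if (dry_weight <= 0) stop("`dry_weight` must be > 0 (g)")
  if (saturated_weight < dry_weight)
    stop("`saturated_weight` must be >= `dry_weight`")
  forces <- as.numeric(forces); released <- as.numeric(released)
  if (length(forces) != length(released))
    stop("`forces` and `released` must have the same length")
  if (is.unsorted(forces, strictly = TRUE))
    stop("`forces` must be strictly increasing")
  if (any(released < 0)) stop("released water masses must be >= 0 (g)")
  structure(
    list(plant_id = as.character(plant_id), species = as.character(species),
         treatment = treatment, saturated_weight = saturated_weight,
         forces = forces, released = setNames(released, forces),
         dry_weight = dry_weight, post_spin_weight = post_spin_weight),
    class = "centrifuge_record"
  )
}

#' @export
print.centrifuge_record <- function(x, ...) {
  cat(sprintf("<centrifuge_record> %s (%s, %s)\n", x$plant_id, x$species, x$treatment))
  cat(sprintf("  saturated %.4g g, dry %.4g g, released %s g at %s g-force\n",
              x$saturated_weight, x$dry_weight,
              paste(signif(x$released, 4), collapse = "/"),
              paste(x$forces, collapse = "/")))
  invisible(x)
}

#' Relative water content
#'
#' RWC = (wet weight - dry weight) / dry weight x 100, in percent. A
#' fully saturated Sphagnum plant can exceed 2000% (it holds over twenty
#' times its biomass in water).
#'
#' @param wet Wet weight (g), vectorised.
#' @param dry Dry weight (g), > 0.
#' @return RWC in percent. A wet weight below the dry weight yields a
#'   negative value with a warning (evaporative loss below dry mass is
#'   physically suspect).
#' @export
relative_water_content <- function(wet, dry) {
  if (any(dry <= 0)) stop("`dry` weight must be > 0 (g)")
  if (any(wet < 0)) stop("`wet` weight must be >= 0 (g)")
  if (any(wet < dry))
    warning("wet weight below dry weight: negative RWC (physically suspect)")
  (wet - dry) / dry * 100
}

#' Percentage weight loss per centrifugation interval
#'
#' The loss at each force is the water released in that interval as a
#' percentage of the initial (saturated) weight — the denominator is
#' always the weight before the first centrifugation, never the running
#' weight — so per-force losses add up to the cumulative loss.
#'
#' @param record A [centrifuge_record()].
#' @return An object of class `fractionation_summary`: per-force and
#'   cumulative percent loss (named by force), `rwc_before`, `rwc_after`,
#'   and `exchangeable_fraction` (total released water over total water).
#' @export
percent_weight_loss <- function(record) {
  stopifnot(inherits(record, "centrifuge_record"))
  per_force <- record$released / record$saturated_weight * 100
  cumulative <- cumsum(per_force)
  rwc <- rwc_before_after(record)
  total_water <- record$saturated_weight - record$dry_weight
  structure(
    list(plant_id = record$plant_id, species = record$species,
         treatment = record$treatment,
         percent_loss_per_force = per_force,
         cumulative_percent_loss = cumulative,
         rwc_before = rwc[["rwc_before"]], rwc_after = rwc[["rwc_after"]],
         exchangeable_fraction =
           if (total_water > 0) sum(record$released) / total_water else 0),
    class = "fractionation_summary"
  )
}

#' RWC before and after centrifugation
#'
#' Both values use the standard RWC formula (dry-weight denominator). The
#' post-spin weight is the measured `post_spin_weight` when present,
#' otherwise `saturated_weight - sum(released)`; if both exist and
#' disagree by more than 1% of the saturated weight the function fails
#' loudly rather than averaging (a transcription-error guard).
#'
#' @param record A [centrifuge_record()].
#' @param normalise `"dry_weight"` (the standard formula) or
#'   `"initial_weight"`, an alternative normalisation in which the water
#'   mass is expressed relative to the weight before centrifugation
#'   instead of the dry weight.
#' @return Named numeric vector `c(rwc_before =, rwc_after =)` in percent;
#'   `rwc_after <= rwc_before` always, with equality iff nothing was
#'   released.
#' @export
rwc_before_after <- function(record, normalise = c("dry_weight", "initial_weight")) {
  stopifnot(inherits(record, "centrifuge_record"))
  normalise <- match.arg(normalise)
  total_released <- sum(record$released)
  avail <- record$saturated_weight - record$dry_weight
  if (total_released > avail + 1e-9)
    stop(sprintf(
      "inconsistent ledger: released %.9g g exceeds available water %.9g g (tolerance 1e-9 g)",
      total_released, avail))
  derived_post <- record$saturated_weight - total_released
  post <- derived_post
  if (!is.null(record$post_spin_weight)) {
    if (abs(record$post_spin_weight - derived_post) >
        0.01 * record$saturated_weight)
      stop(sprintf(
        "measured post-spin weight %.4g g disagrees with ledger-derived %.4g g by more than 1%% of saturated weight",
        record$post_spin_weight, derived_post))
    post <- record$post_spin_weight
  }
  denom <- switch(normalise,
    dry_weight = record$dry_weight,
    initial_weight = record$saturated_weight)
  c(rwc_before = (record$saturated_weight - record$dry_weight) / denom * 100,
    rwc_after = (post - record$dry_weight) / denom * 100)
}

#' Branch contribution to recoverable water
#'
#' Compares the water recovered by centrifugation between intact plants
#' and branch-dissected plants of the same species. Recovered water is
#' totalled per plant (grams, and as percent of the initial weight); the
#' groups are compared with the [compare_groups()] normality-gated test,
#' and the effect (difference of group means, intact minus treated) gets a
#' seeded bootstrap percentile interval.
#'
#' @param intact,treated Lists of [centrifuge_record()]s (same species).
#' @param n_boot Bootstrap resamples for the effect interval (default
#'   10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return A list with `comparison` (a `group_comparison` on grams
#'   recovered), `effect_g`, `effect_ci_g`, `effect_pct`, and the
#'   per-group totals.
#' @export
branch_contribution <- function(intact, treated, n_boot = 10000, conf = 0.95,
                                seed = NULL) {
  if (!length(intact) || !length(treated))
    stop("both record collections must be non-empty")
  all_rec <- c(intact, treated)
  ok <- vapply(all_rec, inherits, logical(1), "centrifuge_record")
  if (!all(ok)) stop("inputs must be centrifuge_record objects")
  sp <- unique(vapply(all_rec, `[[`, character(1), "species"))
  if (length(sp) > 1)
    stop("mixed species in branch contrast: ", paste(sp, collapse = ", "))
  recovered_g <- function(r) sum(r$released)
  recovered_pct <- function(r) sum(r$released) / r$saturated_weight * 100
  gi <- vapply(intact, recovered_g, numeric(1))
  gt <- vapply(treated, recovered_g, numeric(1))
  pi_ <- vapply(intact, recovered_pct, numeric(1))
  pt <- vapply(treated, recovered_pct, numeric(1))
  cmp <- compare_groups(gi, gt,
                        ids_a = vapply(intact, `[[`, character(1), "plant_id"),
                        ids_b = vapply(treated, `[[`, character(1), "plant_id"))
  effect <- mean(gi) - mean(gt)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    mean(sample(gi, replace = TRUE)) - mean(sample(gt, replace = TRUE))
  }, numeric(1)))
  alpha <- 1 - conf
  list(
    species = sp, comparison = cmp,
    effect_g = effect,
    effect_ci_g = unname(quantile(boots, c(alpha / 2, 1 - alpha / 2))),
    effect_pct = mean(pi_) - mean(pt),
    recovered_intact_g = gi, recovered_treated_g = gt,
    n_boot = n_boot
  )
}

#' Correlation between dry weight and saturated RWC
#'
#' Pearson product-moment correlation between plant dry weight and
#' pre-centrifugation RWC across a collection of records. An absence of
#' correlation indicates that water storage scales with something other
#' than biomass (i.e. is held extracellularly).
#'
#' @param records List of [centrifuge_record()]s (n >= 3).
#' @return List with `pearson_r`, `r_squared`, `p_value`, `n`.
#' @export
dryweight_rwc_correlation <- function(records) {
  if (length(records) < 3L) stop("need at least 3 records")
  dw <- vapply(records, `[[`, numeric(1), "dry_weight")
  rwc <- vapply(records, function(r) rwc_before_after(r)[["rwc_before"]], numeric(1))
  if (sd(dw) == 0 || sd(rwc) == 0)
    stop("zero variance in dry weight or RWC: correlation undefined")
  ct <- cor.test(dw, rwc, method = "pearson")
  list(pearson_r = unname(ct$estimate),
       r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(records))
}
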