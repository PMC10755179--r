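#' Simulation configuration
#'
#' Collects every tunable of the serial-passage simulator. The defaults are
#' the conditions of the experimental design this package models: 24 replicate
#' lines founded from one clonal isolate, 31 passages each started from one
#' million thoroughly mixed spores, bulk population sequencing at ~195x and
#' clonal sequencing at ~54x mapped depth.
#'
#' @param n_lines number of replicate evolved lines.
#' @param n_passages number of serial passages (one selection + founder
#'   resampling step per passage).
#' @param founder_count spores replated at each passage.
#' @param mutation_rate expected new selected mutations per line per passage.
#' @param selection_coeff per-passage relative advantage `s` of selected
#'   mutations (classes `5prime`, `3prime`, `other`); neutral mutations have
#'   `s = 0`.
#' @param init_freq frequency at which a new mutation enters the founder pool
#'   of the passage after it arises. The default 1e-4 reflects clonal
#'   expansion over the ~9 generations of vegetative growth within a passage,
#'   so a new mutant is typically present in ~100 of the million founders
#'   rather than as a single spore.
#' @param penetrance_nonfruiting probability that a clone carrying at least
#'   one `5prime`-class mutation is non-fruiting.
#' @param depth_population,depth_clone mean mapped depth for population and
#'   clone samples.
#' @param error_rate per-base sequencing error rate (a read shows a wrong
#'   base with this probability, uniformly over the three other bases).
#' @param ancestral_poly_sites number of sites polymorphic (or miscalled) in
#'   the ancestor, split evenly across the three masking classes
#'   (`ancestor_variant`, `ancestor_uncalled`, `ancestor_maf`).
#' @param ancestor_maf_range range from which the ancestor major allele
#'   frequency at `ancestor_maf` polymorphic sites is drawn (below 0.90 so
#'   the mask must catch them).
#' @param fp_sites number of injected caller false positives, cycled over
#'   `fp_classes`.
#' @param fp_classes character vector of failure classes to inject; see
#'   [emulate_callers()].
#' @param callable_min_reads,callable_min_frac emulation thresholds: a sample
#'   is called alternate when it has at least `callable_min_reads` alternate
#'   reads making up at least `callable_min_frac` of its depth.
#' @param class_probs named probabilities over mutation classes
#'   `c(5prime, 3prime, other, neutral)`.
#' @param seed master seed; all stage substreams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 24L,
                       n_passages = 31L,
                       founder_count = 1e6,
                       mutation_rate = 0.1,
                       selection_coeff = 0.6,
                       init_freq = 1e-4,
                       penetrance_nonfruiting = 1.0,
                       depth_population = 195,
                       depth_clone = 54,
                       error_rate = 1e-3,
                       ancestral_poly_sites = 30L,
                       ancestor_maf_range = c(0.55, 0.89),
                       fp_sites = 11L,
                       fp_classes = c("low_qd", "low_mqm", "strand_bias",
                                      "low_qual", "excess_dp", "missingness",
                                      "high_ac", "caller_a_only",
                                      "caller_b_only", "low_origin_support",
                                      "cross_line_support"),
                       callable_min_reads = 3L,
                       callable_min_frac = 0.05,
                       class_probs = c("5prime" = 0.35, "3prime" = 0.35,
                                       "other" = 0.15, "neutral" = 0.15),
                       seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), n_passages = as.integer(n_passages),
              founder_count = founder_count, mutation_rate = mutation_rate,
              selection_coeff = selection_coeff, init_freq = init_freq,
              penetrance_nonfruiting = penetrance_nonfruiting,
              depth_population = depth_population, depth_clone = depth_clone,
              error_rate = error_rate,
              ancestral_poly_sites = as.integer(ancestral_poly_sites),
              ancestor_maf_range = ancestor_maf_range,
              fp_sites = as.integer(fp_sites), fp_classes = fp_classes,
              callable_min_reads = as.integer(callable_min_reads),
              callable_min_frac = callable_min_frac,
              class_probs = class_probs, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_lines >= 1, cfg$n_passages >= 1, cfg$founder_count >= 1,
    cfg$mutation_rate >= 0,
    cfg$selection_coeff >= 0,
    cfg$init_freq > 0, cfg$init_freq <= 1,
    cfg$penetrance_nonfruiting >= 0, cfg$penetrance_nonfruiting <= 1,
    cfg$depth_population > 0, cfg$depth_clone > 0,
    cfg$error_rate >= 0, cfg$error_rate < 1,
    cfg$ancestral_poly_sites >= 0, cfg$fp_sites >= 0,
    length(cfg$ancestor_maf_range) == 2,
    all(cfg$ancestor_maf_range > 0.5), all(cfg$ancestor_maf_range < 1),
    abs(sum(cfg$class_probs) - 1) < 1e-8
  )
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' Flat keys matching the arguments of [sim_config()]; unknown keys are an
#' error so that typos in a config file do not silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$class_probs)) raw$class_probs <- unlist(raw$class_probs)
  do.call(sim_config, raw)
}
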