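# Model/parameter constructors shared across the simulation, network and
# dating stages.

#' Standard 17-locus Y-STR panel
#'
#' Locus names of the common 17-plex Y-STR typing panel. `DYS385a` and
#' `DYS385b` are duplicated loci with ambiguous allele assignment and are
#' excluded from distance-based analyses by default.
#'
#' @return character vector of 17 locus names.
#' @export
ystr_panel_17 <- function() {
  c("DYS456", "DYS389I", "DYS390", "DYS389II", "DYS458", "DYS19",
    "DYS385a", "DYS385b", "DYS393", "DYS391", "DYS439", "DYS635",
    "DYS392", "GATA-H4", "DYS437", "DYS438", "DYS448")
}

#' Default excluded Y-STR loci
#' @return character vector.
#' @export
ystr_excluded_default <- function() c("DYS385a", "DYS385b")

#' 15-locus Y-STR panel (17-plex minus DYS385a/b)
#' @return character vector of 15 locus names.
#' @export
ystr_panel_15 <- function() setdiff(ystr_panel_17(), ystr_excluded_default())

#' Stepwise mutation model for Y-STR loci
#'
#' Defines the symmetric single-step stepwise mutation model (SMM): at each
#' mutation event a locus gains or loses exactly one repeat unit with equal
#' probability. Mutation counts per lineage of length T generations are
#' Poisson(mu * T) per locus, independently across loci.
#'
#' @param loci character vector of locus names.
#' @param mu_per_locus_per_gen positive mutation rate per locus per
#'   generation (default `6.9e-4`, the evolutionary Y-STR calibration per
#'   25-year generation).
#' @param ancestral_alleles named integer vector of ancestral repeat counts,
#'   one per locus (default 14 repeats everywhere, a typical modal Y-STR
#'   allele). All counts must be >= 1.
#' @return an object of class `str_model`.
#' @export
str_model <- function(loci = ystr_panel_15(),
                      mu_per_locus_per_gen = 6.9e-4,
                      ancestral_alleles = NULL) {
  stopifnot_positive(mu_per_locus_per_gen, "mu_per_locus_per_gen")
  if (!is.character(loci) || length(loci) < 1L || anyDuplicated(loci)) {
    stop("`loci` must be a non-empty character vector without duplicates")
  }
  if (is.null(ancestral_alleles)) {
    ancestral_alleles <- stats::setNames(rep(14L, length(loci)), loci)
  }
  if (is.null(names(ancestral_alleles)) ||
      !setequal(names(ancestral_alleles), loci)) {
    stop("`ancestral_alleles` must be named by every locus in `loci`")
  }
  ancestral_alleles <- ancestral_alleles[loci]
  if (any(ancestral_alleles < 1)) stop("ancestral alleles must be >= 1")
  structure(
    list(loci = loci,
         mu_per_locus_per_gen = mu_per_locus_per_gen,
         ancestral_alleles = as.integer(ancestral_alleles)),
    class = "str_model"
  )
}

#' Genealogy specification for the simulators
#'
#' @param topology `"star"` (all samples coalesce in a single founder
#'   `age_generations` ago) or `"two_level_hierarchy"` (populations nested
#'   in groups).
#' @param n_samples number of sampled chromosomes (>= 2).
#' @param age_generations total genealogy age T in generations (> 0).
#' @param group_sizes for `two_level_hierarchy`: a named list/vector
#'   structure, `list(group = c(pop1 = n1, pop2 = n2), ...)`, i.e. one named
#'   integer vector of population sizes per group; sizes must sum to
#'   `n_samples`.
#' @param divergence_generations for `two_level_hierarchy`: numeric length 2
#'   `c(among_groups, among_populations)` giving the shared drift time (in
#'   generations) accumulated along the group-ancestor and
#'   population-ancestor branches. The residual
#'   `age_generations - sum(divergence_generations)` is the star depth of
#'   samples within each population; the sum must not exceed
#'   `age_generations`. Both zero gives fully exchangeable haplotypes.
#' @param seed integer random seed; all simulators are deterministic given
#'   this seed.
#' @return an object of class `genealogy_spec`.
#' @export
genealogy_spec <- function(topology = c("star", "two_level_hierarchy"),
                           n_samples,
                           age_generations,
                           group_sizes = NULL,
                           divergence_generations = NULL,
                           seed = 1L) {
  topology <- match.arg(topology)
  if (!is.numeric(n_samples) || n_samples < 2) {
    stop("`n_samples` must be >= 2")
  }
  if (!is.numeric(age_generations) || length(age_generations) != 1L ||
      is.na(age_generations) || age_generations < 0) {
    stop("`age_generations` must be a single non-negative number")
  }
  if (topology == "two_level_hierarchy") {
    if (is.null(group_sizes) || is.null(divergence_generations)) {
      stop("two_level_hierarchy requires `group_sizes` and `divergence_generations`")
    }
    if (!is.list(group_sizes) || is.null(names(group_sizes)) ||
        any(!nzchar(names(group_sizes)))) {
      stop("`group_sizes` must be a named list: one vector of population sizes per group")
    }
    sizes <- unlist(group_sizes, use.names = FALSE)
    if (any(sizes < 0) || sum(sizes) != n_samples) {
      stop("`group_sizes` must be non-negative and sum to `n_samples`")
    }
    if (length(divergence_generations) != 2L ||
        any(divergence_generations < 0)) {
      stop("`divergence_generations` must be c(among_groups, among_populations), both >= 0")
    }
    if (sum(divergence_generations) > age_generations) {
      stop("sum of `divergence_generations` must not exceed `age_generations`")
    }
  }
  structure(
    list(topology = topology,
         n_samples = as.integer(n_samples),
         age_generations = age_generations,
         group_sizes = group_sizes,
         divergence_generations = divergence_generations,
         seed = as.integer(seed)),
    class = "genealogy_spec"
  )
}

#' Mutation-rate calibration for rho-based TMRCA
#'
#' The `EMR` preset is the evolutionary mutation-rate calibration,
#' 6.9e-4 per locus per 25-year generation. The observed (genealogical)
#' calibrations `OMRS`, `OMRB` and `OMRG` carry no packaged numeric value
#' and require an explicit `mu_per_locus_per_gen`.
#'
#' @param name one of `"EMR"`, `"OMRS"`, `"OMRB"`, `"OMRG"`, `"custom"`.
#' @param mu_per_locus_per_gen mutation rate per locus per generation;
#'   fixed at `6.9e-4` for `EMR`, required otherwise.
#' @param generation_years years per generation (default 25).
#' @param n_loci number of STR loci entering rho (default 15, the 17-locus
#'   panel minus DYS385a/b).
#' @return an object of class `rate_config`.
#' @export
rate_config <- function(name = c("EMR", "OMRS", "OMRB", "OMRG", "custom"),
                        mu_per_locus_per_gen = NULL,
                        generation_years = 25,
                        n_loci = 15L) {
  name <- match.arg(name)
  if (name == "EMR") {
    if (!is.null(mu_per_locus_per_gen) &&
        !isTRUE(all.equal(mu_per_locus_per_gen, 6.9e-4))) {
      stop("the EMR preset fixes mu_per_locus_per_gen at 6.9e-4")
    }
    mu_per_locus_per_gen <- 6.9e-4
    generation_years <- 25
  }
  if (is.null(mu_per_locus_per_gen)) {
    stop(sprintf("rate '%s' has no packaged default; supply mu_per_locus_per_gen", name))
  }
  stopifnot_positive(mu_per_locus_per_gen, "mu_per_locus_per_gen")
  stopifnot_positive(generation_years, "generation_years")
  stopifnot_positive(n_loci, "n_loci")
  structure(
    list(name = name,
         mu_per_locus_per_gen = mu_per_locus_per_gen,
         generation_years = generation_years,
         n_loci = as.integer(n_loci)),
    class = "rate_config"
  )
}
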