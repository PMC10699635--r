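# Rho-statistic dating: modal ancestral haplotype, mean mutational steps
# to the ancestor (rho) with its star-genealogy standard deviation, and
# conversion to years under configurable mutation-rate calibrations.

#' Modal ancestral haplotype
#'
#' Per locus, the most frequent allele across profiles; ties break to the
#' smallest allele for determinism. Excluded loci (DYS385a/b by default)
#' are dropped.
#'
#' @param profiles an `str_profiles` data frame.
#' @return named integer vector, one allele per retained locus.
#' @export
modal_ancestral <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0L) {
    stop("cannot infer a modal haplotype from an empty profile set")
  }
  m <- allele_matrix(profiles)
  apply(m, 2L, function(a) {
    tab <- table(a)
    alleles <- as.integer(names(tab))
    alleles[order(-as.integer(tab), alleles)][1]
  })
}

#' Rho statistic with star-genealogy standard deviation
#'
#' rho is the mean, over samples, of the total number of single-repeat
#' mutational steps separating each haplotype from the ancestral haplotype
#' (unweighted L1 distance summed over loci). The standard deviation uses
#' the star-genealogy approximation `sigma = sqrt(rho / n)`.
#'
#' @param profiles an `str_profiles` data frame.
#' @param ancestral named integer vector covering every retained locus
#'   (e.g. from [modal_ancestral()]).
#' @return list with `rho`, `sigma`, `n` (profiles used) and `steps`
#'   (per-sample step counts).
#' @export
rho_statistic <- function(profiles, ancestral) {
  loci <- setdiff(str_loci(profiles), str_excluded(profiles))
  missing_loci <- setdiff(loci, names(ancestral))
  if (length(missing_loci)) {
    stop(sprintf("ancestral haplotype lacks loci: %s",
                 paste(missing_loci, collapse = ", ")))
  }
  m <- allele_matrix(profiles, loci)
  ok <- stats::complete.cases(m)
  if (!all(ok)) {
    warning(sprintf("%d profile(s) with missing loci excluded from rho",
                    sum(!ok)))
    m <- m[ok, , drop = FALSE]
  }
  n <- nrow(m)
  if (n == 0L) stop("no complete profiles for rho")
  steps <- rowSums(abs(sweep(m, 2L, ancestral[loci], `-`)))
  rho <- mean(steps)
  list(rho = rho, sigma = sqrt(rho / n), n = n, steps = unname(steps))
}

#' Convert rho to TMRCA in years under mutation-rate calibrations
#'
#' `TMRCA_years = rho / (n_loci * mu_per_locus_per_gen) * generation_years`;
#' the standard deviation scales identically from sigma. Linear in rho, so
#' halving the rate exactly doubles the estimate.
#'
#' @param rho_result list from [rho_statistic()] (fields `rho`, `sigma`, `n`).
#' @param rates a [rate_config()] or list of them.
#' @return the input list with a `tmrca_years` element added: one row per
#'   rate (`rate`, `mu_per_locus_per_gen`, `generation_years`, `n_loci`,
#'   `estimate`, `sd`).
#' @export
tmrca <- function(rho_result, rates) {
  if (inherits(rates, "rate_config")) rates <- list(rates)
  if (!length(rates)) stop("`rates` must contain at least one rate_config")
  rows <- lapply(rates, function(rc) {
    stopifnot(inherits(rc, "rate_config"))
    scale <- rc$generation_years / (rc$n_loci * rc$mu_per_locus_per_gen)
    data.frame(rate = rc$name,
               mu_per_locus_per_gen = rc$mu_per_locus_per_gen,
               generation_years = rc$generation_years,
               n_loci = rc$n_loci,
               estimate = rho_result$rho * scale,
               sd = rho_result$sigma * scale,
               stringsAsFactors = FALSE)
  })
  rho_result$tmrca_years <- do.call(rbind, rows)
  rho_result
}

#' Date SNP-defined sublineages from their STR carriers
#'
#' For each SNP marker, restricts the STR profiles to its derived carriers,
#' infers the modal ancestral haplotype within the carriers, computes rho
#' and converts to years under every supplied rate. Single-carrier
#' sublineages are dated (rho = 0) but flagged low-confidence.
#'
#' @param profiles an `str_profiles` data frame.
#' @param genotypes a `snp_genotypes` data frame over the same samples
#'   (carrier masks), or a named list of logical vectors / sample-id
#'   vectors per SNP.
#' @param rates a [rate_config()] or list of them.
#' @param markers which markers to date (default: all in `genotypes`).
#' @return a data frame shaped like a TMRCA report: one row per SNP and
#'   rate with `snp`, `n_carriers`, `rho`, `sigma`, `rate`, `tmrca_years`,
#'   `sd_years`, `low_confidence`.
#' @export
date_sublineage <- function(profiles, genotypes, rates, markers = NULL) {
  if (inherits(rates, "rate_config")) rates <- list(rates)
  if (is.data.frame(genotypes)) {
    markers <- markers %||% (attr(genotypes, "markers") %||%
      setdiff(names(genotypes), c("sample_id", "population", "group")))
    carrier_sets <- lapply(markers, function(mk) {
      genotypes$sample_id[as.character(genotypes[[mk]]) == "D"]
    })
    names(carrier_sets) <- markers
  } else {
    carrier_sets <- lapply(genotypes, function(x) {
      if (is.logical(x)) profiles$sample_id[x] else as.character(x)
    })
  }
  rows <- list()
  for (mk in names(carrier_sets)) {
    ids <- carrier_sets[[mk]]
    if (!length(ids)) {
      stop(sprintf("SNP '%s' has no derived carriers", mk))
    }
    sub <- profiles[profiles$sample_id %in% ids, , drop = FALSE]
    sub <- new_str_profiles(sub, str_loci(profiles), str_excluded(profiles))
    anc <- modal_ancestral(sub)
    rr <- tmrca(rho_statistic(sub, anc), rates)
    tr <- rr$tmrca_years
    rows[[mk]] <- data.frame(snp = mk, n_carriers = rr$n,
                             rho = rr$rho, sigma = rr$sigma,
                             rate = tr$rate,
                             tmrca_years = tr$estimate,
                             sd_years = tr$sd,
                             low_confidence = rr$n < 2L,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
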