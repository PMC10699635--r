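# Candidate Y-SNP discovery filtering. A candidate survives when it is a
# single-nucleotide variant, absent from the known-variant catalog, outside
# repeat-masked regions, has no other variant (SNV or indel) within half
# the field-of-view window on either side, and is a transversion.

#' Is a substitution a transversion?
#'
#' A transversion exchanges a purine (A/G) for a pyrimidine (C/T) or vice
#' versa; a transition stays within the purine or pyrimidine class.
#'
#' @param ref_base,alt_base single bases in `A`, `C`, `G`, `T` (vectorised,
#'   recycled to a common length).
#' @return logical vector.
#' @export
is_transversion <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  ok <- c("A", "C", "G", "T")
  if (!all(ref_base %in% ok) || !all(alt_base %in% ok)) {
    stop("bases must be single characters in {A, C, G, T}")
  }
  purine <- c("A", "G")
  (ref_base %in% purine) != (alt_base %in% purine)
}

#' Discovery filter configuration
#'
#' @param window_nt total proximity field-of-view width in nucleotides
#'   (default 3000, i.e. +/-1500 nt around the variant).
#' @param require_transversion,exclude_known,exclude_repeats rule toggles.
#' @param allele_aware_known if `TRUE`, known-catalog matching compares
#'   ref/alt alleles as well as position (default position-only).
#' @return a `filter_config` list.
#' @export
filter_config <- function(window_nt = 3000,
                          require_transversion = TRUE,
                          exclude_known = TRUE,
                          exclude_repeats = TRUE,
                          allele_aware_known = FALSE) {
  if (window_nt < 0) stop("`window_nt` must be >= 0")
  structure(list(window_nt = window_nt,
                 require_transversion = require_transversion,
                 exclude_known = exclude_known,
                 exclude_repeats = exclude_repeats,
                 allele_aware_known = allele_aware_known),
            class = "filter_config")
}

#' Filter candidate SNVs by the discovery rules
#'
#' Rules, applied in order per variant (the audit records the first failing
#' rule): (i) the variant is an SNV; (ii) not in the known catalog;
#' (iii) not inside a repeat-mask interval; (iv) no other input variant
#' within `window_nt / 2` nucleotides on either side on the same
#' chromosome — proximity is judged against the FULL input list, including
#' variants rejected by other rules; (v) the substitution is a
#' transversion.
#'
#' @param variants data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` and optionally `id`, `vtype` (inferred from allele lengths when
#'   absent), e.g. from [read_variants()].
#' @param known_catalog data frame with `chrom`, `pos` (and `ref`/`alt` for
#'   allele-aware matching); `NULL` for none.
#' @param repeat_mask data frame with `chrom`, `start`, `end` (0-based
#'   half-open, BED convention); `NULL` for none.
#' @param cfg a [filter_config()].
#' @return list with `kept` (data frame, input position order) and `audit`
#'   (data frame: id, chrom, pos, kept, reason).
#' @export
filter_candidate_snps <- function(variants, known_catalog = NULL,
                                  repeat_mask = NULL,
                                  cfg = filter_config()) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!nrow(v)) {
    empty <- v[0, , drop = FALSE]
    return(list(kept = empty,
                audit = data.frame(id = character(0), chrom = character(0),
                                   pos = integer(0), kept = logical(0),
                                   reason = character(0))))
  }
  if (is.null(v$id)) v$id <- sprintf("var%d", seq_len(nrow(v)))
  if (is.null(v$vtype)) {
    v$vtype <- ifelse(nchar(v$ref) == 1L & nchar(v$alt) == 1L, "snv", "indel")
  }
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]

  key_pos <- paste(v$chrom, v$pos)
  if (anyDuplicated(key_pos)) {
    alleles_per_pos <- tapply(paste(v$ref, v$alt), key_pos,
                              function(x) length(unique(x)))
    if (any(alleles_per_pos > 1)) {
      warning("duplicated positions with conflicting alleles; each evaluated independently")
    }
  }

  half <- cfg$window_nt / 2
  in_mask <- rep(FALSE, nrow(v))
  if (cfg$exclude_repeats && !is.null(repeat_mask) && nrow(repeat_mask)) {
    for (ch in unique(v$chrom)) {
      msel <- repeat_mask$chrom == ch
      if (!any(msel)) next
      ir_mask <- IRanges::IRanges(start = repeat_mask$start[msel] + 1L,
                                  end = repeat_mask$end[msel])
      vsel <- v$chrom == ch
      ir_var <- IRanges::IRanges(start = v$pos[vsel], width = 1L)
      in_mask[vsel] <- IRanges::overlapsAny(ir_var, ir_mask)
    }
  }

  known <- rep(FALSE, nrow(v))
  if (cfg$exclude_known && !is.null(known_catalog) && nrow(known_catalog)) {
    if (cfg$allele_aware_known &&
        all(c("ref", "alt") %in% names(known_catalog))) {
      key_v <- paste(v$chrom, v$pos, v$ref, v$alt)
      key_k <- paste(known_catalog$chrom, known_catalog$pos,
                     known_catalog$ref, known_catalog$alt)
    } else {
      key_v <- paste(v$chrom, v$pos)
      key_k <- paste(known_catalog$chrom, known_catalog$pos)
    }
    known <- key_v %in% key_k
  }

  # proximity against the full input list (sorted by position per chrom)
  near <- rep(FALSE, nrow(v))
  for (ch in unique(v$chrom)) {
    ix <- which(v$chrom == ch)
    p <- v$pos[ix]
    if (length(ix) > 1L) {
      gap_prev <- c(Inf, diff(p))
      gap_next <- c(diff(p), Inf)
      # co-located records (distance 0) also count as neighbours
      near[ix] <- gap_prev <= half | gap_next <= half
    }
  }

  reason <- rep(NA_character_, nrow(v))
  is_snv <- v$vtype == "snv"
  reason[!is_snv] <- "not_snv"
  sel <- is.na(reason) & known
  reason[sel] <- "known_variant"
  sel <- is.na(reason) & in_mask
  reason[sel] <- "repeat_region"
  sel <- is.na(reason) & near
  reason[sel] <- "proximal_variant"
  if (cfg$require_transversion) {
    snv_ok <- is.na(reason) & is_snv
    tv <- rep(FALSE, nrow(v))
    tv[snv_ok] <- is_transversion(v$ref[snv_ok], v$alt[snv_ok])
    reason[snv_ok & !tv] <- "transition"
  }
  kept <- is.na(reason)
  list(
    kept = v[kept, , drop = FALSE],
    audit = data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                       kept = kept,
                       reason = ifelse(kept, "pass", reason),
                       stringsAsFactors = FALSE)
  )
}
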