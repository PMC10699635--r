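# File readers and writers. Tabular outputs are TSV with '#'-prefixed
# provenance comment headers; readers skip comment lines. VCF input goes
# through vcfR; the repeat mask uses BED (0-based half-open) coordinates.

sniff_sep <- function(path) {
  for (ln in readLines(path, n = 50L, warn = FALSE)) {
    if (startsWith(ln, "#") || !nzchar(ln)) next
    return(if (grepl("\t", ln)) "\t" else ",")
  }
  "\t"
}

#' Read a Y-STR profile table
#'
#' Expects a CSV/TSV with a `sample_id` column, optional `population` and
#' `group` columns, and one integer repeat-count column per locus.
#' `DYS385a`/`DYS385b` load but are flagged as excluded from distance-based
#' analyses; locus columns outside the standard 17-plex panel are accepted
#' with a warning. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return an `str_profiles` data frame.
#' @export
read_str_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("header must contain `sample_id`")
  loci <- setdiff(names(df), c("sample_id", "population", "group"))
  if (!length(loci)) stop("no locus columns found")
  known <- ystr_panel_17()
  unknown <- setdiff(loci, known)
  if (length(unknown)) {
    warning(sprintf("locus column(s) outside the standard panel: %s",
                    paste(unknown, collapse = ", ")))
  }
  for (lc in loci) {
    v <- df[[lc]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) | (!is.na(num) & num != round(num)))
    if (length(bad)) {
      stop(sprintf("non-integer repeat count '%s' at row %d, column '%s'",
                   v[bad[1]], bad[1], lc))
    }
    df[[lc]] <- as.integer(num)
  }
  if (is.null(df$population)) df$population <- "pop1"
  if (is.null(df$group)) df$group <- "group1"
  df <- df[, c("sample_id", "population", "group", loci)]
  excl <- intersect(ystr_excluded_default(), loci)
  if (length(excl)) {
    message(sprintf("loci flagged excluded from distance analyses: %s",
                    paste(excl, collapse = ", ")))
  }
  new_str_profiles(df, loci)
}

#' Write a Y-STR profile table as TSV with a provenance header
#' @param profiles an `str_profiles` data frame.
#' @param path output path.
#' @param params named list recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_str_table <- function(profiles, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  utils::write.table(as.data.frame(profiles), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a wide SNP genotype table
#'
#' CSV/TSV with `sample_id` (plus optional `population`/`group`) and one
#' column per marker holding states `A` (ancestral), `D` (derived) or `.`
#' (missing).
#'
#' @param path file path.
#' @return a `snp_genotypes` data frame.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (!"sample_id" %in% names(df)) stop("header must contain `sample_id`")
  markers <- setdiff(names(df), c("sample_id", "population", "group"))
  for (mk in markers) {
    bad <- which(!df[[mk]] %in% c("A", "D", "."))
    if (length(bad)) {
      stop(sprintf("invalid state '%s' at row %d, marker '%s' (expected A/D/.)",
                   df[[mk]][bad[1]], bad[1], mk))
    }
  }
  if (is.null(df$population)) df$population <- "pop1"
  if (is.null(df$group)) df$group <- "group1"
  df <- df[, c("sample_id", "population", "group", markers)]
  structure(df, markers = markers,
            class = c("snp_genotypes", "data.frame"))
}

#' Write a SNP genotype table as TSV with a provenance header
#' @param genotypes a `snp_genotypes` data frame.
#' @inheritParams write_str_table
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  utils::write.table(as.data.frame(genotypes), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read variants from a VCF file
#'
#' @param path a VCF 4.x file (plain or gzipped).
#' @return data frame with `chrom`, `pos` (1-based), `id`, `ref`, `alt`,
#'   `vtype` (`snv`/`indel`); multiallelic records are split by ALT allele.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), vtype = character(0)))
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (a in alts) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        id = ifelse(is.na(fix$ID[i]) | fix$ID[i] == ".",
                    sprintf("var%d", length(rows) + 1L), fix$ID[i]),
        ref = fix$REF[i], alt = a,
        vtype = if (nchar(fix$REF[i]) == 1L && nchar(a) == 1L) "snv" else "indel",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a variant table as a plain-text VCF 4.2 file
#' @param variants data frame with `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=ylineage_%s",
                   tryCatch(as.character(utils::packageVersion("ylineage")),
                            error = function(e) "dev")),
           paste0("##contig=<ID=", paste(unique(variants$chrom)), ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants)) {
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
            variants$chrom, variants$pos,
            variants$id %||% ".", variants$ref, variants$alt)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED repeat mask (0-based half-open intervals)
#' @param path BED file path.
#' @return data frame with `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines[nzchar(lines) & !startsWith(lines, "#")])) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  stats::setNames(df[, 1:3], c("chrom", "start", "end"))
}

#' Write a BED mask
#' @param mask data frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_mask <- function(mask, path) {
  utils::write.table(mask[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a known-variant catalog
#'
#' Either a 2-column TSV (`chrom`, `pos`) or a VCF (by `.vcf` extension).
#'
#' @param path file path.
#' @return data frame with `chrom`, `pos` (and alleles when from VCF).
#' @export
read_known_catalog <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_variants(path)[, c("chrom", "pos", "ref", "alt")]
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                            comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("chrom", "pos") %in% names(df))) {
      names(df)[1:2] <- c("chrom", "pos")
    }
    df$pos <- as.integer(df$pos)
    df
  }
}

#' Write a known-variant catalog as TSV
#' @param catalog data frame with `chrom`, `pos`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_known_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read mutation-rate calibrations from YAML
#'
#' The file holds a list of records with `name`,
#' `mu_per_locus_per_gen`, optional `generation_years` and `n_loci`.
#'
#' @param path YAML file path.
#' @return list of [rate_config()] objects.
#' @export
read_rates_yaml <- function(path) {
  recs <- yaml::read_yaml(path)
  lapply(recs, function(r) {
    rate_config(name = r$name %||% "custom",
                mu_per_locus_per_gen = r$mu_per_locus_per_gen,
                generation_years = r$generation_years %||% 25,
                n_loci = r$n_loci %||% 15L)
  })
}

#' Write a data frame as TSV with a provenance header
#' @param df data frame.
#' @param path output path.
#' @param params named list recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
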