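# Umbrella pipeline: runs the configured stages over the configured input
# files and writes each stage's tables plus a JSON provenance manifest.

#' Pipeline configuration
#'
#' @param str_path Y-STR profile table (CSV/TSV).
#' @param genotypes_path SNP genotype table (CSV/TSV).
#' @param tree_path haplogroup tree YAML/JSON (default: packaged Q-M3 tree).
#' @param vcf_path candidate-variant VCF for the discovery stage.
#' @param mask_path BED repeat mask.
#' @param catalog_path known-variant catalog (TSV or VCF).
#' @param rates_path mutation-rate YAML (default: EMR preset only).
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run, from
#'   `c("discover", "classify", "freq", "network", "tmrca", "amova", "mca")`.
#' @param seed integer seed recorded in provenance and used by seeded stages.
#' @param n_permutations AMOVA permutations.
#' @param epsilon network tolerance.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(str_path = NULL, genotypes_path = NULL,
                            tree_path = NULL, vcf_path = NULL,
                            mask_path = NULL, catalog_path = NULL,
                            rates_path = NULL, out_dir = "ylineage_out",
                            stages = c("discover", "classify", "freq",
                                       "network", "tmrca", "amova", "mca"),
                            seed = 1L, n_permutations = 999L, epsilon = 0) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(str_path = str_path, genotypes_path = genotypes_path,
                 tree_path = tree_path, vcf_path = vcf_path,
                 mask_path = mask_path, catalog_path = catalog_path,
                 rates_path = rates_path, out_dir = out_dir,
                 stages = stages, seed = as.integer(seed),
                 n_permutations = n_permutations, epsilon = epsilon),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages (discover, classify, freq, network,
#' tmrca, amova, mca) on the configured inputs. Each stage writes its
#' outputs under `out_dir`; a JSON provenance manifest (package version,
#' seed, parameters, per-stage status and output files) is always written.
#' A stage failure is recorded and does not stop independent stages.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of per-stage results, with the manifest in
#'   `$manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  manifest <- list(
    tool = "ylineage",
    version = tryCatch(as.character(utils::packageVersion("ylineage")),
                       error = function(e) "dev"),
    seed = config$seed,
    parameters = list(n_permutations = config$n_permutations,
                      epsilon = config$epsilon),
    stages = list()
  )
  outfile <- function(x) file.path(config$out_dir, x)
  run_stage <- function(name, needs, fn) {
    if (!name %in% config$stages) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    missing_in <- needs[vapply(needs, function(p) {
      is.null(config[[p]]) && !(p == "tree_path") }, logical(1))]
    if (length(missing_in)) {
      manifest$stages[[name]] <<- list(
        status = "failed",
        error = sprintf("missing input: %s", paste(missing_in, collapse = ", ")))
      message(sprintf("[%s] skipped: missing input(s) %s", name,
                      paste(missing_in, collapse = ", ")))
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      message(sprintf("[%s] failed: %s", name, conditionMessage(res)))
    } else {
      # record outputs relative to out_dir so reruns compare byte-identical
      manifest$stages[[name]] <<- list(status = "ok",
                                       outputs = basename(res$files))
      results[[name]] <<- res
    }
    invisible(NULL)
  }
  prov <- list(seed = config$seed)
  load_tree_cfg <- function() {
    if (is.null(config$tree_path)) qm3_tree() else load_tree(config$tree_path)
  }

  run_stage("discover", c("vcf_path"), function() {
    variants <- read_variants(config$vcf_path)
    mask <- if (!is.null(config$mask_path)) read_bed_mask(config$mask_path)
    known <- if (!is.null(config$catalog_path)) {
      read_known_catalog(config$catalog_path)
    }
    out <- filter_candidate_snps(variants, known, mask)
    f1 <- outfile("discovery_kept.vcf")
    f2 <- outfile("discovery_audit.json")
    write_variants_vcf(out$kept, f1)
    jsonlite::write_json(out$audit, f2, dataframe = "rows", auto_unbox = TRUE)
    list(value = out, files = c(f1, f2))
  })

  run_stage("classify", c("genotypes_path"), function() {
    gt <- read_genotypes(config$genotypes_path)
    cls <- classify_haplogroup(gt, load_tree_cfg())
    f1 <- outfile("classification.tsv")
    f2 <- outfile("classification_conflicts.json")
    write_tsv_provenance(cls, f1, prov)
    jsonlite::write_json(attr(cls, "conflicts"), f2, dataframe = "rows",
                         auto_unbox = TRUE)
    list(value = cls, files = c(f1, f2))
  })

  run_stage("freq", c("genotypes_path"), function() {
    gt <- read_genotypes(config$genotypes_path)
    tab <- carrier_frequency_table(gt, grouping = "population")
    f1 <- outfile("carrier_frequencies.tsv")
    write_tsv_provenance(tab, f1, prov)
    list(value = tab, files = f1)
  })

  run_stage("network", c("str_path"), function() {
    pr <- read_str_table(config$str_path)
    net <- build_mj_network(pr, epsilon = config$epsilon)
    f1 <- outfile("network.graphml")
    f2 <- outfile("network_edges.tsv")
    export_network(net, f1, "graphml")
    export_network(net, f2, "tsv")
    list(value = net, files = c(f1, f2))
  })

  run_stage("tmrca", c("str_path", "genotypes_path"), function() {
    pr <- read_str_table(config$str_path)
    gt <- read_genotypes(config$genotypes_path)
    rates <- if (is.null(config$rates_path)) {
      list(rate_config("EMR"))
    } else {
      read_rates_yaml(config$rates_path)
    }
    markers <- attr(gt, "markers")
    carried <- markers[vapply(markers, function(mk) any(gt[[mk]] == "D"),
                              logical(1))]
    if (!length(carried)) stop("no marker has derived carriers")
    tab <- date_sublineage(pr, gt, rates, markers = carried)
    f1 <- outfile("tmrca.tsv")
    write_tsv_provenance(tab, f1, prov)
    list(value = tab, files = f1)
  })

  run_stage("amova", c("str_path"), function() {
    pr <- read_str_table(config$str_path)
    res <- amova_two_level(pr, n_permutations = config$n_permutations,
                           seed = config$seed)
    f1 <- outfile("amova.tsv")
    write_tsv_provenance(res$table, f1,
                         c(prov, list(phi = sprintf("%.5f", res$phi),
                                      p = sprintf("%.4f", res$p_values))))
    list(value = res, files = f1)
  })

  run_stage("mca", c("genotypes_path"), function() {
    gt <- read_genotypes(config$genotypes_path)
    res <- mca(gt, supplementary = "population")
    f1 <- outfile("mca_coordinates.tsv")
    co <- rbind(
      data.frame(point = rownames(res$category_coords), type = "category",
                 res$category_coords, check.names = FALSE),
      if (!is.null(res$supplementary_coords)) {
        data.frame(point = rownames(res$supplementary_coords),
                   type = "supplementary", res$supplementary_coords,
                   check.names = FALSE)
      }
    )
    write_tsv_provenance(co, f1,
                         c(prov, list(percent_inertia =
                                        sprintf("%.2f", res$percent_inertia))))
    list(value = res, files = f1)
  })

  mf <- outfile("manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, null = "null")
  results$manifest <- manifest
  invisible(results)
}
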