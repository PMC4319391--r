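# End-to-end pipeline: expression + design + pathways -> gene-level audit,
# PAS profile, pathway cloud, then optionally gene-list enrichment and drug
# screening. Every output table is stamped with the package version and a
# hash of the configuration, and a machine-readable run manifest ties the
# artifacts together. Re-running an identical configuration reproduces
# identical outputs.

pipeline_defaults <- function() {
  list(expression = NULL, design = NULL, pathways = NULL,
       gene_list = NULL, drug_library = NULL,
       normalization = "quantile",
       fold_upper = 3 / 2, fold_lower = 2 / 3, sd_multiplier = 2,
       pseudocount = NULL, min_control_n = 3,
       cloud_threshold = 0, screen_mode = "mimic", weighted_screen = FALSE,
       universe = NULL, out_dir = ".", seed = 1L)
}

#' Assemble a pipeline run configuration
#'
#' Unset fields take the documented defaults; unknown fields are rejected.
#'
#' @param ... configuration fields, see [run_pipeline()].
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- pipeline_defaults()
  upd <- list(...)
  unknown <- setdiff(names(upd), names(cfg))
  assert_that(length(unknown) == 0, "unknown config field(s): ",
              paste(unknown, collapse = ", "))
  cfg[names(upd)] <- upd
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML schema mirroring the [run_config()] fields; values given in
#' `overrides` (e.g. from command-line flags) win over file values.
#'
#' @param path YAML file.
#' @param overrides named list of overriding fields.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  assert_that(file.exists(path), "config file not found: ", path)
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

config_hash <- function(cfg) {
  # the hash fingerprints the scientific configuration; where the outputs
  # land does not change what was computed
  cfg$out_dir <- NULL
  canon <- cfg[order(names(cfg))]
  fnv1a_hash(jsonlite::toJSON(canon, auto_unbox = TRUE, null = "null",
                              digits = NA))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Stages: load and validate inputs; normalize; compute the gene-level
#' signal audit and the pathway activation profile; build the pathway
#' cloud; optionally run gene-list enrichment and drug screening. Artifacts
#' are written to `cfg$out_dir`:
#' `gene_signals.tsv`, `pas_profile.tsv`, `cloud.tsv`, `enrichment.tsv`
#' (if a gene list is given), `drug_ranking.tsv` (if a drug manifest is
#' given) and `run_manifest.json`. On a stage failure the manifest is still
#' written, marked incomplete with the failing stage named.
#'
#' @param cfg a [run_config()], or a named list of its fields.
#' @return invisibly, a list with the in-memory results (`profile`, `cloud`,
#'   `enrichment`, `ranking`) and the `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, cfg)
  assert_that(!is.null(cfg$expression) && !is.null(cfg$design) &&
                !is.null(cfg$pathways),
              "config must set 'expression', 'design' and 'pathways'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass(cfg))
  stamp <- paste0("pascloud ",
                  as.character(utils::packageVersion("pascloud")),
                  " config=", hash)
  manifest <- list(tool = "pascloud",
                   version = as.character(utils::packageVersion("pascloud")),
                   config = unclass(cfg), config_hash = hash,
                   seed = cfg$seed, status = "incomplete", stage = NULL,
                   outputs = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir,
                                             "run_manifest.json"),
                         auto_unbox = TRUE, null = "null", pretty = TRUE,
                         digits = NA)
  }
  fail <- function(e) {
    msg <- conditionMessage(e)
    manifest$stage <<- if (grepl("^stage '", msg)) {
      sub("^stage '([^']*)'.*", "\\1", msg)
    } else "unknown"
    write_manifest()
    stop(e)
  }

  result <- tryCatch({
    policy <- pipeline_stage("policy", tolerance_policy(
      fold_upper = cfg$fold_upper, fold_lower = cfg$fold_lower,
      sd_multiplier = cfg$sd_multiplier, pseudocount = cfg$pseudocount,
      min_control_n = cfg$min_control_n))

    db <- pipeline_stage("load_pathways", read_pathway_db(cfg$pathways))
    m <- pipeline_stage("load_expression",
                        read_expression_matrix(cfg$expression))
    design <- pipeline_stage("load_design", read_group_design(cfg$design))
    m <- pipeline_stage("normalize",
                        normalize_expression(m, cfg$normalization))

    audit <- pipeline_stage("gene_signals", gene_signals(m, design, policy))
    p_audit <- file.path(cfg$out_dir, "gene_signals.tsv")
    write_tsv_stamped(audit, p_audit, stamp)
    manifest$outputs$gene_signals <- basename(p_audit)

    profile <- pipeline_stage("pas_profile",
                              pas_profile(m, design, db, policy))
    p_prof <- file.path(cfg$out_dir, "pas_profile.tsv")
    write_tsv_stamped(as.data.frame(profile), p_prof, stamp)
    manifest$outputs$pas_profile <- basename(p_prof)

    cloud <- pipeline_stage("build_cloud",
                            build_cloud(profile, cfg$cloud_threshold))
    p_cloud <- file.path(cfg$out_dir, "cloud.tsv")
    write_tsv_stamped(as.data.frame(cloud), p_cloud, stamp)
    manifest$outputs$cloud <- basename(p_cloud)
    manifest$summary <- list(
      n_pathways = length(db), cloud_size = nrow(cloud),
      n_activated = sum(cloud$label == "activated"),
      n_repressed = sum(cloud$label == "repressed"))

    enr <- NULL
    if (!is.null(cfg$gene_list)) {
      enr <- pipeline_stage("enrichment", {
        genes <- read_gene_list(cfg$gene_list)
        universe <- if (is.null(cfg$universe)) gene_universe(db) else
          read_gene_list(cfg$universe)
        enrich_pathways(genes, db, universe)
      })
      p_enr <- file.path(cfg$out_dir, "enrichment.tsv")
      write_tsv_stamped(enr, p_enr, stamp)
      manifest$outputs$enrichment <- basename(p_enr)
    }

    ranking <- NULL
    if (!is.null(cfg$drug_library)) {
      ranking <- pipeline_stage("drug_screen", {
        lib <- read_drug_library(cfg$drug_library, db, policy,
                                 cfg$normalization)
        if (nrow(cloud) == 0) {
          stop("target cloud is empty; nothing to screen against")
        }
        rank_drugs(lib, cloud, cfg$screen_mode,
                   weighted = isTRUE(cfg$weighted_screen))
      })
      p_rank <- file.path(cfg$out_dir, "drug_ranking.tsv")
      write_tsv_stamped(as.data.frame(ranking), p_rank, stamp)
      manifest$outputs$drug_ranking <- basename(p_rank)
      manifest$summary$top_drug <- ranking$drug_id[1]
    }

    manifest$status <- "complete"
    manifest$stage <- NULL
    write_manifest()
    list(profile = profile, cloud = cloud, enrichment = enr,
         ranking = ranking, manifest = manifest,
         out_dir = cfg$out_dir)
  }, error = fail)
  invisible(result)
}
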