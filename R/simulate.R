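# Seeded synthetic data: log-normal baseline expression with multiplicative
# fold changes planted on pathway member genes (activators up, repressors
# down, for an activated pathway), plus drug libraries with known mimics and
# decoys. Every stage draws from its own named random stream derived from
# one global seed, so adding a stage never perturbs another stage's draws.

#' Generate a synthetic role-annotated pathway database
#'
#' Pathways are gene-disjoint (each synthetic gene belongs to exactly one
#' pathway), which keeps planted ground truth exact: disturbing one pathway
#' never leaks into another. All role weights have magnitude 1.
#'
#' @param n_pathways number of pathways (default 10).
#' @param size_range inclusive member-count range per pathway (default
#'   c(6, 12)).
#' @param activator_fraction expected fraction of activator members; the
#'   rest are repressors. Each pathway is forced to contain at least one
#'   activator. Default 0.7.
#' @param seed integer seed.
#' @return a [pathway_db()].
#' @export
simulate_pathway_db <- function(n_pathways = 10, size_range = c(6, 12),
                                activator_fraction = 0.7, seed = 1L) {
  assert_that(n_pathways >= 1, "'n_pathways' must be >= 1")
  assert_that(length(size_range) == 2 && size_range[1] >= 1 &&
                size_range[1] <= size_range[2],
              "'size_range' must be an increasing pair of sizes >= 1")
  assert_that(activator_fraction >= 0 && activator_fraction <= 1,
              "'activator_fraction' must lie in [0, 1]")
  with_stream(seed, "pathway_db", {
    sizes <- sample(seq(size_range[1], size_range[2]), n_pathways,
                    replace = TRUE)
    gene_no <- 0
    pws <- lapply(seq_len(n_pathways), function(k) {
      genes <- sprintf("G%05d", gene_no + seq_len(sizes[k]))
      gene_no <<- gene_no + sizes[k]
      roles <- ifelse(stats::runif(sizes[k]) < activator_fraction,
                      "act", "rep")
      if (!any(roles == "act")) roles[1] <- "act"
      pathway(sprintf("PW%03d", k), genes, roles,
              name = sprintf("synthetic pathway %d", k))
    })
    pathway_db(pws)
  })
}

#' Specification of a synthetic case/control expression experiment
#'
#' The generative model: per gene g, a baseline log10 level b_g is drawn
#' uniformly from `baseline_log10_range`; each sample value is
#' `10^(b_g + N(0, biological_sd))`. Case samples are additionally
#' multiplied by the planted fold `f` for activator members of planted
#' pathways and by `1/f` for repressor members, so a fold above 1 activates
#' the pathway.
#'
#' @param db a [pathway_db()].
#' @param planted named numeric vector: pathway id -> fold (> 0). `NULL`
#'   for a null experiment.
#' @param n_case,n_control sample counts (defaults 5 and 5; at least 3
#'   controls are required).
#' @param baseline_log10_range range of baseline log10 expression
#'   (default c(1, 3), i.e. levels between 10 and 1000).
#' @param biological_sd SD of the per-sample log10 noise (default 0.1).
#' @param seed integer global seed.
#' @return an object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(db, planted = NULL, n_case = 5, n_control = 5,
                            baseline_log10_range = c(1, 3),
                            biological_sd = 0.1, seed = 1L) {
  assert_that(inherits(db, "pathway_db"), "'db' must be a pathway_db")
  if (!is.null(planted)) {
    assert_that(is.numeric(planted) && !is.null(names(planted)),
                "'planted' must be a named numeric vector of folds")
    assert_that(all(planted > 0), "planted folds must be > 0")
    missing <- setdiff(names(planted), names(db))
    assert_that(length(missing) == 0, "planted pathway(s) not in the ",
                "database: ", paste(missing, collapse = ", "))
  }
  assert_that(n_case >= 1, "'n_case' must be >= 1")
  assert_that(n_control >= 3, "'n_control' must be >= 3")
  assert_that(biological_sd >= 0, "'biological_sd' must be >= 0")
  structure(list(db = db, planted = planted, n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 baseline_log10_range = baseline_log10_range,
                 biological_sd = biological_sd, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Expected aggregate PAS of a planted pathway under full flag passage:
# activators contribute arr * log10(f), repressors (arr < 0) see fold 1/f
# and contribute |arr| * log10(f) as well.
expected_planted_pas <- function(db, planted) {
  vapply(names(planted), function(id) {
    arr <- db[[id]]$members$arr
    sum(abs(arr)) * log10(planted[[id]])
  }, numeric(1))
}

#' Simulate a case/control expression experiment
#'
#' @param spec a [simulation_spec()].
#' @param stream name of the random stream (default `"matrix"`); drug
#'   simulations pass their own stream names.
#' @return list with `expression` (matrix), `design` ([group_design()]) and
#'   `truth`: the planted folds, the closed-form expected aggregate PAS per
#'   planted pathway (`(sum |arr|) * log10(f)`, attained exactly when every
#'   planted gene passes the tolerance filter), and the generator settings.
#' @export
simulate_experiment <- function(spec, stream = "matrix") {
  assert_that(inherits(spec, "simulation_spec"),
              "'spec' must be a simulation_spec")
  genes <- unlist(lapply(spec$db, function(p) p$members$gene_id),
                  use.names = FALSE)
  genes <- unique(genes)
  ng <- length(genes)
  n <- spec$n_case + spec$n_control
  m <- with_stream(spec$seed, stream, {
    b <- stats::runif(ng, spec$baseline_log10_range[1],
                      spec$baseline_log10_range[2])
    noise <- matrix(stats::rnorm(ng * n, 0, spec$biological_sd), ng, n)
    10^(b + noise)
  })
  dimnames(m) <- list(genes,
                      c(sprintf("case_%02d", seq_len(spec$n_case)),
                        sprintf("ctrl_%02d", seq_len(spec$n_control))))
  if (!is.null(spec$planted)) {
    case_cols <- seq_len(spec$n_case)
    for (id in names(spec$planted)) {
      f <- spec$planted[[id]]
      mem <- spec$db[[id]]$members
      act <- mem$gene_id[mem$arr > 0]
      rep_ <- mem$gene_id[mem$arr < 0]
      # shared genes across planted pathways (possible in user-supplied
      # databases) accumulate folds multiplicatively, in pathway order
      m[act, case_cols] <- m[act, case_cols] * f
      m[rep_, case_cols] <- m[rep_, case_cols] / f
    }
  }
  design <- group_design(case = colnames(m)[seq_len(spec$n_case)],
                         control = colnames(m)[spec$n_case +
                                                 seq_len(spec$n_control)])
  truth <- list(
    planted = spec$planted,
    expected_pas = if (is.null(spec$planted)) numeric(0) else
      expected_planted_pas(spec$db, spec$planted),
    biological_sd = spec$biological_sd, n_case = spec$n_case,
    n_control = spec$n_control, seed = spec$seed, stream = stream)
  list(expression = as_expression_matrix(m), design = design, truth = truth)
}

#' Simulate a drug library with known mimics and decoys
#'
#' Each drug is its own treated/untreated experiment over the same pathway
#' database and generator settings as the target. Mimic drugs plant the
#' target's pathways at fold `f^attenuation`; decoys plant either random
#' pathways disjoint from the target's (`"random_pathways"`) or the target's
#' pathways at reciprocal folds (`"reversed"`, the positive control for
#' minimize-mode screening).
#'
#' @param spec the target's [simulation_spec()] (must have planted
#'   pathways).
#' @param n_mimics,n_decoys drug counts (defaults 1 and 9).
#' @param decoy_mode `"random_pathways"` (default) or `"reversed"`.
#' @param attenuation exponent in (0, 1] shrinking mimic folds toward 1
#'   (default 1 = full-strength mimics).
#' @param seed global seed; defaults to the spec's.
#' @return list with `drugs` (named list; each element has `expression`,
#'   `design`, `truth`) and `truth` (mimic/decoy ids and the decoy mode).
#' @export
simulate_drug_library <- function(spec, n_mimics = 1, n_decoys = 9,
                                  decoy_mode = c("random_pathways",
                                                 "reversed"),
                                  attenuation = 1, seed = spec$seed) {
  decoy_mode <- match.arg(decoy_mode)
  assert_that(inherits(spec, "simulation_spec"),
              "'spec' must be a simulation_spec")
  assert_that(!is.null(spec$planted),
              "the target spec must have planted pathways")
  assert_that(attenuation > 0 && attenuation <= 1,
              "'attenuation' must lie in (0, 1]")
  assert_that(n_mimics >= 0 && n_decoys >= 0 && n_mimics + n_decoys >= 1,
              "the library must contain at least one drug")
  target <- spec$planted
  free <- setdiff(names(spec$db), names(target))
  if (decoy_mode == "random_pathways" && n_decoys > 0 &&
      length(free) < length(target)) {
    stop("not enough non-target pathways for random decoys: need ",
         length(target), ", have ", length(free), call. = FALSE)
  }

  make_drug <- function(id, planted) {
    sp <- simulation_spec(spec$db, planted, spec$n_case, spec$n_control,
                          spec$baseline_log10_range, spec$biological_sd,
                          seed)
    simulate_experiment(sp, stream = paste0("drug_", id))
  }

  drugs <- list()
  mimic_ids <- character(0)
  for (i in seq_len(n_mimics)) {
    id <- sprintf("mimic_%02d", i)
    drugs[[id]] <- make_drug(id, target^attenuation)
    mimic_ids <- c(mimic_ids, id)
  }
  decoy_ids <- character(0)
  for (i in seq_len(n_decoys)) {
    id <- sprintf("decoy_%02d", i)
    planted <- if (decoy_mode == "reversed") {
      1 / target
    } else {
      picked <- with_stream(seed, paste0("decoy_pick_", i),
                            sample(free, length(target)))
      stats::setNames(unname(target), picked)
    }
    drugs[[id]] <- make_drug(id, planted)
    decoy_ids <- c(decoy_ids, id)
  }
  list(drugs = drugs,
       truth = list(mimic_ids = mimic_ids, decoy_ids = decoy_ids,
                    decoy_mode = decoy_mode, attenuation = attenuation))
}

#' Write a simulated experiment to disk
#'
#' Emits the expression TSV, design TSV, pathway GMT and a ground-truth YAML
#' into a directory, so simulated data can feed the command-line pipeline.
#'
#' @param sim result of [simulate_experiment()].
#' @param db the [pathway_db()] used.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             design = file.path(dir, "design.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             truth = file.path(dir, "truth.yaml"))
  write_expression_matrix(sim$expression, paths["expression"])
  write_group_design(sim$design, paths["design"])
  write_pathway_db(db, paths["pathways"])
  truth <- sim$truth
  truth$planted <- as.list(truth$planted)
  truth$expected_pas <- as.list(truth$expected_pas)
  yaml::write_yaml(truth, paths["truth"])
  invisible(paths)
}
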