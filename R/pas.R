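# Pathway activation engine: ECR, BTIF, per-pathway activation strength
# (PAS), the multiplicative cloud-disturbance estimator (SPCD) and the
# signaling pathway cloud.
#
# For a pathway p, PAS_p = sum over member genes n of
#   ARR_n * BTIF_n * log10(ECR_n)
# where ECR is a case sample's expression divided by the control mean, BTIF
# is the 0/1 beyond-tolerance flag, and ARR the signed activator/repressor
# weight. SPCD is the multiplicative counterpart: the product of activator
# levels divided by the product of repressor levels, so 10^PAS = SPCD
# whenever |ARR| = 1 and all flags pass.

#' Case-to-control expression ratio (ECR)
#'
#' The ratio of a gene's expression in a case sample to its mean expression
#' in the normalized control group, with a symmetric pseudocount guarding
#' zero denominators. Vectorized over genes.
#'
#' @param case_value non-negative case expression level(s).
#' @param control_mean non-negative control-group mean(s).
#' @param policy a [tolerance_policy()]; supplies the pseudocount.
#' @param pseudocount overrides the policy pseudocount; when the policy's is
#'   `NULL` (auto) and no override is given, it is resolved from the median
#'   of the supplied values.
#' @return strictly positive finite ratio(s).
#' @export
compute_ecr <- function(case_value, control_mean, policy = tolerance_policy(),
                        pseudocount = NULL) {
  assert_that(all(case_value >= 0) && all(control_mean >= 0),
              "expression levels must be non-negative")
  pc <- pseudocount %||% resolve_pseudocount(policy,
                                             c(case_value, control_mean))
  (case_value + pc) / (control_mean + pc)
}

#' Beyond-tolerance-interval flag (BTIF)
#'
#' Returns 1 when both tolerance criteria hold simultaneously: the ECR lies
#' outside the fold bounds, and the case expression deviates from the
#' control mean by more than `sd_multiplier` control standard deviations.
#' When the control SD is exactly zero the second criterion reduces to "the
#' case value differs from the control mean at all" (a strict inequality
#' against zero would make constant controls unflaggable). Vectorized.
#'
#' @param ecr expression ratio(s) from [compute_ecr()].
#' @param case_value case expression level(s).
#' @param control_mean,control_sd per-gene control statistics
#'   (see [control_stats()]).
#' @param policy a [tolerance_policy()].
#' @return integer flag(s) in \{0, 1\}.
#' @export
compute_btif <- function(ecr, case_value, control_mean, control_sd,
                         policy = tolerance_policy()) {
  fold <- ecr > policy$fold_upper | ecr < policy$fold_lower
  dev <- abs(case_value - control_mean)
  sd_ok <- ifelse(control_sd == 0, dev > 0,
                  dev > policy$sd_multiplier * control_sd)
  as.integer(fold & sd_ok)
}

#' Pathway activation strength (PAS) for one case sample
#'
#' Sums `arr * btif * log10(ecr)` over the pathway members present in the
#' supplied gene signals. Members absent from the signals are skipped;
#' a pathway with no measured member yields `NA` (undefined, distinct from
#' an activation score of zero).
#'
#' @param pw a [pathway()].
#' @param ecr named vector of expression ratios (names = gene symbols).
#' @param btif named 0/1 vector aligned with `ecr`.
#' @return a single signed PAS value, or `NA_real_` when no member is
#'   measured.
#' @export
compute_pas <- function(pw, ecr, btif) {
  assert_that(inherits(pw, "pathway"), "'pw' must be a pathway")
  assert_that(!is.null(names(ecr)), "'ecr' must be a named vector")
  idx <- match(pw$members$gene_id, names(ecr))
  present <- !is.na(idx)
  if (!any(present)) return(NA_real_)
  g <- idx[present]
  sum(pw$members$arr[present] * btif[g] * log10(ecr[g]))
}

#' Signaling pathway cloud disturbance (SPCD) estimator
#'
#' The product of activator expression levels divided by the product of
#' repressor levels, over the pathway members present in `levels`. Neutral
#' members do not enter the product. The proportionality constant is fixed
#' at 1, so only ratios and orderings of SPCD values are meaningful. When
#' the levels supplied are ECRs with all `|arr| = 1` and all flags passing,
#' `10^PAS` equals this value.
#'
#' @param pw a [pathway()].
#' @param levels named vector of strictly positive expression levels (or
#'   ratios), names = gene symbols.
#' @return positive SPCD value, or `NA_real_` when the pathway has no
#'   measured activator or repressor.
#' @export
compute_spcd <- function(pw, levels) {
  assert_that(inherits(pw, "pathway"), "'pw' must be a pathway")
  assert_that(!is.null(names(levels)), "'levels' must be a named vector")
  assert_that(all(levels > 0), "'levels' must be strictly positive ",
              "(apply a pseudocount upstream)")
  m <- pw$members
  idx <- match(m$gene_id, names(levels))
  act <- which(m$arr > 0 & !is.na(idx))
  rep_ <- which(m$arr < 0 & !is.na(idx))
  if (length(act) == 0 && length(rep_) == 0) return(NA_real_)
  prod(levels[idx[act]]) / prod(levels[idx[rep_]])
}

#' Per-gene signal table (audit trail)
#'
#' ECR, BTIF and supporting statistics for every gene and case sample, in
#' long format, so every pathway score can be traced back to the gene-level
#' evidence behind it.
#'
#' @param m expression matrix (already normalized as desired).
#' @param design a [group_design()].
#' @param policy a [tolerance_policy()].
#' @return data frame with columns `gene_id`, `sample_id`, `case_value`,
#'   `control_mean`, `control_sd`, `ecr`, `btif`, `log10_ecr`.
#' @export
gene_signals <- function(m, design, policy = tolerance_policy()) {
  m <- as_expression_matrix(unclass(m))
  validate_design(m, design, policy$min_control_n)
  cs <- control_stats(m, design, policy$min_control_n)
  pc <- resolve_pseudocount(policy, m)
  out <- lapply(design$case, function(s) {
    cv <- m[, s]
    ecr <- compute_ecr(cv, cs$control_mean, policy, pseudocount = pc)
    btif <- compute_btif(ecr, cv, cs$control_mean, cs$control_sd, policy)
    data.frame(gene_id = rownames(m), sample_id = s, case_value = cv,
               control_mean = cs$control_mean, control_sd = cs$control_sd,
               ecr = ecr, btif = btif, log10_ecr = log10(ecr),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pathway activation profile over all case samples
#'
#' Computes the PAS of every pathway for every case sample against the
#' control-group mean, then aggregates per pathway by the arithmetic mean
#' over case samples (with its sample SD). Pathway members absent from the
#' matrix are skipped and reported through the coverage columns; a pathway
#' with no measured member gets `NA` scores.
#'
#' @param m expression matrix (normalize first if desired; see
#'   [normalize_expression()]).
#' @param design a [group_design()].
#' @param db a [pathway_db()].
#' @param policy a [tolerance_policy()].
#' @return an object of class `"pas_profile"`: a list with
#'   \describe{
#'     \item{pas}{pathway-by-case-sample matrix of PAS values}
#'     \item{aggregate}{named vector, mean PAS per pathway}
#'     \item{sd}{named vector, sample SD across case samples (`NA` for a
#'       single case sample)}
#'     \item{n_members, n_measured}{pathway size and measured-member count}
#'     \item{policy, pseudocount}{the policy used and the resolved
#'       pseudocount}
#'   }
#' @export
pas_profile <- function(m, design, db, policy = tolerance_policy()) {
  m <- as_expression_matrix(unclass(m))
  assert_that(inherits(db, "pathway_db"), "'db' must be a pathway_db")
  validate_design(m, design, policy$min_control_n)
  cs <- control_stats(m, design, policy$min_control_n)
  pc <- resolve_pseudocount(policy, m)

  n_case <- length(design$case)
  # gene x case-sample matrix of gated log-ratios btif * log10(ecr)
  contrib <- matrix(0, nrow(m), n_case,
                    dimnames = list(rownames(m), design$case))
  for (s in design$case) {
    cv <- m[, s]
    ecr <- compute_ecr(cv, cs$control_mean, policy, pseudocount = pc)
    btif <- compute_btif(ecr, cv, cs$control_mean, cs$control_sd, policy)
    contrib[, s] <- btif * log10(ecr)
  }

  ids <- names(db)
  pas <- matrix(NA_real_, length(ids), n_case,
                dimnames = list(ids, design$case))
  n_members <- integer(length(ids))
  n_measured <- integer(length(ids))
  for (k in seq_along(ids)) {
    mem <- db[[k]]$members
    idx <- match(mem$gene_id, rownames(m))
    present <- !is.na(idx)
    n_members[k] <- nrow(mem)
    n_measured[k] <- sum(present)
    if (n_measured[k] > 0) {
      pas[k, ] <- colSums(contrib[idx[present], , drop = FALSE] *
                            mem$arr[present])
    }
  }
  aggregate <- rowMeans(pas)
  sds <- if (n_case > 1) apply(pas, 1, stats::sd) else
    stats::setNames(rep(NA_real_, length(ids)), ids)
  structure(list(pas = pas, aggregate = aggregate, sd = sds,
                 n_members = stats::setNames(n_members, ids),
                 n_measured = stats::setNames(n_measured, ids),
                 policy = policy, pseudocount = pc),
            class = "pas_profile")
}

#' @export
print.pas_profile <- function(x, ...) {
  cat("pas_profile:", nrow(x$pas), "pathways x", ncol(x$pas),
      "case samples\n")
  nz <- sum(x$aggregate != 0, na.rm = TRUE)
  cat("  pathways with nonzero aggregate PAS:", nz, "\n")
  if (any(is.na(x$aggregate))) {
    cat("  pathways with undefined PAS (no measured members):",
        sum(is.na(x$aggregate)), "\n")
  }
  invisible(x)
}

#' Flatten a PAS profile to a per-pathway data frame
#'
#' @param x a [pas_profile()].
#' @param ... unused.
#' @return data frame with pathway_id, coverage, per-sample PAS columns,
#'   aggregate and SD.
#' @export
as.data.frame.pas_profile <- function(x, ...) {
  df <- data.frame(pathway_id = rownames(x$pas),
                   n_members = unname(x$n_members),
                   n_measured = unname(x$n_measured),
                   stringsAsFactors = FALSE)
  pas <- as.data.frame(x$pas)
  colnames(pas) <- paste0("pas.", colnames(pas))
  df <- cbind(df, pas)
  df$aggregate_pas <- unname(x$aggregate)
  df$pas_sd <- unname(x$sd)
  rownames(df) <- NULL
  df
}

#' Build the signaling pathway cloud
#'
#' The cloud is the set of pathways whose aggregate PAS magnitude exceeds a
#' threshold, each labeled `activated` (PAS > 0) or `repressed` (PAS < 0),
#' sorted by descending |PAS| with ties broken by pathway id. Pathways with
#' undefined (NA) aggregates are excluded.
#'
#' @param profile a [pas_profile()].
#' @param threshold minimum |aggregate PAS| for inclusion (strict; default 0,
#'   i.e. any nonzero activation enters the cloud).
#' @return an object of class `"pathway_cloud"`: a data frame with columns
#'   `pathway_id`, `pas`, `label`, carrying the threshold as an attribute.
#'   May be empty.
#' @export
build_cloud <- function(profile, threshold = 0) {
  assert_that(inherits(profile, "pas_profile"),
              "'profile' must be a pas_profile")
  assert_that(is.numeric(threshold) && threshold >= 0,
              "'threshold' must be a non-negative number")
  agg <- profile$aggregate
  keep <- !is.na(agg) & abs(agg) > threshold
  df <- data.frame(pathway_id = names(agg)[keep], pas = unname(agg[keep]),
                   stringsAsFactors = FALSE)
  df$label <- ifelse(df$pas > 0, "activated", "repressed")
  df <- df[order(-abs(df$pas), df$pathway_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, threshold = threshold,
            class = c("pathway_cloud", "data.frame"))
}

#' Read a pathway cloud from TSV
#'
#' Expects columns `pathway_id`, `pas` (and optionally `label`); comment
#' lines starting `#` are skipped. Used to feed a precomputed target cloud
#' into the drug screen.
#'
#' @param path file path.
#' @param threshold threshold to record on the object (default 0).
#' @return a `"pathway_cloud"`.
#' @export
read_cloud <- function(path, threshold = 0) {
  df <- read_tsv_plain(path)
  assert_that(all(c("pathway_id", "pas") %in% colnames(df)),
              "cloud file must have columns 'pathway_id' and 'pas'")
  df <- df[, intersect(c("pathway_id", "pas"), colnames(df)), drop = FALSE]
  df$pas <- as.numeric(df$pas)
  assert_that(all(is.finite(df$pas)) && all(df$pas != 0),
              "cloud PAS values must be finite and nonzero")
  df$label <- ifelse(df$pas > 0, "activated", "repressed")
  df <- df[order(-abs(df$pas), df$pathway_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, threshold = threshold,
            class = c("pathway_cloud", "data.frame"))
}
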