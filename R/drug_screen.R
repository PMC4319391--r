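# Drug screening: each candidate drug carries its own pathway activation
# signature (computed from treated-vs-untreated expression, or supplied
# precomputed) and is scored against a target pathway cloud in one of three
# modes -- mimic (reproduce the cloud), minimize (reverse it) or exaggerate
# (amplify it beyond the target's own magnitude).

#' Construct a drug signature
#'
#' @param drug_id identifier.
#' @param pas named numeric vector: pathway id -> aggregate PAS. `NA`
#'   entries mark pathways where the drug's activation is undefined; they
#'   score as zero contribution but reduce the reported coverage.
#' @return an object of class `"drug_signature"`.
#' @export
drug_signature <- function(drug_id, pas) {
  assert_that(is.character(drug_id) && length(drug_id) == 1 &&
                nzchar(drug_id), "'drug_id' must be a non-empty string")
  assert_that(is.numeric(pas) && !is.null(names(pas)),
              "'pas' must be a named numeric vector")
  assert_that(all(is.finite(pas) | is.na(pas)),
              "signature PAS values must be finite or NA")
  structure(list(drug_id = drug_id, pas = pas), class = "drug_signature")
}

#' @export
print.drug_signature <- function(x, ...) {
  cat("drug_signature '", x$drug_id, "': ", sum(!is.na(x$pas)),
      " pathways with defined PAS (of ", length(x$pas), ")\n", sep = "")
  invisible(x)
}

#' Compute a drug's pathway activation signature from expression data
#'
#' Treated samples play the role of cases, untreated samples of controls;
#' the signature is the aggregate PAS vector of [pas_profile()].
#'
#' @param drug_id identifier.
#' @param m expression matrix for the drug experiment.
#' @param design a [group_design()] (case = treated, control = untreated).
#' @param db the shared [pathway_db()].
#' @param policy a [tolerance_policy()].
#' @param normalization `"quantile"` (default) or `"none"`, applied before
#'   profiling.
#' @return a [drug_signature()].
#' @export
drug_profile <- function(drug_id, m, design, db,
                         policy = tolerance_policy(),
                         normalization = c("quantile", "none")) {
  m <- normalize_expression(m, match.arg(normalization))
  prof <- pas_profile(m, design, db, policy)
  drug_signature(drug_id, prof$aggregate)
}

#' Read a precomputed drug signature from TSV
#'
#' Columns `pathway_id` and `pas`; comment lines starting `#` skipped.
#' Allows screening against external signature collections without their
#' raw expression data.
#'
#' @param path file path.
#' @param drug_id identifier; defaults to the file name without extension.
#' @return a [drug_signature()].
#' @export
read_drug_signature <- function(path, drug_id = NULL) {
  df <- read_tsv_plain(path)
  assert_that(all(c("pathway_id", "pas") %in% colnames(df)),
              "signature file must have columns 'pathway_id' and 'pas'")
  drug_id <- drug_id %||% sub("\\.[^.]*$", "", basename(path))
  drug_signature(drug_id,
                 stats::setNames(as.numeric(df$pas), df$pathway_id))
}

#' Load a drug library from a manifest
#'
#' The manifest is a TSV with either columns `drug_id`, `expr_path`,
#' `design_path` (signatures computed via [drug_profile()]) or columns
#' `drug_id`, `signature_path` (precomputed). Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest file path.
#' @param db [pathway_db()], required for the expression form.
#' @param policy,normalization passed to [drug_profile()].
#' @return named list of [drug_signature()] objects.
#' @export
read_drug_library <- function(path, db = NULL, policy = tolerance_policy(),
                              normalization = "quantile") {
  assert_that(file.exists(path), "drug manifest not found: ", path)
  man <- read_tsv_plain(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  assert_that("drug_id" %in% colnames(man),
              "drug manifest must have a 'drug_id' column")
  if ("signature_path" %in% colnames(man)) {
    sigs <- Map(function(id, p) read_drug_signature(resolve(p), id),
                man$drug_id, man$signature_path)
  } else {
    assert_that(all(c("expr_path", "design_path") %in% colnames(man)),
                "drug manifest needs either 'signature_path' or both ",
                "'expr_path' and 'design_path'")
    assert_that(inherits(db, "pathway_db"),
                "'db' is required to profile drug expression data")
    sigs <- Map(function(id, e, d) {
      drug_profile(id, read_expression_matrix(resolve(e)),
                   read_group_design(resolve(d)), db, policy, normalization)
    }, man$drug_id, man$expr_path, man$design_path)
  }
  stats::setNames(sigs, man$drug_id)
}

# Align a drug signature with the cloud's pathways: missing or NA entries
# become 0 (no contribution) and are excluded from coverage.
align_signature <- function(sig, cloud) {
  v <- sig$pas[match(cloud$pathway_id, names(sig$pas))]
  covered <- !is.na(v)
  v[!covered] <- 0
  list(v = unname(v), covered = covered)
}

#' Score one drug against a target pathway cloud
#'
#' Scoring is restricted to the cloud's pathways. Let `t` be the target PAS
#' vector over the cloud and `v` the drug's PAS over the same pathways
#' (zero where undefined). Modes:
#' \describe{
#'   \item{mimic}{cosine similarity of `v` and `t`, in [-1, 1]}
#'   \item{minimize}{cosine similarity of `v` and `-t` (reversal)}
#'   \item{exaggerate}{signed projection ratio `(v . t) / |t|^2`; values
#'     above 1 certify amplitude beyond the target's own}
#' }
#' With `weighted = TRUE` all inner products are weighted by `|t|`, so
#' strongly disturbed pathways dominate the match.
#'
#' @param sig a [drug_signature()].
#' @param cloud a non-empty [build_cloud()] result.
#' @param mode `"mimic"`, `"minimize"` or `"exaggerate"`.
#' @param weighted weight pathways by the magnitude of the target PAS.
#' @return list with `score`, `n_covered` (cloud pathways where the drug's
#'   PAS is defined), `coverage` (fraction), and `zero_signal` (`TRUE` when
#'   the drug shows no activation on any cloud pathway; score is 0).
#' @export
score_drug <- function(sig, cloud,
                       mode = c("mimic", "minimize", "exaggerate"),
                       weighted = FALSE) {
  mode <- match.arg(mode)
  assert_that(inherits(sig, "drug_signature"),
              "'sig' must be a drug_signature")
  assert_that(inherits(cloud, "pathway_cloud") && nrow(cloud) > 0,
              "'cloud' must be a non-empty pathway_cloud")
  t_vec <- cloud$pas
  al <- align_signature(sig, cloud)
  v <- al$v
  w <- if (weighted) abs(t_vec) else rep(1, length(t_vec))
  vt <- sum(w * v * t_vec)
  vv <- sum(w * v * v)
  tt <- sum(w * t_vec * t_vec)
  zero_signal <- vv == 0
  score <- if (zero_signal) {
    0
  } else {
    switch(mode,
           mimic = vt / sqrt(vv * tt),
           minimize = -vt / sqrt(vv * tt),
           exaggerate = vt / tt)
  }
  list(score = score, n_covered = sum(al$covered),
       coverage = mean(al$covered), zero_signal = zero_signal)
}

#' Rank a drug library against a target cloud
#'
#' Drugs are ordered by descending score; ties are broken lexicographically
#' by drug id; ranks are consecutive from 1.
#'
#' @param library named list of [drug_signature()] objects (or the result of
#'   [read_drug_library()]).
#' @param cloud a non-empty [build_cloud()] result.
#' @param mode,weighted see [score_drug()].
#' @return an object of class `"drug_ranking"`: a data frame with columns
#'   `rank`, `drug_id`, `score`, `n_covered`, `coverage`, `zero_signal`.
#' @export
rank_drugs <- function(library, cloud,
                       mode = c("mimic", "minimize", "exaggerate"),
                       weighted = FALSE) {
  mode <- match.arg(mode)
  assert_that(length(library) >= 1, "drug library is empty")
  rows <- lapply(library, function(sig) {
    s <- score_drug(sig, cloud, mode, weighted)
    data.frame(drug_id = sig$drug_id, score = s$score,
               n_covered = s$n_covered, coverage = s$coverage,
               zero_signal = s$zero_signal, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$score, df$drug_id), , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  structure(df, mode = mode, class = c("drug_ranking", "data.frame"))
}
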