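make_cloud <- function(pas) {
  df <- data.frame(pathway_id = names(pas), pas = unname(pas),
                   stringsAsFactors = FALSE)
  df$label <- ifelse(df$pas > 0, "activated", "repressed")
  df <- df[order(-abs(df$pas), df$pathway_id), ]
  rownames(df) <- NULL
  structure(df, threshold = 0, class = c("pathway_cloud", "data.frame"))
}

test_that("score modes behave on identity, antipodal and scaled drugs", {
  cloud <- make_cloud(c(P1 = 2, P2 = -1))
  t_sig <- drug_signature("t", c(P1 = 2, P2 = -1))
  expect_equal(score_drug(t_sig, cloud, "mimic")$score, 1)
  expect_equal(score_drug(t_sig, cloud, "minimize")$score, -1)
  expect_equal(score_drug(t_sig, cloud, "exaggerate")$score, 1)

  anti <- drug_signature("anti", c(P1 = -2, P2 = 1))
  expect_equal(score_drug(anti, cloud, "minimize")$score, 1)

  # doubled amplitude: mimic 1 (v.t = 10), exaggerate 10 / |t|^2 = 2
  dbl <- drug_signature("dbl", c(P1 = 4, P2 = -2))
  expect_equal(score_drug(dbl, cloud, "mimic")$score, 1)
  expect_equal(score_drug(dbl, cloud, "exaggerate")$score, 2)
})

test_that("mimic/minimize are scale-free; exaggerate scales linearly", {
  set.seed(3)
  cloud <- make_cloud(c(A = 1.5, B = -0.7, C = 2.2))
  for (rep in 1:20) {
    v <- stats::setNames(stats::rnorm(3), c("A", "B", "C"))
    s <- drug_signature("d", v)
    k <- stats::runif(1, 0.1, 10)
    sk <- drug_signature("d", k * v)
    expect_equal(score_drug(sk, cloud, "mimic")$score,
                 score_drug(s, cloud, "mimic")$score, tolerance = 1e-12)
    expect_equal(score_drug(sk, cloud, "exaggerate")$score,
                 k * score_drug(s, cloud, "exaggerate")$score,
                 tolerance = 1e-10)
    # mode duality: minimize(v, t) = mimic(v, -t)
    anti_cloud <- make_cloud(-c(A = 1.5, B = -0.7, C = 2.2))
    expect_equal(score_drug(s, cloud, "minimize")$score,
                 score_drug(s, anti_cloud, "mimic")$score,
                 tolerance = 1e-12)
  }
})

test_that("missing pathways score zero but reduce coverage", {
  cloud <- make_cloud(c(P1 = 2, P2 = -1, P3 = 1))
  sparse <- drug_signature("sp", c(P1 = 2, P9 = 5, P3 = NA_real_))
  s <- score_drug(sparse, cloud, "mimic")
  expect_equal(s$n_covered, 1)
  expect_equal(s$coverage, 1 / 3)
  expect_false(s$zero_signal)

  silent <- drug_signature("z", c(P1 = 0, P2 = 0))
  s0 <- score_drug(silent, cloud, "mimic")
  expect_true(s0$zero_signal)
  expect_equal(s0$score, 0)
})

test_that("ranking orders by score with deterministic tie-breaks", {
  cloud <- make_cloud(c(P1 = 2, P2 = -1))
  lib <- list(
    drug_signature("only", c(P1 = 0.1, P2 = 0.2)))
  r1 <- rank_drugs(lib, cloud, "mimic")
  expect_equal(r1$rank, 1L)

  # hand-computed cosines: t = (2, -1)
  lib3 <- list(
    b_match = drug_signature("b_match", c(P1 = 2, P2 = -1)),   # cos 1
    a_orth = drug_signature("a_orth", c(P1 = 1, P2 = 2)),      # cos 0
    c_part = drug_signature("c_part", c(P1 = 1, P2 = 0)))      # cos 2/sqrt(5)
  r <- rank_drugs(lib3, cloud, "mimic")
  expect_equal(r$drug_id, c("b_match", "c_part", "a_orth"))
  expect_equal(r$score, c(1, 2 / sqrt(5), 0), tolerance = 1e-12)
  expect_equal(r$rank, 1:3)

  # exact ties break lexicographically by drug id
  tied <- list(drug_signature("zeta", c(P1 = 2, P2 = -1)),
               drug_signature("alpha", c(P1 = 4, P2 = -2)))
  rt <- rank_drugs(tied, cloud, "mimic")
  expect_equal(rt$drug_id, c("alpha", "zeta"))
})

test_that("drug profiles recover the planted closed form", {
  # planted activation at fold f with noise-free data and constant controls:
  # every member passes the filter, PAS = (m_a + m_r) * log10(f)
  db <- simulate_pathway_db(n_pathways = 3, size_range = c(6, 6), seed = 9)
  spec <- simulation_spec(db, planted = c(PW001 = 10), biological_sd = 0,
                          seed = 9)
  sim <- simulate_experiment(spec)
  sig <- drug_profile("drug", sim$expression, sim$design, db,
                      normalization = "none")
  expect_equal(unname(sig$pas["PW001"]),
               unname(sim$truth$expected_pas["PW001"]), tolerance = 1e-6)
  # 6 members, log10(10) = 1 (pseudocount perturbs below 1e-6 relative)
  expect_equal(unname(sig$pas["PW001"]), 6 * 1, tolerance = 1e-6)
  expect_equal(unname(sig$pas[c("PW002", "PW003")]), c(0, 0))

  # treated identical to untreated -> all-zero signature
  null_spec <- simulation_spec(db, planted = NULL, biological_sd = 0,
                               seed = 9)
  null_sim <- simulate_experiment(null_spec)
  null_sig <- drug_profile("null", null_sim$expression, null_sim$design, db,
                           normalization = "none")
  expect_true(all(null_sig$pas == 0))

  # the signature does not depend on the drug id
  sig2 <- drug_profile("other_name", sim$expression, sim$design, db,
                       normalization = "none")
  expect_equal(unname(sig2$pas), unname(sig$pas))
})

test_that("signature and library TSV round trips work", {
  dir <- withr::local_tempdir()
  sig <- drug_signature("d1", c(P1 = 1.5, P2 = -0.5))
  utils::write.table(
    data.frame(pathway_id = names(sig$pas), pas = sig$pas),
    file.path(dir, "d1.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  sig2 <- read_drug_signature(file.path(dir, "d1.tsv"))
  expect_equal(sig2$drug_id, "d1")
  expect_equal(sig2$pas, sig$pas)

  utils::write.table(
    data.frame(drug_id = "d1", signature_path = "d1.tsv"),
    file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  lib <- read_drug_library(file.path(dir, "manifest.tsv"))
  expect_named(lib, "d1")
  expect_equal(lib$d1$pas, sig$pas)
})
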