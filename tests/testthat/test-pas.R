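test_that("tolerance policy defaults are the method's printed constants", {
  pol <- tolerance_policy()
  expect_identical(pol$fold_upper, 3 / 2)
  expect_identical(pol$fold_lower, 2 / 3)
  expect_identical(pol$sd_multiplier, 2)
  expect_error(tolerance_policy(fold_lower = 1.2), "fold bounds")
  expect_error(tolerance_policy(sd_multiplier = 0), "sd_multiplier")
})

test_that("ECR is the pseudocount-guarded case/control ratio", {
  pol <- tolerance_policy()
  expect_equal(compute_ecr(10, 10, pol), 1, tolerance = 1e-6)
  expect_equal(compute_ecr(20, 10, pol), 2, tolerance = 1e-6)
  r <- compute_ecr(5, 0, pol)
  expect_true(is.finite(r) && r > 1e3)  # zero denominator guarded
  expect_true(compute_ecr(0, 0, pol) == 1)
})

test_that("BTIF requires both the fold and the SD criterion", {
  pol <- tolerance_policy()
  # ecr inside [2/3, 3/2] never flags, whatever the deviation
  expect_identical(compute_btif(1.4, 140, 100, 1, pol), 0L)
  expect_identical(compute_btif(0.7, 70, 100, 1, pol), 0L)
  # fold criterion met but deviation only 1.5 SD -> no flag
  expect_identical(compute_btif(2.0, 103, 100, 2, pol), 0L)
  # both criteria met -> flag
  expect_identical(compute_btif(2.0, 106, 100, 2, pol), 1L)
  expect_identical(compute_btif(0.5, 94, 100, 2, pol), 1L)
  # zero control SD: any deviation counts as beyond two SDs
  expect_identical(compute_btif(2.0, 200, 100, 0, pol), 1L)
  expect_identical(compute_btif(1.0, 100, 100, 0, pol), 0L)
})

test_that("PAS sums signed gated log10 ratios over measured members", {
  pw <- pathway("P", c("A", "B"), c("act", "rep"))
  # all flags zero annihilate the score
  expect_equal(compute_pas(pw, c(A = 100, B = 0.01), c(A = 0, B = 0)), 0)
  # single activator with ECR 10 contributes exactly 1
  pw1 <- pathway("P1", "A", "act")
  expect_equal(compute_pas(pw1, c(A = 10), c(A = 1)), 1)
  # activator up 100x plus repressor down 100x: 2 + 2 = 4
  expect_equal(compute_pas(pw, c(A = 100, B = 0.01), c(A = 1, B = 1)), 4)
  # weighted roles scale their terms
  pwh <- pathway("PH", c("A", "B"), c("act", "rep"), weights = c(0.5, 1))
  expect_equal(compute_pas(pwh, c(A = 100, B = 0.01), c(A = 1, B = 1)), 3)
  # no measured member -> undefined, not zero
  expect_true(is.na(compute_pas(pw, c(Z = 2), c(Z = 1))))
})

test_that("SPCD is the activator/repressor product ratio", {
  pw <- pathway("P", c("A1", "A2", "R1"), c("act", "act", "rep"))
  expect_equal(compute_spcd(pw, c(A1 = 1, A2 = 1, R1 = 1)), 1)
  expect_equal(compute_spcd(pw, c(A1 = 10, A2 = 10, R1 = 2)), 50)
  expect_error(compute_spcd(pw, c(A1 = 0, A2 = 1, R1 = 1)),
               "strictly positive")
  neutral_only <- pathway("N", "X", "neu")
  expect_true(is.na(compute_spcd(neutral_only, c(X = 5))))
})

test_that("10^PAS equals SPCD on ECR inputs with unit roles and full flags", {
  pw <- pathway("P", c("A", "B"), c("act", "rep"))
  ecr <- c(A = 100, B = 0.01)
  pas <- compute_pas(pw, ecr, c(A = 1, B = 1))
  expect_equal(10^pas, compute_spcd(pw, ecr))
  expect_equal(compute_spcd(pw, ecr), 1e4)

  set.seed(11)
  for (rep in 1:50) {
    size <- sample(2:10, 1)
    roles <- sample(c("act", "rep"), size, replace = TRUE)
    genes <- sprintf("g%d", seq_len(size))
    pw <- pathway("RND", genes, roles)
    ecr <- stats::setNames(10^stats::runif(size, -2, 2), toupper(genes))
    pas <- compute_pas(pw, ecr, stats::setNames(rep(1, size), names(ecr)))
    spcd <- compute_spcd(pw, ecr)
    expect_equal(10^pas, spcd, tolerance = 1e-9)
  }
})

test_that("reciprocal ECRs negate PAS when only the fold criterion gates", {
  # the fold thresholds 3/2 and 2/3 are reciprocal, so flipping every ECR
  # to its reciprocal preserves each gene's fold flag and negates its term
  set.seed(23)
  for (rep in 1:30) {
    size <- sample(2:8, 1)
    genes <- toupper(sprintf("g%d", seq_len(size)))
    pw <- pathway("P", genes, sample(c("act", "rep"), size, replace = TRUE))
    ecr <- stats::setNames(10^stats::runif(size, -1, 1), genes)
    btif <- as.integer(ecr > 3 / 2 | ecr < 2 / 3)
    names(btif) <- genes
    expect_equal(compute_pas(pw, 1 / ecr, btif),
                 -compute_pas(pw, ecr, btif), tolerance = 1e-12)
  }
})

test_that("raising a case activator's expression never lowers the PAS", {
  set.seed(31)
  db <- pathway_db(list(pathway("P", c("A", "B", "C"),
                                c("act", "act", "rep"))))
  # a fixed pseudocount keeps "all else" truly fixed when one value moves
  pol <- tolerance_policy(pseudocount = 1e-12)
  for (rep in 1:40) {
    vals <- 10^stats::runif(15, 0.5, 2.5)
    m <- fixture_matrix(c("A", "B", "C"), case = vals[1:6],
                        control = vals[7:15])
    base <- pas_profile(m, fixture_design(), db, pol)
    bumped <- m
    bumped["A", "c1"] <- bumped["A", "c1"] * stats::runif(1, 1, 5)
    after <- pas_profile(as_expression_matrix(unclass(bumped)),
                         fixture_design(), db, pol)
    expect_gte(after$pas["P", "c1"], base$pas["P", "c1"] - 1e-12)
  }
})

test_that("profile aggregates per-sample scores over case samples", {
  db <- pathway_db(list(pathway("P", "A", "act")))
  # case values 100 and 1000 against constant controls of 10:
  # ECR 10 and 100, both flagged -> per-sample PAS 1 and 2
  m <- fixture_matrix("A", case = c(100, 1000), control = c(10, 10, 10))
  prof <- pas_profile(m, fixture_design(), db)
  expect_equal(unname(prof$pas["P", ]), c(1, 2), tolerance = 1e-6)
  expect_equal(unname(prof$aggregate["P"]), 1.5, tolerance = 1e-6)
  expect_equal(unname(prof$sd["P"]), stats::sd(c(1, 2)), tolerance = 1e-6)
  expect_equal(unname(prof$n_measured["P"]), 1L)

  # case identical to the control mean -> all PAS exactly 0
  m0 <- fixture_matrix("A", case = c(10, 10), control = c(8, 10, 12))
  prof0 <- pas_profile(m0, fixture_design(), db)
  expect_identical(unname(prof0$aggregate["P"]), 0)

  # pathway with no measured members is undefined, and reported as such
  db2 <- pathway_db(list(pathway("P", "A", "act"),
                         pathway("Q", "ZZZ", "act")))
  prof2 <- pas_profile(m, fixture_design(), db2)
  expect_true(is.na(prof2$aggregate["Q"]))
  expect_equal(unname(prof2$n_measured["Q"]), 0L)
})

test_that("profile is reproducible bit-for-bit on fixed inputs", {
  set.seed(5)
  db <- random_db()
  genes <- gene_universe(db)
  m <- matrix(10^stats::runif(length(genes) * 5, 0, 3), length(genes), 5,
              dimnames = list(genes, c("c1", "c2", "n1", "n2", "n3")))
  m <- as_expression_matrix(m)
  p1 <- pas_profile(m, fixture_design(), db)
  p2 <- pas_profile(m, fixture_design(), db)
  expect_identical(p1$pas, p2$pas)
  expect_identical(p1$aggregate, p2$aggregate)
})

test_that("cloud construction thresholds, labels and orders pathways", {
  db <- pathway_db(list(pathway("P1", "A", "act"),
                        pathway("P2", "B", "rep"),
                        pathway("P3", "C", "act")))
  fake_profile <- structure(list(
    pas = matrix(c(2, -1, 0.1), 3, 1,
                 dimnames = list(c("P1", "P2", "P3"), "c1")),
    aggregate = c(P1 = 2, P2 = -1, P3 = 0.1),
    sd = c(P1 = NA_real_, P2 = NA_real_, P3 = NA_real_),
    n_members = c(P1 = 1L, P2 = 1L, P3 = 1L),
    n_measured = c(P1 = 1L, P2 = 1L, P3 = 1L)),
    class = "pas_profile")
  cloud <- build_cloud(fake_profile, threshold = 0.5)
  expect_equal(cloud$pathway_id, c("P1", "P2"))
  expect_equal(cloud$label, c("activated", "repressed"))

  # threshold 0 admits every nonzero-PAS pathway
  cloud0 <- build_cloud(fake_profile, threshold = 0)
  expect_equal(nrow(cloud0), 3)

  # an all-zero profile gives an empty cloud
  zero <- fake_profile
  zero$aggregate[] <- 0
  expect_equal(nrow(build_cloud(zero)), 0)
})
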