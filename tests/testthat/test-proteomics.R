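test_that("shared peptide counts split proportionally to unique evidence", {
  peps <- data.frame(peptide_id = c("p1", "p2", "p3"),
                     protein_ids = c("A", "B", "A;B"),
                     bait_1 = c(4, 4, 2))
  prots <- data.frame(protein_id = c("A", "B"), length_aa = c(100, 200))
  d <- distributeSharedCounts(peps, prots)
  expect_equal(d["A", 1], 5)   # 4 + 2 * 4/8
  expect_equal(d["B", 1], 5)

  # uneven unique evidence
  peps$bait_1 <- c(6, 2, 4)
  d <- distributeSharedCounts(peps, prots)
  expect_equal(d["A", 1], 6 + 4 * 6 / 8)
  expect_equal(d["B", 1], 2 + 4 * 2 / 8)

  # no sharing: dSpC equals raw sums
  peps2 <- data.frame(peptide_id = c("p1", "p2", "p3"),
                      protein_ids = c("A", "A", "B"),
                      bait_1 = c(1, 2, 7))
  d2 <- distributeSharedCounts(peps2, prots)
  expect_equal(unname(d2[, 1]), c(3, 7))
})

test_that("shared peptide with no unique evidence splits equally", {
  peps <- data.frame(peptide_id = c("p1", "p2"),
                     protein_ids = c("A;B;C", "C"),
                     bait_1 = c(6, 0))
  prots <- data.frame(protein_id = c("A", "B", "C"),
                      length_aa = c(100, 100, 100))
  d <- distributeSharedCounts(peps, prots)
  expect_equal(unname(d[, 1]), c(2, 2, 2))
  expect_equal(sum(d[, 1]), sum(peps$bait_1))
})

test_that("unknown protein references are an input error", {
  peps <- data.frame(peptide_id = "p1", protein_ids = "A;Z", bait_1 = 1)
  prots <- data.frame(protein_id = "A", length_aa = 100)
  expect_error(distributeSharedCounts(peps, prots), "unknown")
  expect_error(computeDnsaf(matrix(1, 1, 1, dimnames = list("A", "r")),
                            data.frame(protein_id = "A", length_aa = 0)),
               "positive")
})

test_that("distribution matches the brute-force splitter and conserves totals", {
  for (s in 1:40) {
    inst <- random_peptide_instance(s)
    d <- distributeSharedCounts(inst$peptides, inst$proteins)
    expect_equal(d, oracle_distribute(inst$peptides, inst$proteins),
                 tolerance = 1e-12)
    raw <- colSums(inst$peptides[, grep("^bait", names(inst$peptides))])
    expect_true(all(abs(colSums(d) - raw) < 1e-9))
  }
})

test_that("dNSAF is length-normalized and sums to one per live replicate", {
  prots <- data.frame(protein_id = c("A", "B"), length_aa = c(100, 200))
  dspc <- matrix(c(5, 5, 0, 0), 2, 2,
                 dimnames = list(c("A", "B"), c("r1", "r2")))
  dn <- computeDnsaf(dspc, prots)
  expect_equal(dn["A", "r1"], 2 / 3)
  expect_equal(dn["B", "r1"], 1 / 3)
  expect_equal(unname(dn[, "r2"]), c(0, 0))   # all-zero replicate

  # single protein normalizes to 1; zero dSpC gives zero dNSAF
  one <- computeDnsaf(matrix(7, 1, 1, dimnames = list("A", "r")),
                      prots[1, ])
  expect_equal(unname(one[1, 1]), 1)
})

test_that("dNSAF is invariant to rescaling all counts in one replicate", {
  for (s in 1:10) {
    inst <- random_peptide_instance(s, n_rep = 2)
    se <- dnsafExperiment(inst$peptides, inst$proteins)
    scaled <- inst$peptides
    scaled$bait_2 <- scaled$bait_2 * 13
    se2 <- dnsafExperiment(scaled, inst$proteins)
    expect_equal(dNSAF(se)[, "bait_2"], dNSAF(se2)[, "bait_2"],
                 tolerance = 1e-12)
  }
})

test_that("DnsafExperiment validity catches inconsistent assays", {
  inst <- random_peptide_instance(1)
  se <- dnsafExperiment(inst$peptides, inst$proteins)
  expect_s4_class(se, "DnsafExperiment")
  expect_true(validObject(se))
  bad <- se
  SummarizedExperiment::assay(bad, "dNSAF")[1, 1] <-
    SummarizedExperiment::assay(bad, "dNSAF")[1, 1] + 0.5
  expect_error(validObject(bad))
})

test_that("averageNonzero follows the nonzero-replicates convention", {
  expect_equal(averageNonzero(c(0.02, 0, 0.04, 0.06)), 0.04)
  expect_equal(averageNonzero(c(0, 0, 0, 0)), 0)
  expect_equal(averageNonzero(rep(0.03, 4)), 0.03)
})

make_se <- function(bait, ctrl, len = NULL) {
  # build a DnsafExperiment directly from per-protein count matrices by
  # writing one unique peptide per protein
  n <- nrow(bait)
  ids <- sprintf("P%02d", seq_len(n))
  peps <- data.frame(peptide_id = sprintf("pep%02d", seq_len(n)),
                     protein_ids = ids)
  for (j in seq_len(ncol(bait))) peps[[sprintf("bait_%d", j)]] <- bait[, j]
  for (j in seq_len(ncol(ctrl)))
    peps[[sprintf("control_%d", j)]] <- ctrl[, j]
  if (is.null(len)) len <- rep(100, n)
  dnsafExperiment(peps, data.frame(protein_id = ids, length_aa = len))
}

test_that("enrichment fold, infinities and degenerate p values behave", {
  bait <- rbind(c(40, 40, 40, 40),
                c(10, 10, 10, 10),
                c(8, 9, 10, 11))
  ctrl <- rbind(c(10, 10, 10, 10),
                c(10, 10, 10, 10),
                c(0, 0, 0, 0))
  se <- make_se(bait, ctrl)
  res <- enrichmentTest(se)
  # fold is the ratio of nonzero-replicate dNSAF averages
  dn <- dNSAF(se)
  for (i in 1:2)
    expect_equal(res$fold_enrichment[i],
                 averageNonzero(dn[i, 1:4]) / averageNonzero(dn[i, 5:8]),
                 tolerance = 1e-12)
  # absent from control: infinite fold, capped for display, still tested
  expect_true(is.infinite(res$fold_enrichment[3]))
  expect_equal(res$log2_fold[3], 10)
  expect_equal(res$n_present_control[3], 0L)
  expect_lt(res$p_value[3], 0.05)

  # identical bait and control compositions: fold 1, p = 1
  same <- enrichmentTest(make_se(bait, bait))
  expect_equal(same$fold_enrichment, rep(1, 3), tolerance = 1e-12)
  expect_equal(same$p_value, rep(1, 3))

  # zero variance in both conditions: p limits 1 (equal) and 0 (apart)
  const_eq <- enrichmentTest(make_se(rbind(rep(10, 4), rep(30, 4)),
                                     rbind(rep(10, 4), rep(30, 4))))
  expect_true(all(const_eq$degenerate))
  expect_equal(const_eq$p_value, c(1, 1))
  const_ne <- enrichmentTest(make_se(rbind(rep(10, 4), rep(30, 4)),
                                     rbind(rep(30, 4), rep(10, 4))))
  expect_equal(const_ne$p_value, c(0, 0))
})

test_that("the Student t on replicate dNSAF values matches the textbook formula", {
  set.seed(41)
  bait <- matrix(rpois(40, 30), 10, 4)
  ctrl <- matrix(rpois(40, 12), 10, 4)
  se <- make_se(bait, ctrl)
  dn <- dNSAF(se)
  res <- enrichmentTest(se, zeros = "include")
  for (i in seq_len(nrow(dn))) {
    p_ref <- oracle_student(dn[i, 1:4], dn[i, 5:8])
    expect_equal(res$p_value[i], p_ref, tolerance = 1e-9)
  }
})

test_that("hit filter equals exhaustive clause evaluation on random rows", {
  set.seed(7)
  n <- 400
  fold <- sample(c(runif(n - 80, 0, 8), rep(Inf, 40), rep(3, 40)))
  pv <- sample(c(runif(n - 40), rep(0.05, 20), runif(20, 0, 1e-4)))
  pres <- sample(0:4, n, replace = TRUE)
  ctrl_abs <- is.infinite(fold)
  res <- S4Vectors::DataFrame(
    protein_id = sprintf("P%03d", seq_len(n)),
    avg_dnsaf_bait = ifelse(pres > 0, 0.01, 0),
    avg_dnsaf_control = ifelse(ctrl_abs, 0, 0.005),
    fold_enrichment = fold, p_value = pv,
    n_present_bait = pres)
  out <- callHits(res)
  exp <- mapply(oracle_hit, fold, pv, pres, ctrl_abs)
  expect_identical(out$is_hit, unname(exp))
  # boundary semantics: fold exactly at threshold passes, p at alpha fails
  expect_true(oracle_hit(3, 0.01, 4, FALSE))
  expect_false(oracle_hit(10, 0.05, 4, FALSE))
  expect_false(oracle_hit(10, 0.01, 2, TRUE))
  expect_error(callHits(res, pThreshold = 0), "pThreshold")
})

test_that("hit intersections partition the union of hits", {
  hits <- list(A = c("p1", "p2"), B = c("p2"))
  tab <- intersectHits(hits)
  expect_equal(tab$count[tab$baits == "A"], 1)
  expect_equal(tab$proteins[tab$baits == "A"], "p1")
  expect_equal(tab$count[tab$baits == "B"], 0)
  expect_equal(tab$count[tab$baits == "A&B"], 1)
  expect_equal(sum(tab$count), length(unique(unlist(hits))))

  # single bait and disjoint sets
  expect_equal(intersectHits(list(A = c("x", "y")))$count, 2)
  tab2 <- intersectHits(list(A = "x", B = "y", C = character(0)))
  expect_equal(sum(tab2$count[tab2$n_baits > 1]), 0)
  expect_equal(sum(tab2$count), 2)

  # partition property on random hit sets
  set.seed(11)
  hs <- lapply(1:4, function(i) sample(sprintf("g%02d", 1:30),
                                       sample(5:20, 1)))
  names(hs) <- paste0("bait", 1:4)
  tab3 <- intersectHits(hs)
  expect_equal(sum(tab3$count), length(unique(unlist(hs))))
  all_listed <- unlist(strsplit(tab3$proteins[tab3$proteins != ""], ";"))
  expect_setequal(all_listed, unique(unlist(hs)))
  expect_false(any(duplicated(all_listed)))
})

test_that("interaction tables round-trip, including the infinity sentinel", {
  bait <- rbind(c(40, 42, 38, 40), c(9, 10, 11, 10))
  ctrl <- rbind(c(0, 0, 0, 0), c(10, 10, 10, 10))
  se <- make_se(bait, ctrl)
  res <- callHits(enrichmentTest(se))
  dir <- withr::local_tempdir()
  paths <- exportInteractionTables(res, bait = "baitX", dir = dir)
  nodes <- readInteractionNodes(paths[["nodes"]])
  expect_equal(nodes$fold_enrichment, res$fold_enrichment)
  expect_true(is.infinite(nodes$fold_enrichment[1]))
  expect_equal(nodes$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(nodes$is_hit, res$is_hit)
  edges <- utils::read.delim(paths[["edges"]])
  expect_equal(nrow(edges), sum(res$is_hit))
  expect_equal(unique(edges$bait), "baitX")
})
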