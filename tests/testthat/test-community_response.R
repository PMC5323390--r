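test_that("OTU filtering removes organelles, Archaea, unclassified and singletons", {
  fx <- toy_otu_fixture()
  filt <- filter_otus(fx$counts, fx$taxonomy)
  expect_setequal(colnames(filt), c("OTU_A", "OTU_B", "OTU_pair"))
  rem <- attr(filt, "removed")
  expect_equal(rem$organelle, "OTU_chl")
  expect_equal(rem$archaea, "OTU_arc")
  expect_equal(rem$singleton, "OTU_single")
  # count 1 in each of two samples (dataset total 2) is retained
  expect_true("OTU_pair" %in% colnames(filt))
  # a table with nothing to remove passes through unchanged
  clean <- fx$counts[, c("OTU_A", "OTU_pair")]
  expect_equal(unclass(filter_otus(clean, fx$taxonomy))[, ],
               clean[, ], ignore_attr = TRUE)
  expect_error(filter_otus(fx$counts[, "OTU_chl", drop = FALSE],
                           fx$taxonomy), "no OTUs remain")
  expect_error(filter_otus(fx$counts[, c(1, 2)],
                           fx$taxonomy[-1]), "missing")
})

test_that("rarefied richness matches the hypergeometric closed form", {
  set.seed(21)
  counts <- matrix(as.integer(rmultinom(2, 5000,
                                        prob = rlnorm(50, 0, 1.5))),
                   nrow = 2, byrow = TRUE)
  colnames(counts) <- sprintf("T%02d", 1:50)
  rownames(counts) <- c("a", "b")
  res <- rarefied_alpha(counts, depth = 1000, repeats = 200, seed = 1)
  expected <- suppressWarnings(vegan::rarefy(counts, sample = 1000))
  # MC standard error of the mean richness
  for (i in 1:2) {
    reps <- suppressWarnings(
      replicate(50, sum(vegan::rrarefy(counts[i, , drop = FALSE],
                                       1000) > 0)))
    se <- sd(reps) / sqrt(200)
    expect_lt(abs(res$richness[i] - expected[i]), 3 * max(se, 0.05))
  }
})

test_that("rarefaction at full depth returns observed richness; uniform community invS -> S", {
  counts <- rbind(a = c(10L, 20L, 0L, 5L), b = c(1L, 1L, 1L, 32L))
  colnames(counts) <- paste0("T", 1:4)
  res <- rarefied_alpha(counts, depth = 35, repeats = 5, seed = 1)
  expect_equal(res$richness, unname(rowSums(counts > 0)))
  unif <- matrix(rep(500L, 20), nrow = 1,
                 dimnames = list("u", paste0("T", 1:20)))
  res_u <- rarefied_alpha(unif, depth = 9000, repeats = 20, seed = 2)
  expect_equal(res_u$inv_simpson, 20, tolerance = 0.01)
  expect_error(rarefied_alpha(counts, depth = 100), "shallower")
})

test_that("Bray-Curtis hand values and metric axioms hold", {
  x <- rbind(a = c(0.6, 0.4), b = c(0.4, 0.6), c = c(0.6, 0.4))
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["a", "b"], 0.2, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  disjoint <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 2, 5))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  set.seed(31)
  m <- matrix(rpois(60, 8), nrow = 6)
  m[1, ] <- m[1, ] + 1L
  dm <- as.matrix(bray_curtis(m))
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= 1))
  expect_error(bray_curtis(rbind(c(1, 2), c(0, 0))), "all-zero")
})

test_that("NMDS recovers simple geometries deterministically", {
  d3 <- matrix(1, 3, 3) - diag(3)
  rownames(d3) <- colnames(d3) <- c("a", "b", "c")
  fit <- nmds_embed(d3, seed = 1)
  emb <- as.numeric(dist(fit$points))
  expect_lt(diff(range(emb)) / mean(emb), 1e-3)
  # a configuration that perfectly preserves ranks embeds with ~zero stress
  set.seed(32)
  pts <- matrix(rnorm(20), ncol = 2)
  fit2 <- nmds_embed(dist(pts), seed = 2)
  expect_lt(fit2$stress, 0.01)
  fit3 <- nmds_embed(dist(pts), seed = 2)
  expect_identical(fit2$points, fit3$points)
  expect_error(nmds_embed(dist(pts[1:2, ])), "at least 3")
})

test_that("threshold clustering cuts the average-linkage tree as expected", {
  set.seed(33)
  # two tight blobs: within ~0.1, across ~0.9
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.1; d[4:6, 4:6] <- 0.1
  diag(d) <- 0
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  cl <- threshold_clusters(d, 0.7)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:3])), 1)
  expect_equal(length(unique(threshold_clusters(d, 1.0))), 1)
  expect_equal(length(unique(threshold_clusters(d, 0))), 6)
})

test_that("Mantel statistic behaves at its fixed points and under the null", {
  set.seed(34)
  m <- matrix(runif(49), 7, 7); m <- (m + t(m)) / 2; diag(m) <- 0
  res <- mantel_test(m, m, permutations = 99, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  # independent matrices: p should not concentrate near 0
  ps <- suppressWarnings(replicate(60, {
    a <- matrix(runif(36), 6, 6); a <- (a + t(a)) / 2; diag(a) <- 0
    b <- matrix(runif(36), 6, 6); b <- (b + t(b)) / 2; diag(b) <- 0
    mantel_test(a, b, permutations = 99)$p
  }))
  expect_gt(mean(ps > 0.2), 0.5)
  expect_error(mantel_test(m, m[1:5, 1:5]), "same sample")
})

test_that("clr instances are centred and converge to the closed-form clr", {
  counts <- rbind(s1 = c(1L, 1L, 1L, 1L), s2 = c(10L, 5L, 3L, 2L))
  colnames(counts) <- paste0("T", 1:4)
  ens <- clr_transform(counts, n_instances = 400, seed = 1)
  sums <- apply(ens$instances, c(1, 2), sum)
  expect_lt(max(abs(sums)), 1e-8)
  m1 <- colMeans(ens$instances[, "s1", ])
  expect_lt(max(abs(m1)), 0.3)  # symmetric prior, uniform counts; MC error
  # infinite-count limit: instance means -> clr of observed proportions
  big <- rbind(s = c(8e6L, 2e6L))
  colnames(big) <- c("A", "B")
  ens_big <- clr_transform(big, n_instances = 100, seed = 2)
  mb <- colMeans(ens_big$instances[, 1, ])
  expect_equal(unname(mb), c(1, -1), tolerance = 0.01)
  expect_error(clr_transform(rbind(a = c(0L, 0L))), "zero total")
})

test_that("effect sizes separate planted responders and are antisymmetric", {
  fx <- screen_fixture(n_taxa = 30, n_planted = 3, fold = 16,
                       depth = 1e4, seed = 51)
  ens <- clr_transform(fx$counts, n_instances = 64, seed = 3)
  eff <- effect_sizes(ens, fx$groupA, fx$groupB)
  planted <- eff[eff$taxon %in% fx$planted, ]
  expect_true(all(planted$diff > 3 & planted$diff < 5))
  expect_true(all(planted$effect > 4))
  # swapping the groups on the same ensemble negates diff and effect
  rev <- effect_sizes(ens, fx$groupB, fx$groupA)
  expect_equal(rev$diff, -eff$diff)
  expect_equal(rev$effect, -eff$effect)
  expect_error(effect_sizes(ens, fx$groupA[1], fx$groupB), "at least two")
})

test_that("identical groups yield near-zero effects", {
  set.seed(52)
  p <- rlnorm(30, 0, 1); p <- p / sum(p)
  counts <- t(vapply(1:6, function(i) as.integer(rmultinom(1, 1e4, p)),
                     integer(30)))
  rownames(counts) <- paste0("s", 1:6)
  colnames(counts) <- paste0("T", 1:30)
  ens <- clr_transform(counts, n_instances = 64, seed = 4)
  eff <- effect_sizes(ens, paste0("s", 1:3), paste0("s", 4:6))
  expect_lt(stats::median(abs(eff$diff)), 0.2)
  expect_lt(mean(abs(eff$effect) > 4), 0.05)
})

test_that("rDNA responder rules enforce prevalence and one-duplication thresholds", {
  eff <- data.frame(taxon = c("A", "B", "C", "D"),
                    diff = c(3, 0.5, -2.5, 2),
                    dispersion = c(0.3, 0.05, 0.3, 0.3),
                    effect = c(10, 10, -8, 2),
                    p_t = 0.01, p_t_bh = 0.02, p_w = 0.03,
                    infinite_effect = FALSE)
  prev <- c(A = 1, B = 3, C = 3, D = 3)
  res <- classify_responders_rdna(eff, prev)
  # A: huge effect but present in only 1/3 replicates
  expect_false(res$responder[res$taxon == "A"])
  # B: effect 10 but below one duplication
  expect_false(res$responder[res$taxon == "B"])
  # C: strong decrease passes, direction down
  expect_true(res$responder[res$taxon == "C"])
  expect_equal(res$direction[res$taxon == "C"], "down")
  # D: difference passes but effect below 4
  expect_false(res$responder[res$taxon == "D"])
})

test_that("rRNA screen applies the 1% abundance and twofold rules", {
  r0 <- c(A = 0.5, B = 3.0, C = 0.2, D = 0.0, E = 50)
  r23 <- c(A = 1.2, B = 2.0, C = 0.5, D = 1.5, E = 41)
  res <- classify_responders_rrna(r0, r23)
  expect_true(res$responder[res$taxon == "A"])
  expect_equal(res$direction[res$taxon == "A"], "up")
  expect_false(res$responder[res$taxon == "B"])   # ratio 0.67 within (0.5,2)
  expect_false("C" %in% res$taxon)                # never reaches 1%
  expect_true(res$responder[res$taxon == "D"])    # new appearance
  expect_equal(res$note[res$taxon == "D"], "new appearance")
  expect_false(res$responder[res$taxon == "E"])
})

test_that("family aggregation conserves counts and labels unclassified ranks", {
  counts <- rbind(s1 = c(5L, 7L, 2L, 1L), s2 = c(0L, 3L, 4L, 6L))
  colnames(counts) <- paste0("O", 1:4)
  tax <- c(O1 = "Bacteria;Proteobacteria;Gamma;Alteromonadales;Colwelliaceae;Colwellia",
           O2 = "Bacteria;Proteobacteria;Gamma;Alteromonadales;Colwelliaceae;Thalassomonas",
           O3 = "Bacteria;Proteobacteria;Gamma;Alteromonadales;;",
           O4 = "Bacteria;Proteobacteria;Gamma;Alteromonadales;unclassified;")
  fam <- aggregate_to_family(counts, tax)
  expect_true("Colwelliaceae" %in% colnames(fam))
  expect_equal(fam[, "Colwelliaceae"], c(s1 = 12, s2 = 3))
  expect_true("unclassified Alteromonadales" %in% colnames(fam))
  expect_equal(fam[, "unclassified Alteromonadales"], c(s1 = 3, s2 = 10))
  expect_equal(rowSums(fam), rowSums(counts))
})

test_that("Tukey letters separate distant groups and are order-invariant", {
  set.seed(61)
  vals <- c(rnorm(5, 100, 5), rnorm(5, 100, 5), rnorm(5, 10000, 5))
  grp <- rep(c("g1", "g2", "g3"), each = 5)
  res <- anova_tukey(vals, grp, transform = sqrt)
  # a group separated by hundreds of sd shares no letter with the others
  l3 <- strsplit(res$letters[["g3"]], "")[[1]]
  expect_false(any(l3 %in% strsplit(res$letters[["g1"]], "")[[1]]))
  expect_false(any(l3 %in% strsplit(res$letters[["g2"]], "")[[1]]))
  # invariance to group ordering (letters relabelled consistently)
  ord <- sample(length(vals))
  res2 <- anova_tukey(vals[ord], grp[ord], transform = sqrt)
  same1 <- outer(res$letters[grp], res$letters[grp],
                 Vectorize(function(a, b)
                   any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])))
  same2 <- outer(res2$letters[grp], res2$letters[grp],
                 Vectorize(function(a, b)
                   any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])))
  expect_equal(unname(same1), unname(same2))
})

test_that("statistically indistinguishable groups share a letter; degenerate data flagged", {
  set.seed(62)
  vals <- rnorm(15, 50, 5)
  grp <- rep(c("a", "b", "c"), each = 5)
  res <- anova_tukey(vals, grp, transform = identity)
  l <- res$letters
  expect_true(all(l == l[[1]]))
  expect_warning(res_d <- anova_tukey(rep(c(1, 2, 3), each = 3),
                                      rep(c("a", "b", "c"), each = 3),
                                      transform = identity),
                 "degenerate")
  expect_true(res_d$degenerate)
  expect_error(anova_tukey(1:4, c("a", "a", "a", "b")), "two replicates")
})
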