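test_that("initial filter applies strict score and read-support cutoffs", {
  calls <- rbind(
    mutRow(pos = 1, somatic_score = 10.0, dys_alt = 5L), # score boundary
    mutRow(pos = 2, somatic_score = 15, dys_alt = 2L),   # too few reads
    mutRow(pos = 3, somatic_score = 11, dys_alt = 3L),   # boundary pass
    mutRow(pos = 4, somatic_score = 30, scc_alt = 8L))
  out <- initialFilter(calls)
  expect_equal(out$pos, c(3, 4))
})

test_that("clonality model reproduces the triploid worked example", {
  expect_equal(clonalVafThreshold(0.5, 0.7, 3), 0.7 / 3 / 2)
  expect_equal(round(100 * clonalVafThreshold(0.5, 0.7, 3), 1), 11.7)
  # per-copy read contribution p / nT
  expect_equal(round(100 * clonalVafThreshold(1, 0.7, 3), 1), 23.3)
  expect_equal(clonalVafThreshold(1, 1, 2), 0.5)
  expect_identical(clonalVafThreshold(0.5, 1, 2), 0.25)
  expect_error(clonalVafThreshold(0.5, 0.7, 0), "copy number 0")
})

test_that("clonality threshold is linear in c and p, inverse in copy number", {
  for (c0 in c(0.2, 0.5, 1)) for (p0 in c(0.3, 0.7, 1)) {
    expect_equal(clonalVafThreshold(2 * c0 / 2, p0, 3),
                 clonalVafThreshold(c0, p0, 3))
    expect_equal(clonalVafThreshold(c0, p0, 6),
                 clonalVafThreshold(c0, p0, 3) / 2)
  }
  # the mixture variant dilutes by normal DNA instead
  expect_equal(clonalVafThreshold(0.5, 0.7, 3, model = "mixture"),
               0.5 * 0.7 / (0.7 * 3 + 2 * 0.3))
})

test_that("consequence whitelist keeps damaging coding changes only", {
  expect_true(passesEffectFilter("stop_gained"))
  expect_true(passesEffectFilter("frameshift_variant"))
  expect_true(passesEffectFilter("splice_donor_variant,intron_variant"))
  expect_true(passesEffectFilter("missense_variant", sift = "deleterious",
                                 polyphen = "benign"))
  expect_true(passesEffectFilter("missense_variant", sift = "tolerated",
                                 polyphen = "possibly_damaging"))
  expect_false(passesEffectFilter("missense_variant", sift = "tolerated",
                                  polyphen = "benign"))
  expect_false(passesEffectFilter("synonymous_variant"))
  expect_false(passesEffectFilter("missense_variant")) # no labels at all
  expect_equal(passesEffectFilter(c("stop_gained", "synonymous_variant")),
               c(TRUE, FALSE))
})

test_that("stringent filter combines clonality, score and consequence", {
  # SCC is triploid on 8q at purity 0.7: threshold there is 0.1167
  dys <- flatProfile("D", purity = 0.7)
  scc <- profileFromEvents("S", "8q_gain", purity = 0.7) # ratio 1.3 -> cn 3
  at8q <- 5e7
  calls <- rbind(
    mutRow(chrom = "8", pos = at8q, scc_alt = 12L, scc_depth = 100L,
           somatic_score = 20),                       # VAF 0.12 >= 0.1167
    mutRow(chrom = "8", pos = at8q + 1, dys_alt = 10L, dys_depth = 100L,
           scc_alt = 10L, scc_depth = 100L, somatic_score = 40), # VAF 0.10
    mutRow(chrom = "8", pos = at8q + 2, scc_alt = 40L, scc_depth = 100L,
           somatic_score = 30, consequence = "synonymous_variant",
           sift = NA, polyphen = NA),
    mutRow(chrom = "8", pos = at8q + 3, scc_alt = 12L, scc_depth = 100L,
           somatic_score = 15))                       # score boundary fails
  pair <- LesionPair("P", "D", "S", "HGD", "same_block", calls, dys, scc)
  out <- stringentFilter(pair)
  expect_equal(out$scc_cn, rep(3L, 4))
  expect_equal(out$dys_cn, rep(2L, 4))
  expect_equal(out$retained, c(TRUE, FALSE, FALSE, FALSE))
  # dysplasia threshold on flat diploid at 0.7 purity is 0.175
  expect_false(out$dys_pass[2])
})

test_that("filters are monotone in their thresholds", {
  p <- simulatePair(simulationConfig(seed = 81))
  raw <- mutations(p)
  sizes <- vapply(c(5, 10, 20, 40), function(s)
    nrow(initialFilter(raw, scoreMin = s)), 0L)
  expect_true(all(diff(sizes) <= 0))
  sizes <- vapply(c(1L, 3L, 5L, 10L), function(r)
    nrow(initialFilter(raw, minReads = r)), 0L)
  expect_true(all(diff(sizes) <= 0))
  retained <- vapply(c(0.3, 0.5, 0.8), function(cf)
    sum(stringentFilter(p, cellFrac = cf)$retained), 0L)
  expect_true(all(diff(retained) <= 0))
})

test_that("shared/private partition covers the retained set disjointly", {
  dys <- flatProfile("D", purity = 0.8)
  scc <- flatProfile("S", purity = 0.8) # thresholds 0.2 in both lesions
  calls <- rbind(
    mutRow(pos = 1, scc_alt = 30L, dys_alt = 4L, dys_depth = 100L),  # rescue
    mutRow(pos = 2, scc_alt = 30L, dys_alt = 0L),                    # scc only
    mutRow(pos = 3, dys_alt = 30L, scc_alt = 2L),                    # dys only
    mutRow(pos = 4, dys_alt = 30L, scc_alt = 25L))                   # both pass
  pair <- LesionPair("P", "D", "S", "HGD", "same_block", calls, dys, scc)
  part <- partitionShared(stringentFilter(pair))
  expect_equal(part$partition, c("shared", "scc_only", "dysplasia_only",
                                 "shared"))
  expect_true(all(table(part$partition) >= 0))
  expect_equal(nrow(part), sum(stringentFilter(pair)$retained))
})

test_that("simulated mutation pools land in their expected partitions", {
  nClonalShared <- 0; nClonal <- 0; nPrivOwn <- 0; nPriv <- 0
  for (s in 1:25) {
    p <- simulatePair(simulationConfig(seed = 200 + s, cnClass = 2))
    part <- partitionShared(stringentFilter(p))
    cl <- part[part$sim_pool == "clonal", ]
    nClonal <- nClonal + nrow(cl)
    nClonalShared <- nClonalShared + sum(cl$partition == "shared")
    pr <- part[part$sim_pool %in% c("private_dys", "private_scc"), ]
    nPriv <- nPriv + nrow(pr)
    nPrivOwn <- nPrivOwn +
      sum((pr$sim_pool == "private_dys" &
             pr$partition == "dysplasia_only") |
          (pr$sim_pool == "private_scc" & pr$partition == "scc_only"))
  }
  expect_gt(nClonal, 500)
  expect_gte(nClonalShared / nClonal, 0.95)
  if (nPriv > 0) expect_gte(nPrivOwn / nPriv, 0.95)
})

test_that("gene-set tallies intersect partitions with shared precedence", {
  tl <- genesetTally(list(dysplasia_only = "TP53",
                          shared = c("TP53", "NOTCH1"),
                          scc_only = character()), curated = "TP53")
  expect_equal(unname(tl$counts), c(0L, 1L, 0L))
  expect_true(tl$presence$dysplasia_only[tl$presence$gene == "TP53"])
  tl2 <- genesetTally(list(dysplasia_only = "A", shared = "B",
                           scc_only = "C"), curated = c("X", "Y"))
  expect_equal(unname(tl2$counts), c(0L, 0L, 0L))
  expect_error(genesetTally(list(), character()), "empty")
  expect_equal(compareSharedProportions(50, 100, 50, 100), 1)
})
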