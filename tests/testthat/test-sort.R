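# Query ordering/orientation along the reference and the association
# table.

test_that("assignment picks the target with most aligned bases, ties by catalog order", {
  query <- SequenceCatalog(c("q1", "q2"), c(1000, 1000))
  target <- SequenceCatalog(c("t1", "t2"), c(5000, 5000))
  m <- matchTable(qname = c("q1", "q1", "q2", "q2"),
                  qlen = 1000, qstart = c(0, 0, 0, 0),
                  qend = c(300, 600, 400, 400), strand = "+",
                  tname = c("t1", "t2", "t1", "t2"), tlen = 5000,
                  tstart = c(0, 0, 0, 0),
                  tend = c(300, 600, 400, 400),
                  nmatch = c(250, 500, 300, 300),
                  blocklen = c(300, 600, 400, 400))
  plan <- computeSortPlan(buildDotPlot(m, query, target))
  at <- setNames(plan@assignedTargets, plan@queries)
  expect_equal(unname(at["q1"]), "t2")   # more aligned bases on t2
  expect_equal(unname(at["q2"]), "t1")   # tie -> first target in catalog
})

test_that("orientation follows the strand carrying the majority of aligned bases", {
  query <- SequenceCatalog("q1", 1000)
  target <- SequenceCatalog("t1", 5000)
  m <- matchTable(qname = "q1", qlen = 1000, qstart = c(0, 500),
                  qend = c(500, 800), strand = c("-", "+"),
                  tname = "t1", tlen = 5000, tstart = c(0, 1000),
                  tend = c(500, 1300), nmatch = c(400, 250),
                  blocklen = c(500, 300))
  plan <- computeSortPlan(buildDotPlot(m, query, target))
  expect_equal(plan@orientations, "reverse")  # 500 reverse vs 300 forward
  # equal masses -> forward
  m$blocklen <- c(300, 300); m$nmatch <- c(200, 200)
  m$qend <- c(300, 800); m$tend <- c(300, 1300)
  m$identity <- m$nmatch / m$blocklen
  plan2 <- computeSortPlan(buildDotPlot(m, query, target))
  expect_equal(plan2@orientations, "forward")
})

test_that("queries order by weighted target midpoint; unaligned go last", {
  query <- SequenceCatalog(c("late", "early", "lost"), c(1000, 1000, 500))
  target <- SequenceCatalog("t1", 10000)
  m <- matchTable(qname = c("late", "early"), qlen = 1000,
                  qstart = 0, qend = 200, strand = "+", tname = "t1",
                  tlen = 10000, tstart = c(4900, 0), tend = c(5100, 200),
                  nmatch = 150, blocklen = 200)
  plan <- computeSortPlan(buildDotPlot(m, query, target))
  expect_equal(plan@queries, c("early", "late", "lost"))
  expect_true(is.na(plan@assignedTargets[3]))
  tab <- associationTable(plan)
  expect_equal(tab$Target, c("t1", "t1", "None"))
  expect_equal(tab$Query, plan@queries)
})

test_that("applySort mirrors reversed queries and unsort is an exact inverse", {
  fx <- fixturePlot(rearrangementPlan(seed = 21, nFragments = 10,
                                      identity = 0.95))
  plot <- fx$plot
  before <- plotMatches(plot)
  sorted <- applySort(plot)
  expect_true(sorted@sorted)
  # totals conserved
  after <- plotMatches(sorted)
  expect_equal(nrow(after), nrow(before))
  expect_equal(sum(after$nmatch), sum(before$nmatch))
  expect_equal(sum(after$blocklen), sum(before$blocklen))
  expect_equal(sort(after$identity), sort(before$identity))
  restored <- unsort(sorted)
  expect_equal(plotMatches(restored), before)
  expect_equal(names(queryCatalog(restored)), names(queryCatalog(plot)))
  expect_false(restored@sorted)
  # sorting twice is stable
  expect_equal(plotMatches(applySort(sorted)), after)
})

test_that("sort recovers a planted permutation and reversal set", {
  for (seed in c(31, 32, 33)) {
    plan0 <- rearrangementPlan(seed = seed, nFragments = 15,
                               fragmentLength = 500, identity = 0.93)
    fx <- fixturePlot(plan0)
    plan <- computeSortPlan(fx$plot)
    expected_order <- sprintf("frag_%02d", order(plan0$permutation))
    expect_equal(plan@queries, expected_order, info = paste("seed", seed))
    expected_rev <- sprintf("frag_%02d",
                            which(plan0$permutation %in% plan0$reversed))
    expect_setequal(plan@queries[plan@orientations == "reverse"],
                    expected_rev)
  }
})

test_that("reverseQuery mirrors one query and is an involution", {
  query <- SequenceCatalog("q1", 100)
  target <- SequenceCatalog("t1", 100)
  m <- matchTable(qname = "q1", qlen = 100, qstart = 0, qend = 10,
                  strand = "+", tname = "t1", tlen = 100, tstart = 0,
                  tend = 10, nmatch = 10, blocklen = 10)
  plot <- buildDotPlot(m, query, target)
  r1 <- reverseQuery(plot, "q1")
  expect_equal(plotMatches(r1)$qstart, 90)
  expect_equal(plotMatches(r1)$qend, 100)
  expect_equal(plotMatches(r1)$strand, "-")
  r2 <- reverseQuery(r1, "q1")
  expect_equal(plotMatches(r2), plotMatches(plot))
  expect_length(r2@reversedQueries, 0)
  expect_error(reverseQuery(plot, "nope"), "unknown query")
  # query with no matches: a no-op on the match table
  q2 <- SequenceCatalog(c("q1", "empty"), c(100, 50))
  plot2 <- buildDotPlot(m, q2, target)
  expect_equal(plotMatches(reverseQuery(plot2, "empty")),
               plotMatches(plot2))
})

test_that("a plan must cover the query catalog", {
  caps <- toyCatalogs()
  m <- randomMatches(5, caps$query, caps$target, seed = 3)
  plot <- buildDotPlot(m, caps$query, caps$target)
  other <- buildDotPlot(m[m$qname == "q1", , drop = FALSE],
                        SequenceCatalog("q1", 1000), caps$target)
  bad_plan <- computeSortPlan(other)
  expect_error(applySort(plot, bad_plan), "cover")
})
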