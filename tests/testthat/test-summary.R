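# Included-match removal and the reference identity profile, checked
# against a literal per-base array oracle.

test_that("removeIncluded drops strictly contained reference intervals", {
  base <- matchTable(qname = c("a", "b"), qlen = 1000, qstart = c(0, 0),
                     qend = c(100, 250), strand = "+", tname = "t1",
                     tlen = 1000, tstart = c(100, 50), tend = c(200, 300),
                     nmatch = c(90, 200), blocklen = c(100, 250))
  out <- removeIncluded(base)            # A = 100-200 inside B = 50-300
  expect_equal(out$qname, "b")
  # disjoint intervals both kept
  disjoint <- base; disjoint$tstart <- c(0, 500); disjoint$tend <- c(100, 750)
  expect_equal(nrow(removeIncluded(disjoint)), 2)
  # same interval on different targets: no containment
  other <- base; other$tname <- c("t1", "t2"); other$tstart <- c(100, 100)
  other$tend <- c(200, 200)
  expect_equal(nrow(removeIncluded(other)), 2)
})

test_that("equal intervals keep the higher identity, first on ties", {
  m <- matchTable(qname = c("a", "b"), qlen = 1000, qstart = 0, qend = 100,
                  strand = "+", tname = "t1", tlen = 1000, tstart = 100,
                  tend = 200, nmatch = c(50, 90), blocklen = 100)
  out <- removeIncluded(m)
  expect_equal(out$identity, 0.9)
  tie <- m; tie$nmatch <- c(70, 70); tie$identity <- 0.7
  expect_equal(removeIncluded(tie)$qname, "a")
})

test_that("removeIncluded agrees with a pairwise containment oracle", {
  caps <- toyCatalogs()
  for (seed in 1:8) {
    m <- randomMatches(40, caps$query, caps$target, seed = 60 + seed)
    kept <- removeIncluded(m)
    # oracle: quadratic scan for containment / duplicate-interval rule
    n <- nrow(m)
    drop <- logical(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || m$tname[i] != m$tname[j]) next
      same <- m$tstart[i] == m$tstart[j] && m$tend[i] == m$tend[j]
      if (same) {
        if (m$identity[j] > m$identity[i] ||
            (m$identity[j] == m$identity[i] && j < i)) drop[i] <- TRUE
      } else if (m$tstart[j] <= m$tstart[i] && m$tend[i] <= m$tend[j]) {
        drop[i] <- TRUE
      }
    }
    expect_equal(kept, m[!drop, ], ignore_attr = TRUE,
                 info = paste("seed", seed))
  }
})


test_that("the worked single-match profile is exact", {
  q <- SequenceCatalog("q1", 1000); t <- SequenceCatalog("t1", 1000)
  m <- matchTable(qname = "q1", qlen = 1000, qstart = 0, qend = 500,
                  strand = "+", tname = "t1", tlen = 1000, tstart = 0,
                  tend = 500, nmatch = 450, blocklen = 500)
  p <- summaryProfile(buildDotPlot(m, q, t))
  f <- profileFractions(p)
  expect_equal(unname(f["class4"]), 0.5)
  expect_equal(unname(f["no_match"]), 0.5)
  expect_equal(unname(f[c("class1", "class2", "class3")]), rep(0, 3))
})

test_that("overlapping matches attribute each base to the highest class", {
  q <- SequenceCatalog("q1", 1000); t <- SequenceCatalog("t1", 1000)
  m <- matchTable(qname = c("q1", "q1"), qlen = 1000, qstart = c(0, 0),
                  qend = c(600, 600), strand = "+", tname = "t1",
                  tlen = 1000, tstart = c(0, 400), tend = c(600, 1000),
                  nmatch = c(360, 540), blocklen = 600)   # ids 0.6, 0.9
  f <- profileFractions(summaryProfile(buildDotPlot(m, q, t)))
  expect_equal(unname(f["class3"]), 0.4)
  expect_equal(unname(f["class4"]), 0.6)
  expect_equal(unname(f["no_match"]), 0)
})

test_that("empty plots are entirely no_match and fractions always sum to 1", {
  caps <- toyCatalogs()
  empty <- summaryProfile(buildDotPlot(matchTable(), caps$query, caps$target))
  expect_equal(unname(profileFractions(empty)["no_match"]), 1)
  for (seed in 1:10) {
    m <- randomMatches(sample(5:80, 1), caps$query, caps$target,
                       seed = 80 + seed)
    f <- profileFractions(summaryProfile(buildDotPlot(m, caps$query,
                                                      caps$target)))
    expect_equal(sum(f), 1)
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("interval implementation agrees with the per-base oracle", {
  caps <- toyCatalogs(qlens = c(q1 = 5000, q2 = 4000),
                      tlens = c(t1 = 8000, t2 = 6000))
  for (seed in 1:6) {
    m <- randomMatches(50, caps$query, caps$target, seed = 90 + seed)
    plot <- buildDotPlot(m, caps$query, caps$target)
    expect_equal(unname(profileFractions(summaryProfile(plot))),
                 unname(perBaseProfile(plot)), info = paste("seed", seed))
  }
})

test_that("adding a match never increases no_match; the plot is untouched", {
  caps <- toyCatalogs()
  # keep the pipeline's noise filter inert (N < 20) so coverage growth
  # is the only effect of adding matches
  m <- randomMatches(12, caps$query, caps$target, seed = 77)
  plot <- buildDotPlot(m, caps$query, caps$target)
  before <- plotMatches(plot)
  f1 <- profileFractions(summaryProfile(plot))
  expect_equal(plotMatches(plot), before)       # working-copy semantics
  extra <- randomMatches(6, caps$query, caps$target, seed = 78)
  f2 <- profileFractions(summaryProfile(buildDotPlot(rbind(m, extra),
                                                     caps$query,
                                                     caps$target)))
  expect_lte(f2[["no_match"]], f1[["no_match"]])
})

test_that("profile serializers write valid JSON and TSV", {
  caps <- toyCatalogs()
  m <- randomMatches(20, caps$query, caps$target, seed = 55)
  p <- summaryProfile(buildDotPlot(m, caps$query, caps$target))
  js <- tempfile(fileext = ".json"); writeSummaryJson(p, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$total_reference, sum(catalogLengths(caps$target)))
  tsv <- tempfile(fileext = ".tsv"); writeSummaryTsv(p, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 5)
  expect_equal(sum(tab$percent), 100)
})
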