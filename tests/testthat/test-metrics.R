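test_that("confusion counts equal element-wise membership counting", {
  expect_equal(confusion_counts(c("A", "B"), c("A", "B")),
               c(tp = 2, fp = 0, fn = 0))
  expect_equal(confusion_counts(c("A", "B", "C"), c("B", "C", "D")),
               c(tp = 2, fp = 1, fn = 1))
  set.seed(11)
  pool <- sprintf("g%03d", 1:400)
  for (i in 1:20) {
    rec <- sample(pool, sample(0:200, 1))
    grd <- sample(pool, sample(1:200, 1))
    cc <- confusion_counts(rec, grd)
    expect_equal(cc[["tp"]], sum(vapply(rec, `%in%`, logical(1), grd)))
    expect_equal(cc[["fp"]], sum(!vapply(rec, `%in%`, logical(1), grd)))
    expect_equal(cc[["fn"]], sum(!vapply(grd, `%in%`, logical(1), rec)))
    # conservation with derived tn over the pool universe
    tn <- length(setdiff(pool, union(rec, grd)))
    expect_equal(cc[["tp"]] + cc[["fp"]] + cc[["fn"]] + tn, length(pool))
  }
})

test_that("precision/recall and F obey their algebraic identities", {
  pr <- precision_recall(2, 1, 1)
  expect_equal(unname(pr), c(2/3, 2/3))
  expect_warning(pr0 <- precision_recall(0, 0, 5), "empty recovered")
  expect_equal(unname(pr0), c(0, 0))

  set.seed(7)
  for (i in 1:30) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp == 0) fp <- 1
    pr <- precision_recall(tp, fp, fn)
    expect_equal(pr[["precision"]] * (tp + fp), tp)
    P <- pr[["precision"]]; R <- pr[["recall"]]
    f <- f_measure(P, R)
    expect_gte(f, 0)
    expect_lte(f, max(P, R) + 1e-15)
    expect_lte(f, (P + R) / 2 + 1e-15) # harmonic <= arithmetic
  }
  expect_equal(f_measure(0, 0), 0)
  for (x in c(0.1, 0.5, 1)) expect_equal(f_measure(x, x), x)
})

test_that("F-measure reproduces published benchmark arithmetic", {
  expect_equal(round(f_measure(0.498, 0.480), 3), 0.489)
  expect_equal(round(f_measure(0.931, 0.181), 3), 0.303)
})

test_that("fold enrichment matches its formula and invariances", {
  expect_equal(round(fold_enrichment(46, 246, 5335, 400), 3), 2.494)
  expect_equal(round(fold_enrichment(95, 539, 5335, 400), 2), 2.35)
  # selecting the whole network and recovering the whole reference
  expect_equal(fold_enrichment(400, 5335, 5335, 400), 1)
  expect_error(fold_enrichment(5, 0, 100, 10), "undefined")

  # scale invariance in both pairings
  set.seed(3)
  for (i in 1:10) {
    r <- sample(1:50, 1); s <- sample(50:500, 1)
    N <- sample(1000:9000, 1); R <- sample(100:800, 1); c <- sample(2:9, 1)
    fe <- fold_enrichment(r, s, N, R)
    expect_equal(fold_enrichment(r * c, s, N, R * c), fe)
    expect_equal(fold_enrichment(r, s * c, N * c, R), fe)
  }
})

test_that("evaluate fills a complete report row per method", {
  net <- graph_from_pairs(c("A-B", "B-C", "C-D", "D-E", "B-E"))
  g0 <- c("A", "B", "C")
  res <- subnetwork_result("demo", c("B", "C", "D"), net)
  expect_equal(nrow(res$edges), 2) # B-C and C-D induced

  rep1 <- evaluate(res, ground = g0, reference = c("C", "D", "E"),
                   n_network = igraph::vcount(net))
  expect_equal(rep1$tp, 2)
  expect_equal(rep1$fp, 1)
  expect_equal(rep1$fn, 1)
  expect_equal(rep1$precision, 2/3)
  expect_equal(rep1$recall, 2/3)
  expect_equal(rep1$f_measure, 2/3)
  expect_equal(rep1$recovered_in_reference, 2)
  expect_equal(rep1$fold_enrichment, 2 * 5 / (3 * 3))

  # empty selection: zeros, with a warning, enrichment undefined
  expect_warning(
    rep0 <- evaluate(subnetwork_result("none", character(0)),
                     ground = g0, reference = c("C"), n_network = 5),
    "empty")
  expect_equal(rep0$tp, 0)
  expect_equal(rep0$precision, 0)
  expect_true(is.na(rep0$fold_enrichment))

  # a batch of mock results matches per-column recomputation
  set.seed(19)
  nodes <- igraph::V(net)$name
  rows <- do.call(rbind, lapply(1:11, function(i) {
    sel <- sample(nodes, sample(1:5, 1))
    evaluate(subnetwork_result(paste0("m", i), sel, net), ground = g0,
             n_network = 5)
  }))
  for (i in 1:11) {
    expect_equal(rows$tp[i] + rows$fp[i], rows$selected[i])
    expect_equal(rows$tp[i] + rows$fn[i], length(g0))
    with_pr <- precision_recall(rows$tp[i], rows$fp[i], rows$fn[i])
    expect_equal(rows$precision[i], with_pr[["precision"]])
    expect_equal(rows$f_measure[i],
                 f_measure(with_pr[["precision"]], with_pr[["recall"]]))
  }

  # selected nodes outside the network are rejected at construction
  expect_error(subnetwork_result("bad", c("A", "ZZ"), net), "not in the")
})

test_that("external result files score with unknown-gene exclusion", {
  net <- graph_from_pairs(c("A-B", "B-C", "C-D"))
  g0 <- c("A", "B")
  perfect <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A", "B"), perfect)
  partial <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("B", "C", "NOT_A_GENE"), partial)
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)

  rep1 <- evaluate_external(c(perfect = perfect), net, ground = g0)
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$recall, 1)
  expect_equal(rep1$f_measure, 1)

  expect_warning(rep2 <- evaluate_external(c(p = partial), net, ground = g0),
                 "not in the network")
  expect_equal(rep2$selected, 2)
  expect_equal(rep2$tp, 1)

  expect_warning(rep3 <- evaluate_external(c(e = empty), net, ground = g0),
                 "empty")
  expect_equal(rep3$selected, 0)
  expect_equal(rep3$precision, 0)
})

test_that("evaluation tables write rounded TSV rows", {
  net <- graph_from_pairs(c("A-B", "B-C"))
  rep1 <- evaluate(subnetwork_result("m", c("A", "B"), net),
                   ground = c("A", "C"), n_network = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_eval_table(rep1, path)
  back <- read.delim(path)
  expect_equal(back$precision, 0.5)
  expect_equal(back$f_measure, 0.5)
  expect_equal(back$method, "m")
})
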