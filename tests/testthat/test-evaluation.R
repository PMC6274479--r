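# A constructed 1000-molecule ranking with 50 actives, 4 of them in the top
# 10, used by several metric checks (matches the k = 10 selection at 1%).
constructed_ranking <- function() {
  ids <- sprintf("m%04d", 1:1000)
  actives <- c(ids[c(1, 3, 7, 10)], ids[101:146])
  list(r = make_ranking(ids, seq(1, 0.001, length.out = 1000)),
       actives = actives)
}

test_that("recall_at_cutoff matches brute-force counting", {
  cr <- constructed_ranking()
  expect_identical(recall_at_cutoff(cr$r, cr$actives, 1), 8.0)  # 4/50
  expect_identical(recall_at_cutoff(cr$r, cr$actives, 1),
                   oracle_recall(cr$r$ids, cr$actives, 1))
  expect_identical(recall_at_cutoff(cr$r, cr$actives, 5),
                   oracle_recall(cr$r$ids, cr$actives, 5))
  # perfect ranking with |actives| <= k retrieves everything
  ids <- sprintf("m%02d", 1:50)
  perfect <- make_ranking(ids, 50:1)
  expect_identical(recall_at_cutoff(perfect, ids[1:5], 10), 100.0)
  # no actives in the top k
  expect_identical(recall_at_cutoff(perfect, ids[41:50], 10), 0.0)
  expect_error(recall_at_cutoff(perfect, character(0), 10), "non-empty")
  expect_error(recall_at_cutoff(perfect, ids[1], 0), "\\(0, 100\\]")
})

test_that("recall is monotone non-decreasing in the cutoff", {
  withr::with_seed(71, {
    ids <- sprintf("m%03d", 1:200)
    for (rep in 1:5) {
      r <- make_ranking(sample(ids), seq(1, 0, length.out = 200))
      act <- sample(ids, 30)
      recalls <- vapply(c(0.5, 1, 2, 5, 10, 50, 100),
                        function(p) recall_at_cutoff(r, act, p), numeric(1))
      expect_true(all(diff(recalls) >= 0))
      expect_identical(recalls[length(recalls)], 100.0)
    }
  })
})

test_that("sensitivity and specificity count the confusion matrix", {
  ids <- sprintf("m%02d", 1:10)
  r <- make_ranking(ids, 10:1)
  act <- ids[c(1, 2, 5)]
  ss <- sensitivity_specificity(r, act, k = 4)
  expect_equal(unname(ss), c(2 / 3, 5 / 7), tolerance = 1e-15)
  expect_equal(unname(sensitivity_specificity(r, act, k = 10)), c(1, 0))
  expect_equal(unname(sensitivity_specificity(r, act, k = 0)), c(0, 1))
  expect_error(sensitivity_specificity(r, ids, k = 2), "no inactives")
})

test_that("roc_auc matches the Mann-Whitney oracle, with and without ties", {
  withr::with_seed(83, {
    ids <- sprintf("m%03d", 1:100)
    for (rep in 1:10) {
      sc <- round(runif(100), rep %% 3)  # coarse rounding forces ties
      o <- order(-sc, ids, method = "radix")
      r <- make_ranking(ids[o], sc[o])
      act <- sample(ids, 20)
      expect_equal(roc_auc(r, act)$auc,
                   oracle_auc(sc, ids %in% act), tolerance = 1e-10)
    }
  })
})

test_that("roc_auc hits its exact anchors and the reversal identity", {
  ids <- sprintf("m%02d", 1:20)
  r <- make_ranking(ids, 20:1)
  expect_identical(roc_auc(r, ids[1:5])$auc, 1.0)   # actives on top
  expect_identical(roc_auc(r, ids[16:20])$auc, 0.0) # actives at the bottom
  withr::with_seed(89, {
    sc <- runif(20)
    o <- order(-sc, ids, method = "radix")
    fwd <- make_ranking(ids[o], sc[o])
    rev_ <- make_ranking(rev(ids[o]), rev(-sc[o]))
    act <- sample(ids, 6)
    expect_equal(roc_auc(fwd, act)$auc, 1 - roc_auc(rev_, act)$auc,
                 tolerance = 1e-12)
  })
  expect_error(roc_auc(r, ids), "at least one")
})

test_that("label-independent rankings give AUC about one half", {
  ids <- sprintf("m%03d", 1:100)
  act <- ids[1:20]
  aucs <- withr::with_seed(97, vapply(1:1000, function(i) {
    o <- sample(100)
    r <- make_ranking(ids[o], seq(1, 0.01, length.out = 100))
    roc_auc(r, act)$auc
  }, numeric(1)))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("truncated ROC option normalises by the kept FPR range", {
  ids <- sprintf("m%02d", 1:20)
  r <- make_ranking(ids, 20:1)
  expect_equal(roc_auc(r, ids[1:5], max_fpr = 0.2)$auc, 1.0)
  expect_error(roc_auc(r, ids[1:5], max_fpr = 0), "max_fpr")
})

test_that("enrichment_factor follows its formula and self-normalises", {
  cr <- constructed_ranking()
  expect_identical(enrichment_factor(cr$r, cr$actives, 1), 8.0)
  expect_identical(enrichment_factor(cr$r, cr$actives, 1),
                   oracle_ef(cr$r$ids, cr$actives, 1))
  ids <- sprintf("m%02d", 1:50)
  r <- make_ranking(ids, 50:1)
  expect_identical(enrichment_factor(r, ids[40:45], 2), 0.0)  # none on top
  expect_identical(enrichment_factor(r, ids[40:45], 100), 1.0)
})

test_that("bedroc matches the direct-summation oracle and its bounds", {
  ids <- sprintf("m%03d", 1:100)
  r <- make_ranking(ids, seq(1, 0.01, length.out = 100))
  act <- ids[c(1, 2, 3, 50, 100)]
  expect_equal(bedroc(r, act, 20),
               oracle_bedroc(c(1, 2, 3, 50, 100), 100, 5, 20),
               tolerance = 1e-12)
  # frozen value computed from the scalar oracle (cross-checked against an
  # independent implementation during development)
  expect_equal(bedroc(r, act, 20), 0.7137854, tolerance = 1e-6)
  expect_equal(bedroc(r, ids[1:5], 20), 1, tolerance = 1e-6)   # best case
  expect_lt(bedroc(r, ids[96:100], 20), 1e-6)                  # worst case
  expect_error(bedroc(r, ids, 20), "every molecule");
  expect_error(bedroc(r, act, 0), "alpha")
})

test_that("bedroc never decreases when an active moves up", {
  ids <- sprintf("m%03d", 1:100)
  scores <- seq(1, 0.01, length.out = 100)
  act_pos <- c(10, 40, 80)
  base <- bedroc(make_ranking(ids, scores), ids[act_pos], 20)
  for (better in c(39, 20, 5, 1)) {
    moved <- ids
    # move the active at position 40 up to `better`, shifting the block down
    moved <- append(moved[-40], ids[40], after = better - 1)
    val <- bedroc(make_ranking(moved, scores), ids[act_pos], 20)
    expect_gt(val, base)
    base <- val
  }
})

test_that("evaluate_screen averages per class and summarize credits winners", {
  ds <- tiny_dataset(n_classes = 3, per_class = 10, n_decoys = 40)
  reports <- lapply(c("asmtp", "tanimoto"), function(m) {
    res <- screen(ds, screen_config(n_references = 4, seed = 5, measure = m))
    evaluate_screen(res, ds)
  })
  rep1 <- reports[[1]]
  expect_identical(nrow(rep1$per_query), 3L * 4L)
  expect_identical(nrow(rep1$per_class), 3L)
  # per-class value is the arithmetic mean of its per-query values
  for (cl in unique(rep1$per_class$class)) {
    pq <- rep1$per_query[rep1$per_query$class == cl, ]
    pc <- rep1$per_class[rep1$per_class$class == cl, ]
    for (m in c("recall_1", "recall_5", "auc", "ef_1", "bedroc")) {
      expect_equal(pc[[m]], mean(pq[[m]]), tolerance = 1e-12)
    }
  }
  # overall mean equals the mean of class means
  expect_equal(rep1$overall$mean[rep1$overall$metric == "recall_5"],
               mean(rep1$per_class$recall_5), tolerance = 1e-12)

  s <- summarize_evaluations(reports)
  n_best <- s$best_per_class$n_best
  # with ties credited to all, each metric's credits total >= n classes
  for (m in unique(s$best_per_class$metric)) {
    expect_gte(sum(n_best[s$best_per_class$metric == m]), 3L)
  }
})

test_that("summarize detects dominating and tied measures", {
  mk_report <- function(measure, r1) {
    pq <- data.frame(measure = measure,
                     class = rep(c("a", "b"), each = 2),
                     query_id = c("q1", "q2", "q3", "q4"),
                     recall_1 = r1, stringsAsFactors = FALSE)
    pc <- stats::aggregate(pq["recall_1"],
                           by = list(measure = pq$measure, class = pq$class),
                           FUN = mean)
    structure(list(per_query = pq, per_class = pc,
                   overall = data.frame(measure = measure,
                                        metric = "recall_1",
                                        mean = mean(pc$recall_1),
                                        median = median(pc$recall_1)),
                   measure = measure, cutoffs = 1),
              class = "evaluation_report")
  }
  dominator <- mk_report("a", c(50, 60, 70, 80))
  weaker <- mk_report("b", c(10, 20, 30, 40))
  s <- summarize_evaluations(list(dominator, weaker))
  expect_identical(s$best_per_class$n_best[s$best_per_class$measure == "a"], 2L)
  expect_identical(s$best_per_class$n_best[s$best_per_class$measure == "b"], 0L)
  tied <- mk_report("b", c(50, 60, 70, 80))
  s2 <- summarize_evaluations(list(dominator, tied))
  expect_identical(s2$best_per_class$n_best, c(2L, 2L))
  mismatched <- mk_report("b", c(1, 2, 3, 4))
  mismatched$per_query$query_id <- c("zz", "q2", "q3", "q4")
  expect_error(summarize_evaluations(list(dominator, mismatched)),
               "identical query sets")
})

test_that("evaluation reports serialize to tidy CSV", {
  ds <- tiny_dataset(n_classes = 2, per_class = 10, n_decoys = 20)
  res <- screen(ds, screen_config(n_references = 3, seed = 5))
  report <- evaluate_screen(res, ds)
  path <- withr::local_tempfile(fileext = ".csv")
  write_evaluation(report, path)
  tidy <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(names(tidy),
                   c("measure", "class", "query_id", "metric", "cutoff",
                     "value"))
  expect_setequal(unique(tidy$metric),
                  c("recall", "auc", "ef", "bedroc"))
  # per-class rows (empty query_id) mirror the report's per_class block
  pc_rows <- tidy[is.na(tidy$query_id) | tidy$query_id == "", ]
  expect_identical(nrow(pc_rows), 2L * 5L)
})
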