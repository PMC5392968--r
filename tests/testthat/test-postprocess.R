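test_that("age check tags are detected from numbers near explicit age mentions", {
  rules <- default_age_rules()
  expect_identical(detect_age_checktags("children aged 8-10 years", rules),
                   "Child")
  expect_identical(detect_age_checktags("no mention of maturity here", rules),
                   character())
  expect_setequal(detect_age_checktags("patients aged 70 years", rules),
                  "Aged")
  expect_setequal(detect_age_checktags("infants aged 14 months", rules),
                  "Infant")
  # range endpoints that straddle tag boundaries contribute both tags
  expect_setequal(detect_age_checktags("subjects aged 11 to 15 years", rules),
                  c("Child", "Adolescent"))
  # overlapping NLM ranges return the union
  expect_setequal(detect_age_checktags("men aged 21 years", rules),
                  c("Young Adult", "Adult"))
  # numbers far from the keyword are ignored
  expect_identical(
    detect_age_checktags(paste("the age distribution was considered.",
                               strrep("filler words here ", 10),
                               "we enrolled 70 subjects"), rules),
    character())
})

test_that("specificity pruning removes exactly the out-ranked ancestors", {
  v <- toy_vocab()
  pred <- meshrank:::.as_prediction_list(c("TA11", "TA", "TB"),
                                         c(0.9, 0.8, 0.7), "d")
  out <- specificity_prune(pred, v)
  expect_identical(out$descriptor_id, c("TA11", "TB"))
  expect_identical(out$rank, 1:2)
  # parent ranked above its child survives
  pred2 <- meshrank:::.as_prediction_list(c("TA", "TA11"), c(0.9, 0.8), "d")
  expect_identical(specificity_prune(pred2, v)$descriptor_id,
                   c("TA", "TA11"))
  # no hierarchical relations: unchanged
  pred3 <- meshrank:::.as_prediction_list(c("TA1", "TB1"), c(0.9, 0.8), "d")
  expect_identical(specificity_prune(pred3, v)$descriptor_id,
                   c("TA1", "TB1"))
  expect_error(specificity_prune(
    meshrank:::.as_prediction_list(c("TA", "XX"), c(1, 0.5), "d"), v),
    "unknown descriptor")
})

test_that("specificity pruning agrees with a brute-force ancestor scan", {
  for (seed in 1:5) {
    v <- random_tree_vocab(15, seed + 40)
    set.seed(seed)
    ids <- sample(names(v$descriptors), 10)
    pred <- meshrank:::.as_prediction_list(ids, sort(stats::runif(10),
                                                     decreasing = TRUE), "d")
    out <- specificity_prune(pred, v)
    for (i in seq_len(nrow(pred))) {
      id <- pred$descriptor_id[i]
      higher <- pred$descriptor_id[seq_len(i - 1)]
      has_higher_descendant <- any(vapply(higher, function(h)
        oracle_is_ancestor(v, id, h), TRUE))
      expect_identical(!id %in% out$descriptor_id, has_higher_descendant)
    }
  }
})

test_that("the automatic cut-off reproduces the hand-evaluated rule", {
  mk <- function(scores) meshrank:::.as_prediction_list(
    sprintf("D%02d", seq_along(scores)), scores, "d")
  # 0.05 < 0.9 * ln(2) * 0.3 = 0.187...: keep two
  out <- score_cutoff(mk(c(1.0, 0.9, 0.05)), pruning_config())
  expect_identical(nrow(out), 2L)
  expect_identical(out$descriptor_id, c("D01", "D02"))
  # slowly decaying scores are only capped at n_cap
  slow <- mk(1 - 0.01 * (0:29))
  expect_identical(nrow(score_cutoff(slow, pruning_config())), 25L)
  # no violation below the cap keeps everything
  expect_identical(nrow(score_cutoff(mk(c(1, 0.95, 0.9)), pruning_config())),
                   3L)
  # single prediction is always kept
  expect_identical(nrow(score_cutoff(mk(0.4), pruning_config())), 1L)
  # output is a prefix of the capped input
  cut <- score_cutoff(slow, pruning_config(lambda_cut = 5))
  expect_identical(cut$descriptor_id,
                   slow$descriptor_id[seq_len(nrow(cut))])
  expect_lte(nrow(cut), 25L)
})

test_that("postprocess composes its three stages and is idempotent", {
  v <- new_vocabulary(list(
    new_descriptor("TA", "Alpha", tree_numbers = "A"),
    new_descriptor("TA1", "Alpha One", tree_numbers = "A.1"),
    new_descriptor("TB", "Beta", tree_numbers = "B"),
    new_descriptor("TB1", "Beta One", tree_numbers = "B.1"),
    new_descriptor("TC", "Gamma", tree_numbers = "C"),
    new_descriptor("CH", "Child", tree_numbers = "M.1",
                   is_check_tag = TRUE)))
  doc <- new_document("d", title = "t",
                      abstract = "children aged 8-10 years were assessed")
  pred <- meshrank:::.as_prediction_list(
    c("TA1", "TA", "TB", "TC", "TB1"),
    c(0.90, 0.85, 0.80, 0.78, 0.01), "d")
  cfg <- pruning_config()
  rules <- default_age_rules(v)
  got <- postprocess(pred, doc, v, cfg, rules)

  # staged oracle: inject, prune, cut
  injected <- meshrank:::.as_prediction_list(
    c("CH", pred$descriptor_id), c(max(pred$score) + 1e-6, pred$score), "d")
  staged <- score_cutoff(specificity_prune(injected, v), cfg)
  expect_identical(got$descriptor_id, staged$descriptor_id)
  expect_equal(got$score, staged$score)
  # the age tag leads; the out-ranked parent TA is gone; the tail is cut
  expect_identical(got$descriptor_id[1], "CH")
  expect_false("TA" %in% got$descriptor_id)
  expect_false("TB1" %in% got$descriptor_id)
  # idempotence
  again <- postprocess(got, doc, v, cfg, rules)
  expect_identical(again$descriptor_id, got$descriptor_id)
  expect_equal(again$score, got$score)
})

test_that("inert rules leave a flat list unchanged (up to the cap)", {
  v <- toy_vocab()
  doc <- new_document("d", title = "nothing special")
  # parents precede their children, so specificity pruning has no target
  pred <- meshrank:::.as_prediction_list(c("TA", "TA1", "TB"),
                                         c(0.9, 0.85, 0.8), "d")
  out <- postprocess(pred, doc, v, pruning_config(), default_age_rules(v))
  expect_identical(out$descriptor_id, pred$descriptor_id)
})
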