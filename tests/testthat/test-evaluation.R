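test_that("identical segmentations match fully with zero error", {
  s <- segment_set(c(0, 100, 200), c(100, 200, 300), "walk")
  pairs <- match_cycles(s, s)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$overlap, c(100, 100, 100))
  expect_equal(unname(segmentation_error(pairs, 200)[["mean_s"]]), 0)
  expect_equal(unname(duration_error(pairs, 200)[["mean_s"]]), 0)
})

test_that("over-segmentation keeps only the larger-overlap estimate", {
  ref <- segment_set(0, 100, "walk")
  est <- segment_set(c(0, 60), c(60, 100), "walk")
  pairs <- match_cycles(est, ref)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$est_start, 0)
  expect_equal(pairs$est_end, 60)
  expect_equal(pairs$overlap, 60)
  # empty inputs give empty output, not an error
  expect_equal(nrow(match_cycles(segment_set(), ref)), 0)
  expect_equal(nrow(match_cycles(est, segment_set())), 0)
})

test_that("matching equals an independent exhaustive greedy oracle", {
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    cuts_r <- sort(sample(1:99, k))
    cuts_e <- sort(sample(1:99, sample(2:5, 1)))
    ref <- segment_set(c(0, cuts_r), c(cuts_r, 100), "walk")
    est <- segment_set(c(0, cuts_e), c(cuts_e, 100), "walk")
    got <- match_cycles(est, ref)
    # oracle: repeatedly take the global max-overlap pair from the matrix
    ov <- outer(seq_len(nrow(est)), seq_len(nrow(ref)), function(i, j) {
      pmax(0, pmin(est$end[i], ref$end[j]) - pmax(est$start[i], ref$start[j]))
    })
    pairs <- NULL
    while (max(ov) > 0) {
      hit <- which(ov == max(ov), arr.ind = TRUE)
      hit <- hit[order(ref$start[hit[, 2]], est$start[hit[, 1]]), , drop = FALSE]
      i <- hit[1, 1]
      j <- hit[1, 2]
      pairs <- rbind(pairs, data.frame(ei = i, ri = j, overlap = ov[i, j]))
      ov[i, ] <- 0
      ov[, j] <- 0
    }
    pairs <- pairs[order(pairs$ri), ]
    expect_equal(got$est_start, est$start[pairs$ei])
    expect_equal(got$ref_start, ref$start[pairs$ri])
    expect_equal(got$overlap, pairs$overlap)
  }
})

test_that("boundary and duration errors compute the documented arithmetic", {
  ref <- segment_set(c(0, 200, 400), c(200, 400, 600), "walk")
  est <- segment_set(c(0, 200, 400) + 10, c(200, 400, 600) + 10, "walk")
  pairs <- match_cycles(est, ref)
  se <- segmentation_error(pairs, 200)
  expect_equal(unname(se[["mean_s"]]), 0.050)
  expect_equal(unname(se[["sd_s"]]), 0)

  est2 <- segment_set(c(0 + 2, 200 - 4, 400 + 6), c(200 - 4, 400 + 6, 606), "walk")
  se2 <- segmentation_error(match_cycles(est2, ref), 200)
  expect_equal(unname(se2[["mean_s"]]), 0.020)

  # +10% duration on 1 s cycles at 200 Hz
  ref3 <- segment_set(c(0, 200), c(200, 400), "walk")
  est3 <- segment_set(c(0, 220), c(220, 440), "walk")
  de <- duration_error(match_cycles(est3, ref3), 200)
  expect_equal(unname(de[["mean_s"]]), 0.1)
  # symmetry of the duration error
  de_swap <- duration_error(match_cycles(ref3, est3), 200)
  expect_equal(unname(de[["mean_s"]]), unname(de_swap[["mean_s"]]))

  expect_error(segmentation_error(match_cycles(segment_set(), ref), 200), "no matched")
})

test_that("perfect labels give 100% everywhere; one-sided predictions split classes", {
  ref <- rep(c("walk", "run"), each = 50)
  rep1 <- classification_report(ref, ref)
  expect_equal(rep1$per_class$sensitivity, c(100, 100))
  expect_equal(rep1$per_class$specificity, c(100, 100))
  expect_equal(rep1$per_class$f1, c(100, 100))
  expect_equal(unname(rep1$overall[["f1"]]), 100)
  expect_equal(unname(diag(rep1$confusion)), c(100, 100))

  all_walk <- rep("walk", 100)
  rep2 <- classification_report(all_walk, ref)
  expect_equal(rep2$per_class$sensitivity[rep2$per_class$class == "walk"], 100)
  expect_equal(rep2$per_class$sensitivity[rep2$per_class$class == "run"], 0)
})

test_that("a hand-built 3-class confusion fixture matches manual arithmetic", {
  # person 1: rest 20 samples (18 correct, 2 -> walk); walk 10 (8 correct,
  # 2 -> run); run 10 (all correct)
  ref <- c(rep("rest", 20), rep("walk", 10), rep("run", 10))
  est <- c(
    rep("rest", 18), rep("walk", 2),
    rep("walk", 8), rep("run", 2),
    rep("run", 10)
  )
  r <- classification_report(est, ref)
  pc <- r$per_class
  # rest: tp=18 fn=2 fp=0 tn=20 -> sens 90, spec 100, prec 1, f1 2*.9/1.9
  expect_equal(pc$sensitivity[pc$class == "rest"], 90)
  expect_equal(pc$specificity[pc$class == "rest"], 100)
  expect_equal(pc$f1[pc$class == "rest"], 100 * 2 * 0.9 / 1.9)
  # walk: tp=8 fn=2 fp=2 tn=28 -> sens 80, spec 28/30, prec .8, f1 80
  expect_equal(pc$sensitivity[pc$class == "walk"], 80)
  expect_equal(pc$specificity[pc$class == "walk"], 100 * 28 / 30)
  expect_equal(pc$f1[pc$class == "walk"], 80)
  # run: tp=10 fn=0 fp=2 tn=28 -> sens 100, spec 28/30, prec 10/12
  expect_equal(pc$sensitivity[pc$class == "run"], 100)
  expect_equal(pc$f1[pc$class == "run"], 100 * 2 * (10 / 12) / (10 / 12 + 1))
  # overall = unweighted class mean
  expect_equal(
    unname(r$overall[["sensitivity"]]), mean(c(90, 80, 100))
  )
  # confusion rows sum to 100
  expect_equal(unname(rowSums(r$confusion)), rep(100, 3), tolerance = 1e-9)
  expect_equal(r$confusion["rest", "walk"], 10)
  expect_equal(r$confusion["walk", "run"], 20)
})

test_that("person-then-class averaging and absent-class warnings", {
  ref <- c(rep("walk", 10), rep("run", 10), rep("walk", 10))
  est <- c(rep("walk", 10), rep("run", 5), rep("walk", 5), rep("walk", 10))
  subj <- c(rep("p1", 20), rep("p2", 10))
  expect_warning(r <- classification_report(est, ref, subjects = subj), "absent")
  pc <- r$per_class
  # walk sensitivity: p1 100, p2 100 -> 100; run only present for p1: 50
  expect_equal(pc$sensitivity[pc$class == "walk"], 100)
  expect_equal(pc$sensitivity[pc$class == "run"], 50)
})
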