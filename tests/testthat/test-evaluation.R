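# OKS closed forms, the threshold grid, the scale partition, and exact
# agreement of evaluate_dataset with a brute-force oracle.

test_that("OKS closed forms hold", {
  gt <- cbind(c(10, 20, 30), c(10, 20, 30), c(2, 2, 1))
  expect_equal(compute_oks(gt[, 1:2], gt, s = 50, k = 0.1), 1)
  # one labeled keypoint at squared distance 2 s^2 k^2 -> exp(-1)
  s <- 40; k <- 0.1
  d <- sqrt(2) * s * k
  gt1 <- cbind(5, 5, 2)
  expect_equal(compute_oks(cbind(5 + d, 5), gt1, s, k), exp(-1))
  expect_error(compute_oks(cbind(1, 1), cbind(1, 1, 0), 10, 0.1), "undefined")
})

test_that("OKS is monotone in error and invariant to joint rescaling", {
  set.seed(11)
  for (i in 1:200) {
    M <- sample(2:6, 1)
    gt <- cbind(runif(M, 0, 50), runif(M, 0, 50), sample(1:2, M, replace = TRUE))
    pred <- gt[, 1:2] + matrix(rnorm(2 * M, 0, 3), M, 2)
    s <- runif(1, 10, 80); k <- runif(M, 0.05, 0.3)
    o <- compute_oks(pred, gt, s, k)
    expect_gte(o, 0); expect_lte(o, 1)
    # worsen one labeled keypoint -> OKS strictly decreases
    j <- which(gt[, 3] > 0)[1]
    pred2 <- pred
    pred2[j, ] <- gt[j, 1:2] + (pred[j, ] - gt[j, 1:2]) * 3
    expect_lt(compute_oks(pred2, gt, s, k), o + 1e-12)
    # joint rescaling of distances and scale leaves OKS unchanged
    cc <- runif(1, 0.5, 3)
    pred3 <- gt[, 1:2] + (pred - gt[, 1:2]) * cc
    expect_equal(compute_oks(pred3, gt, cc * s, k), o, tolerance = 1e-12)
  }
})

test_that("the threshold grid has ten values and AP50/AP75 are grid entries", {
  th <- oks_thresholds()
  expect_equal(length(th), 10L)
  expect_equal(th, seq(0.5, 0.95, by = 0.05))
  ap <- compute_ap(c(0.6, 0.4))
  expect_equal(ap$AP50, ap$per_threshold[["0.50"]])
  expect_equal(ap$AP75, ap$per_threshold[["0.75"]])
  expect_equal(ap$AP50, 50)
})

test_that("single-instance AP enumerates the thresholds", {
  # OKS = 0.72 passes T in {0.50, ..., 0.70}: 5 of 10 thresholds
  expect_equal(compute_ap(0.72)$AP, 50)
  expect_equal(compute_ap(1)$AP, 100)
  # strict inequality at a threshold boundary
  expect_equal(compute_ap(0.5)$AP50, 0)
  expect_error(compute_ap(numeric(0)), "empty")
})

test_that("the area partition uses inclusive medium bounds", {
  expect_equal(partition_by_scale(32^2), "medium")
  expect_equal(partition_by_scale(96^2), "medium")
  expect_equal(partition_by_scale(96^2 + 1), "large")
  expect_equal(partition_by_scale(100), "small")
  expect_error(partition_by_scale(0), "positive")
})

# build a toy annotation set + predictions with prescribed per-instance OKS
make_eval_case <- function(n, seed) {
  set.seed(seed)
  sc <- toy_schema()
  images <- data.frame(id = 1L, file_name = "im.png", width = 500L, height = 500L)
  anns <- list(); preds <- list()
  areas <- numeric(n)
  for (i in seq_len(n)) {
    area <- sample(c(runif(1, 500, 1020), runif(1, 1100, 9000),
                     runif(1, 9500, 20000)), 1)
    areas[i] <- area
    gt <- cbind(runif(2, 50, 450), runif(2, 50, 450), c(2, sample(0:2, 1)))
    if (all(gt[, 3] == 0)) gt[1, 3] <- 2
    anns[[i]] <- coco_annotation(1L, gt, c(0, 0, sqrt(area), sqrt(area)),
                                 area = area, id = i)
    if (runif(1) < 0.85) {
      pred <- gt[, 1:2] + matrix(rnorm(4, 0, runif(1, 0, 8)), 2, 2)
      preds[[length(preds) + 1L]] <- list(annotation_id = i, image_id = 1L,
                                          keypoints = cbind(pred, 1), score = 1)
    }
  }
  list(aset = annotation_set(images, anns, sc), preds = preds, areas = areas)
}

test_that("evaluate_dataset matches the brute-force oracle on random cases", {
  for (case in 1:100) {
    cs <- make_eval_case(n = sample(1:10, 1), seed = 1000 + case)
    mr <- evaluate_dataset(cs$preds, cs$aset)
    # oracle: recompute OKS per instance directly, missing predictions = 0
    sig <- cs$aset$schema$sigmas
    oks <- vapply(seq_along(cs$aset$annotations), function(i) {
      a <- cs$aset$annotations[[i]]
      p <- Filter(function(x) x$annotation_id == i, cs$preds)
      if (!length(p)) return(0)
      compute_oks(p[[1]]$keypoints[, 1:2], a$keypoints, sqrt(a$area), sig)
    }, numeric(1))
    orc <- oracle_metrics(oks, cs$areas)
    expect_equal(mr$AP, orc$AP)
    expect_equal(mr$AP50, orc$AP50)
    expect_equal(mr$AP75, orc$AP75)
    expect_equal(mr$APM, orc$APM)
    expect_equal(mr$APL, orc$APL)
    expect_equal(mr$AR, orc$AR)
  }
})

test_that("AP is monotone when any instance's OKS improves", {
  oks <- c(0.3, 0.55, 0.8, 0.91)
  base <- compute_ap(oks)$AP
  for (i in seq_along(oks)) {
    up <- oks; up[i] <- min(1, up[i] + 0.2)
    expect_gte(compute_ap(up)$AP, base)
  }
})

test_that("duplicate predictions and empty partitions are handled", {
  cs <- make_eval_case(4, seed = 5)
  dup <- c(cs$preds, cs$preds[1])
  expect_error(evaluate_dataset(dup, cs$aset), "duplicate")
  # a set with only large instances reports APM as NaN
  sc <- toy_schema()
  aset <- annotation_set(
    data.frame(id = 1L, file_name = "x.png", width = 500L, height = 500L),
    list(coco_annotation(1L, cbind(c(10, 20), c(10, 20), c(2, 2)),
                         c(0, 0, 100, 100), id = 1L)), sc)
  preds <- list(list(annotation_id = 1L, image_id = 1L,
                     keypoints = cbind(c(10, 20), c(10, 20), 1), score = 1))
  mr <- evaluate_dataset(preds, aset)
  expect_true(is.nan(mr$APM))
  expect_equal(mr$APL, 100)
  expect_equal(mr$AP, 100)
  expect_equal(mr$AR, 100)
})
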