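# Overlap metrics against a brute-force pixel-enumeration oracle and the
# hand-worked examples.

brute_counts <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1L
      if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1L
      if (pred[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1L
      if (pred[i, j] == 0 && gt[i, j] == 1) fn <- fn + 1L
    }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

test_that("confusion counts match a quadruple-loop tally", {
  set.seed(1)
  for (rep in 1:20) {
    p <- random_mask(8, 8); g <- random_mask(8, 8)
    cc <- confusion(p, g)
    bb <- brute_counts(p, g)
    expect_identical(unclass(cc)[c("tp", "fp", "tn", "fn")], bb)
    expect_identical(cc$tp + cc$fp + cc$tn + cc$fn, 64L)
  }
  expect_error(confusion(random_mask(4, 4), random_mask(4, 5)), "differ")
  expect_error(confusion(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("hand-worked metric examples evaluate exactly", {
  # |P| = 6, |G| = 4, |P n G| = 3 on a 4x4 grid
  p <- matrix(0, 4, 4); p[1, 1:3] <- 1; p[2, 1:3] <- 1
  g <- matrix(0, 4, 4); g[1, 1:3] <- 1; g[3, 1] <- 1
  expect_equal(dsc(p, g), 0.6)
  expect_equal(recall(p, g), 0.75)
  expect_equal(voe(p, g), 4 / 7)
  expect_equal(rvd(p, g), 0.5)
})

test_that("degenerate and limiting cases follow the documented conventions", {
  ones <- matrix(1, 4, 4); zero <- matrix(0, 4, 4)
  expect_identical(unclass(confusion(ones, ones))[c("tp", "fp", "tn", "fn")],
                   list(tp = 16L, fp = 0L, tn = 0L, fn = 0L))
  comp <- 1 - ones; comp[1, 1] <- 1
  cc <- confusion(comp, 1 - comp)
  expect_identical(cc$tp, 0L); expect_identical(cc$tn, 0L)
  expect_equal(dsc(ones, ones), 1)
  disj <- zero; disj[1, ] <- 1
  disj2 <- zero; disj2[3, ] <- 1
  expect_equal(dsc(disj, disj2), 0)
  expect_equal(voe(disj, disj2), 1)
  expect_equal(rvd(disj, disj2), 0)       # equal volumes, disjoint
  expect_equal(rvd(zero, disj2), 1)
  expect_equal(recall(disj, disj), 1)
  expect_equal(recall(disj2, disj), 0)
  expect_warning(expect_equal(dsc(zero, zero), 1), "empty")
  expect_warning(expect_equal(voe(zero, zero), 0), "empty")
  expect_warning(expect_true(is.na(recall(disj, zero))), "undefined")
  expect_warning(expect_true(is.na(rvd(disj, zero))), "undefined")
})

test_that("DSC relates to the raw overlap error by the closed-form identity", {
  set.seed(2)
  for (rep in 1:50) {
    p <- random_mask(10, 10); g <- random_mask(10, 10)
    if (sum(p) + sum(g) == 0) next
    i <- sum(p & g); u <- sum(p | g)
    voe_raw <- 1 - i / u
    expect_equal(dsc(p, g), 2 * (1 - voe_raw) / (2 - voe_raw),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant under simultaneous rigid transforms", {
  set.seed(3)
  p <- random_mask(9, 9); g <- random_mask(9, 9)
  vals <- c(dsc(p, g), recall(p, g), voe(p, g), rvd(p, g))
  rot <- function(m) ns$rot90_k(m, 1)
  expect_equal(c(dsc(rot(p), rot(g)), recall(rot(p), rot(g)),
                 voe(rot(p), rot(g)), rvd(rot(p), rot(g))), vals)
  fl <- function(m) m[, ncol(m):1]
  expect_equal(c(dsc(fl(p), fl(g)), recall(fl(p), fl(g)),
                 voe(fl(p), fl(g)), rvd(fl(p), fl(g))), vals)
})

test_that("report aggregation equals the brute-force mean and round-trips CSV", {
  set.seed(4)
  preds <- lapply(1:6, function(i) random_mask(8, 8))
  gts <- lapply(1:6, function(i) random_mask(8, 8))
  rep <- metric_report(preds, gts)
  expect_equal(rep$aggregate[["dsc"]],
               mean(vapply(1:6, function(i) dsc(preds[[i]], gts[[i]]),
                           numeric(1))))
  f <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, f)
  df <- utils::read.csv(f)
  expect_identical(nrow(df), 7L)           # 6 samples + footer of means
  expect_identical(df$sample_id[7], "mean")
  expect_equal(df$dsc[7], rep$aggregate[["dsc"]])
  expect_s3_class(tidy(rep), "tbl_df")
  expect_identical(nrow(glance(rep)), 1L)
})
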