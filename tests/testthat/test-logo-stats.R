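test_that("icelogo validates inputs and is deterministic", {
  tg <- two_group_divergence_set(n_test = 6L, n_ref = 12L, seed = 2L)
  expect_error(icelogo(tg$test, tg$reference[, 1:10]), "same columns")
  expect_error(icelogo(tg$test, tg$reference, columns = 9999L), "out of range")
  x1 <- icelogo(tg$test, tg$reference, columns = 100:110, iterations = 50L,
                seed = 4L)
  x2 <- icelogo(tg$test, tg$reference, columns = 100:110, iterations = 50L,
                seed = 4L)
  expect_identical(x1$table, x2$table)
})

test_that("p-values use the (r+1)/(n+1) convention and bounds", {
  tg <- two_group_divergence_set(n_test = 6L, n_ref = 12L, seed = 3L)
  x <- icelogo(tg$test, tg$reference, columns = 100:120, iterations = 99L,
               seed = 5L)
  expect_true(all(x$table$p >= 1 / 100))
  expect_true(all(x$table$p <= 1))
  # every p is a multiple of 1/(iterations+1)
  expect_true(all(abs(x$table$p * 100 - round(x$table$p * 100)) < 1e-9))
})

test_that("a fixed diverging column is detected as enriched", {
  tg <- two_group_divergence_set(n_test = 10L, n_ref = 25L,
                                 rate_test = 0.05, rate_ref = 0.05, seed = 6L)
  test <- tg$test
  # plant a full-column W signal at a column where the reference has no W
  col <- which(apply(tg$reference, 2, function(x) all(x != "W")))[1]
  test[, col] <- "W"
  x <- icelogo(test, tg$reference, columns = c(col, col + 1L),
               iterations = 200L, seed = 7L)
  w <- x$table[x$table$column == col & x$table$residue == "W", ]
  expect_true(w$significant)
  expect_gt(w$diff, 0.5)
})

test_that("gaps are excluded from frequency denominators", {
  test <- rbind(a = c("A", "-"), b = c("A", "-"), c = c("A", "W"))
  refm <- rbind(r1 = c("A", "W"), r2 = c("A", "W"), r3 = c("A", "-"),
                r4 = c("A", "W"))
  x <- icelogo(test, refm, iterations = 20L, seed = 1L)
  w <- x$table[x$table$column == 2L & x$table$residue == "W", ]
  expect_equal(w$freq_test, 1)  # 1 of 1 non-gap, not 1 of 3
})

test_that("render_logo writes the table and a text summary", {
  tg <- two_group_divergence_set(n_test = 6L, n_ref = 12L, seed = 8L)
  x <- icelogo(tg$test, tg$reference, columns = 100:105, iterations = 50L,
               seed = 9L)
  tsv <- tempfile(fileext = ".tsv")
  txt <- tempfile(fileext = ".txt")
  lines <- render_logo(x, tsv_file = tsv, text_file = txt)
  expect_true(file.exists(tsv) && file.exists(txt))
  expect_equal(length(lines), 6L)
  tab <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_true(all(c("column", "residue", "diff", "p") %in% names(tab)))
  unlink(c(tsv, txt))
})
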