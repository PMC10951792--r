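small_table <- function(areas) {
  tibble::tibble(cell_id = seq_along(areas), M1.area = areas,
                 relevant = TRUE, cell_type = NA_character_)
}

test_that("filters use inclusive bounds and conjunction", {
  tb <- apply_filters(small_table(c(3, 5, 12)),
                      list(relevance_filter("M1.area", min = 5)))
  expect_equal(tb$relevant, c(FALSE, TRUE, TRUE))    # below 5 removed
  tb2 <- apply_filters(small_table(c(3, 5, 12)), list())
  expect_true(all(tb2$relevant))
  tb3 <- apply_filters(small_table(c(3, 5, 12)),
                       list(relevance_filter("M1.area", min = 5, max = 5)))
  expect_equal(tb3$relevant, c(FALSE, TRUE, FALSE))
  expect_error(apply_filters(small_table(1), list(relevance_filter("M1.blah"))),
               "unknown feature")
  expect_error(relevance_filter("M2.mean"), "Marker I")
})

test_that("classification is first-match, with unknown and excluded fallbacks", {
  tb <- tibble::tibble(
    cell_id = 1:4,
    M1.mean = c(50, 50, 50, 50),
    M2.mean = c(80, 80, 20, 80),
    M2.foci_count = c(9, 7, 9, 9),
    relevant = c(TRUE, TRUE, TRUE, FALSE),
    cell_type = NA_character_)
  pos <- cell_type("positive", "#f00", list(
    constraint(left = "M2.mean", relation = ">", right = "M1.mean"),
    constraint("M2.foci_count", min = 8)))
  out <- classify_cells(tb, list(pos))
  expect_equal(out$cell_type, c("positive", "unknown", "unknown", "excluded"))
  # no types defined: every relevant cell is unknown
  out0 <- classify_cells(tb, list())
  expect_equal(out0$cell_type, c("unknown", "unknown", "unknown", "excluded"))
  # overlapping definitions: earlier type wins, diagnostics list all
  broad <- cell_type("broad", "#0f0", list(constraint("M2.mean", min = 0)))
  out2 <- classify_cells(tb, list(pos, broad))
  expect_equal(out2$cell_type[1], "positive")
  expect_equal(out2$all_matching_types[1], "positive,broad")
  out3 <- classify_cells(tb, list(broad, pos))
  expect_equal(out3$cell_type[1], "broad")
})

test_that("quartile thresholds implement the Q1/Q4 membership recipes", {
  tb <- small_table(as.numeric(1:100))
  q <- quartile_thresholds(tb, "M1.area")
  expect_equal(unname(q), c(25.75, 50.5, 75.25))
  expect_true(80 >= q[["Q3"]])    # value 80 is in the Q4 quartile
  # all-equal distribution: Q4 membership inclusive at the common value
  qe <- quartile_thresholds(small_table(rep(7, 10)), "M1.area")
  expect_equal(unname(qe), c(7, 7, 7))
  expect_true(7 >= qe[["Q3"]])
  expect_error(quartile_thresholds(small_table(c(1, 2, 3)), "M1.area"),
               "at least 4")
})

test_that("classification matches the brute-force evaluator on random tables", {
  withr::local_seed(2468)
  for (k in 1:200) {
    rt <- random_table_and_types()
    got <- classify_cells(rt$table, rt$types)
    expect_equal(got$cell_type, oracle_classify(rt$table, rt$types),
                 info = paste("case", k))
    # partition invariant
    expect_equal(sum(got$cell_type == "excluded") +
                 sum(got$cell_type == "unknown") +
                 sum(!got$cell_type %in% c("excluded", "unknown")),
                 nrow(got))
    expect_true(all(got$cell_type[!got$relevant] == "excluded"))
  }
})

test_that("adding constraints or filters never grows the matched sets", {
  withr::local_seed(1357)
  for (k in 1:20) {
    rt <- random_table_and_types(n_cells = 30)
    types <- rt$types
    if (length(types) == 0) next
    base <- classify_cells(rt$table, types[1])
    extra <- types[[1]]
    extra$constraints <- c(extra$constraints,
                           list(constraint("M1.area", max = 50)))
    narrowed <- classify_cells(rt$table, list(extra))
    expect_lte(sum(narrowed$cell_type == extra$name),
               sum(base$cell_type == types[[1]]$name))
    f0 <- apply_filters(rt$table, list())
    f1 <- apply_filters(rt$table, list(relevance_filter("M1.area", min = 20)))
    expect_lte(sum(f1$relevant), sum(f0$relevant))
  }
})

test_that("quadrant counts partition the relevant cells", {
  tb <- tibble::tibble(cell_id = 1:4, M1.area = c(1, 1, 9, 9),
                       M2.mean = c(1, 9, 1, 9),
                       relevant = TRUE, cell_type = NA_character_)
  q <- quadrant_counts(tb, "M1.area", "M2.mean", 5, 5)
  expect_equal(unlist(q[1, ]), c(n_LL = 1, n_LH = 1, n_HL = 1, n_HH = 1))
  # all below both thresholds
  q2 <- quadrant_counts(tb, "M1.area", "M2.mean", 50, 50)
  expect_equal(q2$n_LL, 4)
  # a cell exactly at a threshold counts as high
  q3 <- quadrant_counts(tb, "M1.area", "M2.mean", 9, 9)
  expect_equal(q3$n_HH, 1)
  expect_equal(q3$n_HL + q3$n_HH, 2)
  # conservation under random thresholds
  withr::local_seed(11)
  for (k in 1:20) {
    rt <- random_table_and_types(n_cells = 25)
    qq <- quadrant_counts(rt$table, "M1.area", "M2.mean",
                          runif(1, -10, 120), runif(1, -10, 300))
    expect_equal(qq$n_LL + qq$n_LH + qq$n_HL + qq$n_HH,
                 sum(rt$table$relevant))
  }
  expect_error(quadrant_counts(tb, "M1.nope", "M2.mean", 1, 1), "unknown feature")
})
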