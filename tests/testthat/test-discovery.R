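make_events <- function(step_ids, times) {
  tibble::tibble(
    user_id = "u1", item_id = step_ids, item_kind = "step",
    access_path = "menu",
    timestamp = as.POSIXct("2017-03-01", tz = "UTC") + 60 * times
  )
}

test_that("search matches title, then keywords, then tags, case-insensitively", {
  cat_ <- example_catalog()
  res <- search_catalog("mind", cat_)
  expect_equal(res$id[1], "s_mind")
  expect_equal(res$matched_via[1], "title")
  expect_equal(search_catalog("MIND", cat_)$id, res$id)
  # keyword-only match ranks after title matches
  kw <- search_catalog("job", cat_)
  expect_equal(kw$matched_via, "keyword")
  expect_equal(kw$id, "s_work")
  # tag-only match
  tg <- search_catalog("Kicking", cat_)
  expect_equal(nrow(tg), 0)
  expect_equal(nrow(search_catalog("qqqq", cat_)), 0)
  expect_error(search_catalog("   ", cat_), class = "steprec_usage_error")
})

test_that("all_steps sorts case-insensitively with stable id ties", {
  cat_ <- test_catalog()  # titles Zen Garden, apple picking, Mango Tango
  expect_equal(all_steps(cat_)$title,
               c("apple picking", "Mango Tango", "Zen Garden"))
  empty <- generate_catalog(generation_spec(n_steps = 0, n_actions = 0))
  expect_equal(nrow(all_steps(empty)), 0)
})

test_that("the four rankings order by their documented keys", {
  cat_ <- test_catalog()  # steps s1 s2 s3
  ev <- make_events(c(rep("s1", 5), rep("s2", 2)), 1:7)
  comments <- tibble::tibble(step_id = c("s1", "s3"), n_comments = c(2L, 9L))
  rl <- steps_people_are_taking(ev, comments, cat_, k = 10)
  expect_equal(rl$taken_most_often$step_id, c("s1", "s2"))
  expect_equal(rl$hidden_treasures$step_id, c("s3", "s2", "s1"))
  expect_equal(rl$recently_taken$step_id[1], "s2")   # latest visit
  expect_equal(rl$got_people_talking$step_id, c("s3", "s1"))
})

test_that("no events means empty popularity lists but full hidden treasures", {
  cat_ <- test_catalog()
  rl <- steps_people_are_taking(make_events(character(0), numeric(0)),
                                tibble::tibble(step_id = character(0),
                                               n_comments = integer(0)),
                                cat_)
  expect_equal(nrow(rl$recently_taken), 0)
  expect_equal(nrow(rl$taken_most_often), 0)
  expect_equal(rl$hidden_treasures$step_id, c("s1", "s2", "s3"))
  expect_true(all(rl$hidden_treasures$key == 0))
})

test_that("most-taken and hidden-treasures are disjoint under distinct counts", {
  cat_ <- test_catalog()
  ev <- make_events(c(rep("s1", 5), rep("s2", 2), "s3"), 1:8)
  rl <- steps_people_are_taking(ev, tibble::tibble(step_id = character(0),
                                                   n_comments = integer(0)),
                                cat_, k = 1)
  expect_equal(length(intersect(rl$taken_most_often$step_id,
                                rl$hidden_treasures$step_id)), 0)
})

test_that("rankings are permutations of catalog steps and truncate in place", {
  cat_ <- test_catalog()
  ev <- make_events(c("s1", "s2", "s1"), 1:3)
  full <- steps_people_are_taking(ev, tibble::tibble(step_id = "s1",
                                                     n_comments = 3L), cat_)
  cut <- steps_people_are_taking(ev, tibble::tibble(step_id = "s1",
                                                    n_comments = 3L), cat_, k = 1)
  for (nm in names(full)) {
    expect_true(all(full[[nm]]$step_id %in% cat_$items$id))
    expect_equal(anyDuplicated(full[[nm]]$step_id), 0)
    expect_equal(cut[[nm]]$step_id, utils::head(full[[nm]]$step_id, 1))
  }
})

test_that("events referencing unknown steps are rejected", {
  expect_error(
    steps_people_are_taking(make_events("ghost", 1),
                            tibble::tibble(step_id = character(0),
                                           n_comments = integer(0)),
                            test_catalog()),
    class = "steprec_validation_error")
})
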