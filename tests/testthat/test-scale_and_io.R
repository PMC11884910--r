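test_that("the default instrument has 17 items with the documented ranges", {
  sc <- hrsd17_scale()
  expect_equal(nrow(sc$items), 17L)
  expect_true(all(sc$items$min_score == 0L))
  expect_equal(sum(sc$items$max_score == 2L), 4L)
  expect_equal(sum(sc$items$max_score == 4L), 13L)
  expect_false(anyDuplicated(sc$items$label) > 0)
  # the three remission-relevant items sit at their standard positions
  expect_equal(sc$items$label[c(3, 8, 15)],
               c("suicidality", "retardation", "hypochondriasis"))
})

test_that("scale construction rejects invalid item definitions", {
  expect_error(symptom_scale(c("a", "a"), 4), "unique")
  expect_error(symptom_scale(c("a", "b"), c(4, 3)), "max_score")
  expect_error(symptom_scale(character(0), integer(0)), "at least one")
})

test_that("cohort validation enforces ranges, coding and lengths", {
  sc <- scale5
  ok <- matrix(1L, 3, 5, dimnames = list(NULL, sc$items$label))
  expect_s3_class(cohort_table(ok, c(0, 1, 1), scale = sc), "cohort_table")
  bad <- ok; bad[2, "insight"] <- 3L
  expect_error(cohort_table(bad, c(0, 1, 1), scale = sc), "row 2.*insight.*\\[0, 2\\]")
  expect_error(cohort_table(ok, c(0, 1, 2), scale = sc), "only 0/1")
  expect_error(cohort_table(ok, c(0, 1), scale = sc), "length")
  expect_error(cohort_table(ok, c(0, 1, 1), moderator = c(0, 2, 1), scale = sc),
               "moderator")
  expect_error(cohort_table(ok[0, , drop = FALSE], integer(0), scale = sc), "empty")
})

test_that("a cohort file with 161 valid rows loads as 161 patients", {
  co <- sample_cohort(default_paper_like_model(seed = 3), scale17,
                      sim_config(161, seed = 31))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  loaded <- load_cohort(path)
  expect_equal(n_patients(loaded), 161L)
  expect_identical(loaded$scores, co$scores)
  expect_identical(loaded$outcome, co$outcome)
})

test_that("load_cohort enforces the schema and reports dropped rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- sample_cohort(default_paper_like_model(seed = 3), scale17,
                      sim_config(20, seed = 32))
  df <- as.data.frame(co$scores)
  df$remission <- co$outcome

  # unknown column
  bad <- cbind(df, extra = 1)
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_cohort(path), "unknown column")

  # missing item column
  write.csv(df[, -3], path, row.names = FALSE)
  expect_error(load_cohort(path), "missing column.*suicidality")

  # out-of-range score names the offending data row
  bad <- df; bad$suicidality[7] <- 5
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_cohort(path), "row 7.*suicidality")

  # header but no rows
  write.csv(df[0, ], path, row.names = FALSE)
  expect_error(load_cohort(path), "empty cohort")

  # complete-case dropping with reported count
  bad <- df
  bad$guilt[2] <- NA
  bad$remission[5] <- NA
  write.csv(bad, path, row.names = FALSE)
  expect_message(loaded <- load_cohort(path), "dropped 2 of 20")
  expect_equal(n_patients(loaded), 18L)
})

test_that("complete-case dropping is order-independent", {
  co <- sample_cohort(default_paper_like_model(seed = 3), scale17,
                      sim_config(40, seed = 33))
  df <- as.data.frame(co$scores)
  df$remission <- co$outcome
  df$guilt[c(4, 19)] <- NA
  perm <- withr::with_seed(1, sample(nrow(df)))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p1, row.names = FALSE)
  write.csv(df[perm, ], p2, row.names = FALSE)
  a <- suppressMessages(load_cohort(p1))
  b <- suppressMessages(load_cohort(p2))
  ord <- function(x) {
    key <- apply(cbind(x$scores, x$outcome), 1, paste, collapse = ",")
    order(key)
  }
  expect_identical(a$scores[ord(a), ], b$scores[ord(b), ])
  expect_identical(a$outcome[ord(a)], b$outcome[ord(b)])
})

test_that("network serialization round-trips in both formats", {
  cfg <- estimation_config(cv_seed = 5)
  net <- suppressWarnings(estimate_network(cohort5, cfg))
  for (ext in c(".json", ".graphml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_network(net, path)
    back <- read_network(path)
    expect_identical(back$node_labels, net$node_labels)
    expect_identical(back$node_types, net$node_types)
    expect_equal(back$adjacency, net$adjacency, tolerance = 1e-12)
    expect_equal(back$predictability, net$predictability, tolerance = 1e-12)
    expect_identical(back$sign_undefined, net$sign_undefined)
  }
})

test_that("an empty network serializes as all nodes and zero edges", {
  adj <- matrix(0, 18, 18)
  net <- fake_network(adj)
  for (ext in c(".json", ".graphml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_network(net, path)
    back <- read_network(path)
    expect_length(back$node_labels, 18L)
    expect_true(all(back$adjacency == 0))
  }
})

test_that("a negative edge weight keeps its sign on disk", {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- -0.3
  net <- fake_network(adj)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  txt <- jsonlite::fromJSON(path)
  expect_equal(txt$edges$weight, -0.3)
  expect_equal(txt$edges$sign, "negative")
  expect_equal(read_network(path)$adjacency[1, 2], -0.3)
})

test_that("writing to an unwritable path fails cleanly", {
  net <- fake_network(matrix(0, 2, 2))
  expect_error(suppressWarnings(write_network(net, "/nonexistent-dir/x.json")),
               "cannot write")
})
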