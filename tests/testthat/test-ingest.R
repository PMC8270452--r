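test_that("deduplication keeps the first record per id and drops OOC", {
  posts <- make_posts(c("a", "a", "b", "c", "c"), days = 1, labels = "F")
  out <- deduplicate(posts)
  expect_equal(nrow(out), 3)
  expect_equal(out$post_id, c("a", "b", "c"))
  expect_equal(attr(out, "n_duplicates"), 2L)

  # first occurrence wins
  posts2 <- make_posts(c("x", "x"), days = 1, labels = c("F", "C"))
  expect_equal(deduplicate(posts2)$label, "F")

  # OOC dropped unless asked for
  posts3 <- make_posts(c("a", "b"), days = 1, labels = c("F", "OOC"))
  expect_equal(deduplicate(posts3)$post_id, "a")
  expect_equal(nrow(deduplicate(posts3, keep_ooc = TRUE)), 2)

  empty <- make_posts(character(0), days = integer(0), labels = character(0))
  expect_equal(nrow(deduplicate(empty)), 0)
})

test_that("daily aggregation bins posts, zero-fills days, sums interactions", {
  posts <- make_posts(c("a", "b", "c"), days = 2, labels = "F",
                      likes = c(2, 0, 0), retweets = c(1, 0, 0))
  s <- aggregate_daily(posts, "2018-01-01", "2018-01-03")
  expect_equal(nrow(s), 3)
  expect_equal(unlist(s[2, c("n_F", "n_C", "n_U")], use.names = FALSE),
               c(3L, 0L, 0L))
  expect_equal(s$volume, c(0L, 3L, 0L))
  expect_equal(s$interactions[2], 6L)       # 3 posts + 2 likes + 1 retweet
  expect_equal(s$interactions[c(1, 3)], c(0L, 0L))

  # posts outside the range are excluded (and counted)
  s2 <- aggregate_daily(posts, "2018-01-02", "2018-01-02")
  expect_equal(attr(s2, "n_out_of_range"), 0L)
  s3 <- aggregate_daily(posts, "2018-01-03", "2018-01-04")
  expect_equal(attr(s3, "n_out_of_range"), 3L)
  expect_equal(sum(s3$volume), 0L)

  expect_error(aggregate_daily(posts, "2018-01-05", "2018-01-01"),
               "date range")
})

test_that("aggregation is order-invariant and conserves record counts", {
  set.seed(7)
  n <- 300
  posts <- make_posts(sprintf("p%03d", 1:n), days = sample(1:20, n, TRUE),
                      labels = sample(c("F", "C", "U"), n, TRUE,
                                      prob = c(.7, .16, .14)),
                      likes = rpois(n, 2), retweets = rpois(n, 1))
  s1 <- aggregate_daily(posts, "2018-01-01", "2018-01-20")
  s2 <- aggregate_daily(posts[sample.int(n), ], "2018-01-01", "2018-01-20")
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_equal(sum(s1$volume), n)
  expect_equal(s1$volume, s1$n_F + s1$n_C + s1$n_U)
  expect_true(all(s1$interactions >= s1$volume))
})

test_that("polarity summary reports pooled proportions and valid CIs", {
  s <- make_series(rbind(c(40, 10, 8), c(30, 6, 6)))
  ps <- polarity_summary(s, seed = 1)
  expect_equal(unname(ps$proportions),
               c(70, 16, 14) / 100)
  expect_equal(ps$p_hesitant, 0.30)
  expect_equal(sum(ps$proportions), 1, tolerance = 1e-12)
  # intervals contain the point estimates
  expect_true(all(ps$ci[1, ] <= ps$proportions &
                    ps$proportions <= ps$ci[2, ]))
  expect_true(ps$ci_hesitant[1] <= ps$p_hesitant &
                ps$p_hesitant <= ps$ci_hesitant[2])

  # day-blocked variant behaves the same way
  pd <- polarity_summary(s, ci_method = "day_block", seed = 1,
                         n_boot = 500)
  expect_true(all(pd$ci[1, ] <= pd$proportions &
                    pd$proportions <= pd$ci[2, ]))

  # all favourable
  s2 <- make_series(cbind(5:7, 0, 0))
  ps2 <- polarity_summary(s2, seed = 1)
  expect_equal(unname(ps2$proportions[1]), 1)
  expect_equal(ps2$p_hesitant, 0)

  expect_error(polarity_summary(make_series(cbind(0, 0, 0))), "zero total")
})

test_that("post and daily-series CSV round trips preserve the data", {
  tmp <- tempfile(fileext = ".csv")
  posts <- make_posts(c("a", "b", "bad"), days = 1,
                      labels = c("F", "U", "nonsense"), likes = 1)
  write.csv(data.frame(posts[, 1, drop = FALSE],
                       timestamp = format(posts$timestamp,
                                          "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                       posts[, 3:5]),
            tmp, row.names = FALSE)
  got <- suppressMessages(read_posts(tmp))
  expect_equal(nrow(got), 2)                  # unknown label rejected
  expect_equal(attr(got, "n_rejected"), 1L)
  expect_equal(got$post_id, c("a", "b"))
  expect_s3_class(got$timestamp, "POSIXct")

  s <- make_series(rbind(c(3, 1, 0), c(0, 0, 0), c(2, 2, 2)),
                   interactions = c(10, 0, 6))
  tmp2 <- tempfile(fileext = ".csv")
  write_daily_series(s, tmp2)
  expect_equal(as.data.frame(read_daily_series(tmp2)), as.data.frame(s))
})

test_that("daily series constructor enforces its invariants", {
  expect_error(make_series(rbind(c(1, 1, -1))), "non-negative")
  expect_error(daily_polarity(as.Date(c("2018-01-01", "2018-01-03")),
                              c(1, 1), c(0, 0), c(0, 0)), "consecutive")
  expect_error(make_series(rbind(c(2, 2, 2)), interactions = 3),
               "interactions")
  # proportions matrix has NA rows exactly on empty days
  s <- make_series(rbind(c(1, 1, 0), c(0, 0, 0)))
  p <- polarity_proportions(s)
  expect_equal(p[1, ], c(F = 0.5, C = 0.5, U = 0))
  expect_true(all(is.na(p[2, ])))
})
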