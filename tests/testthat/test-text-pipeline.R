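test_that("preprocessing lowercases, strips noise, and drops stopwords", {
  expect_equal(preprocess_text("I feel SO empty..."), list(c("feel", "empty")))
  expect_equal(preprocess_text(""), list(character(0)))
  expect_equal(preprocess_text("http://x.co 123 !!"), list(character(0)))
  expect_equal(preprocess_text("@someone you won't CARE, right?!"),
               list(c("care", "right")))
  # options: custom stopwords and minimum token length
  expect_equal(preprocess_text("alpha be bee", stopwords = "alpha"),
               list(c("be", "bee")))
  expect_equal(preprocess_text("go going gone", min_len = 5), list("going"))
})

test_that("document-term matrices match hand enumeration", {
  docs <- c("wolf pack hunts", "wolf sleeps", "pack sleeps deeply", "quiet night")
  labs <- c(1, 1, 0, 0)
  dtm <- build_dtm(docs, labs, min_df = 2)
  # terms in >= 2 docs: pack, sleeps, wolf (lexicographic)
  expect_identical(dtm$vocab, c("pack", "sleeps", "wolf"))
  expect_equal(unname(dtm$x),
               rbind(c(1L, 0L, 1L), c(0L, 1L, 1L), c(1L, 1L, 0L), c(0L, 0L, 0L)))
  expect_identical(dtm$labels, c(1L, 1L, 0L, 0L))
  # disjoint documents at min_df = 1 give orthogonal unit rows
  d2 <- build_dtm(c("apple", "zebra"), c(0, 1), min_df = 1)
  expect_equal(unname(d2$x), rbind(c(1L, 0L), c(0L, 1L)))
  expect_error(build_dtm(docs, labs, min_df = 10), "min_df")
  expect_error(build_dtm(docs, c(1, 2, 0, 0)), "0/1")
})

test_that("matrix construction is permutation-equivariant with binary entries", {
  set.seed(5)
  docs <- c("deep dark night", "dark wolf night", "deep wolf", "night wolf dark")
  labs <- c(1, 0, 1, 0)
  perm <- sample(4)
  a <- build_dtm(docs, labs, min_df = 2)
  b <- build_dtm(docs[perm], labs[perm], min_df = 2)
  expect_identical(a$vocab, b$vocab)
  expect_equal(a$x[perm, ], b$x)
  expect_true(all(a$x %in% 0:1))
  expect_true(all(colSums(a$x) >= 2))
})

test_that("train/test split is exact, stratified, and seed-deterministic", {
  x <- matrix(rbinom(200, 1, 0.5), 20, 10, dimnames = list(NULL, letters[1:10]))
  dtm <- chaoswolf:::new_dtm(x, rep(c(1L, 0L), c(16L, 4L)))
  sp <- split_dtm(dtm, 0.8, seed = 1)
  expect_identical(sort(c(sp$idx_train, sp$idx_test)), 1:20)
  expect_equal(nrow(sp$train$x), 16)
  # stratification preserves the 4:1 imbalance in both splits
  expect_equal(sum(sp$train$labels), 13)
  expect_equal(sum(sp$test$labels), 3)
  sp2 <- split_dtm(dtm, 0.8, seed = 1)
  expect_identical(sp$idx_train, sp2$idx_train)
  # unstratified 10-row split at 0.8 gives 8/2
  d10 <- chaoswolf:::new_dtm(x[1:10, ], rep(c(1L, 0L), 5))
  s10 <- split_dtm(d10, 0.8, stratified = FALSE, seed = 2)
  expect_equal(c(nrow(s10$train$x), nrow(s10$test$x)), c(8, 2))
  lone <- chaoswolf:::new_dtm(x[1:5, ], c(1L, 1L, 1L, 1L, 0L))
  expect_error(split_dtm(lone, 0.8), "2 members")
})

test_that("corpus files round-trip with quoting and label validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    text = c("feeling low, very low", "a fine day", "empty inside"),
    label = c("depressive", "non-depressive", "1"))
  utils::write.csv(df, path, row.names = FALSE)
  got <- read_corpus(path)
  expect_equal(nrow(got), 3)
  expect_identical(got$label, c(1L, 0L, 1L))
  expect_identical(got$text[1], "feeling low, very low")
  bad <- data.frame(text = c("x", "y"), label = c("maybe", "1"))
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_corpus(path), "row\\(s\\) 1.*maybe")
})

test_that("document-term matrices round-trip through TSV", {
  docs <- c("wolf pack hunts", "wolf sleeps", "pack sleeps deeply")
  dtm <- build_dtm(docs, c(1, 0, 0), min_df = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dtm(dtm, path)
  back <- read_dtm(path)
  expect_equal(back$x, dtm$x)
  expect_identical(back$labels, dtm$labels)
  expect_identical(back$vocab, dtm$vocab)
})
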