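test_that("read_dic parses a minimal well-formed dictionary", {
  lex <- read_dic(write_mini_dic())
  expect_s3_class(lex, "mpm_lexicon")
  expect_equal(lex$categories$name, c("posemo", "negemo"))
  expect_equal(nrow(lex$entries), 3)
  expect_equal(lex$entries$pattern, c("happ", "sad", "love"))
  expect_equal(lex$entries$is_prefix, c(TRUE, FALSE, FALSE))
  # multi-category membership
  expect_equal(lex$entries$category_ids[[3]], c(1L, 2L))
})

test_that("read_dic rejects malformed input with informative errors", {
  expect_error(read_dic(write_mini_dic(c("%", "x\tposemo", "%", "sad\t2"))),
               "malformed category header")
  expect_error(read_dic(write_mini_dic(c("%", "1\tposemo", "%", "sad\t9"))),
               "unknown category id")
  expect_error(read_dic(write_mini_dic(c("%", "%"))), "empty lexicon")
  expect_error(read_dic(write_mini_dic(c("%", "1\tposemo", "%",
                                         "sad\t1", "sad\t1"))),
               "duplicate")
})

test_that("the bundled toy dictionary round-trips through write_dic", {
  lex <- toy_lexicon()
  out <- tempfile(fileext = ".dic")
  write_dic(lex, out)
  again <- read_dic(out)
  expect_identical(lex$categories, again$categories)
  expect_identical(lex$entries$pattern, again$entries$pattern)
  expect_identical(lex$entries$is_prefix, again$entries$is_prefix)
  expect_identical(lex$entries$category_ids, again$entries$category_ids)
})

test_that("tokenize lowercases, keeps internal apostrophes, splits on the rest", {
  expect_equal(tokenize("It's a Trap!"), c("it's", "a", "trap"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("well-known 42 facts"), c("well", "known", "facts"))
  # a leading apostrophe is not internal, so it is stripped
  expect_equal(tokenize("’Tis done"), c("tis", "done"))
  # token count is exact by construction
  expect_length(tokenize(paste(rep("word", 1000), collapse = " ")), 1000)
})

test_that("score_text computes percent-of-words category scores", {
  lex <- toy_lexicon()
  toks <- c("pleasure", tokenize("one two three four five six seven eight nine"))
  fv <- score_text(toks, lex)
  expect_equal(fv$posemo, 10)
  expect_equal(fv$word_count, 10)
  # tokens entirely outside the lexicon score zero everywhere
  fv0 <- score_text(c("zzz", "yyy"), lex)
  expect_true(all(fv0[, lex$categories$name] == 0))
  # zero tokens: degenerate flag, no division
  fvd <- score_text(character(0), lex)
  expect_true(attr(fvd, "degenerate"))
  expect_true(all(fvd[, lex$categories$name] == 0))
})

test_that("score_text agrees with a brute-force hand count", {
  lex <- toy_lexicon()
  set.seed(71)
  vocab <- c("pleasure", "joy", "happily", "grief", "sadness", "mate",
             "because", "see", "the", "it", "was", "now", "zzz", "qqq")
  for (rep in 1:5) {
    toks <- sample(vocab, 200, replace = TRUE)
    fv <- score_text(toks, lex)
    # independent count: iterate entries per token
    counts <- setNames(numeric(nrow(lex$categories)), lex$categories$name)
    for (tok in toks) {
      for (i in seq_len(nrow(lex$entries))) {
        pat <- lex$entries$pattern[i]
        hit <- if (lex$entries$is_prefix[i]) startsWith(tok, pat) else tok == pat
        if (hit) {
          nms <- lex$categories$name[match(lex$entries$category_ids[[i]],
                                           lex$categories$id)]
          counts[nms] <- counts[nms] + 1
        }
      }
    }
    expect_equal(unlist(fv[, names(counts)]),
                 100 * counts / length(toks), ignore_attr = TRUE)
  }
})

test_that("a literal entry takes precedence over a prefix stem of the same string", {
  lex <- read_dic(write_mini_dic(c("%", "1\tposemo", "2\tnegemo", "%",
                                   "glad\t1", "glad*\t2")))
  fv <- score_text(c("glad", "gladly"), lex)
  # "glad" counts only for the literal's category; "gladly" only the prefix
  expect_equal(fv$posemo, 50)
  expect_equal(fv$negemo, 50)
})

test_that("scoring is invariant to token order and bounded for disjoint categories", {
  lex <- toy_lexicon()
  set.seed(72)
  toks <- sample(c("pleasure", "grief", "mate", "because", "see", "zzz"),
                 150, replace = TRUE)
  a <- score_text(toks, lex)
  b <- score_text(sample(toks), lex)
  expect_equal(a[, -1], b[, -1])
  # disjoint single-membership categories cannot sum above 100
  disjoint <- c("posemo", "negemo", "cogproc", "percept")
  expect_lte(sum(a[, disjoint]), 100)
})

test_that("segment_text chunks and merges the remainder as specified", {
  toks <- as.character(seq_len(500))
  segs <- segment_text(toks, 250)
  expect_length(segs, 2)
  expect_equal(lengths(segs), c(250L, 250L))

  segs <- segment_text(as.character(1:260), 250)
  expect_length(segs, 1)
  expect_length(segs[[1]], 260)

  # short remainder merges into the previous chunk; long remainder stands
  expect_equal(lengths(segment_text(as.character(1:600), 250)),
               c(250L, 350L))
  expect_equal(lengths(segment_text(as.character(1:630), 250)),
               c(250L, 250L, 130L))
  expect_equal(segment_text(character(0)), list())

  # partition property: concatenation restores the token sequence
  for (n in c(1, 100, 249, 251, 375, 1000)) {
    toks <- as.character(seq_len(n))
    expect_identical(unlist(segment_text(toks, 250)), toks)
  }
})

test_that("score_corpus scores a directory layout, whole and segmented", {
  lex <- toy_lexicon()
  dir <- tempfile("corpus")
  gen_toy_corpus(c(posemo = 10, cogproc = 5), lex, n_docs = 3, dir = dir,
                 doc_length = 600, seed = 81)
  tab <- score_corpus(dir, lex)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$author, rep("toy_author", 3))
  expect_equal(tab$word_count, rep(600L, 3))
  seg <- score_corpus(dir, lex, segment = 250)
  # 600 tokens at target 250 -> chunks of 250 and 350
  expect_equal(nrow(seg), 6)
  expect_true(all(seg$doc %in% c("doc001", "doc002", "doc003")))
  # feature tables round-trip through CSV
  path <- tempfile(fileext = ".csv")
  write_features(tab, path)
  back <- read_features(path)
  expect_equal(back$posemo, tab$posemo, tolerance = 1e-6)
})
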