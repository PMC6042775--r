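# Shared fixture builders: tiny in-code dictionaries and feature tables.

# Minimal two-category dictionary written to a temp file.
write_mini_dic <- function(lines = NULL) {
  path <- tempfile(fileext = ".dic")
  if (is.null(lines)) {
    lines <- c("%", "1\tposemo", "2\tnegemo", "%",
               "happ*\t1", "sad\t2", "love\t1\t2")
  }
  writeLines(lines, path)
  path
}

toy_lexicon <- function() {
  read_dic(system.file("extdata", "toy.dic", package = "mpmap"))
}

# Feature table covering every default-scheme variable, including the four
# proprietary summary columns, for cluster-construction tests.
full_feature_table <- function(n = 12, seed = 402) {
  vars <- unique(unlist(default_cluster_scheme()))
  mpmap:::with_seed(seed, {
    X <- matrix(runif(n * length(vars), 20, 80), n,
                dimnames = list(NULL, vars))
    data.frame(doc_id = sprintf("doc%02d", seq_len(n)),
               author = "author01", word_count = 1000L,
               as.data.frame(X), check.names = FALSE)
  })
}

# Single-author table over the open (non-proprietary) variables.
open_feature_table <- function(n = 16, seed = 403, within_sd = 2.5) {
  prof <- mpmap:::with_seed(seed, {
    mu <- pmin(pmax(rnorm(length(default_variables()), 50, 5), 0), 100)
    names(mu) <- default_variables()
    author_profile("author01", mu, cov = within_sd)
  })
  gen_author_feature_table(list(prof), n, seed = seed + 1L)
}

open_scheme <- function() mpmap:::reduced_default_scheme()
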