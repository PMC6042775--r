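# Dictionary handling, tokenization, scoring and segmentation.

#' Read a LIWC-format (.dic) category dictionary
#'
#' Parses the conventional `.dic` dialect: a header delimited by lines
#' containing only `%`, holding one `id<TAB>name` pair per line, followed by
#' entry lines `word<TAB>id [id ...]`. A trailing `*` on a word marks a
#' prefix stem ("happ*" matches any token starting with "happ"); all other
#' entries match tokens literally. A word may list several category ids.
#'
#' @param path Path to a `.dic` file.
#' @return An object of class `mpm_lexicon`: a list with
#'   `categories` (data frame with columns `id`, `name`) and `entries`
#'   (data frame with columns `pattern`, `is_prefix` and list-column
#'   `category_ids`), in file order.
#' @seealso [write_dic()], [score_text()]
#' @examples
#' dic <- system.file("extdata", "toy.dic", package = "mpmap")
#' lex <- read_dic(dic)
#' lex$categories
#' @export
read_dic <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) > 0) lines[1] <- sub("^\uFEFF", "", lines[1])
  raw <- trimws(lines)
  pct <- which(raw == "%")
  if (length(pct) < 2) {
    stop("not a .dic file: expected a '%'-delimited category header in ",
         path, call. = FALSE)
  }
  head_lines <- if (pct[2] - pct[1] > 1L) seq.int(pct[1] + 1L, pct[2] - 1L)
                else integer(0)
  head_lines <- head_lines[nzchar(raw[head_lines])]
  if (length(head_lines) == 0) {
    stop("empty lexicon: no categories defined in ", path, call. = FALSE)
  }
  cats <- lapply(head_lines, function(i) {
    parts <- strsplit(raw[i], "[\t ]+")[[1]]
    id <- suppressWarnings(as.integer(parts[1]))
    if (length(parts) < 2 || is.na(id)) {
      stop("malformed category header at line ", i, ": '", raw[i], "'",
           call. = FALSE)
    }
    list(id = id, name = paste(parts[-1], collapse = " "))
  })
  categories <- data.frame(
    id = vapply(cats, `[[`, integer(1), "id"),
    name = vapply(cats, `[[`, character(1), "name"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(categories$id)) {
    stop("duplicate category id in header of ", path, call. = FALSE)
  }

  body_lines <- if (length(raw) > pct[2]) seq.int(pct[2] + 1L, length(raw))
                else integer(0)
  body_lines <- body_lines[nzchar(raw[body_lines])]
  if (length(body_lines) == 0) {
    stop("empty lexicon: no word entries in ", path, call. = FALSE)
  }
  entries <- lapply(body_lines, function(i) {
    parts <- strsplit(raw[i], "[\t ]+")[[1]]
    ids <- suppressWarnings(as.integer(parts[-1]))
    if (length(parts) < 2 || anyNA(ids)) {
      stop("malformed entry at line ", i, ": '", raw[i], "'", call. = FALSE)
    }
    unknown <- setdiff(ids, categories$id)
    if (length(unknown) > 0) {
      stop("entry at line ", i, " references unknown category id ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    word <- tolower(parts[1])
    is_prefix <- endsWith(word, "*")
    pattern <- if (is_prefix) substr(word, 1L, nchar(word) - 1L) else word
    if (!nzchar(pattern)) {
      stop("empty pattern at line ", i, call. = FALSE)
    }
    list(pattern = pattern, is_prefix = is_prefix, ids = unique(ids))
  })
  out <- data.frame(
    pattern = vapply(entries, `[[`, character(1), "pattern"),
    is_prefix = vapply(entries, `[[`, logical(1), "is_prefix"),
    stringsAsFactors = FALSE
  )
  out$category_ids <- lapply(entries, `[[`, "ids")
  if (anyDuplicated(out[, c("pattern", "is_prefix")])) {
    stop("duplicate dictionary entry (same pattern and prefix flag) in ",
         path, call. = FALSE)
  }
  structure(list(categories = categories, entries = out),
            class = "mpm_lexicon")
}

#' Write a lexicon back to LIWC .dic format
#'
#' @param lexicon An `mpm_lexicon` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dic <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "mpm_lexicon"))
  header <- paste(lexicon$categories$id, lexicon$categories$name, sep = "\t")
  body <- vapply(seq_len(nrow(lexicon$entries)), function(i) {
    word <- lexicon$entries$pattern[i]
    if (lexicon$entries$is_prefix[i]) word <- paste0(word, "*")
    paste(c(word, lexicon$entries$category_ids[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c("%", header, "%", body), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.mpm_lexicon <- function(x, ...) {
  cat("<mpm_lexicon>", nrow(x$categories), "categories,",
      nrow(x$entries), "entries (",
      sum(x$entries$is_prefix), "prefix stems )\n")
  invisible(x)
}

#' Tokenize text into lowercase word tokens
#'
#' A token is a maximal run of letters, optionally joined by internal
#' apostrophes ("it's" is one token). Digits, punctuation and hyphens act as
#' separators; curly apostrophes are normalized to straight ones. The number
#' of tokens defines a document's word count.
#'
#' @param text A character vector; elements are concatenated.
#' @return Character vector of tokens (empty for empty input).
#' @examples
#' tokenize("It's a Trap!")
#' @export
tokenize <- function(text) {
  text <- paste(text, collapse = "\n")
  if (!nzchar(text)) return(character(0))
  text <- tolower(chartr("’", "'", text))
  m <- gregexpr("\\p{L}+(?:'\\p{L}+)*", text, perl = TRUE)
  toks <- regmatches(text, m)[[1]]
  if (length(toks) == 0) character(0) else toks
}

#' Split a token sequence into ~fixed-length segments
#'
#' Consecutive non-overlapping chunks of `target` tokens. A final remainder
#' shorter than `target / 2` is merged into the previous chunk when one
#' exists; otherwise it is kept as its own (short) segment.
#'
#' @param tokens Character vector of tokens.
#' @param target Target segment length in tokens (default 250).
#' @return A list of character vectors; concatenating them restores
#'   `tokens` exactly.
#' @export
segment_text <- function(tokens, target = 250) {
  stopifnot(is.numeric(target), length(target) == 1L, target >= 1)
  target <- as.integer(target)
  n <- length(tokens)
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = target)
  ends <- pmin(starts + target - 1L, n)
  segs <- Map(function(s, e) tokens[s:e], starts, ends)
  k <- length(segs)
  if (k >= 2L && length(segs[[k]]) < target / 2) {
    segs[[k - 1L]] <- c(segs[[k - 1L]], segs[[k]])
    segs[[k]] <- NULL
  }
  unname(segs)
}

#' Score tokens against a category dictionary
#'
#' Each category is scored as `100 * matched / total` tokens: the percent of
#' words in the document that belong to the category. A token matches a
#' literal entry by equality and a prefix entry when the stem is a leading
#' substring of the token; when the same pattern string exists both as a
#' literal entry and a prefix stem, the literal entry takes precedence for
#' tokens equal to it. A token may count toward several categories. The
#' summary variable `Sixltr` (percent of tokens longer than six letters) is
#' computed alongside the dictionary categories.
#'
#' @param tokens Character vector of tokens (see [tokenize()]).
#' @param lexicon An `mpm_lexicon`.
#' @param doc_id Document identifier stored with the result.
#' @return A one-row data frame with columns `doc_id`, `word_count`, one
#'   column per category name, and `Sixltr`. A zero-token input yields all
#'   zero scores and attribute `degenerate = TRUE`.
#' @examples
#' lex <- read_dic(system.file("extdata", "toy.dic", package = "mpmap"))
#' score_text(tokenize("pleasure and joy before grief"), lex)
#' @export
score_text <- function(tokens, lexicon, doc_id = "doc") {
  stopifnot(inherits(lexicon, "mpm_lexicon"))
  if (nrow(lexicon$entries) == 0) stop("empty lexicon", call. = FALSE)
  wc <- length(tokens)
  cats <- lexicon$categories
  counts <- integer(nrow(cats))
  names(counts) <- as.character(cats$id)
  if (wc > 0L) {
    ent <- lexicon$entries
    lit <- ent[!ent$is_prefix, , drop = FALSE]
    pre <- ent[ent$is_prefix, , drop = FALSE]
    if (nrow(lit) > 0) {
      hit <- match(tokens, lit$pattern)
      tab <- table(hit[!is.na(hit)])
      for (j in names(tab)) {
        ids <- as.character(lit$category_ids[[as.integer(j)]])
        counts[ids] <- counts[ids] + as.integer(tab[[j]])
      }
    }
    if (nrow(pre) > 0) {
      for (j in seq_len(nrow(pre))) {
        stem <- pre$pattern[j]
        n_match <- sum(startsWith(tokens, stem))
        # literal precedence: a token equal to a stem that also exists as a
        # literal entry is already counted by that literal entry
        if (stem %in% lit$pattern) n_match <- n_match - sum(tokens == stem)
        if (n_match > 0) {
          ids <- as.character(pre$category_ids[[j]])
          counts[ids] <- counts[ids] + n_match
        }
      }
    }
  }
  scores <- if (wc > 0L) 100 * counts / wc else counts * 0
  out <- data.frame(doc_id = doc_id, word_count = wc,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cats))) out[[cats$name[i]]] <- unname(scores[i])
  out$Sixltr <- if (wc > 0L) 100 * sum(nchar(tokens) > 6L) / wc else 0
  attr(out, "degenerate") <- wc == 0L
  out
}

#' Score a corpus directory into a feature table
#'
#' Expects one sub-directory per author containing one UTF-8 `.txt` file per
#' document. With `segment` set, each document is split into ~`segment`-word
#' chunks (see [segment_text()]) and one row is produced per chunk, with the
#' parent document recorded in column `doc`.
#'
#' @param corpus_dir Root corpus directory.
#' @param lexicon An `mpm_lexicon`.
#' @param segment Optional target segment length in tokens; `NULL` scores
#'   whole documents.
#' @return A feature table: data frame with columns `doc_id`, `author`,
#'   `word_count`, the category variables and `Sixltr` (plus `doc` and
#'   `segment` when segmenting).
#' @export
score_corpus <- function(corpus_dir, lexicon, segment = NULL) {
  authors <- list.dirs(corpus_dir, recursive = FALSE, full.names = TRUE)
  if (length(authors) == 0) {
    stop("no author sub-directories under ", corpus_dir, call. = FALSE)
  }
  rows <- list()
  for (adir in authors) {
    author <- basename(adir)
    files <- sort(list.files(adir, pattern = "\\.txt$", full.names = TRUE))
    for (f in files) {
      doc <- sub("\\.txt$", "", basename(f))
      toks <- tokenize(readLines(f, encoding = "UTF-8", warn = FALSE))
      if (is.null(segment)) {
        fv <- score_text(toks, lexicon, doc_id = doc)
        fv$author <- author
        rows[[length(rows) + 1L]] <- fv
      } else {
        segs <- segment_text(toks, target = segment)
        for (i in seq_along(segs)) {
          fv <- score_text(segs[[i]], lexicon,
                           doc_id = sprintf("%s_s%03d", doc, i))
          fv$author <- author
          fv$doc <- doc
          fv$segment <- i
          rows[[length(rows) + 1L]] <- fv
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  front <- intersect(c("doc_id", "author", "doc", "segment", "word_count"),
                     names(out))
  out[, c(front, setdiff(names(out), front))]
}

#' Read and write feature tables
#'
#' Plain CSV with header `doc_id, author, word_count, <variable...>`;
#' numeric values round-trip exactly to at least six decimal places.
#'
#' @param path CSV file path.
#' @return `read_features()` returns the feature table data frame.
#' @export
read_features <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("doc_id", "word_count")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0) {
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @param features Feature table data frame.
#' @rdname read_features
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
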