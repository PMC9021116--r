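# Corpus -> document-term matrix utilities: tokenization, stopword removal,
# Porter stemming, and sparsity filtering.

#' Read a corpus CSV
#'
#' Expects UTF-8 CSV/TSV with header columns `id`, `date`, `text` and an
#' optional `group`. Records are sorted by (id, date).
#'
#' @param file Path to the file.
#' @param sep Field separator (`","` or `"\t"`).
#' @return A data frame with columns `id`, `date` (POSIXct), `text` and
#'   optionally `group`.
#' @export
read_corpus <- function(file, sep = ",") {
  x <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                         stringsAsFactors = FALSE, comment.char = "",
                         encoding = "UTF-8")
  need <- c("id", "date", "text")
  if (!all(need %in% names(x))) {
    stop("corpus file must have columns id, date, text")
  }
  d <- as.POSIXct(x$date, tz = "UTC",
                  tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                 "%Y-%m-%d", "%m/%d/%Y %H:%M", "%m/%d/%Y"))
  if (anyNA(d)) stop("unparseable timestamps in 'date' column")
  x$date <- d
  x[order(x$id, x$date), , drop = FALSE]
}

#' English stopword list
#'
#' The fixed Snowball-style English stopword list shipped with the package
#' (so that preprocessing is bit-reproducible).
#'
#' @return Character vector of stopwords.
#' @export
dynega_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "dynega")
  readLines(path, encoding = "UTF-8")
}

#' Preprocess a corpus into token streams
#'
#' Lowercases each text, strips URLs (`http(s)://...`, `www....`),
#' punctuation and numbers, splits on non-alphabetic characters, removes
#' stopwords, and Porter-stems the remaining tokens. Records whose text
#' becomes empty are retained (they produce all-zero document rows) with a
#' warning.
#'
#' @param text Character vector of raw documents.
#' @param stopwords Character vector of stopwords to drop (applied before
#'   stemming); defaults to [dynega_stopwords()].
#' @return A list of character vectors (stemmed tokens per document).
#' @export
preprocess_corpus <- function(text, stopwords = dynega_stopwords()) {
  if (length(text) == 0) stop("empty corpus")
  text <- tolower(enc2utf8(as.character(text)))
  text <- gsub("https?://[^[:space:]]+", " ", text)
  text <- gsub("www\\.[^[:space:]]+", " ", text)
  tokens <- strsplit(text, "[^a-z]+")
  tokens <- lapply(tokens, function(tk) {
    tk <- tk[nzchar(tk)]
    tk <- tk[!tk %in% stopwords]
    porter_stem(tk)
  })
  n_empty <- sum(lengths(tokens) == 0)
  if (n_empty > 0) {
    warning(n_empty, " document(s) became empty after preprocessing; ",
            "retained as all-zero rows")
  }
  tokens
}

#' Build a document-term matrix with a sparsity filter
#'
#' Counts stemmed tokens per document and removes terms whose sparsity (the
#' fraction of documents in which the term does not occur) exceeds
#' `sparsity`. Columns are sorted lexicographically.
#'
#' @param tokens List of token vectors from [preprocess_corpus()].
#' @param sparsity Threshold in (0, 1]; a term is kept iff its sparsity is
#'   `<= sparsity`. `1` keeps every term.
#' @return A dense integer matrix (documents x terms) with the vocabulary as
#'   column names.
#' @export
build_dtm <- function(tokens, sparsity = 0.9935) {
  if (!is.numeric(sparsity) || sparsity <= 0 || sparsity > 1) {
    stop("sparsity threshold must be in (0, 1]")
  }
  n <- length(tokens)
  if (n == 0) stop("empty corpus")
  vocab <- sort(unique(unlist(tokens)))
  dtm <- matrix(0L, n, length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    if (length(tokens[[i]])) {
      tb <- table(tokens[[i]])
      dtm[i, names(tb)] <- as.integer(tb)
    }
  }
  doc_freq <- colSums(dtm > 0)
  keep <- (1 - doc_freq / n) <= sparsity
  dtm[, keep, drop = FALSE]
}

#' Write a document-term matrix bundle
#'
#' Writes sparse MatrixMarket counts (`counts.mtx`), the vocabulary
#' (`vocabulary.tsv`) and optional row metadata (`rows.tsv`) into a
#' directory.
#'
#' @param dtm Matrix from [build_dtm()].
#' @param dir Output directory (created if needed).
#' @param row_meta Optional data frame of per-document metadata.
#' @return Invisibly, `dir`.
#' @export
write_dtm <- function(dtm, dir, row_meta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(dtm != 0, arr.ind = TRUE)
  sm <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2],
                             x = as.numeric(dtm[idx]), dims = dim(dtm))
  Matrix::writeMM(sm, file.path(dir, "counts.mtx"))
  utils::write.table(data.frame(term = colnames(dtm)),
                     file.path(dir, "vocabulary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(row_meta)) {
    utils::write.table(row_meta, file.path(dir, "rows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Porter stemmer
#'
#' Reduces English words to their stems with the original Porter suffix
#' stripping algorithm (the five-step 1980 formulation). Input is expected to
#' be lowercase alphabetic tokens; words of two letters or fewer are returned
#' unchanged.
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of stems.
#'
#' @examples
#' porter_stem(c("caresses", "ponies", "relational", "generalizations"))
#' @export
porter_stem <- function(words) {
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

# --- Porter algorithm internals (operate on one word as a character vector) -

p_is_cons <- function(ch, i) {
  # consonant classification; y is a vowel iff preceded by a consonant
  out <- logical(length(ch))
  for (k in seq_along(ch)) {
    c0 <- ch[k]
    if (c0 %in% c("a", "e", "i", "o", "u")) {
      out[k] <- FALSE
    } else if (c0 == "y") {
      out[k] <- if (k == 1) TRUE else !out[k - 1]
    } else {
      out[k] <- TRUE
    }
  }
  out[i]
}

p_measure <- function(stem) {
  if (length(stem) == 0) return(0L)
  cons <- p_is_cons(stem, seq_along(stem))
  # count VC transitions in the consonant/vowel pattern
  rle_v <- rle(cons)$values
  sum(rle_v[-length(rle_v)] == FALSE & rle_v[-1] == TRUE)
}

p_has_vowel <- function(stem) {
  length(stem) > 0 && any(!p_is_cons(stem, seq_along(stem)))
}

p_double_cons <- function(w) {
  n <- length(w)
  n >= 2 && w[n] == w[n - 1] && p_is_cons(w, n)
}

p_cvc <- function(w) {
  n <- length(w)
  if (n < 3) return(FALSE)
  cons <- p_is_cons(w, c(n - 2, n - 1, n))
  cons[1] && !cons[2] && cons[3] && !(w[n] %in% c("w", "x", "y"))
}

p_ends <- function(w, suf) {
  n <- length(w); k <- nchar(suf)
  n >= k && paste(w[(n - k + 1):n], collapse = "") == suf
}

p_chop <- function(w, k) w[seq_len(length(w) - k)]

porter_stem1 <- function(word) {
  if (nchar(word) <= 2 || grepl("[^a-z]", word)) return(word)
  w <- strsplit(word, "")[[1]]

  # Step 1a
  if (p_ends(w, "sses")) w <- p_chop(w, 2)
  else if (p_ends(w, "ies")) w <- p_chop(w, 2)
  else if (!p_ends(w, "ss") && p_ends(w, "s")) w <- p_chop(w, 1)

  # Step 1b
  step1b2 <- FALSE
  if (p_ends(w, "eed")) {
    if (p_measure(p_chop(w, 3)) > 0) w <- p_chop(w, 1)
  } else if (p_ends(w, "ed") && p_has_vowel(p_chop(w, 2))) {
    w <- p_chop(w, 2); step1b2 <- TRUE
  } else if (p_ends(w, "ing") && p_has_vowel(p_chop(w, 3))) {
    w <- p_chop(w, 3); step1b2 <- TRUE
  }
  if (step1b2) {
    if (p_ends(w, "at") || p_ends(w, "bl") || p_ends(w, "iz")) {
      w <- c(w, "e")
    } else if (p_double_cons(w) && !(w[length(w)] %in% c("l", "s", "z"))) {
      w <- p_chop(w, 1)
    } else if (p_measure(w) == 1 && p_cvc(w)) {
      w <- c(w, "e")
    }
  }

  # Step 1c
  if (p_ends(w, "y") && p_has_vowel(p_chop(w, 1))) w[length(w)] <- "i"

  # Step 2 (condition: m > 0 on the stem before the suffix)
  rules2 <- list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
    c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
    c("entli", "ent"), c("eli", "e"), c("ousli", "ous"),
    c("ization", "ize"), c("ation", "ate"), c("ator", "ate"),
    c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
    c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"),
    c("biliti", "ble"))
  w <- p_apply_rules(w, rules2, min_m = 1)

  # Step 3
  rules3 <- list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", ""))
  w <- p_apply_rules(w, rules3, min_m = 1)

  # Step 4 (condition: m > 1)
  rules4 <- list(
    c("ement", ""), c("ance", ""), c("ence", ""), c("able", ""),
    c("ible", ""), c("ment", ""), c("ant", ""), c("ent", ""), c("ism", ""),
    c("ate", ""), c("iti", ""), c("ous", ""), c("ive", ""), c("ize", ""),
    c("ion", NA), c("al", ""), c("er", ""), c("ic", ""), c("ou", ""))
  n0 <- length(w)
  for (r in rules4) {
    if (p_ends(w, r[1])) {
      stem <- p_chop(w, nchar(r[1]))
      if (identical(r[1], "ion")) {
        # only strip "ion" after s or t
        if (length(stem) > 0 && stem[length(stem)] %in% c("s", "t") &&
            p_measure(stem) > 1) {
          w <- stem
        }
      } else if (p_measure(stem) > 1) {
        w <- stem
      }
      break
    }
  }

  # Step 5a
  if (p_ends(w, "e")) {
    stem <- p_chop(w, 1)
    m <- p_measure(stem)
    if (m > 1 || (m == 1 && !p_cvc(stem))) w <- stem
  }
  # Step 5b
  if (p_measure(w) > 1 && p_double_cons(w) && w[length(w)] == "l") {
    w <- p_chop(w, 1)
  }
  paste(w, collapse = "")
}

p_apply_rules <- function(w, rules, min_m) {
  for (r in rules) {
    if (p_ends(w, r[1])) {
      stem <- p_chop(w, nchar(r[1]))
      if (p_measure(stem) >= min_m) {
        w <- c(stem, strsplit(r[2], "")[[1]])
      }
      return(w)
    }
  }
  w
}
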