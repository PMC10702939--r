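# Compact English stopword list (function words only); configurable at every
# call site.
.stopwords_en <- c(
  "a", "about", "above", "after", "again", "against", "all", "am", "an",
  "and", "any", "are", "aren", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "cannot", "could",
  "couldn", "did", "didn", "do", "does", "doesn", "doing", "don", "down",
  "during", "each", "few", "for", "from", "further", "had", "hadn", "has",
  "hasn", "have", "haven", "having", "he", "her", "here", "hers", "herself",
  "him", "himself", "his", "how", "i", "if", "in", "into", "is", "isn", "it",
  "its", "itself", "just", "ll", "me", "more", "most", "mustn", "my",
  "myself", "no", "nor", "not", "now", "of", "off", "on", "once", "only",
  "or", "other", "ought", "our", "ours", "ourselves", "out", "over", "own",
  "re", "same", "shan", "she", "should", "shouldn", "so", "some", "such",
  "than", "that", "the", "their", "theirs", "them", "themselves", "then",
  "there", "these", "they", "this", "those", "through", "to", "too", "under",
  "until", "up", "ve", "very", "was", "wasn", "we", "were", "weren", "what",
  "when", "where", "which", "while", "who", "whom", "why", "will", "with",
  "won", "would", "wouldn", "you", "your", "yours", "yourself", "yourselves",
  # apostrophe-stripped contractions ("don't" tokenizes to "dont")
  "arent", "cant", "couldnt", "didnt", "doesnt", "dont", "hadnt", "hasnt",
  "havent", "hes", "id", "ill", "im", "isnt", "ive", "its", "lets",
  "mustnt", "shant", "shes", "shouldnt", "thats", "theres", "theyll",
  "theyre", "theyve", "wasnt", "werent", "weve", "whats", "wont", "wouldnt",
  "youd", "youll", "youre", "youve")

#' English stopword list
#'
#' The default stopword list used by \code{\link{preprocess_text}}: a compact
#' set of English function words. Supply your own character vector to any
#' caller to override it.
#'
#' @return Character vector of lowercase stopwords.
#' @export
english_stopwords <- function() .stopwords_en

#' Tokenize and clean raw text
#'
#' Deterministic pipeline: lowercase, strip URLs and user handles, strip
#' digits and punctuation, split on whitespace, drop stopwords, drop tokens
#' shorter than \code{min_len}.
#'
#' @param text character vector of raw documents.
#' @param stopwords character vector of tokens to drop.
#' @param min_len minimum surviving token length (default 2).
#' @return A list of character vectors (one token vector per document;
#'   possibly empty).
#' @examples
#' preprocess_text("I feel SO empty...") # list(c("feel", "empty"))
#' @export
preprocess_text <- function(text, stopwords = english_stopwords(),
                            min_len = 2L) {
  text <- tolower(as.character(text))
  text <- gsub("(https?://|www\\.)\\S+", " ", text)
  text <- gsub("@\\w+", " ", text)
  text <- gsub("'", "", text)           # contractions collapse: don't -> dont
  text <- gsub("[^a-z]+", " ", text)    # digits, punctuation, symbols
  toks <- strsplit(trimws(text), "\\s+")
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    tk <- tk[!(tk %in% stopwords)]
    tk[nchar(tk) >= min_len]
  })
}

#' Build a binary document-term matrix
#'
#' The vocabulary is every token occurring in at least \code{min_df}
#' documents, ordered lexicographically. Entry (d, w) is 1 when term w
#' occurs in document d after preprocessing, else 0 — term frequency is
#' deliberately discarded (presence encoding).
#'
#' @param text character vector of raw documents, or a data frame with
#'   \code{text} and \code{label} columns as returned by
#'   \code{\link{read_corpus}}.
#' @param labels binary (0/1) labels, one per document; taken from
#'   \code{text$label} when a corpus data frame is given.
#' @param min_df minimum document frequency for a term to enter the
#'   vocabulary (default 2).
#' @param ... passed to \code{\link{preprocess_text}}.
#' @return An object of class \code{"dtm"}: list with \code{x} (binary
#'   matrix, terms as column names), \code{vocab}, and \code{labels}.
#' @export
build_dtm <- function(text, labels = NULL, min_df = 2L, ...) {
  if (is.data.frame(text)) {
    if (is.null(labels)) labels <- text$label
    text <- text$text
  }
  if (is.null(labels)) stop("`labels` required", call. = FALSE)
  if (length(labels) != length(text))
    stop("one label per document required", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  if (length(text) == 0L) stop("empty corpus", call. = FALSE)
  toks <- lapply(preprocess_text(text, ...), unique)
  df <- table(unlist(toks))
  vocab <- sort(names(df[df >= min_df]))
  if (length(vocab) == 0L)
    stop("no term reaches min_df = ", min_df, "; lower `min_df`",
         call. = FALSE)
  x <- matrix(0L, length(toks), length(vocab),
              dimnames = list(NULL, vocab))
  for (d in seq_along(toks)) {
    hit <- match(toks[[d]], vocab)
    x[d, hit[!is.na(hit)]] <- 1L
  }
  new_dtm(x, as.integer(labels))
}

new_dtm <- function(x, labels) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  structure(list(x = x, vocab = colnames(x), labels = as.integer(labels)),
            class = "dtm")
}

#' @export
print.dtm <- function(x, ...) {
  cat(sprintf("Binary document-term matrix: %d documents x %d terms (%d positive labels)\n",
              nrow(x$x), ncol(x$x), sum(x$labels)))
  invisible(x)
}

#' @export
dim.dtm <- function(x) dim(x$x)

#' Train/test split of a document-term matrix
#'
#' Disjoint, exhaustive partition of the rows; stratified by label by
#' default so both splits preserve the class imbalance. Deterministic under
#' \code{seed}.
#'
#' @param dtm a \code{\link{build_dtm}} object.
#' @param train_fraction fraction of rows in the training split (default 0.8).
#' @param stratified stratify by label (default TRUE).
#' @param seed integer seed.
#' @return List with \code{train} and \code{test}, both \code{"dtm"} objects,
#'   plus the row indices used.
#' @export
split_dtm <- function(dtm, train_fraction = 0.8, stratified = TRUE,
                      seed = NULL) {
  stopifnot(inherits(dtm, "dtm"),
            train_fraction > 0, train_fraction < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(dtm$x)
  if (stratified) {
    if (any(table(dtm$labels) < 2L))
      stop("stratified split needs at least 2 members per class",
           call. = FALSE)
    idx_train <- integer(0)
    for (cl in sort(unique(dtm$labels))) {
      rows <- which(dtm$labels == cl)
      n_tr <- round(length(rows) * train_fraction)
      idx_train <- c(idx_train, sample(rows, n_tr))
    }
    idx_train <- sort(idx_train)
  } else {
    idx_train <- sort(sample.int(n, round(n * train_fraction)))
  }
  idx_test <- setdiff(seq_len(n), idx_train)
  list(train = new_dtm(dtm$x[idx_train, , drop = FALSE], dtm$labels[idx_train]),
       test = new_dtm(dtm$x[idx_test, , drop = FALSE], dtm$labels[idx_test]),
       idx_train = idx_train, idx_test = idx_test)
}

#' Read a labeled corpus / persist a document-term matrix
#'
#' `read_corpus()` reads a CSV/TSV file with \code{text} and \code{label}
#' columns (quoting-safe). Labels may be 0/1 or the strings
#' "non-depressive"/"depressive"; anything else is rejected with its row
#' number. `write_dtm()`/`read_dtm()` persist a binary matrix as TSV with
#' the vocabulary as header and the label as the first column, so that
#' \code{read_dtm(write_dtm(x))} restores \code{x} exactly.
#'
#' @param path file path.
#' @param sep field separator (comma default; use "\\t" for TSV).
#' @return `read_corpus()`: data frame with \code{text} and integer
#'   \code{label}; `read_dtm()`: a \code{"dtm"} object.
#' @export
read_corpus <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                         stringsAsFactors = FALSE, comment.char = "",
                         colClasses = "character")
  if (!all(c("text", "label") %in% names(d)))
    stop("corpus file needs `text` and `label` columns", call. = FALSE)
  lab <- tolower(trimws(d$label))
  map <- c("0" = 0L, "1" = 1L, "non-depressive" = 0L, "depressive" = 1L)
  bad <- which(!(lab %in% names(map)))
  if (length(bad))
    stop("unknown label(s) at data row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(d$label[bad]), collapse = ", "), call. = FALSE)
  data.frame(text = d$text, label = unname(map[lab]),
             stringsAsFactors = FALSE)
}

#' @rdname read_corpus
#' @param dtm a \code{"dtm"} object.
#' @export
write_dtm <- function(dtm, path) {
  stopifnot(inherits(dtm, "dtm"))
  out <- data.frame(label = dtm$labels, dtm$x, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_corpus
#' @export
read_dtm <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         comment.char = "")
  x <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(x) <- "integer"
  new_dtm(x, d[[1L]])
}
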