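#' Specification for a synthetic planted-feature corpus
#'
#' Emulates the structure of a preprocessed social-media depression corpus:
#' a binary, high-dimensional, class-imbalanced document-term matrix in
#' which a small planted subset of informative terms suffices for
#' near-perfect classification. Informative columns are present with
#' probability \code{p_pos} in the positive ("depressive") class and
#' \code{p_neg} in the negative class; background columns are
#' Bernoulli(\code{q_background}) in both classes.
#'
#' The default class imbalance (83.1\% positive) mirrors a 3937/900
#' depressive/non-depressive composition; the default matrix size keeps a
#' full wrapper search tractable while preserving the planted-subset
#' structure.
#'
#' @param n_docs number of documents.
#' @param vocab_size number of terms.
#' @param n_informative number of planted informative terms
#'   (\code{<= vocab_size}).
#' @param positive_fraction fraction of documents in class 1.
#' @param p_pos,p_neg informative-term presence probabilities by class;
#'   requires \code{0 <= p_neg < p_pos <= 1}.
#' @param q_background background-term presence probability.
#' @param seed integer seed.
#' @return An object of class \code{"synth_spec"}.
#' @export
synth_spec <- function(n_docs = 400L, vocab_size = 80L, n_informative = 10L,
                       positive_fraction = 0.831, p_pos = 0.9, p_neg = 0.1,
                       q_background = 0.5, seed = NULL) {
  if (n_informative > vocab_size)
    stop("`n_informative` must not exceed `vocab_size`", call. = FALSE)
  if (!(p_neg >= 0 && p_neg < p_pos && p_pos <= 1))
    stop("need 0 <= p_neg < p_pos <= 1", call. = FALSE)
  if (q_background < 0 || q_background > 1)
    stop("`q_background` must lie in [0, 1]", call. = FALSE)
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("`positive_fraction` must lie in (0, 1)", call. = FALSE)
  structure(list(n_docs = as.integer(n_docs),
                 vocab_size = as.integer(vocab_size),
                 n_informative = as.integer(n_informative),
                 positive_fraction = positive_fraction,
                 p_pos = p_pos, p_neg = p_neg,
                 q_background = q_background, seed = seed),
            class = "synth_spec")
}

# pronounceable pseudo-words, alphabetic, length >= 6, never stopwords
.synth_vocab <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  words <- character(0)
  need <- n
  while (length(words) < n) {
    w <- replicate(need, paste0(sample(cons, 3, TRUE), sample(vow, 3, TRUE),
                                collapse = ""))
    words <- unique(c(words, setdiff(w, english_stopwords())))
    need <- n - length(words)
  }
  words[seq_len(n)]
}

#' Generate a synthetic document-term matrix with planted features
#'
#' Draws labels to match the specified class imbalance (counts rounded to
#' sum to \code{n_docs}, row order shuffled), then fills informative and
#' background columns from their class-conditional Bernoulli
#' probabilities. Deterministic under the spec's seed.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @return List with \code{dtm} (a \code{"dtm"} object with a generated
#'   vocabulary) and \code{truth} (logical mask marking the planted
#'   informative columns).
#' @export
synth_dtm <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!is.null(spec$seed)) set.seed(as.integer(spec$seed))
  n <- spec$n_docs
  m <- spec$vocab_size
  n_pos <- round(n * spec$positive_fraction)
  labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
  vocab <- sort(.synth_vocab(m))
  truth <- seq_len(m) %in% sample.int(m, spec$n_informative)
  x <- matrix(0L, n, m, dimnames = list(NULL, vocab))
  for (j in seq_len(m)) {
    p <- if (truth[j]) ifelse(labels == 1L, spec$p_pos, spec$p_neg)
         else spec$q_background
    x[, j] <- as.integer(runif(n) < p)
  }
  list(dtm = new_dtm(x, labels), truth = truth)
}

#' Render a synthetic matrix as a pseudo-text corpus
#'
#' Each matrix row becomes a whitespace-joined document over the generated
#' vocabulary (token order shuffled within the document). Tokens are
#' alphabetic, at least six characters, and never stopwords, so the default
#' \code{\link{preprocess_text}} pipeline preserves them and
#' \code{\link{build_dtm}} with \code{min_df = 1} recovers the planted
#' matrix up to column ordering.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @return List with \code{corpus} (data frame with \code{text} and
#'   \code{label}), \code{dtm}, and \code{truth} as in
#'   \code{\link{synth_dtm}}.
#' @export
synth_corpus <- function(spec = synth_spec()) {
  sim <- synth_dtm(spec)
  vocab <- sim$dtm$vocab
  text <- apply(sim$dtm$x, 1L, function(row) {
    present <- vocab[row == 1L]
    paste(sample(present), collapse = " ")
  })
  list(corpus = data.frame(text = text, label = sim$dtm$labels,
                           stringsAsFactors = FALSE),
       dtm = sim$dtm, truth = sim$truth)
}
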