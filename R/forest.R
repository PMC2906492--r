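# R-side random forest driver over the compiled CART builder.
#
# For classification, class imbalance is handled by down-sampling: every
# tree's bootstrap draws the same number of samples (with replacement) from
# each class, that number being the minority-class size. The per-tree in-bag
# class counts are stored so the 1:1 contract is directly inspectable.

growForest <- function(X, y, ntree, mtry, minnode, classification, seed) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  n <- nrow(X)
  withSeed(seed, {
    if (classification) {
      pos <- which(y == 1)
      neg <- which(y == 0)
      m <- min(length(pos), length(neg))
      draws <- lapply(seq_len(ntree), function(t)
        c(sample(pos, m, replace = TRUE), sample(neg, m, replace = TRUE)))
    } else {
      draws <- lapply(seq_len(ntree), function(t)
        sample.int(n, n, replace = TRUE))
    }
    trees <- lapply(draws, function(idx)
      cpp_build_tree(X, as.numeric(y), as.integer(idx - 1L),
                     as.integer(mtry), as.integer(minnode), classification))
    inbag <- if (classification) {
      t(vapply(draws, function(idx)
        c(pos = sum(y[idx] == 1), neg = sum(y[idx] == 0)), numeric(2)))
    } else {
      matrix(lengths(draws), ncol = 1, dimnames = list(NULL, "n"))
    }
    list(trees = trees, inbag = inbag, classification = classification)
  })
}

# Per-tree predictions: matrix [nrow(X) x ntree] of leaf values
# (class-1 leaf fraction for classification, leaf mean for regression).
forestTreeValues <- function(forest, X) {
  vapply(forest$trees, function(tr) cpp_predict_tree(tr, X),
         numeric(nrow(X)))
}

# Aggregate prediction. Classification: O = fraction of trees whose vote
# (leaf fraction > 0.5) is the stabilizing class. Regression: mean of tree
# means.
forestPredict <- function(forest, X, return_votes = FALSE) {
  V <- forestTreeValues(forest, X)
  if (is.null(dim(V))) V <- matrix(V, nrow = nrow(X))
  if (forest$classification) {
    votes <- V > 0.5
    O <- rowMeans(votes)
    if (return_votes) return(list(O = O, votes = votes))
    O
  } else {
    rowMeans(V)
  }
}
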