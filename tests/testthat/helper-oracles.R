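# Brute-force oracles, independent of the implementation paths they check.

# dense-vector cosine enumeration for sense selection
oracle_best_sense <- function(profiles, context_counts, vocab) {
  dense <- function(v) {
    out <- setNames(numeric(length(vocab)), vocab)
    out[names(v)] <- as.numeric(v)
    out
  }
  cx <- dense(context_counts)
  best <- NULL
  best_score <- -Inf
  for (cui in sort(names(profiles))) {
    p <- dense(profiles[[cui]])
    den <- sqrt(sum(p^2)) * sqrt(sum(cx^2))
    score <- if (den == 0) 0 else sum(p * cx) / den
    if (score > best_score + 1e-12) {
      best <- cui
      best_score <- score
    }
  }
  best
}

# n-gram / skip-bigram enumeration and clipped recall
oracle_ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character(0))
  out <- character(0)
  for (i in 1:(length(tokens) - n + 1)) {
    out <- c(out, paste(tokens[i:(i + n - 1)], collapse = " "))
  }
  out
}

oracle_su_units <- function(tokens, skip, unigrams = TRUE) {
  out <- if (unigrams) tokens else character(0)
  L <- length(tokens)
  if (L >= 2) {
    for (i in 1:(L - 1)) {
      for (j in (i + 1):L) {
        if (j - i - 1 <= skip) out <- c(out, paste(tokens[i], tokens[j]))
      }
    }
  }
  out
}

oracle_recall <- function(peer_units, ref_units) {
  if (length(ref_units) == 0) return(NA_real_)
  matched <- 0
  for (u in unique(ref_units)) {
    matched <- matched + min(sum(ref_units == u), sum(peer_units == u))
  }
  matched / length(ref_units)
}
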