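# Independent naive (quadratic-time) oracles for the complexity estimators
# and the rank statistics. These deliberately use plain string/loop code so
# they share nothing with the package kernels they check.

# LZ'76 exhaustive history: each component is the shortest extension not
# reproducible as a substring of the preceding history; a trailing
# reproducible fragment counts as one final component.
lz76_naive <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  comp <- 0L
  l <- 1L
  while (l <= n) {
    k <- 1L
    repeat {
      if (l + k - 1L > n) break                    # incomplete final component
      sub <- paste(ch[l:(l + k - 1L)], collapse = "")
      hist <- if (l + k - 2L >= 1L) paste(ch[1:(l + k - 2L)], collapse = "") else ""
      if (!grepl(sub, hist, fixed = TRUE)) break   # shortest non-reproducible
      k <- k + 1L
    }
    comp <- comp + 1L
    l <- l + k
  }
  comp
}

# LZ'78 incremental dictionary; trailing already-known fragment is one phrase
lz78_naive <- function(s) {
  ch <- strsplit(s, "")[[1]]
  dict <- character(0)
  cur <- ""
  phrases <- 0L
  for (c in ch) {
    cur <- paste0(cur, c)
    if (!(cur %in% dict)) {
      dict <- c(dict, cur)
      phrases <- phrases + 1L
      cur <- ""
    }
  }
  if (nzchar(cur)) phrases <- phrases + 1L
  phrases
}

# Greedy right-anchored T-decomposition, string-slicing version
titchener_naive <- function(s) {
  n <- nchar(s)
  stopifnot(n >= 2)
  pats <- character(0)
  exps <- integer(0)
  tc <- 0
  rem <- substr(s, 1L, n - 1L)
  while (nchar(rem) > 0L) {
    start <- nchar(rem)                            # literal position
    if (length(pats)) {
      for (l in seq_along(pats)) {
        p <- pats[l]; pl <- nchar(p); cnt <- 0L
        while (cnt < exps[l] && start - pl >= 1L &&
               substr(rem, start - pl, start - 1L) == p) {
          start <- start - pl
          cnt <- cnt + 1L
        }
      }
    }
    pat <- substr(rem, start, nchar(rem))
    pl <- nchar(pat)
    k <- 1L
    while (start - pl >= 1L && substr(rem, start - pl, start - 1L) == pat) {
      start <- start - pl
      k <- k + 1L
    }
    pats <- c(pats, pat)
    exps <- c(exps, k)
    tc <- tc + log2(k + 1)
    rem <- substr(rem, 1L, start - 1L)
  }
  tc
}

# Pincus ApEn by direct double loop (Chebyshev distance, self-matches in)
apen_naive <- function(x, m, r_abs) {
  n <- length(x)
  phi <- function(mm) {
    N <- n - mm + 1L
    cnt <- numeric(N)
    for (i in 1:N) {
      for (j in 1:N) {
        if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) <= r_abs)
          cnt[i] <- cnt[i] + 1
      }
    }
    mean(log(cnt / N))
  }
  phi(m) - phi(m + 1L)
}

# Richman-Moorman SampEn by direct pair loop (self-matches out)
sampen_naive <- function(x, m, r_abs) {
  n <- length(x)
  N <- n - m
  A <- 0L; B <- 0L
  for (i in 1:(N - 1L)) {
    for (j in (i + 1L):N) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r_abs) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r_abs) A <- A + 1L
      }
    }
  }
  list(A = A, B = B, sampen = if (B > 0) -log(A / B) else NA_real_)
}

# AUC by explicit pair enumeration, cases-low orientation
auc_naive <- function(scores, labels) {
  ca <- scores[labels == "case"]
  co <- scores[labels == "control"]
  tot <- 0
  for (a in ca) for (b in co) tot <- tot + (b > a) + 0.5 * (b == a)
  tot / (length(ca) * length(co))
}

random_string <- function(len, alphabet = c("0", "1")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
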