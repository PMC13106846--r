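#' Symbol string container
#'
#' A thin wrapper around a character scalar recording the coarse-graining
#' scheme and the declared alphabet of a symbolised ECG strip.
#'
#' @param text Character scalar, the symbol sequence.
#' @param scheme One of `"TC"`, `"XD"`, `"FD"` or `"raw"`.
#' @param alphabet Character vector of admissible symbols.
#' @return An object of class `symbol_string`.
#' @export
symbol_string <- function(text, scheme = "raw", alphabet = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.null(alphabet)) alphabet <- sort(unique(strsplit(text, "")[[1]]))
  chars <- strsplit(text, "")[[1]]
  if (length(chars) && !all(chars %in% alphabet))
    stop("symbol string contains characters outside its declared alphabet")
  structure(text, class = "symbol_string", scheme = scheme, alphabet = alphabet)
}

#' @export
print.symbol_string <- function(x, ...) {
  n <- nchar(unclass(x))
  head <- substr(unclass(x), 1L, 60L)
  cat(sprintf("<symbol_string %s, n=%d, alphabet={%s}>\n  %s%s\n",
              attr(x, "scheme"), n, paste(attr(x, "alphabet"), collapse = ","),
              head, if (n > 60L) "..." else ""))
  invisible(x)
}

.as_text <- function(s) {
  if (inherits(s, "symbol_string")) return(unclass(s))
  stopifnot(is.character(s), length(s) == 1L)
  s
}

#' Lempel-Ziv 1976 complexity
#'
#' Number of components in the exhaustive-history decomposition of a symbol
#' string (Lempel & Ziv 1976), computed with the Kaspar-Schuster scan.
#' The final, possibly incomplete, component counts as one.
#'
#' @param s A `symbol_string` or character scalar.
#' @return Integer component count.
#' @export
lz76 <- function(s) {
  s <- .as_text(s)
  if (nchar(s) == 0L) stop("lz76: empty string")
  lz76_count(s)
}

#' Lempel-Ziv 1978 complexity
#'
#' Number of phrases in the incremental-dictionary parsing of a symbol
#' string (Lempel & Ziv 1978). Each phrase is the shortest prefix of the
#' remaining input not yet in the dictionary; a trailing fragment that is
#' already a dictionary entry counts as one final phrase.
#'
#' @inheritParams lz76
#' @return Integer phrase count.
#' @export
lz78 <- function(s) {
  s <- .as_text(s)
  if (nchar(s) == 0L) stop("lz78: empty string")
  lz78_count(s)
}

#' Titchener T-complexity
#'
#' T-complexity of a symbol string by greedy T-decomposition: the string is
#' decomposed right-to-left as `p_m^k_m ... p_1^k_1 a`, where `a` is the
#' final literal and each pattern is the longest codeword of the T-code
#' grown so far. The complexity is `sum(log2(k_i + 1))`, in taugs.
#'
#' @inheritParams lz76
#' @return Numeric T-complexity (taugs).
#' @export
titchener <- function(s) {
  s <- .as_text(s)
  if (nchar(s) < 2L) stop("titchener: string length must be >= 2")
  tcomp_cpp(s)
}

#' Shannon entropy of a symbol string
#'
#' Order-1 (single-symbol) Shannon entropy over observed symbol frequencies.
#'
#' @inheritParams lz76
#' @return Entropy in bits per symbol.
#' @export
shannon_entropy <- function(s) {
  s <- .as_text(s)
  if (nchar(s) == 0L) stop("shannon_entropy: empty string")
  p <- table(strsplit(s, "")[[1]])
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Entropy estimator parameters
#'
#' Embedding length and tolerance for approximate and sample entropy.
#' The tolerance is expressed as a fraction of the series standard
#' deviation (the field-standard parameterisation); `m = 2`, `r = 0.2`
#' are the conventional defaults.
#'
#' @param m Integer embedding length, `>= 1`.
#' @param r Positive tolerance as a fraction of the series sd.
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2L, r = 0.2) {
  m <- as.integer(m)
  if (m < 1L) stop("entropy_params: m must be >= 1")
  if (!is.numeric(r) || r <= 0) stop("entropy_params: r must be > 0")
  structure(list(m = m, r = r), class = "entropy_params")
}

.entropy_tolerance <- function(x, r) {
  s <- stats::sd(x)
  tol <- r * s
  if (!is.finite(tol) || tol <= 0) {
    # zero-variance series: a relative tolerance degenerates; apply a small
    # absolute floor so constant series report zero entropy rather than NaN
    tol <- 1e-10
    message("entropy tolerance degenerated on a zero-variance series; ",
            "absolute floor 1e-10 applied")
  }
  tol
}

#' Approximate entropy (ApEn)
#'
#' Pincus approximate entropy of a real-valued series with Chebyshev
#' distance, self-matches included: `phi(m) - phi(m+1)`.
#'
#' @param x Numeric series (e.g. the raw voltage samples of a strip).
#' @param params An [entropy_params()] object.
#' @return Approximate entropy (nats).
#' @export
approx_entropy <- function(x, params = entropy_params()) {
  stopifnot(is.numeric(x))
  if (length(x) <= params$m + 1L)
    stop("approx_entropy: series too short for embedding length m")
  apen_cpp(as.numeric(x), params$m, .entropy_tolerance(x, params$r))
}

#' Sample entropy (SampEn)
#'
#' Richman-Moorman sample entropy: `-ln(A/B)` over distinct template pairs,
#' self-matches excluded; `B` counts length-`m` matches, `A` length-`m+1`.
#'
#' @inheritParams approx_entropy
#' @return Sample entropy (nats).
#' @export
sample_entropy <- function(x, params = entropy_params()) {
  stopifnot(is.numeric(x))
  if (length(x) <= params$m + 1L)
    stop("sample_entropy: series too short for embedding length m")
  cnt <- sampen_counts(as.numeric(x), params$m, .entropy_tolerance(x, params$r))
  if (cnt$B == 0) stop("sample_entropy: no template matches (B = 0); entropy undefined")
  -log(cnt$A / cnt$B)  # Inf when no m+1 matches exist
}

#' Length-normalise a complexity value
#'
#' Converts raw estimator output to a per-sample rate: LZ'76 counts are
#' normalised by `n / log2(n)`, LZ'78 counts and T-complexity by the
#' sequence length `n`; Shannon, approximate and sample entropy are already
#' rates and pass through unchanged.
#'
#' @param value Raw estimator output.
#' @param estimator One of `"LZ76"`, `"LZ78"`, `"Titchener"`, `"Shannon"`,
#'   `"ApEn"`, `"SampEn"`.
#' @param n Source length in samples (`>= 2`).
#' @return Normalised value (bit/sample where defined).
#' @export
normalize_complexity <- function(value, estimator, n) {
  if (n < 2) stop("normalize_complexity: n must be >= 2")
  estimator <- match.arg(estimator,
                         c("LZ76", "LZ78", "Titchener", "Shannon", "ApEn", "SampEn"))
  switch(estimator,
         LZ76      = value * log2(n) / n,
         LZ78      = value / n,
         Titchener = value / n,
         value)
}

#' Compute one estimator on one strip representation
#'
#' Dispatches a named estimator to its input: symbolic estimators
#' (LZ76, LZ78, Titchener, Shannon) consume a symbol string; ApEn and
#' SampEn consume the raw voltage samples.
#'
#' @param estimator Estimator name as in [normalize_complexity()].
#' @param sym Symbol string (used by symbolic estimators).
#' @param x Raw numeric series (used by ApEn/SampEn).
#' @param params [entropy_params()] for the entropy estimators.
#' @return List with `raw`, `normalised` and `n`.
#' @export
complexity_value <- function(estimator, sym = NULL, x = NULL,
                             params = entropy_params()) {
  estimator <- match.arg(estimator,
                         c("LZ76", "LZ78", "Titchener", "Shannon", "ApEn", "SampEn"))
  if (estimator %in% c("ApEn", "SampEn")) {
    if (is.null(x)) stop("complexity_value: ", estimator, " needs the raw series")
    raw <- if (estimator == "ApEn") approx_entropy(x, params) else sample_entropy(x, params)
    n <- length(x)
  } else {
    if (is.null(sym)) stop("complexity_value: ", estimator, " needs a symbol string")
    raw <- switch(estimator,
                  LZ76 = lz76(sym), LZ78 = lz78(sym),
                  Titchener = titchener(sym), Shannon = shannon_entropy(sym))
    n <- nchar(.as_text(sym))
  }
  list(estimator = estimator, raw = raw,
       normalised = normalize_complexity(raw, estimator, n), n = n)
}
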