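# Independent oracles for the primer-alignment scoring scheme
# (match +1, mismatch 0, gap open -1, gap extend -0.5), written in plain R
# and kept deliberately separate from the package's compiled implementation.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_match <- function(pc, tc) {
  tc %in% c("A", "C", "G", "T") && tc %in% ORACLE_IUPAC[[pc]]
}

# Gotoh fitting-alignment DP: whole primer, free template ends.
oracle_score <- function(primer, template) {
  p <- strsplit(primer, "", fixed = TRUE)[[1L]]
  t <- strsplit(template, "", fixed = TRUE)[[1L]]
  m <- length(p); n <- length(t)
  M <- matrix(-Inf, m + 1L, n + 1L)
  X <- matrix(-Inf, m + 1L, n + 1L)
  Y <- matrix(-Inf, m + 1L, n + 1L)
  M[1L, ] <- 0
  for (i in 2L:(m + 1L)) {
    X[i, 1L] <- max(M[i - 1L, 1L] - 1, X[i - 1L, 1L] - 0.5)
    for (j in 2L:(n + 1L)) {
      s <- as.numeric(oracle_match(p[i - 1L], t[j - 1L]))
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - 1, X[i - 1L, j] - 0.5,
                     Y[i - 1L, j] - 1)
      Y[i, j] <- max(M[i, j - 1L] - 1, Y[i, j - 1L] - 0.5,
                     X[i, j - 1L] - 1)
    }
  }
  max(M[m + 1L, ], X[m + 1L, ])
}

# Exhaustive enumeration of every alignment of the full primer against any
# template window, with affine gap runs scored directly. Exponential; only
# for tiny instances, used to validate oracle_score itself.
enum_score <- function(primer, template) {
  p <- strsplit(primer, "", fixed = TRUE)[[1L]]
  t <- strsplit(template, "", fixed = TRUE)[[1L]]
  m <- length(p); n <- length(t)
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > m) {
      best <<- max(best, score)
      return(invisible())
    }
    if (j <= n) {
      rec(i + 1L, j + 1L, score + as.numeric(oracle_match(p[i], t[j])), "M")
    }
    rec(i + 1L, j, score - if (identical(prev, "X")) 0.5 else 1, "X")
    if (j <= n && !identical(prev, "")) {
      rec(i, j + 1L, score - if (identical(prev, "Y")) 0.5 else 1, "Y")
    }
  }
  for (start in 1L:(n + 1L)) rec(1L, start, 0, "")
  best
}

# random IUPAC primer with a controllable number of degenerate positions
random_primer <- function(len, n_degenerate = 0L) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_degenerate > 0L) {
    pos <- sample(len, min(n_degenerate, len))
    amb <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
    bases[pos] <- sample(amb, length(pos), replace = TRUE)
  }
  paste(bases, collapse = "")
}

random_template <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# plant a (possibly mutated) binding site for `primer` inside a random
# template so alignment scores are not dominated by chance hits
template_with_site <- function(primer, len, n_mut = 0L) {
  site <- vapply(strsplit(primer, "", fixed = TRUE)[[1L]], function(ch) {
    sample(ORACLE_IUPAC[[ch]], 1L)
  }, character(1L))
  if (n_mut > 0L) {
    pos <- sample(length(site), min(n_mut, length(site)))
    site[pos] <- vapply(site[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1L))
  }
  site <- paste(site, collapse = "")
  pad <- max(0L, len - nchar(site))
  left <- sample(0L:pad, 1L)
  paste0(random_template(left), site, random_template(pad - left))
}
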