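#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rlnorm rpois runif setNames t.test var
#' @importFrom utils read.delim write.table head
NULL

# Taxonomy IDs of the 23 vertebrate species used for conserved-site counting.
# Human, mouse and rat are required in every conserved site.
VERTEBRATE_TAXA <- c(
  10090L, 10116L, 10141L, 13616L, 28377L, 30611L, 37347L, 42254L,
  8364L, 9031L, 9258L, 9361L, 9365L, 9371L, 9544L, 9598L,
  9606L, 9615L, 9685L, 9785L, 9796L, 9913L, 9986L
)

REQUIRED_TAXA <- c(9606L, 10090L, 10116L)
REFERENCE_TAXON <- 10116L  # rat: coordinates are reported on this species

MATCH_TYPES <- c("7mer-m8", "7mer-1a", "8mer-1a")

TRF_CLASSES <- c("FIVE_PRIME", "THREE_PRIME_CCA", "THREE_PRIME_U",
                 "INTERNAL", "FULL_LENGTH_EXCLUDED")

AGE_PATTERNS <- c("MONO_UP", "MONO_DOWN", "DIP", "PEAK", "FLAT")

# --- sequence helpers -------------------------------------------------------

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T, N allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# RNA -> DNA normalization applied at every input boundary
rna_to_dna <- function(x) chartr("uU", "tT", x)

check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the DNA alphabet: %s",
                 what, paste(head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# All overlapping start positions of `pattern` in `subject` (plain character).
find_all <- function(pattern, subject) {
  k <- nchar(pattern)
  n <- nchar(subject)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  starts[substring(subject, starts, starts + k - 1L) == pattern]
}

random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# --- hierarchical RNG -------------------------------------------------------

# One master integer seed feeds independent child streams keyed by strings,
# so regenerating one file never perturbs the others. Polynomial rolling
# hash mod (2^31 - 1), always a valid 32-bit seed.
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
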