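## Small shared helpers: seeded RNG streams, sequence utilities, quality codecs.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a root seed and a stream name
#'
#' One root seed drives every simulation; per-sample / per-stage streams are
#' derived by hashing the stream name so that results do not depend on the
#' order in which samples are processed.
#'
#' @param root integer root seed.
#' @param name character stream name (e.g. a sample id).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(paste(name, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(root) + h) %% 2147483647)
}

## Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

## Transversion partners of each base (purine <-> pyrimidine changes only).
TRANSVERSION_PARTNERS <- list(
  A = c("C", "T"), C = c("A", "G"), G = c("C", "T"), T = c("A", "G")
)

#' Is a ref/alt substitution a transversion?
#'
#' @param ref,alt single-character bases (vectorised).
#' @return Logical vector.
#' @export
is_transversion <- function(ref, alt) {
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  out <- rep(FALSE, length(ref))
  out[ok] <- purine[ref[ok]] != purine[alt[ok]]
  out
}

## Vectorised reverse complement of plain character sequences.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Phred+33 codecs for base-quality strings.
qual_to_int <- function(q) utf8ToInt(q) - 33L
int_to_qual <- function(x) intToUtf8(x + 33L)

## Split one long string of per-base quality characters into per-read strings.
split_string <- function(big, lens) {
  stop_at <- cumsum(lens)
  substring(big, stop_at - lens + 1L, stop_at)
}

## Sum of phred scores per read (duplicate-collapse score).
qual_sums <- function(quals) {
  vapply(quals, function(q) sum(utf8ToInt(q)) - 33L * nchar(q), numeric(1),
         USE.NAMES = FALSE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Apply substitutions (pos -> base) to a sequence string.
apply_variants <- function(seq, pos, base) {
  if (length(pos) == 0L) return(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  s[pos] <- base
  paste(s, collapse = "")
}
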