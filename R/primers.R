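# IUPAC-aware primer matching. Bases are encoded as 4-bit sets
# (A=1, C=2, G=4, T=8); two codes are compatible iff their sets intersect.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.iupac_masks <- function(x, what = "sequence") {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- .IUPAC_MASK[ch]
  if (anyNA(m)) {
    bad <- unique(ch[is.na(m)])
    stop(what, " contains non-nucleotide character(s): ",
         paste(bad, collapse = ", "))
  }
  unname(m)
}

#' Define a degenerate primer pair
#'
#' Both primers are written 5'-to-3' on their own strand, in the IUPAC
#' nucleotide alphabet. `max_mismatches` is the per-primer mismatch budget
#' used by the in-silico PCR scan; `three_prime_protected` is the number of
#' 3'-terminal bases in which no mismatch is tolerated (a mismatch near the
#' 3' end blocks polymerase extension, so such sites would not amplify).
#'
#' @param forward,reverse IUPAC nucleotide strings.
#' @param max_mismatches Integer >= 0, mismatches tolerated per primer site.
#' @param three_prime_protected Integer >= 0, protected 3'-terminal bases.
#' @return An object of class `primer_pair`.
#' @examples
#' primer_pair("ACGTRYACGTACGTACGTAC", "TGCAKMTGCATGCATGCATG")
#' @export
primer_pair <- function(forward, reverse, max_mismatches = 2L,
                        three_prime_protected = 3L) {
  stopifnot(is.character(forward), length(forward) == 1L, nchar(forward) > 0L,
            is.character(reverse), length(reverse) == 1L, nchar(reverse) > 0L)
  max_mismatches <- as.integer(max_mismatches)
  three_prime_protected <- as.integer(three_prime_protected)
  if (max_mismatches < 0L || three_prime_protected < 0L)
    stop("max_mismatches and three_prime_protected must be >= 0")
  if (max_mismatches > min(nchar(forward), nchar(reverse)))
    stop("max_mismatches exceeds primer length")
  .iupac_masks(forward, "forward primer")
  .iupac_masks(reverse, "reverse primer")
  structure(
    list(forward = toupper(forward), reverse = toupper(reverse),
         max_mismatches = max_mismatches,
         three_prime_protected = three_prime_protected),
    class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("primer pair\n")
  cat("  forward:", x$forward, sprintf("(%d nt)\n", nchar(x$forward)))
  cat("  reverse:", x$reverse, sprintf("(%d nt)\n", nchar(x$reverse)))
  cat("  max mismatches/primer:", x$max_mismatches,
      " 3'-protected bases:", x$three_prime_protected, "\n")
  invisible(x)
}

#' Match a primer against a genome window
#'
#' Counts positions where the window base is not contained in the primer
#' base's IUPAC set. Returns `NA` (no match) if the count exceeds
#' `max_mismatches` or if any mismatch falls within the
#' `three_prime_protected` terminal bases of the primer.
#'
#' @param primer IUPAC string (5'-to-3').
#' @param window Nucleotide string of the same length, already oriented so
#'   that it reads 5'-to-3' along the primer (i.e. reverse-complemented
#'   beforehand for minus-strand sites).
#' @param max_mismatches Mismatch budget.
#' @param three_prime_protected Protected 3'-terminal positions.
#' @return Integer mismatch count, or `NA_integer_` for no match.
#' @examples
#' match_primer("ACRT", "ACGT", 0, 0)   # 0: R covers G
#' match_primer("ACGT", "ACGA", 1, 1)   # NA: mismatch in protected 3' base
#' @export
match_primer <- function(primer, window, max_mismatches = 2L,
                         three_prime_protected = 3L) {
  pm <- .iupac_masks(primer, "primer")
  wm <- .iupac_masks(window, "window")
  if (length(pm) != length(wm))
    stop("window length (", length(wm), ") != primer length (", length(pm), ")")
  mis <- bitwAnd(pm, wm) == 0L
  n <- sum(mis)
  if (n > max_mismatches) return(NA_integer_)
  if (three_prime_protected > 0L) {
    prot <- seq.int(length(pm) - min(three_prime_protected, length(pm)) + 1L,
                    length(pm))
    if (any(mis[prot])) return(NA_integer_)
  }
  as.integer(n)
}

# Vectorized IUPAC-aware Hamming distance of one primer against many
# equal-length strings. Used by read trimming; no 3'-protection rule here.
.hamming_iupac <- function(primer, strings) {
  pm <- .iupac_masks(primer, "primer")
  n <- length(strings)
  if (n == 0L) return(integer(0))
  mm <- integer(n)
  up <- toupper(strings)
  for (i in seq_along(pm)) {
    ch <- substr(up, i, i)
    wm <- .IUPAC_MASK[ch]
    wm[is.na(wm)] <- 0L # non-nucleotide never matches
    mm <- mm + as.integer(bitwAnd(pm[i], wm) == 0L)
  }
  mm
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
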