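# Internal sequence-alphabet helpers. The package's single internal alphabet
# is uppercase DNA (ACGTN); RNA input (U) is folded to T on the way in and
# sRNA sequences are printed back in RNA for reports.

.DNA_BASES <- c("A", "C", "G", "T")

#' Fold a nucleotide string to the canonical internal alphabet
#'
#' Uppercases and converts U to T. Any character outside ACGTN raises an
#' error naming the offending sequence.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector in uppercase DNA alphabet.
#' @keywords internal
fold_dna <- function(x) {
  out <- chartr("u", "T", toupper(x))
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    stop("sequence contains characters outside ACGTUN: ",
         substr(out[which(bad)[1L]], 1L, 40L))
  }
  out
}

#' Convert internal DNA strings to RNA for reporting
#' @param x character vector in DNA alphabet.
#' @return character vector with T replaced by U.
#' @keywords internal
dna_to_rna <- function(x) chartr("T", "U", x)

#' Reverse complement of DNA strings
#' @param x character vector in DNA alphabet (ACGTN).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (sum(nchar(x)) < 2000L) {
    # cheap pure-R path for short queries; avoids XStringSet overhead
    return(vapply(x, function(s) {
      paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
            collapse = "")
    }, character(1), USE.NAMES = FALSE))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# complement of single bases, vectorised
comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# uniform random DNA string(s); uses the current RNG stream
random_dna <- function(n_bases, n = 1L) {
  vapply(seq_len(n), function(i) {
    paste(sample(.DNA_BASES, n_bases, replace = TRUE), collapse = "")
  }, character(1))
}

# save/restore the global RNG state so seeded operations do not disturb the
# caller's RNG stream
save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  }
  invisible(NULL)
}
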