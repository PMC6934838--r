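## Sequence containers and FASTA I/O.
##
## Sequences live in Biostrings DNAStringSet objects restricted to the
## alphabet {A,C,G,T,N}. All coordinates inside the package are 0-based,
## half-open; writers convert to the 1-based closed convention of GFF3.

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Read a nucleotide FASTA file
#'
#' Reads a FASTA file into a [Biostrings::DNAStringSet], uppercasing
#' residues and restricting the alphabet to A, C, G, T, N. Record ids are
#' the first whitespace-delimited token of each header. Structural problems
#' (missing header, empty record, invalid character) raise an error naming
#' the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one entry per record, input order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("FASTA parse error: file is empty: ", path)
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("FASTA parse error at line ", nonempty[1],
         ": expected a '>' header before sequence data")
  }
  headers <- which(startsWith(trimws(lines), ">"))
  ## every header must be followed by at least one sequence line before the
  ## next header / end of file
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    body <- lines[seq.int(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    if (bounds[i + 1L] - bounds[i] <= 1L || length(body) == 0L) {
      stop("FASTA parse error at line ", headers[i],
           ": record has an empty sequence")
    }
    bad <- grepl("[^ACGTNacgtn]", body)
    if (any(bad)) {
      off <- headers[i] + which(bad)[1]
      stop("FASTA parse error at line ", off,
           ": character outside alphabet {A,C,G,T,N}")
    }
  }
  x <- Biostrings::readDNAStringSet(path)
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#'
#' @param x A named `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @param width Line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  x <- as_dna_set(x)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Watson-Crick reverse complement; `N` maps to `N`.
#'
#' @param x A `DNAString`, `DNAStringSet` or character vector.
#' @return Same container type as the input (character in, character out).
#' @export
reverse_complement <- function(x) {
  if (is.character(x)) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  } else {
    Biostrings::reverseComplement(x)
  }
}

## ---- internal helpers -------------------------------------------------

as_dna <- function(x) {
  if (is(x, "DNAString")) return(x)
  if (is(x, "DNAStringSet")) {
    stopifnot(length(x) == 1L)
    return(x[[1L]])
  }
  stopifnot(is.character(x), length(x) == 1L)
  check_alphabet(x)
  Biostrings::DNAString(toupper(x))
}

as_dna_set <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  stopifnot(is.character(x))
  check_alphabet(x)
  Biostrings::DNAStringSet(toupper(x))
}

check_alphabet <- function(x) {
  bad <- grepl("[^ACGTNacgtn]", x)
  if (any(bad)) {
    stop("sequence contains characters outside alphabet {A,C,G,T,N}")
  }
  invisible(TRUE)
}

dna_chars <- function(x) strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1]]

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
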