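#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement matchPattern BString PhredQuality
#' @importFrom stats cor dhyper fisher.test p.adjust rpois setNames runif
#' @importFrom utils write.table read.table head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of a DNA sequence
#'
#' Vectorised over character input; alphabet `A/C/G/T/N` (case preserved as
#' upper case).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(toupper(x))))
}

rna_to_dna <- function(x) chartr("Uu", "Tt", x)
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

## split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

## deterministic uniform random DNA of length n (uses the current RNG stream)
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of upper-case DNA sequences.
#' @export
read_fasta <- function(path) {
  ss <- readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeXStringSet(DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file (Phred+33).
#' @return tibble with columns `id`, `sequence`, `quality` (quality as the
#'   raw Phred+33 string).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  }
  n <- length(lines) / 4
  if (n == 0) {
    return(tibble(id = character(), sequence = character(),
                  quality = character()))
  }
  idx <- seq_len(n)
  tibble(
    id = sub("^@", "", lines[4 * idx - 3]),
    sequence = toupper(lines[4 * idx - 2]),
    quality = lines[4 * idx]
  )
}

#' Write a read tibble to FASTQ (Phred+33)
#'
#' @param reads tibble with `id`, `sequence`, `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- character(4 * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$sequence
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

## mean Phred score of a quality string (Phred+33)
mean_phred <- function(quality) {
  vapply(quality, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

## write a tibble as TSV
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, check.names = FALSE))
}
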