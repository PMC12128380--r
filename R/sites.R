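#' Scan a sequence for restriction-enzyme recognition sites
#'
#' Finds every (possibly overlapping) exact occurrence of a recognition
#' motif — e.g. HaeIII's `GGCC` — in a nucleotide sequence, case
#' insensitively. `N` in the sequence never matches a motif letter, so
#' ambiguous positions cannot create spurious sites. Matching is done with
#' [Biostrings::matchPattern()].
#'
#' @param sequence A single nucleotide string over `A/C/G/T/N` (any case),
#'   or a `Biostrings::DNAString`.
#' @param motif Non-empty recognition motif over `A/C/G/T`.
#' @return Integer vector of 0-based start offsets of each match (the
#'   convention of most motif-scanning tools; add 1 for R-style positions).
#' @export
#' @examples
#' find_recognition_sites("AGGCCT", "GGCC")    # 1
#' find_recognition_sites("GGCCGGCC", "GGCC")  # 0 4
find_recognition_sites <- function(sequence, motif = "GGCC") {
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string", call. = FALSE)
  if (length(motif) != 1L || !nzchar(motif))
    stop("motif must be a single non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  if (grepl("[^ACGT]", motif))
    stop("motif contains characters outside {A,C,G,T}", call. = FALSE)
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence),
                                   fixed = TRUE)
  as.integer(Biostrings::start(hits)) - 1L
}

#' Scan FASTA sequences for recognition sites
#'
#' Applies [find_recognition_sites()] to every record of a FASTA file.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @param motif Recognition motif, as in [find_recognition_sites()].
#' @return A named list of 0-based offset vectors, one per FASTA record.
#' @export
find_recognition_sites_fasta <- function(path, motif = "GGCC") {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i)
    find_recognition_sites(as.character(seqs[[i]]), motif))
  names(out) <- names(seqs)
  out
}
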