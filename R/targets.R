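## Encoders for non-drug interaction partners: k-mer vectors for miRNA
## sequences and a pluggable protein embedding (transformer language
## model as an optional plug-in; deterministic composition fallback).

.aaAlphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' k-mer frequency encoding of an RNA (or DNA) sequence
#'
#' Counts all overlapping length-k windows over the U-to-T mapped
#' alphabet \{A, C, G, T\}; the vector has length 4^k with lexicographic
#' k-mer order. With \code{normalize} the counts become frequencies
#' summing to one.
#'
#' @param seq character sequence over A/C/G/U (T tolerated).
#' @param k window length (1 <= k <= nchar(seq)).
#' @param normalize return frequencies instead of counts.
#' @return named numeric vector of length 4^k with attribute "k".
#' @export
kmerEncode <- function(seq, k = 3L, normalize = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(gsub("\\s", "", seq))
  seq <- chartr("U", "T", seq)
  if (grepl("[^ACGT]", seq))
    stopMv("AlphabetError", "invalid character(s) in sequence: %s",
           paste(unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]]),
                 collapse = ", "))
  if (k < 1 || k > nchar(seq))
    stopMv("LengthError", "k = %d out of range for sequence of length %d",
           k, nchar(seq))
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  v <- as.numeric(counts)
  names(v) <- names(counts)
  if (normalize && sum(v) > 0) v <- v / sum(v)
  structure(v, k = as.integer(k))
}

## registry for an optional external protein language-model backend
.proteinBackends <- new.env(parent = emptyenv())

#' Register a protein embedding backend
#'
#' Plugs an external embedding function (e.g. a transformer protein
#' language model producing mean-pooled residue embeddings) into
#' \code{\link{proteinEncode}} under the name "esm2_plugin".
#'
#' @param name backend name.
#' @param fun function(seq) -> numeric vector, fixed dimension.
#' @export
registerProteinBackend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .proteinBackends)
  invisible(name)
}

#' Protein sequence embedding
#'
#' The default \code{fallback_kmer_composition} backend is deterministic
#' and dependency-free: amino-acid composition (20 dims) concatenated
#' with 2-mer frequencies (400 dims), total 420 for every sequence.
#' \code{esm2_plugin} delegates to a registered external language-model
#' backend (see \code{\link{registerProteinBackend}}) and fails with
#' instructions if none is installed. X residues are tolerated and
#' dropped into a neutral bin (excluded from composition counts).
#'
#' @param seq amino-acid sequence (20-letter alphabet; X tolerated).
#' @param backend "fallback_kmer_composition" or "esm2_plugin".
#' @return numeric embedding vector with attribute "backend".
#' @export
proteinEncode <- function(seq,
                          backend = c("fallback_kmer_composition",
                                      "esm2_plugin")) {
  backend <- match.arg(backend)
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(gsub("\\s", "", seq))
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c(.aaAlphabet, "X"))
  if (length(bad))
    stopMv("AlphabetError", "invalid residue(s): %s",
           paste(bad, collapse = ", "))
  if (backend == "esm2_plugin") {
    fun <- if (exists("esm2_plugin", envir = .proteinBackends))
      get("esm2_plugin", envir = .proteinBackends) else NULL
    if (is.null(fun))
      stopMv("BackendUnavailableError", paste(
        "no esm2 backend registered; install an external protein",
        "language model and register it with",
        'registerProteinBackend("esm2_plugin", fun), or use the',
        "fallback_kmer_composition backend"))
    return(structure(as.numeric(fun(seq)), backend = backend))
  }
  chars <- strsplit(gsub("X", "", seq), "")[[1]]
  comp <- setNames(numeric(20), .aaAlphabet)
  if (length(chars)) {
    tab <- table(chars)
    comp[names(tab)] <- as.numeric(tab) / length(chars)
  }
  dimers <- as.vector(outer(.aaAlphabet, .aaAlphabet, paste0))
  dimerFreq <- setNames(numeric(400), sort(dimers))
  if (length(chars) >= 2) {
    w <- paste0(chars[-length(chars)], chars[-1])
    tw <- table(w)
    dimerFreq[names(tw)] <- as.numeric(tw) / length(w)
  }
  structure(c(comp, dimerFreq), backend = backend)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (RNA, DNA or protein).
#' @return named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Encode a set of miRNA sequences as a k-mer feature matrix
#'
#' @param seqs named character vector (e.g. from
#'   \code{\link{readFastaSequences}}).
#' @param k k-mer length.
#' @param normalize frequencies instead of counts.
#' @return matrix (sequences x 4^k) with sequence ids as rownames.
#' @export
kmerEncodeSet <- function(seqs, k = 3L, normalize = TRUE) {
  m <- t(vapply(seqs, function(s) as.numeric(kmerEncode(s, k, normalize)),
                numeric(4^k)))
  rownames(m) <- names(seqs)
  colnames(m) <- names(kmerEncode(paste(rep("ACGT", k), collapse = ""),
                                  k, FALSE))
  m
}
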