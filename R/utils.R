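# Internal helpers shared across modules.

ck_msg <- function(...) {
  if (isTRUE(getOption("cobakit.verbose", TRUE))) message("[cobakit] ", ...)
}

# IUPAC nucleotide and amino-acid alphabets (gap characters excluded).
.NT_ALPHABET <- strsplit("ACGTUNRYSWKMBDHV", "")[[1]]
.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYBZJXUO*", "")[[1]]

check_alphabet <- function(seqs, alphabet, what) {
  bad <- vapply(seqs, function(s) {
    chars <- unique(strsplit(s, "")[[1]])
    any(!chars %in% alphabet)
  }, logical(1))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the allowed alphabet: %s",
                 what, paste(names(seqs)[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Reverse complement that tolerates IUPAC ambiguity codes.
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
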